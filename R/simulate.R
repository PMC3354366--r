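#' Pedigree simulation plan
#'
#' @param founders number of founder animals (generation 0).
#' @param generations number of descendant generations.
#' @param matings matings per generation.
#' @param offspring offspring per mating.
#' @export
pedigree_plan <- function(founders, generations, matings, offspring) {
  stopifnot(founders >= 1, generations >= 0, matings >= 0, offspring >= 1)
  structure(list(founders = founders, generations = generations,
                 matings = matings, offspring = offspring),
            class = "gensem_pedigree_plan")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are assigned alternating sexes; each later generation is
#' produced by random mating (sire and dam drawn from the previous
#' generation, so selfing is impossible by construction). Deterministic
#' given the seed.
#'
#' @param plan a [pedigree_plan()].
#' @param seed integer RNG seed (optional; uses the current RNG state if
#'   `NULL`).
#' @return a `gensem_pedigree`.
#' @export
simulate_pedigree <- function(plan, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (plan$generations > 0 && plan$matings > 0 && plan$founders < 2)
    stop("infeasible plan: matings require at least 2 founders (no selfing)")
  id <- function(g, k) sprintf("G%d_%03d", g, k)
  animal <- id(0L, seq_len(plan$founders))
  sire <- rep(NA_character_, plan$founders)
  dam <- rep(NA_character_, plan$founders)
  sex <- rep_len(c("M", "F"), plan$founders)
  prev <- data.frame(animal = animal, sex = sex, stringsAsFactors = FALSE)
  if (plan$generations > 0 && plan$matings > 0) {
    if (!all(c("M", "F") %in% prev$sex))
      stop("infeasible plan: founders must include both sexes")
    for (g in seq_len(plan$generations)) {
      males <- prev$animal[prev$sex == "M"]
      females <- prev$animal[prev$sex == "F"]
      ns <- sample(males, plan$matings, replace = TRUE)
      nd <- sample(females, plan$matings, replace = TRUE)
      kids <- id(g, seq_len(plan$matings * plan$offspring))
      animal <- c(animal, kids)
      sire <- c(sire, rep(ns, each = plan$offspring))
      dam <- c(dam, rep(nd, each = plan$offspring))
      ksex <- sample(rep_len(c("M", "F"), length(kids)))
      prev <- data.frame(animal = kids, sex = ksex, stringsAsFactors = FALSE)
    }
  }
  validate_and_sort(data.frame(animal, sire, dam, stringsAsFactors = FALSE))
}

#' Simulate additive genetic effects with covariance G0 (x) A
#'
#' Sequential Mendelian sampling along the sorted pedigree: founders draw
#' `N(0, G0)`; a non-founder takes the mean of its known parents' values
#' plus a Mendelian-sampling deviation `N(0, d_i * G0)` with
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one known), `1` (founder). This is exactly a draw
#' from `N(0, G0 (x) A)`.
#'
#' @param ped a `gensem_pedigree`.
#' @param g0 t x t symmetric PSD genetic covariance (singular allowed).
#' @param seed optional integer seed.
#' @param f optional precomputed inbreeding coefficients.
#' @return q x t matrix of genetic values, rownames = animal IDs.
#' @export
simulate_genetic_effects <- function(ped, g0, seed = NULL, f = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g0 <- as.matrix(g0)
  t <- nrow(g0)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  # PSD square root (g0 may be singular)
  eg <- eigen(g0, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  M <- eg$vectors %*% (sqrt(ev) * t(eg$vectors))
  idx <- stats::setNames(seq_len(n), ped$animal)
  u <- matrix(0, n, t, dimnames = list(ped$animal, colnames(g0)))
  z <- matrix(stats::rnorm(n * t), n, t)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    mu <- numeric(t); di <- 1
    if (!is.na(s) && !is.na(d)) {
      mu <- 0.5 * (u[idx[s], ] + u[idx[d], ])
      di <- 0.5 - 0.25 * (f[idx[s]] + f[idx[d]])
    } else if (!is.na(s)) {
      mu <- 0.5 * u[idx[s], ]; di <- 0.75 - 0.25 * f[idx[s]]
    } else if (!is.na(d)) {
      mu <- 0.5 * u[idx[d], ]; di <- 0.75 - 0.25 * f[idx[d]]
    }
    u[i, ] <- mu + sqrt(di) * as.numeric(M %*% z[i, ])
  }
  u
}

#' Simulation scenario
#'
#' Bundles everything needed to generate a pedigreed multi-trait dataset
#' under a known recursive causal structure: the pedigree plan, the true
#' structure and structural coefficients, season effects, and the SEM-scale
#' dispersion matrices.
#'
#' @param traits trait labels (causal order).
#' @param structure a `causal_structure` over `traits`.
#' @param lambda_values named numeric vector of structural coefficients
#'   (`"from->to"` names), one per edge of `structure`.
#' @param g0 t x t genetic covariance (SEM scale).
#' @param psi0 length-t positive residual variances (SEM scale).
#' @param beta `n_seasons` x t matrix of fixed season effects on the SEM
#'   scale (including any trait baseline).
#' @param plan a [pedigree_plan()].
#' @param n_phenotyped number of phenotyped animals (the most recent
#'   animals in the pedigree).
#' @export
simulation_scenario <- function(traits, structure, lambda_values, g0, psi0,
                                beta, plan, n_phenotyped) {
  g0 <- as.matrix(g0); beta <- as.matrix(beta)
  t <- length(traits)
  stopifnot(identical(structure$traits, traits),
            nrow(g0) == t, length(psi0) == t, ncol(beta) == t,
            all(psi0 > 0), isTRUE(all.equal(g0, t(g0), tolerance = 1e-8)))
  if (min(eigen(g0, symmetric = TRUE, only.values = TRUE)$values) < -1e-8 * max(diag(g0)))
    stop("g0 must be positive semi-definite")
  lambda <- lambda_matrix(structure, lambda_values)
  structure(list(traits = traits, structure = structure, lambda = lambda,
                 g0 = g0, psi0 = as.numeric(psi0), beta = beta,
                 n_seasons = nrow(beta), plan = plan,
                 n_phenotyped = n_phenotyped),
            class = "gensem_scenario")
}

#' Named scenario presets
#'
#' * `"paper_model_C"` — five quail traits (bw, w35, afe, aew, ne), six
#'   hatch seasons, causal graph `bw->aew`, `w35->afe->ne` with structural
#'   coefficients (-0.408, -0.052, -0.113), and the published Model-C
#'   dispersion estimates as generating values.
#' * `"null_no_causal"` — same dispersions, empty causal structure.
#' * `"fully_recursive_demo"` — all 10 lower-triangular coefficients free,
#'   scaled to give moderate effects across the very different trait units.
#'
#' @param name preset name.
#' @return a `gensem_scenario`.
#' @export
scenario_presets <- function(name) {
  presets <- c("paper_model_C", "null_no_causal", "fully_recursive_demo")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  traits <- c("bw", "w35", "afe", "aew", "ne")
  t <- length(traits)
  # Model-C generating dispersions (SEM scale)
  gsd <- sqrt(c(0.45, 185.36, 14.09, 0.89, 5.19))
  gcor <- diag(t)
  gcor[lower.tri(gcor)] <- c(0.45, 0.21, 0.80, 0.07,   # with bw
                             0.21, 0.58, 0.19,          # with w35
                             0.16, 0.09,                # with afe
                             0.05)                      # with aew
  gcor <- gcor + t(gcor) - diag(t)
  g0 <- outer(gsd, gsd) * gcor
  dimnames(g0) <- list(traits, traits)
  psi0 <- c(0.33, 195.78, 34.65, 0.68, 30.62)
  means <- c(10.06, 262.30, 53.32, 13.58, 29.98)
  n_seasons <- 6

  st <- switch(name,
    paper_model_C = causal_structure(traits, c("bw->aew", "w35->afe", "afe->ne")),
    null_no_causal = causal_structure(traits),
    fully_recursive_demo = fully_recursive_structure(traits))
  lv <- switch(name,
    paper_model_C = c("bw->aew" = -0.408, "w35->afe" = -0.052,
                      "afe->ne" = -0.113),
    null_no_causal = NULL,
    fully_recursive_demo = {
      sd_all <- sqrt(diag(g0) + psi0)
      ed <- st$edges
      stats::setNames(0.2 * sd_all[match(ed$to, traits)] /
                        sd_all[match(ed$from, traits)] *
                        rep_len(c(1, -1), nrow(ed)),
                      paste0(ed$from, "->", ed$to))
    })
  lambda <- lambda_matrix(st, lv)
  # season effects: evenly spaced within +/- 0.25 phenotypic SD around the
  # trait baseline, mapped to the SEM scale through (I - Lambda)
  sd_ph <- sqrt(diag(reduce_residual_covariance(lambda, psi0) +
                     reduce_genetic_covariance(lambda, g0)))
  offsets <- seq(-0.25, 0.25, length.out = n_seasons)
  beta_reduced <- outer(offsets, sd_ph) + matrix(means, n_seasons, t, byrow = TRUE)
  beta <- beta_reduced %*% t(diag(t) - lambda)
  colnames(beta) <- traits
  # pedigree plan emulating the quail study: 850 phenotyped hens drawn
  # from a 2,000-animal multi-generation pedigree (the study's pedigree
  # was deeper still; 2,000 keeps genetic effects well separated from the
  # phenotypic regressions at tractable cost)
  simulation_scenario(traits, st, lv, g0, psi0, beta,
                      plan = pedigree_plan(80, 4, 80, 6),
                      n_phenotyped = 850)
}

#' Simulate phenotypes under a scenario
#'
#' Generates the reduced-model phenotypes
#' `y = (I - Lambda)^-1 (X beta + u + e)` for the `n_phenotyped` most
#' recent animals of the pedigree, with hatch seasons assigned uniformly at
#' random and diagonal-covariance residuals. The full truth (scenario,
#' genetic effects, residuals) is recorded in the returned dataset.
#'
#' @param ped a `gensem_pedigree` compatible with the scenario plan.
#' @param scenario a `gensem_scenario`.
#' @param seed optional integer seed.
#' @return a `gensem_dataset`: list with `phenotypes` (data frame `animal`,
#'   `season`, one column per trait), `pedigree`, and `truth`
#'   (scenario, `u` q x t, `e` n x t).
#' @export
simulate_phenotypes <- function(ped, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traits <- scenario$traits
  t <- length(traits)
  q <- nrow(ped)
  n <- min(scenario$n_phenotyped, q)
  keep <- ped$animal[(q - n + 1L):q]
  u <- simulate_genetic_effects(ped, scenario$g0)
  season <- sample.int(scenario$n_seasons, n, replace = TRUE)
  e <- matrix(stats::rnorm(n * t), n, t) %*% diag(sqrt(scenario$psi0))
  colnames(e) <- traits
  B <- solve(diag(t) - scenario$lambda)
  y <- (scenario$beta[season, , drop = FALSE] + u[keep, , drop = FALSE] + e) %*% t(B)
  ph <- data.frame(animal = keep, season = season, stringsAsFactors = FALSE)
  ph[traits] <- as.data.frame(y)
  structure(list(phenotypes = ph, pedigree = ped,
                 truth = list(scenario = scenario, u = u, e = e)),
            class = "gensem_dataset")
}

#' Simulate a complete dataset from a scenario
#'
#' Convenience wrapper: [simulate_pedigree()] then [simulate_phenotypes()]
#' under one seed.
#'
#' @param scenario a `gensem_scenario` (or preset name).
#' @param seed integer seed.
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  if (is.character(scenario)) scenario <- scenario_presets(scenario)
  if (!is.null(seed)) set.seed(seed)
  ped <- simulate_pedigree(scenario$plan)
  simulate_phenotypes(ped, scenario)
}

#' Write a dataset to delimited files
#'
#' Writes `phenotypes.csv` (animal, season, trait columns),
#' `pedigree.csv` (animal, sire, dam; `0` = unknown) and a `truth.json`
#' sidecar with the scenario parameters.
#'
#' @param dataset a `gensem_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph_path <- file.path(dir, "phenotypes.csv")
  ped_path <- file.path(dir, "pedigree.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(dataset$phenotypes, ph_path, row.names = FALSE)
  ped <- as.data.frame(dataset$pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  utils::write.csv(ped[c("animal", "sire", "dam")], ped_path, row.names = FALSE)
  sc <- dataset$truth$scenario
  truth <- list(
    traits = sc$traits,
    edges = paste(sc$structure$edges$from, "->", sc$structure$edges$to),
    lambda = sc$lambda, g0 = sc$g0, psi0 = sc$psi0, beta = sc$beta,
    n_seasons = sc$n_seasons, n_phenotyped = sc$n_phenotyped,
    plan = unclass(sc$plan))
  jsonlite::write_json(truth, truth_path, digits = NA, pretty = TRUE)
  invisible(c(ph_path, ped_path, truth_path))
}
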