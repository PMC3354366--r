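#' Prior hyperparameters for the SEM Gibbs sampler
#'
#' Inverse-Wishart prior on the genetic covariance
#' (`IW(nu_g, g0_scale)`) and independent scaled inverse-chi-square priors
#' on the residual variances (`Inv-chi2(nu_psi, s2_j)`); season effects and
#' structural coefficients get unbounded uniform priors.
#'
#' @param nu_g genetic prior degrees of freedom (must exceed t - 1).
#' @param g0_scale t x t prior scale matrix.
#' @param nu_psi residual prior degrees of freedom.
#' @param s2 length-t vector of residual prior scales.
#' @export
hyperparameters <- function(nu_g, g0_scale, nu_psi, s2) {
  g0_scale <- as.matrix(g0_scale)
  t <- nrow(g0_scale)
  stopifnot(nu_g > t - 1, length(s2) == t, all(s2 > 0), nu_psi > 0,
            all(diag(g0_scale) > 0))
  structure(list(nu_g = nu_g, g0_scale = g0_scale,
                 nu_psi = nu_psi, s2 = as.numeric(s2)),
            class = "gensem_hyperparameters")
}

#' Published hyperparameters for the five quail traits
#'
#' The prior settings used for the quail analysis: `s2 = (0.6, 400, 70,
#' 0.7, 40)` with `nu_psi = 3`; `nu_g = 7` with diagonal genetic prior
#' scale `(0.3, 200, 30, 0.3, 10)`.
#'
#' @param traits trait labels (defaults to the quail trait order).
#' @export
quail_hyperparameters <- function(traits = c("bw", "w35", "afe", "aew", "ne")) {
  stopifnot(length(traits) == 5)
  g0_scale <- diag(c(0.3, 200, 30, 0.3, 10))
  dimnames(g0_scale) <- list(traits, traits)
  hyperparameters(nu_g = 7, g0_scale = g0_scale, nu_psi = 3,
                  s2 = c(0.6, 400, 70, 0.7, 40))
}

default_hyperparameters <- function(y) {
  # weakly informative data-scaled prior for non-quail trait sets
  v <- apply(y, 2, stats::var)
  t <- ncol(y)
  g0_scale <- diag(0.5 * v, nrow = t)
  dimnames(g0_scale) <- list(colnames(y), colnames(y))
  hyperparameters(nu_g = t + 2, g0_scale = g0_scale, nu_psi = 3, s2 = 0.5 * v)
}

#' MCMC settings
#'
#' Defaults follow the published run: a single chain of 300,000 iterations
#' with the first 100,000 discarded as burn-in and no thinning. Tests and
#' examples use much smaller profiles.
#'
#' @param n_iter total iterations.
#' @param burnin burn-in iterations (< `n_iter`).
#' @param thin thinning interval.
#' @param seed integer RNG seed; the chain is deterministic given it.
#' @export
mcmc_settings <- function(n_iter = 300000, burnin = 100000, thin = 1, seed = 1) {
  stopifnot(n_iter > 0, burnin >= 0, burnin < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "gensem_mcmc_settings")
}

dataset_fingerprint <- function(dataset, traits) {
  y <- as.matrix(dataset$phenotypes[, traits, drop = FALSE])
  paste(nrow(y), ncol(y), format(sum(y), digits = 15),
        format(sum(y^2), digits = 15), sep = "/")
}

#' Fit a recursive SEM by Gibbs sampling
#'
#' Fits the mixed-effects structural equation model
#' `y = Lambda y + X beta + u + e`, `u ~ N(0, G0 (x) A)`,
#' `e ~ N(0, Psi0 (x) I)` with `Psi0` diagonal, for a given acyclic causal
#' structure. Each Gibbs cycle draws, in turn, the per-trait location
#' block (season effects plus that trait's structural coefficients), the
#' genetic effects in per-animal blocks over the whole pedigree using the
#' sparse inverse relationship matrix, the genetic covariance from its
#' inverse-Wishart full conditional, and each residual variance from its
#' scaled inverse-chi-square full conditional. The per-draw conditional
#' deviance is recorded for DIC computation.
#'
#' @param dataset a `gensem_dataset` (phenotypes + pedigree); see
#'   [simulate_phenotypes()] or [read_phenotypes()].
#' @param structure a `causal_structure` over the phenotype trait columns.
#' @param hyper a [hyperparameters()] object (default: weakly informative,
#'   scaled to the data).
#' @param settings an [mcmc_settings()] object.
#' @param init optional warm-start state: list with `beta` (n_seasons x t),
#'   `lambda` (free entries in chain order), `psi`, `g0`, `u` (q x t).
#'   Default: OLS-based starting values.
#' @return a `gensem_chain`: retained draws of the free Lambda entries,
#'   season effects, residual variances and G0; per-draw deviance; running
#'   posterior mean of the genetic effects.
#' @export
fit_sem <- function(dataset, structure, hyper = NULL,
                    settings = mcmc_settings(), init = NULL) {
  traits <- structure$traits
  ph <- dataset$phenotypes
  miss <- setdiff(traits, names(ph))
  if (length(miss)) stop("phenotype columns missing: ", paste(miss, collapse = ", "))
  y <- as.matrix(ph[, traits, drop = FALSE])
  if (anyNA(y)) stop("missing phenotype values are not supported")
  n <- nrow(y); t <- length(traits)
  season_f <- factor(ph$season)
  if (any(table(season_f) == 0L))
    stop("empty hatch-season class: fixed effects not estimable")
  season <- as.integer(season_f) - 1L
  p <- nlevels(season_f)

  ped <- dataset$pedigree
  anim <- match(as.character(ph$animal), ped$animal)
  if (anyNA(anim))
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(utils::head(ph$animal[is.na(anim)], 3), collapse = ", "))
  q <- nrow(ped)
  row_of <- rep(-1L, q)
  row_of[anim] <- seq_len(n) - 1L

  if (is.null(hyper)) hyper <- default_hyperparameters(y)
  stopifnot(nrow(hyper$g0_scale) == t)
  parents <- lapply(traits, function(tr)
    match(structure_parents(structure, tr), traits) - 1L)

  Ainv <- a_inverse(ped)
  g0_init <- 0.5 * stats::cov(y) + diag(1e-6 * apply(y, 2, stats::var), t)

  set.seed(settings$seed)
  raw <- gibbs_sem_cpp(y, season, p, anim - 1L, row_of,
                       methods::as(Ainv, "CsparseMatrix"), parents,
                       hyper$g0_scale, hyper$nu_g, hyper$s2, hyper$nu_psi,
                       g0_init, settings$n_iter, settings$burnin,
                       settings$thin, init)

  lam_names <- unlist(lapply(traits, function(tr) {
    pa <- structure_parents(structure, tr)
    if (length(pa)) paste0("lambda:", pa, "->", tr) else character(0)
  }))
  colnames(raw$lambda) <- lam_names
  colnames(raw$beta) <- as.vector(vapply(traits, function(tr)
    paste0("beta:", tr, ":s", levels(season_f)), character(p)))
  colnames(raw$psi) <- paste0("psi:", traits)
  colnames(raw$g0) <- paste0("g0:", rep(traits, each = t), ":", rep(traits, t))
  rownames(raw$u_mean) <- ped$animal
  colnames(raw$u_mean) <- traits

  out <- list(
    draws = list(lambda = raw$lambda, beta = raw$beta, psi = raw$psi,
                 g0 = raw$g0),
    deviance = as.numeric(raw$deviance),
    u_mean = raw$u_mean,
    structure = structure, traits = traits,
    season_levels = levels(season_f),
    settings = settings, hyper = hyper,
    n = n, q = q,
    dataset_id = dataset_fingerprint(dataset, traits))
  class(out) <- "gensem_chain"
  out
}

#' @export
print.gensem_chain <- function(x, ...) {
  cat("gensem_chain:", nrow(x$draws$psi), "retained draws,",
      length(x$traits), "traits,", x$n, "records,", x$q, "pedigree animals\n")
  cat("structure:", if (nrow(x$structure$edges))
    paste(format_structure(x$structure), collapse = ", ") else "(no edges)", "\n")
  invisible(x)
}

#' Fit the fully recursive SEM
#'
#' Fits [fit_sem()] with every entry below the diagonal of Lambda free
#' under the declared trait order, and additionally stores, for every
#' retained draw, the reduced-scale residual covariance
#' `R0* = (I - Lambda)^-1 Psi0 (I - Lambda)^-T`. By likelihood
#' equivalence this fit plays the role of the multiple-trait animal model,
#' and the `R0*` draws are the posterior samples used by the causal
#' structure search.
#'
#' @inheritParams fit_sem
#' @param traits trait order (defaults to the scenario traits if the
#'   dataset carries one, else the phenotype columns after animal/season).
#' @return a `gensem_chain` with an extra `r0_star` draw block.
#' @export
fit_fully_recursive <- function(dataset, traits = NULL, hyper = NULL,
                                settings = mcmc_settings()) {
  if (is.null(traits)) {
    traits <- if (!is.null(dataset$truth$scenario))
      dataset$truth$scenario$traits
    else setdiff(names(dataset$phenotypes), c("animal", "season"))
  }
  st <- fully_recursive_structure(traits)
  chain <- fit_sem(dataset, st, hyper = hyper, settings = settings)
  chain$r0_star <- r0_star_draws(chain)
  chain
}

chain_lambda <- function(chain, draw_values) {
  v <- draw_values
  names(v) <- sub("^lambda:", "", names(v))
  lambda_matrix(chain$structure, v)
}

#' Reduced-scale residual covariance draws from a chain
#'
#' @param chain a `gensem_chain`.
#' @return m x (t*t) matrix, one vectorized `R0*` per retained draw.
#' @export
r0_star_draws <- function(chain) {
  t <- length(chain$traits)
  m <- nrow(chain$draws$psi)
  out <- matrix(NA_real_, m, t * t,
                dimnames = list(NULL, paste0("r0star:",
                                             rep(chain$traits, each = t), ":",
                                             rep(chain$traits, t))))
  for (s in seq_len(m)) {
    L <- chain_lambda(chain, chain$draws$lambda[s, ])
    out[s, ] <- as.vector(reduce_residual_covariance(L, chain$draws$psi[s, ]))
  }
  out
}

all_draws <- function(chain) {
  blocks <- chain$draws
  if (!is.null(chain$r0_star)) blocks <- c(blocks, list(r0_star = chain$r0_star))
  do.call(cbind, unname(blocks))
}

#' Posterior summaries from a chain
#'
#' Posterior mean, standard deviation and highest-posterior-density
#' interval for selected parameters.
#'
#' @param chain a `gensem_chain`.
#' @param selector regular expression matched against parameter names
#'   (e.g. `"^lambda"`, `"^psi"`, `"r0star"`); `NULL` selects everything.
#' @param content HPD probability content in (0, 1).
#' @return data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `content`.
#' @export
posterior_summary <- function(chain, selector = NULL, content = 0.95) {
  m <- all_draws(chain)
  keep <- if (is.null(selector)) colnames(m)
          else grep(selector, colnames(m), value = TRUE)
  if (!length(keep)) stop("selector matches no parameters")
  res <- lapply(keep, function(nm) {
    x <- m[, nm]
    h <- hpd_interval(x, content)
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               lower = h[1], upper = h[2], content = content,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
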