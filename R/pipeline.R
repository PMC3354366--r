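#' Read a phenotype table
#'
#' Delimited text (comma or tab, sniffed) with a header line: an animal
#' column, a season column and one column per trait. Missing values are
#' not allowed and raise an error naming the offending cell.
#'
#' @param path file path.
#' @param traits trait column names expected in the file.
#' @return data frame with columns `animal`, `season`, then the traits.
#' @export
read_phenotypes <- function(path, traits) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("animal", "season", tolower(traits))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  names(df) <- c("animal", "season", traits)
  for (cn in names(df)) {
    bad <- which(is.na(df[[cn]]) | df[[cn]] == "")
    if (length(bad))
      stop("missing value in phenotype file at row ", bad[1L],
           ", column '", cn, "'")
  }
  df$animal <- as.character(df$animal)
  df$season <- match(df$season, sort(unique(df$season)))  # contiguous codes
  df
}

#' Assemble a dataset from phenotype and pedigree files
#'
#' @param phenotypes path to the phenotype file ([read_phenotypes()]).
#' @param pedigree path to the pedigree file ([read_pedigree()]).
#' @param traits trait column names.
#' @return a `gensem_dataset` (without a truth record).
#' @export
read_dataset <- function(phenotypes, pedigree, traits) {
  ph <- read_phenotypes(phenotypes, traits)
  ped <- read_pedigree(pedigree)
  unknown <- setdiff(ph$animal, ped$animal)
  if (length(unknown))
    stop("phenotyped animal(s) not in pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  out <- list(phenotypes = ph, pedigree = ped, truth = NULL)
  class(out) <- "gensem_dataset"
  out
}

#' Default temporal order of the quail traits
#'
#' Hatch weight first, then 35-day weight, then age at first egg; egg
#' weight and egg number are recorded over the same laying window and are
#' therefore tied (never auto-oriented between each other).
#' @export
quail_time_order <- function() {
  c(bw = 1, w35 = 2, afe = 3, aew = 4, ne = 4)
}

#' Pipeline configuration
#'
#' @param preset scenario preset name ([scenario_presets()]) or a
#'   `gensem_scenario` for simulated input, or `NULL` when reading files.
#' @param phenotypes,pedigree input file paths (used when `preset` is
#'   `NULL`).
#' @param traits trait order (causal order for the fully recursive fit).
#' @param hyper [hyperparameters()]; default: published quail priors for
#'   the quail trait set, else data-scaled.
#' @param settings [mcmc_settings()].
#' @param contents HPD probability contents for the search.
#' @param time_order named time ranks for temporal orienting (`NULL`
#'   disables the override).
#' @param seed master seed for simulation and sampling.
#' @export
pipeline_config <- function(preset = NULL, phenotypes = NULL, pedigree = NULL,
                            traits = c("bw", "w35", "afe", "aew", "ne"),
                            hyper = NULL, settings = mcmc_settings(),
                            contents = c(0.70, 0.75, 0.80, 0.85, 0.90, 0.95),
                            time_order = quail_time_order(), seed = 1) {
  stopifnot(all(contents > 0 & contents < 1))
  if (is.null(preset) && (is.null(phenotypes) || is.null(pedigree)))
    stop("either a preset or phenotype + pedigree paths are required")
  structure(list(preset = preset, phenotypes = phenotypes,
                 pedigree = pedigree, traits = traits, hyper = hyper,
                 settings = settings, contents = contents,
                 time_order = time_order, seed = as.integer(seed)),
            class = "gensem_pipeline_config")
}

structure_key <- function(st) paste(sort(format_structure(st)), collapse = ";")

#' Run the full causal-search pipeline
#'
#' Executes the three-step procedure end to end: (1) fit the fully
#' recursive SEM (the multiple-trait animal model by likelihood
#' equivalence) and collect posterior draws of the reduced residual
#' covariance R0*; (2) run the IC search on those draws at every requested
#' HPD content and orient the resulting graphs with the temporal order;
#' (3) fit a SEM for every distinct fully oriented structure obtained and
#' compare them, and the MTAM, by DIC. Reduced-scale dispersion summaries
#' (R0*, G0*, heritabilities) are reported for the DIC-preferred model.
#' Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param keep_chains keep full chains in the report (memory-heavy).
#' @return a `gensem_report` list.
#' @export
run_pipeline <- function(config, keep_chains = FALSE) {
  traits <- config$traits
  dataset <- if (!is.null(config$preset)) {
    simulate_dataset(config$preset, seed = config$seed)
  } else {
    read_dataset(config$phenotypes, config$pedigree, traits)
  }
  hyper <- config$hyper
  if (is.null(hyper) && identical(sort(traits),
                                  sort(c("bw", "w35", "afe", "aew", "ne"))))
    hyper <- quail_hyperparameters(traits)

  settings <- config$settings
  settings$seed <- config$seed
  fr <- fit_fully_recursive(dataset, traits, hyper = hyper,
                            settings = settings)

  search <- search_over_contents(fr$r0_star, config$contents, traits)

  oriented <- list()
  skipped <- character(0)
  structures <- list()
  for (nm in names(search$graphs)) {
    g <- search$graphs[[nm]]
    og <- if (is.null(config$time_order)) g
          else temporal_orient(g, config$time_order)
    oriented[[nm]] <- og
    if (nrow(og$undirected) || nrow(og$bidirected) ||
        (!is.null(og$tied_undirected) && nrow(og$tied_undirected))) {
      warning("content ", nm, ": structure not fully oriented; ",
              "SEM fit skipped for it")
      skipped <- c(skipped, nm)
      next
    }
    st <- causal_structure(traits, og$directed)
    key <- structure_key(st)
    structures[[if (nzchar(key)) key else "(empty)"]] <- st
  }

  fits <- list(); dics <- list()
  k <- 0L
  for (key in names(structures)) {
    k <- k + 1L
    s2 <- settings
    s2$seed <- settings$seed + k
    ch <- fit_sem(dataset, structures[[key]], hyper = hyper, settings = s2)
    fits[[key]] <- ch
    dics[[key]] <- dic(ch, dataset, label = if (nzchar(key)) key else "(empty)")
  }
  dics[["MTAM"]] <- dic(fr, dataset, label = "MTAM (fully recursive)")
  dic_table <- if (length(dics) >= 2L) compare_dic(dics) else NULL

  preferred_label <- if (!is.null(dic_table)) dic_table$label[1L] else "MTAM (fully recursive)"
  preferred_chain <- if (preferred_label == "MTAM (fully recursive)") fr
                     else fits[[preferred_label]]
  reduced <- reduced_summaries(preferred_chain)

  out <- list(
    config = config,
    dataset_n = nrow(dataset$phenotypes),
    pedigree_q = nrow(dataset$pedigree),
    search = search,
    oriented = oriented,
    skipped_contents = skipped,
    structures = structures,
    dic_table = dic_table,
    preferred = preferred_label,
    reduced_summary = reduced,
    mtam_summary = posterior_summary(fr, "^(r0star|g0):"),
    decision_log = do.call(rbind, lapply(names(search$graphs), function(nm) {
      lg <- search$graphs[[nm]]$log
      if (is.null(lg)) return(NULL)
      cbind(content = nm, lg)
    })),
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("gensem")),
                      n_iter = settings$n_iter, burnin = settings$burnin,
                      thin = settings$thin))
  if (keep_chains) out$chains <- c(list(MTAM = fr), fits)
  class(out) <- "gensem_report"
  out
}

#' Reduced-scale dispersion summaries from a fitted chain
#'
#' Per retained draw, maps the SEM dispersions to the MTAM scale
#' (`R0* = (I-L)^-1 Psi0 (I-L)^-T`, `G0* = (I-L)^-1 G0 (I-L)^-T`) and
#' computes heritabilities `g*_jj / (g*_jj + r*_jj)`; returns posterior
#' summaries of all three.
#'
#' @param chain a `gensem_chain`.
#' @param content HPD content for the intervals.
#' @return data frame of posterior summaries.
#' @export
reduced_summaries <- function(chain, content = 0.95) {
  traits <- chain$traits
  t <- length(traits)
  m <- nrow(chain$draws$psi)
  r0 <- matrix(NA_real_, m, t * t)
  g0s <- matrix(NA_real_, m, t * t)
  h2 <- matrix(NA_real_, m, t)
  for (s in seq_len(m)) {
    L <- chain_lambda(chain, chain$draws$lambda[s, ])
    G <- matrix(chain$draws$g0[s, ], t, t)
    R <- reduce_residual_covariance(L, chain$draws$psi[s, ])
    Gs <- reduce_genetic_covariance(L, G)
    r0[s, ] <- as.vector(R)
    g0s[s, ] <- as.vector(Gs)
    h2[s, ] <- diag(Gs) / (diag(Gs) + diag(R))
  }
  nm2 <- paste0(rep(traits, each = t), ":", rep(traits, t))
  colnames(r0) <- paste0("r0star:", nm2)
  colnames(g0s) <- paste0("g0star:", nm2)
  colnames(h2) <- paste0("h2:", traits)
  draws <- cbind(r0, g0s, h2)
  out <- do.call(rbind, lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    h <- hpd_interval(x, content)
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               lower = h[1L], upper = h[2L], content = content,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a partial graph
#'
#' @param pg a `gensem_partial_graph`.
#' @param format `"edgelist"` (orientation marks `->`, `-`, `<->`),
#'   `"dot"`, or `"graphml"`.
#' @return character vector of lines.
#' @export
format_partial_graph <- function(pg, format = c("edgelist", "dot", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    return(c(if (nrow(pg$directed)) paste(pg$directed$from, "->", pg$directed$to),
             if (nrow(pg$undirected)) paste(pg$undirected$a, "-", pg$undirected$b),
             if (nrow(pg$bidirected)) paste(pg$bidirected$a, "<->", pg$bidirected$b)))
  }
  if (format == "dot") {
    return(c("digraph partial_graph {",
             paste0("  \"", pg$traits, "\";"),
             if (nrow(pg$directed))
               paste0("  \"", pg$directed$from, "\" -> \"", pg$directed$to, "\";"),
             if (nrow(pg$undirected))
               paste0("  \"", pg$undirected$a, "\" -> \"", pg$undirected$b,
                      "\" [dir=none];"),
             if (nrow(pg$bidirected))
               paste0("  \"", pg$bidirected$a, "\" -> \"", pg$bidirected$b,
                      "\" [dir=both];"),
             "}"))
  }
  edge_xml <- function(a, b, kind)
    paste0("    <edge source=\"", a, "\" target=\"", b,
           "\"><data key=\"kind\">", kind, "</data></edge>")
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"kind\" for=\"edge\" attr.name=\"kind\" attr.type=\"string\"/>",
    "  <graph edgedefault=\"directed\">",
    paste0("    <node id=\"", pg$traits, "\"/>"),
    if (nrow(pg$directed))
      edge_xml(pg$directed$from, pg$directed$to, "directed"),
    if (nrow(pg$undirected))
      edge_xml(pg$undirected$a, pg$undirected$b, "undirected"),
    if (nrow(pg$bidirected))
      edge_xml(pg$bidirected$a, pg$bidirected$b, "conflict"),
    "  </graph>", "</graphml>")
}

#' Write a pipeline report to disk
#'
#' Graphs as DOT, GraphML and edge lists, tables (DIC, reduced summaries,
#' decision log, stability) as CSV, and a JSON summary with config echo
#' and provenance.
#'
#' @param report a `gensem_report` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_report <- function(report, outdir) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  wr <- function(lines, name) writeLines(lines, file.path(outdir, name))
  for (nm in names(report$search$graphs)) {
    g <- report$search$graphs[[nm]]
    og <- report$oriented[[nm]]
    tag <- gsub("[^0-9]", "", nm)
    wr(format_partial_graph(g, "dot"), paste0("ic_graph_", tag, ".dot"))
    wr(format_partial_graph(g, "graphml"), paste0("ic_graph_", tag, ".graphml"))
    wr(format_partial_graph(g, "edgelist"), paste0("ic_graph_", tag, ".edges"))
    wr(format_partial_graph(og, "dot"), paste0("oriented_", tag, ".dot"))
    wr(format_partial_graph(og, "edgelist"), paste0("oriented_", tag, ".edges"))
  }
  utils::write.csv(report$search$stability,
                   file.path(outdir, "edge_stability.csv"), row.names = FALSE)
  if (!is.null(report$dic_table))
    utils::write.csv(report$dic_table, file.path(outdir, "dic.csv"),
                     row.names = FALSE)
  utils::write.csv(report$reduced_summary,
                   file.path(outdir, "reduced_summary.csv"), row.names = FALSE)
  if (!is.null(report$decision_log))
    utils::write.csv(report$decision_log,
                     file.path(outdir, "decision_log.csv"), row.names = FALSE)
  summary <- list(
    preferred = report$preferred,
    contents = report$config$contents,
    skipped_contents = report$skipped_contents,
    structures = lapply(report$structures, format_structure),
    n_phenotyped = report$dataset_n, pedigree_size = report$pedigree_q,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
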