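#' Deviance information criterion for a fitted SEM
#'
#' `DIC = 2 * Dbar - D(theta_bar)`, where `Dbar` is the posterior mean of
#' the per-draw conditional deviance (recorded during sampling) and
#' `D(theta_bar)` is the deviance evaluated at the elementwise posterior
#' means of the structural coefficients, season effects, genetic effects
#' and residual variances. The effective number of parameters is
#' `pD = Dbar - D(theta_bar)`.
#'
#' @param chain a `gensem_chain` from [fit_sem()] or
#'   [fit_fully_recursive()].
#' @param dataset the dataset the chain was fitted to.
#' @param label optional model label for reports.
#' @return a `gensem_dic` list: `Dbar`, `D_at_mean`, `pD`, `DIC`, `label`,
#'   `dataset_id`.
#' @export
dic <- function(chain, dataset, label = NULL) {
  if (is.null(chain$deviance) || !length(chain$deviance))
    stop("chain carries no stored deviances")
  if (is.null(chain$u_mean))
    stop("chain carries no posterior means of the genetic effects")
  own_id <- dataset_fingerprint(dataset, chain$traits)
  if (!identical(own_id, chain$dataset_id))
    stop("dataset does not match the one the chain was fitted to")
  traits <- chain$traits
  t <- length(traits)
  p <- length(chain$season_levels)
  lambda_bar <- chain_lambda(chain, colMeans(chain$draws$lambda))
  beta_bar <- matrix(colMeans(chain$draws$beta), nrow = p, ncol = t,
                     dimnames = list(chain$season_levels, traits))
  params <- list(lambda = lambda_bar, beta = beta_bar,
                 u = chain$u_mean, psi = colMeans(chain$draws$psi),
                 traits = traits)
  # align season codes with the rows of the fitted beta
  ds <- dataset
  ds$phenotypes$season <- match(as.character(dataset$phenotypes$season),
                                chain$season_levels)
  d_at_mean <- deviance_sem(ds, params)
  dbar <- mean(chain$deviance)
  out <- list(Dbar = dbar, D_at_mean = d_at_mean, pD = dbar - d_at_mean,
              DIC = 2 * dbar - d_at_mean,
              label = label %||% paste(format_structure(chain$structure),
                                       collapse = ", "),
              dataset_id = chain$dataset_id)
  class(out) <- "gensem_dic"
  out
}

#' @export
print.gensem_dic <- function(x, ...) {
  cat(sprintf("DIC %.2f (Dbar %.2f, D(mean) %.2f, pD %.1f)  [%s]\n",
              x$DIC, x$Dbar, x$D_at_mean, x$pD, x$label))
  invisible(x)
}

#' Rank models by DIC
#'
#' @param models list of `gensem_dic` results fitted to the same dataset.
#' @param margin practical-equivalence margin: models within `margin` DIC
#'   units of the best are flagged.
#' @return data frame sorted by DIC with columns `label`, `DIC`, `Dbar`,
#'   `pD`, `delta`, `rank`, `within_margin`.
#' @export
compare_dic <- function(models, margin = 2) {
  stopifnot(length(models) >= 2L)
  ids <- vapply(models, function(m) m$dataset_id, "")
  if (length(unique(ids)) != 1L)
    stop("DIC results come from different datasets")
  df <- do.call(rbind, lapply(models, function(m)
    data.frame(label = m$label, DIC = m$DIC, Dbar = m$Dbar, pD = m$pD,
               stringsAsFactors = FALSE)))
  df <- df[order(df$DIC), , drop = FALSE]
  df$delta <- df$DIC - df$DIC[1L]
  df$rank <- rank(df$DIC, ties.method = "min")
  df$within_margin <- df$delta <= margin
  rownames(df) <- NULL
  df
}
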