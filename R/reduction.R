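#' Reduced-scale residual covariance
#'
#' Maps the SEM residual dispersion to the residual covariance of the
#' phenotypes conditional on genetic effects (the multiple-trait animal
#' model scale): `R0* = (I - Lambda)^-1 Psi0 (I - Lambda)^-T`.
#'
#' @param lambda t x t structural coefficient matrix (zero diagonal,
#'   row = affected trait).
#' @param psi0 diagonal residual variances: a positive vector of length t,
#'   or a t x t matrix whose diagonal is used if non-diagonal entries are
#'   zero. A full symmetric matrix is also accepted (used when evaluating
#'   an unstructured-residual model through the same transform).
#' @return symmetric t x t matrix.
#' @export
reduce_residual_covariance <- function(lambda, psi0) {
  B <- solve(diag(nrow(lambda)) - lambda)
  P <- if (is.matrix(psi0)) psi0 else diag(psi0, nrow = length(psi0))
  out <- B %*% P %*% t(B)
  dimnames(out) <- dimnames(lambda)
  (out + t(out)) / 2
}

#' Reduced-scale genetic covariance
#'
#' Genetic effects propagate through the same linear transform as the
#' residuals: `G0* = (I - Lambda)^-1 G0 (I - Lambda)^-T`.
#'
#' @param lambda structural coefficient matrix.
#' @param g0 t x t symmetric genetic covariance on the SEM scale.
#' @return symmetric t x t matrix.
#' @export
reduce_genetic_covariance <- function(lambda, g0) {
  reduce_residual_covariance(lambda, g0)
}

#' Trait heritabilities from reduced-scale dispersions
#'
#' `h_j^2 = g*_jj / (g*_jj + r*_jj)` per trait.
#'
#' @param g0_star reduced genetic covariance (t x t).
#' @param r0_star reduced residual covariance (t x t).
#' @return numeric vector of length t in `[0, 1]`.
#' @export
heritabilities <- function(g0_star, r0_star) {
  g <- diag(as.matrix(g0_star)); r <- diag(as.matrix(r0_star))
  tot <- g + r
  if (any(tot <= 0)) stop("zero or negative total variance for some trait")
  stats::setNames(g / tot, rownames(g0_star))
}

#' Covariance matrix to correlation matrix
#' @param v symmetric covariance matrix.
#' @export
cov_to_cor <- function(v) stats::cov2cor(as.matrix(v))

#' Conditional log-likelihood of a recursive SEM
#'
#' Log density of the phenotypes given structural coefficients, fixed
#' effects, genetic effects and residual variances: a multivariate normal
#' with mean `(I - Lambda)^-1 (X beta + u)` and covariance
#' `(I - Lambda)^-1 Psi0 (I - Lambda)^-T` per animal. Residuals are
#' independent across animals, so the computation works on t x t blocks
#' and never materializes an (nt) x (nt) matrix.
#'
#' @param dataset a `gensem_dataset` (see [simulate_phenotypes()]) or any
#'   list with a `phenotypes` data frame holding `animal`, `season` and the
#'   trait columns.
#' @param params list with elements `lambda` (t x t), `beta`
#'   (n_seasons x t matrix of season effects), `u` (n x t matrix of
#'   genetic effects for the phenotyped animals, rownames = animal IDs, or
#'   a larger matrix covering them), `psi` (length-t vector of residual
#'   variances, or a full t x t residual covariance), and `traits`
#'   (optional; defaults to colnames of `lambda`).
#' @return scalar log-likelihood in nats.
#' @export
conditional_log_likelihood <- function(dataset, params) {
  traits <- params$traits %||% colnames(params$lambda)
  ph <- dataset$phenotypes
  y <- as.matrix(ph[, traits, drop = FALSE])
  n <- nrow(y); t <- length(traits)
  # season codes index beta rows directly (codes are 1..n_seasons)
  season <- if (is.numeric(ph$season)) as.integer(ph$season)
            else as.integer(factor(ph$season))
  beta <- as.matrix(params$beta)
  if (nrow(beta) < max(season)) stop("beta has fewer rows than season levels")
  u <- as.matrix(params$u)
  if (!is.null(rownames(u)) && !is.null(ph$animal)) {
    u <- u[match(as.character(ph$animal), rownames(u)), , drop = FALSE]
    if (anyNA(u)) stop("genetic effects missing for some phenotyped animals")
  }
  B <- solve(diag(t) - params$lambda)
  R <- reduce_residual_covariance(params$lambda, params$psi)
  ch <- tryCatch(chol(R), error = function(e)
    stop("reduced residual covariance is not positive definite"))
  mu <- (beta[season, , drop = FALSE] + u) %*% t(B)
  z <- backsolve(ch, t(y - mu), transpose = TRUE)
  -0.5 * n * t * log(2 * pi) - n * sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Conditional deviance
#'
#' `-2` times the conditional log-likelihood ([conditional_log_likelihood()]).
#'
#' @inheritParams conditional_log_likelihood
#' @return scalar deviance.
#' @export
deviance_sem <- function(dataset, params) {
  -2 * conditional_log_likelihood(dataset, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
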