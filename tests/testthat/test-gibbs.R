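# small fitted chain reused by several blocks
local_chain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulate_dataset(tiny_model_c(), seed = 61)
      cache <<- list(
        dataset = d,
        chain = fit_fully_recursive(d, hyper = quail_hyperparameters(),
                                    settings = mcmc_settings(600, 200, 2,
                                                             seed = 62)))
    }
    cache
  }
})

fake_chain <- function(draws_vec) {
  # minimal chain object for posterior_summary arithmetic checks
  m <- length(draws_vec)
  st <- causal_structure("t1")
  out <- list(draws = list(lambda = matrix(numeric(0), m, 0),
                           beta = matrix(draws_vec, m, 1,
                                         dimnames = list(NULL, "beta:t1:s1")),
                           psi = matrix(1, m, 1,
                                        dimnames = list(NULL, "psi:t1")),
                           g0 = matrix(1, m, 1,
                                       dimnames = list(NULL, "g0:t1:t1"))),
              structure = st, traits = "t1")
  class(out) <- "gensem_chain"
  out
}

test_that("chains are deterministic given the seed and sized by the settings", {
  env <- local_chain()
  ch <- env$chain
  # (600 - 200) / 2 retained draws
  expect_equal(nrow(ch$draws$psi), 200)
  expect_equal(length(ch$deviance), 200)

  ch2 <- fit_fully_recursive(env$dataset, hyper = quail_hyperparameters(),
                             settings = mcmc_settings(600, 200, 2, seed = 62))
  expect_identical(ch$draws, ch2$draws)
  expect_identical(ch$u_mean, ch2$u_mean)

  ch3 <- fit_fully_recursive(env$dataset, hyper = quail_hyperparameters(),
                             settings = mcmc_settings(600, 200, 2, seed = 63))
  expect_false(identical(ch$draws$psi, ch3$draws$psi))
})

test_that("every stored R0* draw is positive definite", {
  ch <- local_chain()$chain
  t <- length(ch$traits)
  mins <- apply(ch$r0_star, 1, function(v)
    min(eigen(matrix(v, t, t), symmetric = TRUE, only.values = TRUE)$values))
  expect_true(all(mins > 0))
  expect_true(all(ch$draws$psi > 0))
})

test_that("a single-trait fully recursive fit reduces to the residual variance", {
  traits <- "t1"
  sc <- simulation_scenario(traits, causal_structure(traits), NULL,
                            g0 = matrix(0.5, 1, 1), psi0 = 1,
                            beta = matrix(c(0, 1), 2, 1),
                            plan = pedigree_plan(40, 1, 20, 2),
                            n_phenotyped = 40)
  d <- simulate_dataset(sc, seed = 64)
  ch <- fit_fully_recursive(d, traits = traits,
                            settings = mcmc_settings(300, 100, 1, seed = 65))
  expect_equal(as.numeric(ch$r0_star), as.numeric(ch$draws$psi))
})

test_that("posterior_summary computes means and HPD intervals", {
  cst <- fake_chain(rep(4.2, 50))
  s <- posterior_summary(cst, "^beta")
  expect_equal(s$mean, 4.2)
  expect_equal(s$upper - s$lower, 0)

  s2 <- posterior_summary(fake_chain(1:100), "^beta")
  expect_equal(s2$mean, 50.5)

  set.seed(66)
  s3 <- posterior_summary(fake_chain(rnorm(2e4)), "^beta", content = 0.95)
  expect_equal(s3$lower, -1.96, tolerance = 0.04)
  expect_equal(s3$upper, 1.96, tolerance = 0.04)

  expect_error(posterior_summary(cst, "^nothing"), "matches no parameter")
})

test_that("with negligible genetics the residual posterior matches the conjugate closed form", {
  # founders only, one season; genetic prior pushed toward zero so the
  # model collapses to independent normal regressions with known
  # normal-inverse-chi-square posteriors
  n <- 150
  traits <- c("t1", "t2")
  ped <- validate_and_sort(data.frame(animal = paste0("f", 1:n),
                                      sire = "0", dam = "0"))
  set.seed(67)
  psi_true <- c(2, 0.5)
  y <- cbind(1.5 + rnorm(n, sd = sqrt(psi_true[1])),
             -0.7 + rnorm(n, sd = sqrt(psi_true[2])))
  ph <- data.frame(animal = ped$animal, season = 1)
  ph[traits] <- as.data.frame(y)
  d <- list(phenotypes = ph, pedigree = ped)
  class(d) <- "gensem_dataset"

  hyp <- hyperparameters(nu_g = 5000, g0_scale = diag(1e-4, 2) * 5000,
                         nu_psi = 3, s2 = c(1, 1))
  ch <- fit_sem(d, causal_structure(traits), hyper = hyp,
                settings = mcmc_settings(3000, 500, 1, seed = 68))
  for (j in 1:2) {
    ssr <- sum((y[, j] - mean(y[, j]))^2)
    df_post <- 3 + n - 1
    mean_closed <- (3 * 1 + ssr) / (df_post - 2)
    mean_gibbs <- mean(ch$draws$psi[, j])
    expect_equal(mean_gibbs, mean_closed, tolerance = 0.06 * mean_closed)
  }
})

test_that("location posteriors concentrate at the per-trait least-squares solution", {
  # no genetic variance in truth and a near-zero genetic prior: the
  # posterior mean of (beta, lambda) approaches OLS of y_j on seasons and
  # parent traits
  traits <- c("a", "b")
  st <- causal_structure(traits, "a->b")
  sc <- simulation_scenario(traits, st, c("a->b" = 0.8),
                            g0 = matrix(0, 2, 2), psi0 = c(1, 1),
                            beta = matrix(c(0, 2, 1, 3), 2, 2),
                            plan = pedigree_plan(250, 0, 0, 1),
                            n_phenotyped = 250)
  d <- simulate_dataset(sc, seed = 69)
  hyp <- hyperparameters(nu_g = 5000, g0_scale = diag(1e-4, 2) * 5000,
                         nu_psi = 3, s2 = c(1, 1))
  ch <- fit_sem(d, st, hyper = hyp,
                settings = mcmc_settings(2000, 500, 1, seed = 70))
  y <- as.matrix(d$phenotypes[, traits])
  ols <- stats::lm(y[, "b"] ~ 0 + factor(d$phenotypes$season) + y[, "a"])
  lam_hat <- unname(rev(coef(ols))[1])
  lam_post <- mean(ch$draws$lambda[, "lambda:a->b"])
  expect_equal(lam_post, lam_hat, tolerance = 0.02)
  expect_equal(lam_post, 0.8, tolerance = 3.5 * sd(ch$draws$lambda[, 1]) + 0.02)
})

test_that("successive-conditional simulation keeps dispersion parameters at their prior", {
  # Geweke-style joint-distribution check at tiny n: alternating
  # data simulation and one Gibbs sweep must leave the prior marginals of
  # psi and diag(G0) invariant (compared here through quantiles on the
  # log scale, where these heavy-tailed priors are well behaved)
  n <- 10
  traits <- c("t1", "t2")
  st <- causal_structure(traits)
  ped <- validate_and_sort(data.frame(animal = paste0("f", 1:n),
                                      sire = "0", dam = "0"))
  hyp <- hyperparameters(nu_g = 6, g0_scale = diag(c(1, 2)), nu_psi = 5,
                         s2 = c(1, 2))
  rinvchisq <- function(k, nu, s2) nu * s2 / stats::rchisq(k, nu)
  riw11 <- function(k, nu, S) {
    vapply(seq_len(k), function(i) {
      W <- stats::rWishart(1, nu, solve(S))[, , 1]
      solve(W)[1, 1]
    }, 0)
  }
  set.seed(71)
  K <- 800
  state <- list(beta = matrix(0, 1, 2),
                lambda = numeric(0),
                psi = rinvchisq(2, 5, c(1, 2)),
                g0 = {
                  W <- stats::rWishart(1, 6, solve(diag(c(1, 2))))[, , 1]
                  solve(W)
                },
                u = matrix(0, n, 2))
  # initial u from its prior given g0
  state$u <- matrix(rnorm(2 * n), n, 2) %*% chol(state$g0)
  psi_chain <- matrix(NA_real_, K, 2)
  g11_chain <- numeric(K)
  for (k in seq_len(K)) {
    e <- matrix(rnorm(2 * n), n, 2) %*% diag(sqrt(state$psi), 2)
    y <- matrix(state$beta, n, 2, byrow = TRUE) + state$u + e
    ph <- data.frame(animal = ped$animal, season = 1)
    ph[traits] <- as.data.frame(y)
    d <- list(phenotypes = ph, pedigree = ped)
    class(d) <- "gensem_dataset"
    ch <- fit_sem(d, st, hyper = hyp,
                  settings = mcmc_settings(1, 0, 1, seed = 7000 + k),
                  init = state)
    state <- list(beta = matrix(ch$draws$beta[1, ], 1, 2),
                  lambda = numeric(0),
                  psi = as.numeric(ch$draws$psi[1, ]),
                  g0 = matrix(ch$draws$g0[1, ], 2, 2),
                  u = ch$u_mean)
    psi_chain[k, ] <- state$psi
    g11_chain[k] <- state$g0[1, 1]
  }
  prior_psi <- rinvchisq(4000, 5, 1)
  prior_g11 <- riw11(2000, 6, diag(c(1, 2)))
  for (qq in c(0.25, 0.5, 0.75)) {
    expect_equal(quantile(log(psi_chain[, 1]), qq),
                 quantile(log(prior_psi), qq), tolerance = 0.25,
                 ignore_attr = TRUE)
    expect_equal(quantile(log(g11_chain), qq),
                 quantile(log(prior_g11), qq), tolerance = 0.35,
                 ignore_attr = TRUE)
  }
})
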