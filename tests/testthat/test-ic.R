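quail <- c("bw", "w35", "afe", "aew", "ne")

# published MTAM residual dispersion (posterior means): SDs + correlations
mtam_r0 <- function() {
  v <- c(0.32, 210.74, 35.19, 0.79, 31.02)
  r <- diag(5)
  r[lower.tri(r)] <- c(0.03, 0.07, -0.24, -0.07,
                       -0.13, 0.12, 0.01, -0.08, -0.12, -0.01)
  r <- r + t(r) - diag(5)
  s <- sqrt(v)
  out <- outer(s, s) * r
  dimnames(out) <- list(quail, quail)
  out
}

test_that("partial correlations match marginal and regression-residual oracles", {
  R <- mtam_r0()
  # empty conditioning set: the marginal residual correlation
  expect_equal(partial_correlation(R, "bw", "aew"), -0.24, tolerance = 1e-12)

  # diagonal covariance: all partial correlations vanish
  D <- diag(c(1, 2, 3, 4, 5))
  expect_equal(partial_correlation(D, 1, 2), 0)
  expect_equal(partial_correlation(D, 2, 5, c(1, 3)), 0)

  # single-element conditioning set vs explicit residual-covariance oracle
  set.seed(51)
  for (rep in 1:20) {
    M <- matrix(rnorm(25), 5)
    S <- crossprod(M) + diag(5) * 0.2
    idx <- sample(5, 3)
    j <- idx[1]; jp <- idx[2]; k <- idx[3]
    num <- S[j, jp] - S[j, k] * S[jp, k] / S[k, k]
    den <- sqrt((S[j, j] - S[j, k]^2 / S[k, k]) *
                (S[jp, jp] - S[jp, k]^2 / S[k, k]))
    expect_equal(partial_correlation(S, j, jp, k), num / den,
                 tolerance = 1e-10)
  }

  expect_error(partial_correlation(diag(3), 1, 2, 2), "exclude")
  expect_error(partial_correlation(matrix(1, 3, 3), 1, 2), "singular")
})

test_that("skeleton search finds separating sets exactly", {
  traits <- c("x", "y", "z")
  chain <- matrix(0L, 3, 3, dimnames = list(traits, traits))
  chain["x", "y"] <- 1L; chain["y", "z"] <- 1L      # x -> y -> z
  pg <- ic_skeleton(dsep_decider(chain), traits)
  expect_equal(pg_signature(pg$directed, pg$undirected), "x-y;y-z")
  expect_equal(pg$sepsets[["x|z"]], "y")

  # always-dependent oracle: complete graph
  alldep <- function(a, b, s) "dependent"
  pg2 <- ic_skeleton(alldep, traits)
  expect_equal(nrow(pg2$undirected), 3)
  # decision log covers every queried subset for every present edge
  expect_equal(nrow(pg2$log), 3 * 2)  # 3 pairs x 2 subsets each
})

test_that("collider discovery orients v-structures and only those", {
  traits <- c("x", "y", "z")
  vstr <- matrix(0L, 3, 3, dimnames = list(traits, traits))
  vstr["x", "z"] <- 1L; vstr["y", "z"] <- 1L        # x -> z <- y
  dec <- dsep_decider(vstr)
  pg <- orient_propagate(ic_colliders(ic_skeleton(dec, traits), dec))
  expect_equal(pg_signature(pg$directed, pg$undirected), "x -> z;y -> z")

  chain <- matrix(0L, 3, 3, dimnames = list(traits, traits))
  chain["x", "y"] <- 1L; chain["y", "z"] <- 1L
  decc <- dsep_decider(chain)
  pgc <- ic_colliders(ic_skeleton(decc, traits), decc)
  expect_equal(nrow(pgc$directed), 0)               # chain: stays undirected
})

test_that("Meek propagation handles the textbook local patterns", {
  # R1: 1 -> 2 - 3 with 1,3 non-adjacent orients 2 -> 3
  pg <- gensem:::new_partial_graph(c("a", "b", "c"))
  pg$directed <- data.frame(from = "a", to = "b", stringsAsFactors = FALSE)
  pg$undirected <- data.frame(a = "b", b = "c", stringsAsFactors = FALSE)
  out <- orient_propagate(pg)
  expect_true(gensem:::pg_directed(out, "b", "c"))

  # undirected triangle: no rule fires
  tri <- gensem:::new_partial_graph(c("a", "b", "c"))
  tri$undirected <- data.frame(a = c("a", "b", "a"), b = c("b", "c", "c"),
                               stringsAsFactors = FALSE)
  out2 <- orient_propagate(tri)
  expect_equal(nrow(out2$directed), 0)
  expect_equal(nrow(out2$undirected), 3)
})

test_that("IC with a d-separation oracle recovers the CPDAG on random DAGs", {
  set.seed(52)
  for (rep in 1:40) {
    amat <- random_dag(5, p_edge = runif(1, 0.2, 0.7))
    traits <- rownames(amat)
    dec <- dsep_decider(amat)
    pg <- orient_propagate(ic_colliders(ic_skeleton(dec, traits), dec))
    oracle <- cpdag_bruteforce(amat)
    expect_equal(pg_signature(pg$directed, pg$undirected),
                 pg_signature(oracle$directed, oracle$undirected))
  }
})

test_that("consistent-extension verdicts match exhaustive orientation search", {
  # chordless undirected 4-cycle: not extendable
  cyc <- gensem:::new_partial_graph(c("a", "b", "c", "d"))
  cyc$undirected <- data.frame(a = c("a", "b", "c", "d"),
                               b = c("b", "c", "d", "a"),
                               stringsAsFactors = FALSE)
  expect_false(has_consistent_extension(cyc)$extendable)

  # undirected tree: extendable, witness acyclic with same skeleton
  tree <- gensem:::new_partial_graph(c("a", "b", "c", "d"))
  tree$undirected <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "d"),
                                stringsAsFactors = FALSE)
  res <- has_consistent_extension(tree)
  expect_true(res$extendable)
  expect_equal(nrow(res$witness$edges), 3)

  set.seed(53)
  for (rep in 1:60) {
    t <- sample(3:6, 1)
    traits <- paste0("v", seq_len(t))
    pg <- gensem:::new_partial_graph(traits)
    dird <- list(); und <- list()
    ord <- sample(traits)  # hidden order keeps directed part acyclic
    for (i in seq_len(t - 1)) for (j in seq.int(i + 1, t)) {
      if (runif(1) > 0.45) next
      kind <- runif(1)
      if (kind < 0.5) und[[length(und) + 1]] <-
          data.frame(a = traits[i], b = traits[j])
      else {
        fr <- if (match(traits[i], ord) < match(traits[j], ord)) c(i, j) else c(j, i)
        dird[[length(dird) + 1]] <-
          data.frame(from = traits[fr[1]], to = traits[fr[2]])
      }
    }
    if (length(und)) pg$undirected <- do.call(rbind, und)
    if (length(dird)) pg$directed <- do.call(rbind, dird)
    got <- has_consistent_extension(pg)
    want <- extension_bruteforce(traits, pg$directed, pg$undirected)
    expect_equal(got$extendable, want)
    if (got$extendable && nrow(pg$undirected)) {
      # witness keeps the input's directed edges
      wd <- paste(got$witness$edges$from, got$witness$edges$to)
      expect_true(all(paste(pg$directed$from, pg$directed$to) %in% wd))
    }
  }
})

test_that("temporal orienting applies the time order and reports new colliders", {
  torder <- quail_time_order()

  # the published skeleton orients to bw->aew, w35->afe->ne
  pg <- gensem:::new_partial_graph(quail)
  pg$undirected <- data.frame(a = c("bw", "w35", "afe"),
                              b = c("aew", "afe", "ne"),
                              stringsAsFactors = FALSE)
  out <- temporal_orient(pg, torder)
  expect_equal(pg_signature(out$directed, out$undirected),
               "afe -> ne;bw -> aew;w35 -> afe")
  expect_equal(nrow(out$new_colliders), 0)

  # extra w35-aew edge creates the reported collider bw -> aew <- w35
  pg2 <- gensem:::new_partial_graph(quail)
  pg2$undirected <- data.frame(a = c("bw", "w35", "afe", "w35"),
                               b = c("aew", "afe", "ne", "aew"),
                               stringsAsFactors = FALSE)
  out2 <- temporal_orient(pg2, torder)
  expect_true(gensem:::pg_directed(out2, "w35", "aew"))
  expect_equal(nrow(out2$new_colliders), 1)
  expect_setequal(c(out2$new_colliders$j, out2$new_colliders$jp),
                  c("bw", "w35"))

  # all traits at one time point: nothing oriented, ties listed
  flat <- stats::setNames(rep(1, 5), quail)
  out3 <- temporal_orient(pg, flat)
  expect_equal(nrow(out3$directed), 0)
  expect_equal(nrow(out3$tied_undirected), 3)

  # conflict with an already-directed edge errors
  pg4 <- gensem:::new_partial_graph(quail)
  pg4$directed <- data.frame(from = "afe", to = "w35", stringsAsFactors = FALSE)
  expect_error(temporal_orient(pg4, torder), "afe -> w35")
})

test_that("sharp posterior samples reproduce the point-estimate IC output", {
  sc <- scenario_presets("paper_model_C")
  Rtrue <- reduce_residual_covariance(sc$lambda, sc$psi0)
  set.seed(54)
  m <- 400
  draws <- t(vapply(seq_len(m), function(i) {
    E <- matrix(rnorm(25, sd = 2e-4), 5)
    as.vector(Rtrue * (1 + (E + t(E)) / 2))
  }, numeric(25)))
  res <- search_over_contents(draws, 0.95, sc$traits)
  pg <- res$graphs[[1]]
  expect_setequal(strsplit(pg_signature(pg$directed, pg$undirected), ";")[[1]],
                  c("aew-bw", "afe-w35", "afe-ne"))
})

test_that("independence verdicts are monotone in HPD content", {
  set.seed(55)
  m <- 300
  draws <- t(vapply(seq_len(m), function(i) {
    M <- matrix(rnorm(16, sd = 0.6), 4)
    as.vector(crossprod(M) + diag(4) * 0.5)
  }, numeric(16)))
  dec <- ic_decider(draws, paste0("v", 1:4))
  pairs <- utils::combn(paste0("v", 1:4), 2)
  for (ct in list(c(0.70, 0.95), c(0.6, 0.8, 0.99))) {
    for (i in seq_len(ncol(pairs))) {
      verdicts <- vapply(sort(ct), function(cc)
        dec$query(pairs[1, i], pairs[2, i], character(0), cc)$verdict, "")
      # once null, never back to dependent at higher content
      if (any(verdicts == "null")) {
        first <- which(verdicts == "null")[1]
        expect_true(all(verdicts[first:length(verdicts)] == "null"))
      }
    }
  }
})

test_that("the search prunes edges as the HPD content grows", {
  # wider intervals can only remove dependence verdicts, so the 0.95
  # skeleton is nested in the 0.70 skeleton for the same samples
  set.seed(56)
  sc <- scenario_presets("paper_model_C")
  Rtrue <- reduce_residual_covariance(sc$lambda, sc$psi0)
  ch <- chol(Rtrue)
  for (rep in 1:5) {
    draws <- t(vapply(1:250, function(i) {
      X <- matrix(rnorm(60 * 5), 60) %*% ch     # wishart-ish noise
      as.vector(crossprod(X) / 60)
    }, numeric(25)))
    res <- search_over_contents(draws, c(0.70, 0.95), sc$traits)
    skel <- function(pg) {
      e <- rbind(stats::setNames(pg$undirected, c("a", "b")),
                 stats::setNames(pg$directed, c("a", "b")))
      if (!nrow(e)) return(character(0))
      apply(e, 1, function(r) paste(sort(r), collapse = "-"))
    }
    expect_true(all(skel(res$graphs[["0.95"]]) %in% skel(res$graphs[["0.7"]])))
  }
})
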