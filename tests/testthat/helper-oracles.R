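# Independent oracles used across the suite. Everything here is written
# from first principles (path enumeration, exhaustive search, dense
# linear algebra) and never calls the package's own graph or likelihood
# code paths it is meant to check.

# ---- DAGs and d-separation -------------------------------------------

# random DAG adjacency matrix (amat[i, j] = 1 means i -> j)
random_dag <- function(t, p_edge = 0.4) {
  ord <- sample.int(t)
  amat <- matrix(0L, t, t)
  for (i in seq_len(t - 1)) for (j in seq.int(i + 1, t)) {
    if (stats::runif(1) < p_edge) amat[ord[i], ord[j]] <- 1L
  }
  dimnames(amat) <- list(paste0("v", seq_len(t)), paste0("v", seq_len(t)))
  amat
}

dag_descendants <- function(amat, v) {
  t <- nrow(amat)
  seen <- rep(FALSE, t)
  stack <- v
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    kids <- which(amat[x, ] == 1L & !seen)
    seen[kids] <- TRUE
    stack <- c(stack, kids)
  }
  which(seen)
}

# brute-force d-separation: enumerate all simple undirected paths between
# j and jp; blocked-path rules applied triple by triple
dsep <- function(amat, j, jp, s) {
  t <- nrow(amat)
  adj <- (amat + t(amat)) > 0
  desc_in_s <- function(b) b %in% s || any(dag_descendants(amat, b) %in% s)
  connected <- FALSE
  walk <- function(path) {
    if (connected) return(invisible())
    last <- path[length(path)]
    if (last == jp) {
      if (length(path) >= 3) {
        for (k in 2:(length(path) - 1)) {
          a <- path[k - 1]; b <- path[k]; cc <- path[k + 1]
          collider <- amat[a, b] == 1L && amat[cc, b] == 1L
          blocked <- if (collider) !desc_in_s(b) else b %in% s
          if (blocked) return(invisible())
        }
      }
      connected <<- TRUE
      return(invisible())
    }
    for (nxt in which(adj[last, ])) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(j)
  !connected
}

# IC decision function driven by exact d-separation in a DAG
dsep_decider <- function(amat, traits = rownames(amat)) {
  function(a, b, s) {
    ia <- match(a, traits); ib <- match(b, traits)
    is <- match(s, traits)
    if (dsep(amat, ia, ib, is)) "null" else "dependent"
  }
}

# ---- brute-force CPDAG ------------------------------------------------

dag_vstructs <- function(amat) {
  t <- nrow(amat)
  adj <- (amat + t(amat)) > 0
  out <- character(0)
  for (b in seq_len(t)) {
    pa <- which(amat[, b] == 1L)
    if (length(pa) < 2) next
    for (i in seq_len(length(pa) - 1)) for (k in seq.int(i + 1, length(pa))) {
      a <- pa[i]; cc <- pa[k]
      if (!adj[a, cc]) out <- c(out, paste(min(a, cc), b, max(a, cc)))
    }
  }
  sort(out)
}

is_acyclic_amat <- function(amat) {
  t <- nrow(amat)
  m <- amat
  deg <- colSums(m)
  left <- rep(TRUE, t)
  repeat {
    src <- which(left & deg == 0)
    if (!length(src)) break
    for (v in src) {
      deg <- deg - m[v, ]
      left[v] <- FALSE
      m[v, ] <- 0L
    }
  }
  !any(left)
}

# CPDAG by enumeration: orient the skeleton every possible way, keep the
# acyclic orientations with the DAG's v-structures, and mark an edge
# directed only when all survivors agree
cpdag_bruteforce <- function(amat) {
  t <- nrow(amat)
  traits <- rownames(amat)
  skel <- which(upper.tri(amat) & ((amat + t(amat)) > 0), arr.ind = TRUE)
  k <- nrow(skel)
  target <- dag_vstructs(amat)
  keep <- list()
  for (mask in seq_len(max(1, 2^k)) - 1) {
    cand <- matrix(0L, t, t)
    for (e in seq_len(k)) {
      a <- skel[e, 1]; b <- skel[e, 2]
      if (bitwAnd(mask, bitwShiftL(1, e - 1)) > 0) cand[a, b] <- 1L
      else cand[b, a] <- 1L
    }
    if (k == 0) cand <- matrix(0L, t, t)
    if (is_acyclic_amat(cand) && identical(dag_vstructs(cand), target))
      keep[[length(keep) + 1]] <- cand
  }
  directed <- data.frame(from = character(0), to = character(0),
                         stringsAsFactors = FALSE)
  undirected <- data.frame(a = character(0), b = character(0),
                           stringsAsFactors = FALSE)
  for (e in seq_len(k)) {
    a <- skel[e, 1]; b <- skel[e, 2]
    dir_ab <- all(vapply(keep, function(m) m[a, b] == 1L, TRUE))
    dir_ba <- all(vapply(keep, function(m) m[b, a] == 1L, TRUE))
    if (dir_ab) directed <- rbind(directed, data.frame(from = traits[a],
                                                       to = traits[b]))
    else if (dir_ba) directed <- rbind(directed, data.frame(from = traits[b],
                                                            to = traits[a]))
    else undirected <- rbind(undirected, data.frame(a = traits[a],
                                                    b = traits[b]))
  }
  list(directed = directed, undirected = undirected)
}

# canonical edge-set strings for graph comparison
pg_signature <- function(directed, undirected) {
  d <- if (nrow(directed)) sort(paste(directed$from, "->", directed$to))
       else character(0)
  u <- if (nrow(undirected))
    sort(apply(undirected, 1, function(r) paste(sort(r), collapse = "-")))
  else character(0)
  paste(c(d, u), collapse = ";")
}

# ---- consistent-extension brute force --------------------------------

uc_signature <- function(directed_df, adjacent) {
  # unshielded colliders of a directed edge set, as strings
  out <- character(0)
  tos <- unique(directed_df$to)
  for (b in tos) {
    pa <- directed_df$from[directed_df$to == b]
    if (length(pa) < 2) next
    cmb <- utils::combn(sort(pa), 2)
    for (i in seq_len(ncol(cmb))) {
      if (!adjacent(cmb[1, i], cmb[2, i]))
        out <- c(out, paste(cmb[1, i], b, cmb[2, i]))
    }
  }
  sort(out)
}

extension_bruteforce <- function(traits, directed, undirected) {
  adj_pairs <- rbind(data.frame(a = directed$from, b = directed$to),
                     undirected)
  adjacent <- function(x, y)
    any((adj_pairs$a == x & adj_pairs$b == y) |
        (adj_pairs$a == y & adj_pairs$b == x))
  base_uc <- uc_signature(directed, adjacent)
  k <- nrow(undirected)
  amat_of <- function(df) {
    m <- matrix(0L, length(traits), length(traits),
                dimnames = list(traits, traits))
    if (nrow(df)) m[cbind(match(df$from, traits), match(df$to, traits))] <- 1L
    m
  }
  for (mask in seq_len(max(1, 2^k)) - 1) {
    cand <- directed
    for (e in seq_len(k)) {
      if (bitwAnd(mask, bitwShiftL(1, e - 1)) > 0)
        cand <- rbind(cand, data.frame(from = undirected$a[e],
                                       to = undirected$b[e]))
      else
        cand <- rbind(cand, data.frame(from = undirected$b[e],
                                       to = undirected$a[e]))
    }
    if (!is_acyclic_amat(amat_of(cand))) next
    if (all(uc_signature(cand, adjacent) %in% base_uc)) return(TRUE)
  }
  FALSE
}

# ---- dense Gaussian likelihood oracle --------------------------------

mvn_logdens <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# ---- random pedigrees (exercises unknown-parent cases) ---------------

random_pedigree <- function(n, p_founder = 0.3) {
  animal <- paste0("a", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= 2 || stats::runif(1) < p_founder) next
    pool <- animal[seq_len(i - 1)]
    sire[i] <- sample(pool, 1)
    if (stats::runif(1) < 0.85) {
      d <- sample(pool, 1)
      if (d != sire[i]) dam[i] <- d
    }
  }
  validate_and_sort(data.frame(animal, sire, dam, stringsAsFactors = FALSE))
}

# small quick scenario used by the sampler tests
tiny_model_c <- function(founders = 20, gens = 2, matings = 15, offs = 3,
                         n_phen = 60) {
  sc <- scenario_presets("paper_model_C")
  sc$plan <- pedigree_plan(founders, gens, matings, offs)
  sc$n_phenotyped <- n_phen
  sc
}
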