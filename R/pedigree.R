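#' Validate and topologically sort a pedigree
#'
#' Takes raw animal/sire/dam triples in any order and returns a validated
#' pedigree in which every parent precedes its offspring. Ordering is
#' deterministic: records are sorted by generation depth (founders first)
#' and, within a depth, by their position in the input.
#'
#' Unknown parents may be coded as `NA`, the empty string, or the literal
#' `"0"`; internally they are stored as `NA`. IDs are treated as opaque
#' strings, never as numbers.
#'
#' @param records a data frame (or matrix) whose first three columns are
#'   animal, sire and dam identifiers.
#' @return an object of class `gensem_pedigree`: a data frame with columns
#'   `animal`, `sire`, `dam` (character, `NA` = unknown parent) in
#'   topological order.
#' @examples
#' ped <- validate_and_sort(data.frame(
#'   animal = c("c", "a", "b"), sire = c("a", "0", "0"), dam = c("b", "0", "0")))
#' ped$animal
#' @export
validate_and_sort <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (ncol(records) < 3L)
    stop("pedigree records need three columns: animal, sire, dam")
  ped <- data.frame(
    animal = as.character(records[[1L]]),
    sire   = normalize_parent(records[[2L]]),
    dam    = normalize_parent(records[[3L]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(ped$animal) || any(ped$animal == ""))
    stop("missing animal ID in pedigree records")
  if (anyDuplicated(ped$animal))
    stop("duplicated animal ID(s): ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  undefined <- setdiff(known, ped$animal)
  if (length(undefined))
    stop("parent ID(s) never defined as an animal: ",
         paste(sort(undefined), collapse = ", "))

  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  sire_i <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  dam_i  <- ifelse(is.na(ped$dam),  NA_integer_, idx[ped$dam])

  # generation depth by memoized DFS; a cycle shows up as a revisit of an
  # in-progress node
  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 = unseen, 1 = in progress, 2 = done
  depth_of <- function(i) {
    if (state[i] == 2L) return(depth[i])
    if (state[i] == 1L)
      stop("cycle in parentage involving animal '", ped$animal[i], "'")
    state[i] <<- 1L
    d <- 0L
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) d <- max(d, depth_of(p) + 1L)
    }
    depth[i] <<- d
    state[i] <<- 2L
    d
  }
  for (i in seq_len(n)) depth_of(i)

  ord <- order(depth, seq_len(n))
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "depth") <- depth[ord]
  class(out) <- c("gensem_pedigree", "data.frame")
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

#' Read a pedigree file
#'
#' Reads a 3-column delimited text file (animal, sire, dam). The delimiter
#' (comma or tab) is sniffed from the first line, and a header line is
#' detected by matching common column names. `"0"` and empty fields denote
#' unknown parents.
#'
#' @param path path to the pedigree file.
#' @return a validated, topologically sorted [validate_and_sort()] pedigree.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  fields <- tolower(gsub("[\"']", "", trimws(strsplit(first, sep, fixed = TRUE)[[1L]])))
  has_header <- any(fields %in% c("animal", "id", "sire", "dam", "father", "mother"))
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "character", strip.white = TRUE,
                           blank.lines.skip = TRUE)
  validate_and_sort(raw)
}

#' Numerator relationship matrix
#'
#' Builds the additive (numerator) relationship matrix **A** from a
#' pedigree by the tabular method. Inbreeding is fully accumulated:
#' the diagonal is `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param ped a `gensem_pedigree` from [validate_and_sort()].
#' @return a dense symmetric q x q matrix with animal IDs as dimnames.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "gensem_pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + 0.5 * A[si, j]
      if (di > 0L) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' @param ped a `gensem_pedigree`.
#' @return named vector of inbreeding coefficients `F_i = a_ii - 1`.
#' @export
inbreeding <- function(ped) {
  diag(relationship_matrix(ped)) - 1
}

#' Inverse of the numerator relationship matrix
#'
#' Assembles the sparse inverse of **A** directly from the pedigree using
#' the per-individual rules, with inbreeding accounted for through the
#' Mendelian sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `d_i = 0.75 - 0.25 F_p` (one parent known), `d_i = 1` (founder).
#'
#' @param ped a `gensem_pedigree`.
#' @param f optional precomputed inbreeding coefficients in pedigree order
#'   (defaults to [inbreeding()]).
#' @return a sparse symmetric [Matrix::Matrix] with animal IDs as dimnames.
#' @export
a_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "gensem_pedigree"))
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- v
  }
  for (i in seq_len(n)) {
    par <- c(s[i], d[i])
    par <- par[par > 0L]
    di <- switch(length(par) + 1L,
                 1,                                  # no known parent
                 0.75 - 0.25 * f[par],               # one known parent
                 0.5 - 0.25 * (f[s[i]] + f[d[i]]))   # both known
    alpha <- 1 / di
    add(i, i, alpha)
    for (p in par) {
      add(i, p, -alpha / 2)
      add(p, i, -alpha / 2)
    }
    for (p in par) for (q in par) add(p, q, alpha / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}
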