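#' Causal structure among traits
#'
#' A directed acyclic graph over trait labels. The structure determines
#' which off-diagonal entries of the structural coefficient matrix Lambda
#' are free parameters: edge `parent -> child` frees entry
#' `Lambda[child, parent]` (row = affected trait).
#'
#' @param traits character vector of trait labels (the declared trait order).
#' @param edges two-column data frame or matrix (`from`, `to`) of directed
#'   edges; may be empty. Also accepts a character vector of `"A->B"` strings.
#' @return an object of class `causal_structure` with fields `traits` and
#'   `edges` (data frame with columns `from`, `to`).
#' @examples
#' causal_structure(c("bw", "w35", "afe"), c("w35->afe"))
#' @export
causal_structure <- function(traits, edges = NULL) {
  traits <- as.character(traits)
  stopifnot(length(traits) >= 1, !anyDuplicated(traits))
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L) {
    ed <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  } else if (is.character(edges)) {
    parts <- strsplit(gsub(" ", "", edges), "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed edge spec: ", edges[bad][1L])
    ed <- data.frame(from = vapply(parts, `[`, "", 1L),
                     to   = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    ed <- data.frame(from = as.character(edges[[1L]]),
                     to   = as.character(edges[[2L]]),
                     stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(c(ed$from, ed$to)), traits)
  if (length(unknown))
    stop("edge endpoint(s) not in trait list: ", paste(unknown, collapse = ", "))
  if (any(ed$from == ed$to)) stop("self-edges are not allowed")
  if (anyDuplicated(paste(ed$from, ed$to))) stop("duplicated edges")
  st <- structure(list(traits = traits, edges = ed),
                  class = "causal_structure")
  if (is_cyclic(st)) stop("causal structure contains a cycle")
  st
}

#' @export
print.causal_structure <- function(x, ...) {
  cat("causal_structure over", length(x$traits), "traits:",
      paste(x$traits, collapse = ", "), "\n")
  if (nrow(x$edges) == 0L) cat("  (no edges)\n")
  else cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

is_cyclic <- function(st) {
  adj <- adjacency_matrix(st)
  # repeated elimination of sink-free nodes
  remaining <- rep(TRUE, length(st$traits))
  repeat {
    outdeg <- rowSums(adj[remaining, remaining, drop = FALSE])
    if (!length(outdeg)) return(FALSE)
    sinks <- names(outdeg)[outdeg == 0]
    if (!length(sinks)) return(TRUE)
    remaining[match(sinks, st$traits)] <- FALSE
  }
}

adjacency_matrix <- function(st) {
  t <- length(st$traits)
  m <- matrix(0L, t, t, dimnames = list(st$traits, st$traits))
  if (nrow(st$edges))
    m[cbind(match(st$edges$from, st$traits), match(st$edges$to, st$traits))] <- 1L
  m
}

#' Parents of a trait in a causal structure
#' @param st a `causal_structure`.
#' @param trait a trait label.
#' @return character vector of parent traits (in trait order).
#' @export
structure_parents <- function(st, trait) {
  p <- st$edges$from[st$edges$to == trait]
  st$traits[st$traits %in% p]
}

#' Fully recursive structure
#'
#' Every entry below the diagonal of Lambda free under the declared trait
#' order: trait j receives an edge from every earlier trait.
#'
#' @param traits trait labels in causal order.
#' @export
fully_recursive_structure <- function(traits) {
  t <- length(traits)
  ed <- do.call(rbind, lapply(seq_len(t)[-1], function(j)
    data.frame(from = traits[seq_len(j - 1L)], to = traits[j],
               stringsAsFactors = FALSE)))
  causal_structure(traits, ed)
}

#' Build a Lambda matrix from a structure and coefficient values
#'
#' @param st a `causal_structure`.
#' @param values named numeric vector: names `"from->to"`, or a vector in
#'   the order of `st$edges` rows.
#' @return t x t matrix with zero diagonal; entry `[to, from]` holds the
#'   structural coefficient.
#' @export
lambda_matrix <- function(st, values = NULL) {
  t <- length(st$traits)
  L <- matrix(0, t, t, dimnames = list(st$traits, st$traits))
  ne <- nrow(st$edges)
  if (ne == 0L) return(L)
  if (is.null(values)) values <- rep(0, ne)
  if (!is.null(names(values))) {
    key <- paste0(st$edges$from, "->", st$edges$to)
    miss <- setdiff(key, names(values))
    if (length(miss)) stop("missing coefficient(s): ", paste(miss, collapse = ", "))
    values <- values[key]
  } else if (length(values) != ne) {
    stop("need ", ne, " coefficient values")
  }
  L[cbind(match(st$edges$to, st$traits), match(st$edges$from, st$traits))] <- values
  L
}

#' Serialize a structure to an edge-list string or DOT
#' @param st a `causal_structure`.
#' @param format `"edgelist"` or `"dot"`.
#' @return character vector of lines.
#' @export
format_structure <- function(st, format = c("edgelist", "dot")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    if (nrow(st$edges) == 0L) return(character(0))
    return(paste(st$edges$from, "->", st$edges$to))
  }
  c("digraph causal_structure {",
    paste0("  \"", st$traits, "\";"),
    if (nrow(st$edges)) paste0("  \"", st$edges$from, "\" -> \"", st$edges$to, "\";"),
    "}")
}
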