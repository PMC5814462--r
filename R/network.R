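#' Weighted network container
#'
#' A light container for an undirected weighted graph: a node count `N`
#' (nodes are labelled `0 .. N-1`) and an edge table with columns `from`,
#' `to`, `weight` and optionally `type` (an integer weight-type label used
#' by the bulk/surface edge observables). Edges are stored canonically with
#' `from < to`; self-loops and duplicate undirected pairs are rejected.
#'
#' Weights must be non-negative; a zero weight is admitted only as the
#' diluted limit of a bimodal assignment, where weak links carry no
#' influence but remain topologically present.
#'
#' @param edges data.frame with integer columns `from`, `to` (0-based node
#'   ids), numeric `weight`, and optionally integer `type`.
#' @param N node count; defaults to `max(from, to) + 1`.
#' @return an object of class `weighted_network`.
#' @export
weighted_network <- function(edges, N = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) stop("edge list is empty")
  if (!all(c("from", "to", "weight") %in% names(edges)))
    stop("edges must have columns from, to, weight")
  from <- as.integer(edges$from)
  to <- as.integer(edges$to)
  w <- as.numeric(edges$weight)
  if (anyNA(from) || anyNA(to) || anyNA(w)) stop("NA in edge list")
  if (any(from == to)) stop("self-loops are not allowed")
  if (any(w < 0)) stop("negative edge weight")
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to)
  if (anyDuplicated(key)) stop("duplicate undirected edge")
  if (is.null(N)) N <- max(to) + 1L
  N <- as.integer(N)
  if (any(from < 0L) || any(to >= N)) stop("node ids must lie in [0, N)")
  out <- data.frame(from = from, to = to, weight = w)
  if (!is.null(edges$type)) out$type <- as.integer(edges$type)
  ord <- order(out$from, out$to)
  structure(list(N = N, edges = out[ord, , drop = FALSE]),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges\n", x$N, nrow(x$edges)))
  w <- x$edges$weight
  cat(sprintf("  weight: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(w), stats::sd(w), min(w), max(w)))
  if (!is.null(x$edges$type))
    cat("  types:", paste(names(table(x$edges$type)), table(x$edges$type),
                          sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Node degrees of a weighted network
#'
#' @param net a [weighted_network()].
#' @return integer vector of length `N` (0-based node order).
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  tabulate(c(net$edges$from, net$edges$to) + 1L, nbins = net$N)
}

#' Node strengths of a weighted network
#'
#' The strength of node i is the sum of weights on its incident edges.
#'
#' @inheritParams network_degrees
#' @return numeric vector of length `N`.
#' @export
network_strengths <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  idx <- c(net$edges$from, net$edges$to) + 1L
  agg <- rowsum(rep(net$edges$weight, 2L), idx)
  s <- numeric(net$N)
  s[as.integer(rownames(agg))] <- agg[, 1L]
  s
}

#' Read a weighted or signed edge list
#'
#' Parses a TSV file with one edge per line: `from<TAB>to<TAB>weight`.
#' Lines starting with `#` are skipped. In the signed dialect the third
#' column must be `+1` or `-1` (a bare `+`/`-` is also accepted).
#'
#' @param path file path.
#' @param signed if `TRUE`, parse the third column as a tie sign and return
#'   a data.frame `from, to, sign` instead of a network.
#' @param N optional node count override.
#' @return a [weighted_network()], or a data.frame if `signed = TRUE`.
#' @export
read_edge_list <- function(path, signed = FALSE, N = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields",
                 idx[bad[1L]], path))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  from <- suppressWarnings(as.integer(m[, 1L]))
  to <- suppressWarnings(as.integer(m[, 2L]))
  badid <- which(is.na(from) | is.na(to))
  if (length(badid) > 0L)
    stop(sprintf("malformed line %d in %s: non-integer node id",
                 idx[badid[1L]], path))
  if (signed) {
    sg <- m[, 3L]
    sg[sg == "+"] <- "+1"; sg[sg == "-"] <- "-1"
    sgn <- suppressWarnings(as.integer(sg))
    badsg <- which(is.na(sgn) | !(sgn %in% c(-1L, 1L)))
    if (length(badsg) > 0L)
      stop(sprintf("malformed line %d in %s: sign must be +1 or -1",
                   idx[badsg[1L]], path))
    return(data.frame(from = from, to = to, sign = sgn))
  }
  w <- suppressWarnings(as.numeric(m[, 3L]))
  badw <- which(is.na(w))
  if (length(badw) > 0L)
    stop(sprintf("malformed line %d in %s: non-numeric weight",
                 idx[badw[1L]], path))
  badpos <- which(w <= 0)
  if (length(badpos) > 0L)
    stop(sprintf("non-positive weight on line %d in %s",
                 idx[badpos[1L]], path))
  loop <- which(from == to)
  if (length(loop) > 0L)
    stop(sprintf("self-loop on line %d in %s: self-loops are removed from %s",
                 idx[loop[1L]], path, "these networks"))
  # undirected deduplication: keep first occurrence of each pair
  lo <- pmin(from, to); hi <- pmax(from, to)
  dup <- duplicated(paste(lo, hi))
  weighted_network(data.frame(from = from[!dup], to = to[!dup],
                              weight = w[!dup]), N = N)
}

#' Write a weighted network as a TSV edge list
#'
#' @param net a [weighted_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  lines <- sprintf("%d\t%d\t%s", net$edges$from, net$edges$to,
                   vapply(net$edges$weight, format, "", digits = 15L))
  writeLines(lines, path)
  invisible(path)
}
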