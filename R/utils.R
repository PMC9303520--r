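# shared helpers: edge indexing, symmetry checks

#' Edge index from a symmetric mask
#'
#' Extracts the upper-triangle \code{TRUE} entries of a symmetric logical
#' matrix as an ordered list of 0-based node pairs (i < j, lexicographic).
#'
#' @param mask symmetric logical matrix; the diagonal is ignored.
#' @return integer matrix with columns \code{i}, \code{j} (0-based node ids).
#' @export
edge_index_from_mask <- function(mask) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask))
  ut <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  idx <- cbind(i = ut[, 1] - 1L, j = ut[, 2] - 1L)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' All node pairs of an n-node graph
#'
#' @param n node count.
#' @return integer matrix of 0-based pairs (i < j) in lexicographic order.
#' @export
all_node_pairs <- function(n) {
  edge_index_from_mask(matrix(TRUE, n, n))
}

#' Rebuild a symmetric mask from an edge index
#'
#' @param edge_index 0-based pair matrix as from [edge_index_from_mask()].
#' @param n node count.
#' @return symmetric logical matrix with \code{FALSE} diagonal.
#' @export
mask_from_edge_index <- function(edge_index, n) {
  m <- matrix(FALSE, n, n)
  if (nrow(edge_index)) {
    m[cbind(edge_index[, 1] + 1L, edge_index[, 2] + 1L)] <- TRUE
    m[cbind(edge_index[, 2] + 1L, edge_index[, 1] + 1L)] <- TRUE
  }
  m
}

check_edge_index <- function(edge_index, n_nodes = NULL) {
  if (!is.matrix(edge_index) || ncol(edge_index) != 2)
    stop("edge_index must be a two-column matrix of 0-based node pairs")
  if (nrow(edge_index) == 0) return(invisible(edge_index))
  if (any(edge_index[, 1] >= edge_index[, 2]))
    stop("edge_index pairs must satisfy i < j")
  if (anyDuplicated(paste(edge_index[, 1], edge_index[, 2])))
    stop("edge_index contains duplicate pairs")
  if (!is.null(n_nodes) && any(edge_index < 0 | edge_index >= n_nodes))
    stop("edge_index refers to node ids outside 0..", n_nodes - 1L)
  invisible(edge_index)
}

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be square")
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop(what, " is not symmetric (tolerance ", tol, ")")
  invisible(m)
}

# stable small-integer stream seed for a (seed, subject, salt) triple.
# Subject ids are hashed with a Horner rolling hash and the combination is
# scrambled through Lehmer (multiplicative-congruential) rounds so that
# structured id sequences do not induce structured seeds; all arithmetic
# stays exact in doubles and the result stays below 2^31 for set.seed().
lehmer_mix <- function(x) {
  x <- (x %% 2147483646) + 1
  for (k in 1:3) x <- (x * 48271) %% 2147483647
  x
}

derive_seed <- function(seed, id, salt = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 1000003
  x <- (lehmer_mix(abs(as.numeric(seed)) + 1) +
          lehmer_mix(h + 1) * 2 + salt * 16807) %% 2147483647
  as.integer(lehmer_mix(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
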