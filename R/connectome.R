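# Connectome container and construction: streamline endpoint assignment,
# trilinear sampling of a scalar volume along resampled polylines, bundle
# medians, subject connectomes, consensus group connectomes, and
# vectorization onto a fixed edge index.

#' Construct a connectome object
#'
#' A connectome is a symmetric node-by-node matrix of edge R1 weights
#' (s^-1) with a companion presence mask and, optionally, streamline
#' counts. Weights must be finite and positive wherever present; the
#' diagonal is ignored (self-loops excluded).
#'
#' @param weights symmetric numeric matrix.
#' @param present symmetric logical matrix.
#' @param nodes node table (data.frame with \code{node_id}, \code{label}).
#' @param streamline_count optional symmetric integer matrix.
#' @param subject_id optional identifier carried along.
#' @return list of class \code{r1_connectome}.
#' @export
new_connectome <- function(weights, present, nodes,
                           streamline_count = NULL, subject_id = NULL) {
  check_symmetric(weights, what = "weights")
  check_symmetric(present * 1, what = "present")
  if (!all(dim(weights) == dim(present)))
    stop("weights and present dimensions differ")
  if (nrow(weights) != nrow(nodes))
    stop("matrix dimension does not match the node table")
  diag(present) <- FALSE
  w <- weights[present]
  if (length(w) && (any(!is.finite(w)) || any(w <= 0)))
    stop("present edge weights must be finite and positive")
  structure(
    list(weights = weights, present = present, nodes = nodes,
         streamline_count = streamline_count, subject_id = subject_id),
    class = "r1_connectome"
  )
}

#' @export
print.r1_connectome <- function(x, ...) {
  ne <- sum(x$present[upper.tri(x$present)])
  cat("R1-weighted connectome:", nrow(x$nodes), "nodes,", ne, "edges",
      if (!is.null(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  invisible(x)
}

# label value at a continuous 0-based voxel-center point; NA out of bounds
label_at_point <- function(labels, p) {
  vox <- round(p) + 1
  d <- dim(labels)
  if (any(vox < 1) || any(vox > d)) return(NA_integer_)
  labels[vox[1], vox[2], vox[3]]
}

#' Assign streamlines to node pairs by their endpoints
#'
#' A streamline joins unordered pair (i, j) iff its first point falls in
#' node i's voxels and its last point in node j's (distinct, nonzero
#' labels); all other streamlines are discarded. In the label volume node
#' id k is stored as voxel value k + 1 (0 = background). Points use
#' 0-based voxel-center coordinates. Out-of-bounds endpoints discard the
#' streamline with a logged count rather than raising.
#'
#' @param streamlines list of n-by-3 point matrices.
#' @param labels integer 3-D label array.
#' @return list with \code{edges} (named list keyed \code{"i|j"} of
#'   streamline indices), \code{n_assigned}, \code{n_discarded},
#'   \code{n_out_of_bounds}.
#' @export
assign_streamline_endpoints <- function(streamlines, labels) {
  edges <- list()
  n_oob <- 0L
  n_disc <- 0L
  for (s in seq_along(streamlines)) {
    pts <- streamlines[[s]]
    if (!is.matrix(pts) || ncol(pts) != 3 || nrow(pts) < 1) {
      n_disc <- n_disc + 1L
      next
    }
    v1 <- label_at_point(labels, pts[1, ])
    v2 <- label_at_point(labels, pts[nrow(pts), ])
    if (is.na(v1) || is.na(v2)) {
      n_oob <- n_oob + 1L
      n_disc <- n_disc + 1L
      next
    }
    if (v1 == 0 || v2 == 0 || v1 == v2) {
      n_disc <- n_disc + 1L
      next
    }
    ij <- sort(c(v1, v2)) - 1L    # labels are node_id + 1
    key <- paste0(ij[1], "|", ij[2])
    edges[[key]] <- c(edges[[key]], s)
  }
  if (n_oob > 0)
    message(n_oob, " streamline(s) discarded for out-of-bounds endpoints")
  list(edges = edges, n_assigned = length(streamlines) - n_disc,
       n_discarded = n_disc, n_out_of_bounds = n_oob)
}

# vectorized trilinear interpolation at 0-based voxel-center points,
# clamped to the volume bounds
trilinear_at <- function(volume, pts) {
  d <- dim(volume)
  pts <- pmin(pmax(pts, 0), matrix(d - 1, nrow(pts), 3, byrow = TRUE))
  p0 <- floor(pts)
  fr <- pts - p0
  i0 <- p0 + 1
  i1 <- pmin(i0 + 1, matrix(d, nrow(pts), 3, byrow = TRUE))
  g <- function(a, b, c) volume[cbind(a, b, c)]
  v000 <- g(i0[, 1], i0[, 2], i0[, 3]); v100 <- g(i1[, 1], i0[, 2], i0[, 3])
  v010 <- g(i0[, 1], i1[, 2], i0[, 3]); v110 <- g(i1[, 1], i1[, 2], i0[, 3])
  v001 <- g(i0[, 1], i0[, 2], i1[, 3]); v101 <- g(i1[, 1], i0[, 2], i1[, 3])
  v011 <- g(i0[, 1], i1[, 2], i1[, 3]); v111 <- g(i1[, 1], i1[, 2], i1[, 3])
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Sample a scalar volume along a streamline
#'
#' Resamples the polyline at a uniform arc-length step (the endpoint is
#' always included) and interpolates the volume trilinearly at each
#' sample. Coordinates are 0-based with the voxel-center convention; the
#' step is in voxel units (isotropic 1 mm voxels make it mm).
#'
#' @param volume numeric 3-D array.
#' @param polyline n-by-3 matrix of points, n >= 2.
#' @param step arc-length sampling step (> 0), default 0.5.
#' @return numeric vector of >= 2 interpolated values.
#' @export
sample_metric_along_streamline <- function(volume, polyline, step = 0.5) {
  if (!is.matrix(polyline) || ncol(polyline) != 3 || nrow(polyline) < 2)
    stop("polyline must be an n-by-3 matrix with n >= 2")
  if (step <= 0) stop("`step` must be positive")
  seg <- sqrt(rowSums(diff(polyline)^2))
  L <- sum(seg)
  if (L == 0) stop("degenerate zero-length polyline")
  cl <- c(0, cumsum(seg))
  s <- seq(0, L, by = step)
  if (s[length(s)] < L) s <- c(s, L)
  pts <- vapply(1:3, function(k)
    stats::approx(cl, polyline[, k], xout = s, ties = "ordered")$y,
    numeric(length(s)))
  if (!is.matrix(pts)) pts <- matrix(pts, nrow = 1)
  trilinear_at(volume, pts)
}

#' Bundle edge weight: median R1 over a streamline bundle
#'
#' The weight of a connection is the median R1 along its bundle. The
#' default pools every sample of every streamline in the bundle into one
#' median; \code{method = "per_streamline"} instead takes the median of
#' per-streamline medians (a sensitivity variant). Even counts use the
#' midpoint convention.
#'
#' @param samples_per_streamline list of numeric sample vectors, one per
#'   streamline; at least one nonempty.
#' @param method \code{"pooled"} (default) or \code{"per_streamline"}.
#' @return scalar R1 weight.
#' @export
compute_edge_weight <- function(samples_per_streamline,
                                method = c("pooled", "per_streamline")) {
  method <- match.arg(method)
  if (!length(samples_per_streamline) ||
      !sum(lengths(samples_per_streamline)))
    stop("empty bundle: no samples to aggregate")
  if (method == "pooled") {
    stats::median(unlist(samples_per_streamline, use.names = FALSE))
  } else {
    stats::median(vapply(samples_per_streamline, stats::median, numeric(1)))
  }
}

#' Build a subject connectome from streamlines and an R1 volume
#'
#' For every node pair with a nonempty bundle, samples the volume along
#' each assigned streamline and takes the bundle median as the edge
#' weight; presence marks nonempty bundles. Symmetric by construction and
#' invariant to streamline ordering.
#'
#' @param streamlines list of point matrices.
#' @param edge_map result of [assign_streamline_endpoints()].
#' @param volume R1 volume (3-D array).
#' @param nodes node table.
#' @param step sampling step, see [sample_metric_along_streamline()].
#' @param method bundle aggregation, see [compute_edge_weight()].
#' @return an \code{r1_connectome} with streamline counts.
#' @export
build_subject_connectome <- function(streamlines, edge_map, volume, nodes,
                                     step = 0.5,
                                     method = c("pooled", "per_streamline")) {
  method <- match.arg(method)
  n <- nrow(nodes)
  lab <- nodes$label
  W <- matrix(0, n, n, dimnames = list(lab, lab))
  P <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  K <- matrix(0L, n, n, dimnames = list(lab, lab))
  for (key in names(edge_map$edges)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]]) + 1L
    ids <- sort(edge_map$edges[[key]])
    samp <- lapply(ids, function(s)
      sample_metric_along_streamline(volume, streamlines[[s]], step))
    w <- compute_edge_weight(samp, method)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- w
    P[ij[1], ij[2]] <- P[ij[2], ij[1]] <- TRUE
    K[ij[1], ij[2]] <- K[ij[2], ij[1]] <- length(ids)
  }
  new_connectome(W, P, nodes, streamline_count = K)
}

#' Consensus group connectome
#'
#' Retains an edge iff it is present in at least \code{consensus_fraction}
#' of the subjects (\code{count / total >= fraction}, so an exact tie at
#' the threshold is kept), and weights it by the median across the
#' subjects in which it is present.
#'
#' @param subjects nonempty list of connectomes sharing one node table.
#' @param consensus_fraction presence threshold in (0, 1], default 0.5.
#' @return an \code{r1_connectome}.
#' @export
build_group_connectome <- function(subjects, consensus_fraction = 0.5) {
  if (!length(subjects)) stop("empty subject list")
  if (consensus_fraction <= 0 || consensus_fraction > 1)
    stop("`consensus_fraction` must lie in (0, 1]")
  n <- nrow(subjects[[1]]$nodes)
  if (!all(vapply(subjects, function(s) nrow(s$nodes) == n, logical(1))))
    stop("subjects do not share a node table")
  pres_count <- Reduce(`+`, lapply(subjects, function(s) s$present * 1L))
  keep <- pres_count / length(subjects) >= consensus_fraction
  diag(keep) <- FALSE
  lab <- subjects[[1]]$nodes$label
  W <- matrix(0, n, n, dimnames = list(lab, lab))
  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    vals <- vapply(subjects, function(s)
      if (s$present[i, j]) s$weights[i, j] else NA_real_, numeric(1))
    W[i, j] <- W[j, i] <- stats::median(vals, na.rm = TRUE)
  }
  new_connectome(W, keep, subjects[[1]]$nodes)
}

#' Vectorize a connectome onto a fixed edge index
#'
#' @param connectome an \code{r1_connectome}.
#' @param edge_index ordered 0-based pair matrix (i < j, no duplicates).
#' @return list of class \code{r1_edge_vector} with \code{values}
#'   (\code{NA} marks absent edges) and \code{edge_index}.
#' @export
vectorize_connectome <- function(connectome, edge_index) {
  check_edge_index(edge_index, n_nodes = nrow(connectome$nodes))
  eidx <- cbind(edge_index[, 1] + 1L, edge_index[, 2] + 1L)
  vals <- ifelse(connectome$present[eidx], connectome$weights[eidx], NA_real_)
  structure(list(values = vals, edge_index = edge_index),
            class = "r1_edge_vector")
}

#' Rebuild a connectome from an edge vector
#'
#' Inverse of [vectorize_connectome()] on present edges: \code{NA} values
#' become absent edges.
#'
#' @param values numeric vector aligned with \code{edge_index}.
#' @param edge_index ordered 0-based pair matrix.
#' @param nodes node table.
#' @return an \code{r1_connectome}.
#' @export
devectorize_connectome <- function(values, edge_index, nodes) {
  check_edge_index(edge_index, n_nodes = nrow(nodes))
  if (length(values) != nrow(edge_index))
    stop("values length does not match edge_index")
  n <- nrow(nodes)
  lab <- nodes$label
  W <- matrix(0, n, n, dimnames = list(lab, lab))
  P <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  pres <- !is.na(values)
  eidx <- cbind(edge_index[, 1] + 1L, edge_index[, 2] + 1L)
  W[eidx[pres, , drop = FALSE]] <- values[pres]
  W[eidx[pres, 2:1, drop = FALSE]] <- values[pres]
  P[eidx[pres, , drop = FALSE]] <- TRUE
  P[eidx[pres, 2:1, drop = FALSE]] <- TRUE
  new_connectome(W, P, nodes)
}

#' Edge index of a connectome's present edges
#'
#' @param connectome an \code{r1_connectome} (typically a consensus
#'   group connectome).
#' @return ordered 0-based pair matrix.
#' @export
consensus_edge_index <- function(connectome) {
  edge_index_from_mask(connectome$present)
}
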