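# Toy labeled phantom: cuboid node blocks in a 3-D grid, straight
# streamlines between block centers, and an R1 volume that is piecewise
# constant per node block and per edge corridor, so recovered edge
# weights have a known ground truth.

#' Generate a labeled phantom volume with streamlines
#'
#' Places every template node as a disjoint cuboid of labeled voxels on a
#' regular 3-D lattice, paints each template edge as a straight corridor
#' of known constant R1 between the two block centers (dilated by one
#' voxel so trilinear interpolation is exact inside the corridor), and
#' emits one straight streamline per edge whose endpoints lie inside the
#' two incident blocks. Node blocks are painted after corridors, so block
#' voxels keep the node value. The planted per-corridor values are
#' returned as ground truth for the volume-sampling stage.
#'
#' @param template an \code{r1_template}.
#' @param grid_shape integer triple of voxel dimensions.
#' @param seed integer RNG seed for the corridor values.
#' @param block node block side length in voxels.
#' @param corridor_range range of planted corridor R1 values (s^-1).
#' @param node_value R1 value inside node blocks.
#' @param background_value R1 value elsewhere.
#' @return list with \code{labels} (3-D integer array, node id k stored
#'   as k + 1, 0 background), \code{r1} (3-D numeric array),
#'   \code{streamlines} (list of 2-point matrices, 0-based voxel-center
#'   coordinates), \code{edge_values} (data.frame \code{i}, \code{j},
#'   \code{value}), \code{node_positions}.
#' @export
generate_phantom <- function(template, grid_shape = c(24, 24, 24), seed = 1,
                             block = 2, corridor_range = c(0.6, 1.1),
                             node_value = 1.0, background_value = 0.7) {
  stopifnot(inherits(template, "r1_template"))
  n <- nrow(template$nodes)
  d <- as.integer(grid_shape)
  if (length(d) != 3 || any(d < block + 2))
    stop("grid_shape must be a triple of dimensions > block + 1")
  # lattice of block origins with >= 1 voxel gap between blocks
  k_axis <- ceiling(n^(1 / 3))
  margin <- 1L
  if (k_axis > 1) {
    spacing <- (d - block - 2 * margin) / (k_axis - 1)
    if (any(spacing < block + 1))
      stop("nodes cannot be placed disjointly on this grid")
  } else spacing <- rep(0, 3)
  origins <- matrix(0, n, 3)
  idx <- 0L
  for (z in 0:(k_axis - 1)) for (y in 0:(k_axis - 1)) for (x in 0:(k_axis - 1)) {
    if (idx >= n) break
    idx <- idx + 1L
    origins[idx, ] <- margin + round(c(x, y, z) * spacing)
  }
  centers <- origins + (block - 1) / 2

  labels <- array(0L, dim = d)
  r1 <- array(background_value, dim = d)

  el <- template$edge_index
  set.seed(as.integer(seed))
  vals <- stats::runif(nrow(el), corridor_range[1], corridor_range[2])

  paint_cube <- function(arr, center_vox, val) {
    lo <- pmax(center_vox - 1L, 0L)
    hi <- pmin(center_vox + 1L, d - 1L)
    arr[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- val
    arr
  }
  streamlines <- vector("list", nrow(el))
  for (e in seq_len(nrow(el))) {
    a <- centers[el[e, 1] + 1L, ]
    b <- centers[el[e, 2] + 1L, ]
    L <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(4 * L)))
    for (t in ts) {
      p <- round(a + t * (b - a))
      r1 <- paint_cube(r1, as.integer(p), vals[e])
    }
    streamlines[[e]] <- rbind(a, b)
    dimnames(streamlines[[e]]) <- NULL
  }
  for (v in seq_len(n)) {
    o <- origins[v, ]
    labels[(o[1]:(o[1] + block - 1)) + 1,
           (o[2]:(o[2] + block - 1)) + 1,
           (o[3]:(o[3] + block - 1)) + 1] <- v   # node id v-1 stored as v
    r1[(o[1]:(o[1] + block - 1)) + 1,
       (o[2]:(o[2] + block - 1)) + 1,
       (o[3]:(o[3] + block - 1)) + 1] <- node_value
  }
  list(labels = labels, r1 = r1, streamlines = streamlines,
       edge_values = data.frame(i = el[, 1], j = el[, 2], value = vals),
       node_positions = centers)
}
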