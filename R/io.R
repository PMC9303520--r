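# Plain-text interchange formats: manifest CSV, node-table TSV, square
# matrix TSV with label headers, edge-table TSV, streamline JSONL, a
# simple text volume format (NIfTI supported when RNifti is installed),
# and JSON reports.

valid_groups <- c("HC", "PDnonRBD", "PDRBD")

#' Write / read a subject manifest CSV
#'
#' Columns: \code{subject_id}, \code{group}, \code{age}, \code{sex},
#' then one column per clinical score. Reading validates group and sex
#' labels and reports the offending row number.
#'
#' @param manifest data.frame as from [generate_manifest()].
#' @param path file path.
#' @return \code{read_manifest}: the validated data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!m$group %in% valid_groups)
  if (length(bad))
    stop("manifest row ", bad[1], ": unknown group label '",
         m$group[bad[1]], "'")
  bad <- which(!m$sex %in% c("F", "M"))
  if (length(bad))
    stop("manifest row ", bad[1], ": sex must be F or M, got '",
         m$sex[bad[1]], "'")
  if (any(!is.finite(m$age) | m$age <= 0)) {
    bad <- which(!is.finite(m$age) | m$age <= 0)
    stop("manifest row ", bad[1], ": age must be a positive number")
  }
  m
}

#' Write / read a node table TSV
#'
#' @param nodes node table data.frame.
#' @param path file path.
#' @export
write_node_table <- function(nodes, path) {
  utils::write.table(nodes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  nd <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "label") %in% names(nd)))
    stop("node table must have node_id and label columns")
  if (!identical(as.integer(nd$node_id), seq_len(nrow(nd)) - 1L))
    stop("node_id must be contiguous 0..N-1 in order")
  if (anyDuplicated(nd$label)) stop("node labels must be unique")
  nd
}

#' Write / read a labeled square matrix TSV
#'
#' The header row and first column carry the node labels. Reading a
#' matrix declared symmetric checks symmetry within tolerance and errors
#' otherwise.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @param symmetric require symmetry on read.
#' @param tol symmetry tolerance.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(cbind(label = rownames(m), as.data.frame(m)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, symmetric = TRUE, tol = 1e-8) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  lab <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- lab
  if (ncol(m) != nrow(m)) stop("matrix TSV is not square")
  if (!identical(colnames(m), lab))
    stop("matrix TSV header labels do not match the row labels")
  if (symmetric) check_symmetric(m, tol = tol, what = basename(path))
  m
}

#' Write / read a connectome as weight + presence TSV pair
#'
#' Writes \code{<prefix>_weights.tsv}, \code{<prefix>_present.tsv} (0/1)
#' and \code{<prefix>_nodes.tsv}.
#'
#' @param connectome an \code{r1_connectome}.
#' @param prefix path prefix.
#' @export
write_connectome <- function(connectome, prefix) {
  write_matrix_tsv(connectome$weights, paste0(prefix, "_weights.tsv"))
  write_matrix_tsv(connectome$present * 1L, paste0(prefix, "_present.tsv"))
  write_node_table(connectome$nodes, paste0(prefix, "_nodes.tsv"))
  invisible(prefix)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(prefix) {
  W <- read_matrix_tsv(paste0(prefix, "_weights.tsv"))
  P <- read_matrix_tsv(paste0(prefix, "_present.tsv")) > 0
  nodes <- read_node_table(paste0(prefix, "_nodes.tsv"))
  new_connectome(W, P, nodes)
}

#' Write a connectome as a long edge table TSV
#'
#' Columns: \code{node_i}, \code{node_j} (labels), \code{weight},
#' \code{present}, \code{n_streamlines}.
#'
#' @param connectome an \code{r1_connectome}.
#' @param path file path.
#' @export
write_edge_table <- function(connectome, path) {
  idx <- edge_index_from_mask(connectome$present |
                                connectome$weights != 0)
  lab <- connectome$nodes$label
  eidx <- cbind(idx[, 1] + 1L, idx[, 2] + 1L)
  k <- connectome$streamline_count
  df <- data.frame(
    node_i = lab[eidx[, 1]], node_j = lab[eidx[, 2]],
    weight = connectome$weights[eidx],
    present = as.integer(connectome$present[eidx]),
    n_streamlines = if (is.null(k)) NA_integer_ else k[eidx],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read streamlines as JSON lines
#'
#' One JSON object per line: \code{{"points": [[x,y,z], ...]}} in 0-based
#' voxel coordinates. Malformed lines raise with the line number.
#'
#' @param streamlines list of n-by-3 point matrices.
#' @param path file path.
#' @export
write_streamlines_jsonl <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in streamlines) {
    writeLines(jsonlite::toJSON(list(points = unname(s)), digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_streamlines_jsonl
#' @export
read_streamlines_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(seq_along(lines), function(k) {
    obj <- tryCatch(jsonlite::fromJSON(lines[k]),
                    error = function(e) stop("streamline file line ", k,
                                             ": ", conditionMessage(e)))
    if (is.null(obj$points))
      stop("streamline file line ", k, ": missing 'points'")
    pts <- as.matrix(obj$points)
    if (ncol(pts) != 3)
      stop("streamline file line ", k, ": points must be x,y,z triples")
    pts
  })
}

#' Write / read a scalar volume
#'
#' Plain-text volume format: a header line \code{R1VOL nx ny nz} followed
#' by whitespace-separated values in R array (x-fastest) order. Paths
#' ending in \code{.nii} / \code{.nii.gz} use NIfTI via the RNifti
#' package when installed.
#'
#' @param volume numeric 3-D array.
#' @param path file path (\code{.txt} or \code{.nii}/\code{.nii.gz}).
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to write NIfTI volumes")
    RNifti::writeNifti(RNifti::asNifti(volume), path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("R1VOL", paste(dim(volume), collapse = " ")), con)
  writeLines(paste(format(as.vector(volume), digits = 17), collapse = " "),
             con)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI volumes")
    return(array(as.numeric(RNifti::readNifti(path)),
                 dim = dim(RNifti::readNifti(path))))
  }
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (hdr[1] != "R1VOL" || length(hdr) != 4)
    stop("volume file line 1: expected header 'R1VOL nx ny nz'")
  d <- as.integer(hdr[2:4])
  vals <- as.numeric(strsplit(trimws(paste(lines[-1], collapse = " ")),
                              "\\s+")[[1]])
  if (length(vals) != prod(d))
    stop("volume file: expected ", prod(d), " values, found ", length(vals))
  array(vals, dim = d)
}

#' Write a JSON report
#'
#' @param x list to serialize.
#' @param path file path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
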