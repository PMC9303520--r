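# Partial least squares on edge data: mean-centering (group contrast) and
# behavioral (edge-score correlation) cross-blocks, SVD into latent
# variables, permutation significance of singular values, bootstrap-ratio
# edge reliability, and confound correlation checks.

#' Assemble the subjects-by-edges data matrix
#'
#' Stacks subject edge vectors over a fixed edge index (typically the
#' consensus edge set). Edges absent in a subject are imputed per policy:
#' \code{"edge_median"} (default) fills with that edge's median over the
#' subjects possessing it; \code{"fail"} raises on any missing cell.
#'
#' @param connectomes named list of subject connectomes.
#' @param edge_index ordered 0-based pair matrix.
#' @param groups optional per-subject labels, aligned with
#'   \code{connectomes}.
#' @param impute \code{"edge_median"} or \code{"fail"}.
#' @return list with \code{X} (subjects x edges, rownames = subject ids),
#'   \code{groups}, \code{edge_index}.
#' @export
assemble_data_matrix <- function(connectomes, edge_index, groups = NULL,
                                 impute = c("edge_median", "fail")) {
  impute <- match.arg(impute)
  check_edge_index(edge_index)
  X <- t(vapply(connectomes, function(cn)
    vectorize_connectome(cn, edge_index)$values,
    numeric(nrow(edge_index))))
  rownames(X) <- names(connectomes)
  if (anyNA(X)) {
    if (impute == "fail") {
      bad <- which(is.na(X), arr.ind = TRUE)[1, ]
      stop("missing edge weight for subject ", rownames(X)[bad[1]],
           ", edge ", edge_index[bad[2], 1], "-", edge_index[bad[2], 2])
    }
    for (e in which(colSums(is.na(X)) > 0)) {
      v <- X[, e]
      if (all(is.na(v)))
        stop("edge ", edge_index[e, 1], "-", edge_index[e, 2],
             " is absent in every subject")
      X[is.na(v), e] <- stats::median(v, na.rm = TRUE)
    }
  }
  list(X = X, groups = groups, edge_index = edge_index)
}

#' Group mean-centered deviation matrix
#'
#' One row per group: the group's edge means minus the unweighted grand
#' mean of the group means, so unequal group sizes do not tilt the
#' contrast. Rows sum to zero per edge.
#'
#' @param X subjects-by-edges matrix.
#' @param groups per-subject labels; every group needs >= 2 subjects.
#' @return groups-by-edges matrix with group rownames (sorted).
#' @export
mean_center_by_group <- function(X, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("`groups` does not match rows of X")
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 subjects")
  M <- t(vapply(lev, function(g) colMeans(X[groups == g, , drop = FALSE]),
                numeric(ncol(X))))
  sweep(M, 2, colMeans(M))
}

#' Behavioral cross-block: within-group score-edge correlations
#'
#' Pearson correlation of every score column with every edge, computed
#' within group and stacked group-blocks row-wise (standard behavioral
#' PLS practice); with a single (or no) group label, a plain
#' scores-by-edges correlation matrix. \code{mode = "covariance"} is a
#' sensitivity variant.
#'
#' @param X subjects-by-edges matrix.
#' @param Y subjects-by-scores matrix (column names kept).
#' @param groups optional per-subject labels.
#' @param mode \code{"correlation"} (default) or \code{"covariance"}.
#' @return (groups x scores)-by-edges matrix.
#' @export
behavior_cross_block <- function(X, Y, groups = NULL,
                                 mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("X and Y row counts differ")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("score", seq_len(ncol(Y)))
  if (is.null(groups)) groups <- rep("all", nrow(X))
  lev <- sort(unique(as.character(groups)))
  blocks <- lapply(lev, function(g) {
    sel <- groups == g
    Yg <- Y[sel, , drop = FALSE]
    Xg <- X[sel, , drop = FALSE]
    zv <- which(apply(Yg, 2, stats::var) == 0)
    if (length(zv))
      stop("zero variance in score column '", colnames(Y)[zv[1]],
           "' within group ", g)
    B <- if (mode == "correlation") suppressWarnings(stats::cor(Yg, Xg))
         else stats::cov(Yg, Xg)
    if (any(!is.finite(B)))
      stop("non-finite cross-block entries (zero-variance edge within group ",
           g, ")")
    rownames(B) <- if (length(lev) > 1) paste0(g, ":", colnames(Y))
                   else colnames(Y)
    B
  })
  do.call(rbind, blocks)
}

#' Singular value decomposition of a PLS cross-block
#'
#' Full SVD ordered by singular value; each latent variable (LV) pairs a
#' design salience column (left singular vector) with an edge salience
#' column (right singular vector). The sign of each LV is fixed so the
#' largest-magnitude edge salience is positive. Subject scores are the
#' projection of X onto the edge saliences.
#'
#' @param cross_block design-by-edges matrix.
#' @param X optional subjects-by-edges matrix for subject scores.
#' @return list of class \code{r1_pls} with \code{singular_values},
#'   \code{edge_saliences}, \code{design_saliences},
#'   \code{subject_scores} (or NULL).
#' @export
pls_svd <- function(cross_block, X = NULL) {
  if (any(!is.finite(cross_block))) stop("cross-block must be finite")
  s <- svd(cross_block)
  V <- s$v
  U <- s$u
  for (k in seq_along(s$d)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) {
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  rownames(U) <- rownames(cross_block)
  structure(
    list(singular_values = s$d, edge_saliences = V, design_saliences = U,
         subject_scores = if (!is.null(X)) X %*% V else NULL),
    class = "r1_pls"
  )
}

# cross-block dispatcher shared by the resampling routines
pls_cross_block <- function(X, groups = NULL, Y = NULL, ...) {
  if (is.null(Y)) mean_center_by_group(X, groups)
  else behavior_cross_block(X, Y, groups, ...)
}

#' Permutation p-values for PLS latent variables
#'
#' Each permutation randomly reorders the subject rows of X relative to
#' the group labels (mean-centering mode) or to the score rows
#' (behavioral mode), recomputes the cross-block and its singular values.
#' The p-value of LV k is the plain proportion of permutations whose k-th
#' singular value meets or exceeds the observed one (so p can be 0);
#' \code{add_one = TRUE} uses the (count + 1)/(n + 1) variant.
#'
#' @param X subjects-by-edges matrix.
#' @param groups group labels (mean-centering mode, Y = NULL).
#' @param Y subjects-by-scores matrix (behavioral mode).
#' @param n_perm number of permutations (>= 1), default 500.
#' @param seed integer RNG seed.
#' @param add_one use add-one smoothing.
#' @return list with \code{p} (per LV), \code{observed} singular values,
#'   \code{n_perm}.
#' @export
permutation_pvalues <- function(X, groups = NULL, Y = NULL, n_perm = 500,
                                seed = 1, add_one = FALSE) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  obs <- svd(pls_cross_block(X, groups, Y))$d
  set.seed(as.integer(seed))
  cnt <- numeric(length(obs))
  n <- nrow(X)
  for (b in seq_len(n_perm)) {
    Xp <- X[sample.int(n), , drop = FALSE]
    d <- svd(pls_cross_block(Xp, groups, Y))$d
    cnt <- cnt + (d >= obs)
  }
  p <- if (add_one) (cnt + 1) / (n_perm + 1) else cnt / n_perm
  list(p = p, observed = obs, n_perm = n_perm)
}

#' Bootstrap ratios for edge saliences
#'
#' Resamples subjects with replacement within group, recomputes the
#' cross-block SVD per resample, aligns the chosen LV's edge saliences to
#' the original by sign (dot product), and divides each original salience
#' by the standard deviation of its aligned bootstrap replicates. A
#' resample leaving any group degenerate (all rows identical, or a
#' zero-variance score column in behavioral mode) is redrawn up to a
#' retry budget.
#'
#' @param X subjects-by-edges matrix.
#' @param groups group labels (kept fixed across resamples); NULL treats
#'   all subjects as one group (behavioral single-group mode).
#' @param Y optional subjects-by-scores matrix (behavioral mode).
#' @param lv latent variable index, default 1.
#' @param n_boot number of bootstrap resamples (>= 2), default 500.
#' @param seed integer RNG seed.
#' @param max_redraw retry budget per degenerate resample.
#' @return list with \code{bsr}, \code{salience}, \code{se} per edge.
#' @export
bootstrap_ratios <- function(X, groups = NULL, Y = NULL, lv = 1,
                             n_boot = 500, seed = 1, max_redraw = 100) {
  if (n_boot < 2) stop("`n_boot` must be >= 2")
  fit0 <- pls_svd(pls_cross_block(X, groups, Y))
  if (lv > length(fit0$singular_values)) stop("`lv` exceeds the LV count")
  v0 <- fit0$edge_saliences[, lv]
  grp <- if (is.null(groups)) rep("all", nrow(X)) else as.character(groups)
  by_grp <- split(seq_len(nrow(X)), grp)
  # resampled rows are laid out group-block by group-block
  grp_b <- rep(names(by_grp), lengths(by_grp))
  set.seed(as.integer(seed))
  sal <- matrix(NA_real_, length(v0), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (try in seq_len(max_redraw)) {
      cand <- unlist(lapply(by_grp, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      # degeneracy: a group's resampled rows all identical, or (behavioral)
      # a zero-variance score column within a group
      ok <- TRUE
      for (g in names(by_grp)) {
        sel <- cand[grp_b == g]
        if (nrow(unique(X[sel, , drop = FALSE])) < 2) ok <- FALSE
        if (!is.null(Y)) {
          Yg <- as.matrix(Y)[sel, , drop = FALSE]
          if (any(apply(Yg, 2, stats::var) == 0)) ok <- FALSE
        }
        if (!ok) break
      }
      if (ok) { idx <- cand; break }
    }
    if (is.null(idx))
      stop("bootstrap retry budget exhausted on degenerate resamples")
    Xb <- X[idx, , drop = FALSE]
    Yb <- if (is.null(Y)) NULL else as.matrix(Y)[idx, , drop = FALSE]
    fb <- svd(pls_cross_block(Xb, if (is.null(groups)) NULL else grp_b, Yb))
    vb <- fb$v[, lv]
    if (sum(vb * v0) < 0) vb <- -vb
    sal[, b] <- vb
  }
  se <- apply(sal, 1, stats::sd)
  list(bsr = v0 / se, salience = v0, se = se)
}

#' Threshold reliable edges by bootstrap ratio
#'
#' Selects edges with |BSR| strictly above the threshold and partitions
#' them by sign. The default 2.56 corresponds to a 99% normal confidence
#' band (the exact two-sided quantile 2.576 is also usable).
#'
#' @param bsr per-edge bootstrap ratios.
#' @param edge_index optional 0-based pair matrix aligned with
#'   \code{bsr}.
#' @param threshold positive cutoff, default 2.56.
#' @param labels optional node labels for readable output.
#' @return data.frame with \code{edge} (index), optional \code{i},
#'   \code{j}, \code{node_i}, \code{node_j}, \code{bsr},
#'   \code{direction}.
#' @export
threshold_reliable_edges <- function(bsr, edge_index = NULL,
                                     threshold = 2.56, labels = NULL) {
  if (threshold <= 0) stop("`threshold` must be positive")
  sel <- which(is.finite(bsr) & abs(bsr) > threshold)
  out <- data.frame(edge = sel, bsr = bsr[sel],
                    direction = ifelse(bsr[sel] > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  if (!is.null(edge_index) && nrow(out)) {
    out$i <- edge_index[sel, 1]
    out$j <- edge_index[sel, 2]
    if (!is.null(labels)) {
      out$node_i <- labels[out$i + 1L]
      out$node_j <- labels[out$j + 1L]
    }
  }
  out
}

#' Confound correlations of LV subject scores with age and sex
#'
#' Pearson r and two-sided p of the latent-variable subject scores
#' against age and against sex coded F = 0, M = 1.
#'
#' @param subject_scores numeric vector of per-subject LV scores.
#' @param age numeric ages.
#' @param sex "F"/"M" labels or 0/1 codes.
#' @return list with \code{r_age}, \code{p_age}, \code{r_sex},
#'   \code{p_sex}.
#' @export
lv_confound_check <- function(subject_scores, age, sex) {
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(as.character(sex) == "M")
  ra <- pearson_with_p(subject_scores, age)
  rs <- pearson_with_p(subject_scores, sex)
  list(r_age = ra$statistic, p_age = ra$p,
       r_sex = rs$statistic, p_sex = rs$p)
}
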