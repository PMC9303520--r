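# Epicenter ring analysis: reference adjacency, first/second ring
# decomposition, per-subject ring medians, covariate-adjusted group
# comparison with FDR, and epicenter-internal comparisons.

#' Consensus reference adjacency over a cohort
#'
#' Presence-consensus adjacency pooled over all subjects (both groups),
#' using the same "at least" rule as [build_group_connectome()], so ring
#' definitions are identical across groups.
#'
#' @param connectomes nonempty list of subject connectomes.
#' @param consensus_fraction presence threshold in (0, 1], default 0.5.
#' @return symmetric logical adjacency with \code{FALSE} diagonal.
#' @export
derive_reference_adjacency <- function(connectomes, consensus_fraction = 0.5) {
  if (!length(connectomes)) stop("empty cohort")
  pres <- Reduce(`+`, lapply(connectomes, function(s) s$present * 1L))
  adj <- pres / length(connectomes) >= consensus_fraction
  diag(adj) <- FALSE
  adj
}

#' Define first and second rings around an epicenter
#'
#' The first ring is the set of nodes directly connected to any epicenter
#' node; the second ring the set of nodes connected to the epicenter only
#' indirectly through a single first-ring node (a node adjacent to both an
#' epicenter and a first-ring node belongs to the first ring: the direct
#' connection wins). First-ring edges join an epicenter node to a
#' first-ring node; second-ring edges join a first-ring node to a
#' second-ring node. Edges among first-ring nodes belong to neither ring.
#'
#' @param adjacency symmetric logical matrix.
#' @param epicenter_nodes 0-based node ids.
#' @param name epicenter name carried into results.
#' @return list of class \code{ring_definition} with the three disjoint
#'   node sets (0-based), the two edge sets (0-based pair matrices) and a
#'   \code{note} flagging empty rings.
#' @export
define_rings <- function(adjacency, epicenter_nodes, name = "epicenter") {
  check_symmetric(adjacency * 1, what = "adjacency")
  n <- nrow(adjacency)
  epi <- as.integer(epicenter_nodes)
  if (any(epi < 0 | epi >= n)) stop("epicenter node ids outside 0..", n - 1L)
  e1 <- epi + 1L
  nb1 <- which(colSums(adjacency[e1, , drop = FALSE]) > 0)
  first <- setdiff(nb1, e1)
  nb2 <- if (length(first))
    which(colSums(adjacency[first, , drop = FALSE]) > 0) else integer(0)
  second <- setdiff(nb2, union(first, e1))

  pairs_between <- function(a, b) {
    if (!length(a) || !length(b)) return(matrix(integer(0), 0, 2))
    gr <- expand.grid(a = a, b = b)
    gr <- gr[adjacency[cbind(gr$a, gr$b)], , drop = FALSE]
    if (!nrow(gr)) return(matrix(integer(0), 0, 2))
    el <- cbind(pmin(gr$a, gr$b), pmax(gr$a, gr$b)) - 1L
    el <- unique(el)
    el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  note <- if (!length(first)) "epicenter has no neighbors: rings are empty"
          else if (!length(second)) "second ring is empty"
          else NA_character_
  structure(
    list(epicenter_name = name, epicenter_nodes = sort(epi),
         first_ring_nodes = sort(first) - 1L,
         second_ring_nodes = sort(second) - 1L,
         first_ring_edges = pairs_between(e1, first),
         second_ring_edges = pairs_between(first, second),
         note = note),
    class = "ring_definition"
  )
}

#' Per-subject median R1 over a ring's edges
#'
#' Median of the subject's weights over the ring edges present in that
#' subject; edges the subject lacks are dropped (not imputed). Returns
#' \code{NA} with a warning when no ring edge is present or the ring is
#' empty.
#'
#' @param connectome an \code{r1_connectome}.
#' @param ring_edges 0-based pair matrix.
#' @return scalar R1 median or \code{NA}.
#' @export
subject_ring_median <- function(connectome, ring_edges) {
  if (!nrow(ring_edges)) {
    warning("empty ring edge set: returning NA")
    return(NA_real_)
  }
  eidx <- cbind(ring_edges[, 1] + 1L, ring_edges[, 2] + 1L)
  pres <- connectome$present[eidx]
  if (!any(pres)) {
    warning("no ring edge present in this subject: returning NA")
    return(NA_real_)
  }
  stats::median(connectome$weights[eidx][pres])
}

#' Ring medians for every subject, epicenter and ring
#'
#' @param connectomes named list of subject connectomes.
#' @param rings list of \code{ring_definition} objects.
#' @return long data.frame with \code{subject_id}, \code{epicenter},
#'   \code{ring} ("first"/"second"), \code{value}.
#' @export
ring_subject_medians <- function(connectomes, rings) {
  rows <- list()
  for (rd in rings) {
    for (ring in c("first", "second")) {
      edges <- if (ring == "first") rd$first_ring_edges else rd$second_ring_edges
      vals <- vapply(connectomes, function(cn)
        suppressWarnings(subject_ring_median(cn, edges)), numeric(1))
      rows[[paste(rd$epicenter_name, ring)]] <- data.frame(
        subject_id = names(connectomes), epicenter = rd$epicenter_name,
        ring = ring, value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted group comparison of ring medians
#'
#' Per (epicenter, ring): ANCOVA of the subject ring medians on group
#' (healthy controls vs PD, pooled across PD subgroups by default) with
#' age and sex (F = 0, M = 1) as covariates, then Benjamini-Hochberg FDR
#' across all tests in the family.
#'
#' @param medians long data.frame from [ring_subject_medians()].
#' @param manifest subject manifest with \code{subject_id}, \code{group},
#'   \code{age}, \code{sex}.
#' @param pool_pd treat both PD subgroups as one PD group (default TRUE).
#' @return data.frame with \code{epicenter}, \code{ring}, \code{n},
#'   \code{F}, \code{p}, \code{q}, ordered as tested.
#' @export
compare_ring_groups <- function(medians, manifest, pool_pd = TRUE) {
  df <- merge(medians, manifest[, c("subject_id", "group", "age", "sex")],
              by = "subject_id", sort = FALSE)
  df <- df[is.finite(df$value), , drop = FALSE]
  df$grp <- if (pool_pd) ifelse(df$group == "HC", "HC", "PD") else df$group
  df$sex01 <- as.integer(df$sex == "M")
  cells <- unique(df[, c("epicenter", "ring")])
  res <- lapply(seq_len(nrow(cells)), function(r) {
    sub <- df[df$epicenter == cells$epicenter[r] & df$ring == cells$ring[r], ]
    if (length(unique(sub$grp)) < 2)
      stop("both groups must be represented for epicenter ",
           cells$epicenter[r], ", ", cells$ring[r], " ring")
    ft <- ancova_group_F(sub$value, sub$grp,
                         cbind(age = sub$age, sex = sub$sex01))
    data.frame(epicenter = cells$epicenter[r], ring = cells$ring[r],
               n = nrow(sub), F = ft$statistic, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Epicenter-internal group comparison
#'
#' Two-sample t test (pooled variance by default, Welch optional)
#' comparing the per-subject epicenter-internal R1 medians between
#' healthy controls and the pooled PD group, per epicenter.
#'
#' @param epicenter_values long data.frame with \code{subject_id},
#'   \code{epicenter}, \code{value} (as from [generate_epicenter_r1()]).
#' @param manifest subject manifest.
#' @param welch use Welch's t instead of pooled variance.
#' @return data.frame with \code{epicenter}, \code{t}, \code{df},
#'   \code{p}.
#' @export
epicenter_internal_comparison <- function(epicenter_values, manifest,
                                          welch = FALSE) {
  df <- merge(epicenter_values, manifest[, c("subject_id", "group")],
              by = "subject_id", sort = FALSE)
  df$grp <- ifelse(df$group == "HC", "HC", "PD")
  eps <- unique(df$epicenter)
  res <- lapply(eps, function(e) {
    sub <- df[df$epicenter == e & is.finite(df$value), ]
    x <- sub$value[sub$grp == "HC"]
    y <- sub$value[sub$grp == "PD"]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 subjects per group for epicenter ", e)
    ft <- two_sample_t(x, y, welch = welch)
    data.frame(epicenter = e, t = ft$statistic, df = ft$df[1], p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
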