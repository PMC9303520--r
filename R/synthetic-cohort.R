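# Synthetic cohort generator: subject manifests with demographics and
# clinical scores, a template network with planted disease / behavior
# subnetworks, per-subject R1-weighted connectomes, behavior scores, and
# per-subject epicenter R1 scalars. Everything is a pure function of its
# arguments including the seed.

#' Default demographic and clinical-score moments per group
#'
#' Group-wise means and SDs used by [generate_manifest()]: age, proportion
#' of females, and the clinical scores (MDS-UPDRS III off-medication,
#' Hoehn & Yahr stage, MMSE, MoCA, Mattis DRS, disease duration in months).
#' Values mirror a published PD case-control cohort of 35 HC, 59 PD without
#' RBD and 22 PD with RBD. Scores absent for a group (disease duration in
#' controls) are \code{NULL} and generated as \code{NA}.
#'
#' @return nested list keyed by group then field.
#' @export
default_demographics <- function() {
  list(
    HC = list(
      age = c(61.2, 9.16), female_prop = 12 / 35,
      scores = list(
        mds_updrs_iii_off = c(5.14, 5.15), hy = c(0, 0),
        mmse = c(29.48, 0.78), moca = c(28.03, 1.48),
        mattis = c(139.88, 3.85), disease_duration_months = NULL
      )
    ),
    PDnonRBD = list(
      age = c(60.83, 10.21), female_prop = 37 / 59,
      scores = list(
        mds_updrs_iii_off = c(31.07, 8.24), hy = c(2.00, 0.19),
        mmse = c(28.90, 1.36), moca = c(27.61, 2.20),
        mattis = c(138.71, 5.25), disease_duration_months = c(17.11, 12.69)
      )
    ),
    PDRBD = list(
      age = c(63.86, 7.47), female_prop = 15 / 22,
      scores = list(
        mds_updrs_iii_off = c(29.09, 7.40), hy = c(2.09, 0.29),
        mmse = c(29.14, 1.08), moca = c(27.64, 2.48),
        mattis = c(139.27, 3.96), disease_duration_months = c(23.91, 10.89)
      )
    )
  )
}

# truncated-normal draw by rejection; degenerate sd = 0 returns the mean
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# natural bounds for clinical scores (ceilings of the instruments)
score_bounds <- list(
  mds_updrs_iii_off = c(0, 132), hy = c(0, 5), mmse = c(0, 30),
  moca = c(0, 30), mattis = c(0, 144), disease_duration_months = c(0, Inf)
)

#' Generate a synthetic subject manifest
#'
#' Draws demographics and clinical scores for a three-group cohort
#' (healthy controls, PD without RBD, PD with RBD). Ages are normal draws
#' per group truncated to \code{age_bounds}; sex is Bernoulli at the
#' group's female proportion; clinical scores are independent normals at
#' the group moments, clipped to each instrument's range. Deterministic
#' given \code{seed}.
#'
#' @param n_hc,n_pdnonrbd,n_pdrbd nonnegative group sizes
#'   (cohort defaults: 35 / 59 / 22).
#' @param seed integer RNG seed.
#' @param demographics moments as from [default_demographics()].
#' @param age_bounds truncation interval for age in years.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{age}, \code{sex} and one column per clinical score.
#' @examples
#' m <- generate_manifest(5, 5, 2, seed = 1)
#' table(m$group)
#' @export
generate_manifest <- function(n_hc, n_pdnonrbd, n_pdrbd, seed,
                              demographics = default_demographics(),
                              age_bounds = c(35, 90)) {
  ns <- c(HC = n_hc, PDnonRBD = n_pdnonrbd, PDRBD = n_pdrbd)
  if (any(ns < 0)) stop("group counts must be nonnegative")
  if (any(ns != round(ns))) stop("group counts must be integers")
  set.seed(as.integer(seed))
  score_names <- names(demographics[[1]]$scores)
  rows <- list()
  k <- 0L
  for (g in names(ns)) {
    n <- as.integer(ns[[g]])
    if (n == 0) next
    mom <- demographics[[g]]
    age <- rnorm_trunc(n, mom$age[1], mom$age[2], age_bounds[1], age_bounds[2])
    sex <- ifelse(stats::runif(n) < mom$female_prop, "F", "M")
    sc <- lapply(score_names, function(s) {
      ms <- mom$scores[[s]]
      if (is.null(ms)) return(rep(NA_real_, n))
      b <- score_bounds[[s]] %||% c(-Inf, Inf)
      pmin(pmax(stats::rnorm(n, ms[1], ms[2]), b[1]), b[2])
    })
    names(sc) <- score_names
    rows[[g]] <- data.frame(
      subject_id = sprintf("sub-%03d", k + seq_len(n)),
      group = g, age = age, sex = sex, sc,
      stringsAsFactors = FALSE
    )
    k <- k + n
  }
  if (!length(rows)) {
    out <- data.frame(subject_id = character(0), group = character(0),
                      age = numeric(0), sex = character(0))
    for (s in score_names) out[[s]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect model for the synthetic cohort
#'
#' Bundles the generative parameters of [generate_subject_edges()] and
#' [generate_behavior_scores()]: \code{delta} is the fractional R1
#' reduction applied to affected edges in PD subjects; \code{sigma_subject}
#' the SD of the per-subject lognormal global scaling (mimicking R1
#' calibration differences between scans); \code{sigma_edge} the SD of
#' additive per-edge noise in s^-1; \code{behavior_slope} converts the mean
#' R1 deficit over the planted behavior subnetwork into clinical-score
#' units, with normal noise \code{behavior_noise_sd} around
#' \code{behavior_intercept}.
#'
#' @param delta fractional R1 reduction on affected PD edges, in \[0, 1).
#' @param sigma_subject lognormal SD of the subject scaling factor.
#' @param sigma_edge SD of additive edge noise (s^-1).
#' @param behavior_slope score units per unit mean R1 deficit.
#' @param behavior_noise_sd score noise SD.
#' @param behavior_intercept score at zero deficit.
#' @param seed integer seed from which all subject-level draws derive.
#' @return list of class \code{r1_effect_model}.
#' @export
effect_model <- function(delta = 0.05, sigma_subject = 0.02,
                         sigma_edge = 0.02, behavior_slope = 250,
                         behavior_noise_sd = 4, behavior_intercept = 30,
                         seed = 1) {
  if (delta < 0 || delta >= 1) stop("`delta` must lie in [0, 1)")
  if (sigma_subject < 0 || sigma_edge < 0 || behavior_noise_sd < 0)
    stop("noise SDs must be nonnegative")
  structure(
    list(delta = delta, sigma_subject = sigma_subject,
         sigma_edge = sigma_edge, behavior_slope = behavior_slope,
         behavior_noise_sd = behavior_noise_sd,
         behavior_intercept = behavior_intercept, seed = as.integer(seed)),
    class = "r1_effect_model"
  )
}

#' Default epicenter groups for the synthetic parcellation
#'
#' Eight bilateral epicenter candidates mirroring the regions commonly
#' proposed as PD spreading origins: four subcortical (substantia nigra,
#' nucleus basalis of Meynert, hippocampus, amygdala) and four brainstem
#' (medulla, pons, midbrain, locus coeruleus). Node ids 0..15 of the
#' default template, two per region.
#'
#' @return named list of 0-based node-id vectors.
#' @export
default_epicenters <- function() {
  nm <- c("SN", "NBM", "hippocampus", "amygdala",
          "medulla", "pons", "midbrain", "LC")
  stats::setNames(lapply(seq_along(nm), function(k) c(2L * k - 2L, 2L * k - 1L)), nm)
}

make_node_table <- function(n_nodes, epicenter_spec) {
  node_id <- seq_len(n_nodes) - 1L
  label <- character(n_nodes)
  hemisphere <- character(n_nodes)
  region_class <- character(n_nodes)
  epicenter_group <- rep(NA_character_, n_nodes)
  brainstem <- c("medulla", "pons", "midbrain", "LC")
  for (nm in names(epicenter_spec)) {
    ids <- epicenter_spec[[nm]] + 1L
    label[ids] <- if (length(ids) == 2) paste0(nm, c("_L", "_R"))
                  else paste0(nm, "_", seq_along(ids))
    hemisphere[ids] <- if (length(ids) == 2) c("L", "R") else "midline"
    region_class[ids] <- if (nm %in% brainstem) "brainstem" else "subcortical"
    epicenter_group[ids] <- nm
  }
  rest <- which(label == "")
  if (length(rest)) {
    lobes <- c("frontal", "parietal", "temporal", "occipital")
    lob <- lobes[((seq_along(rest) - 1L) %/% 2L) %% 4L + 1L]
    hemi <- c("L", "R")[(seq_along(rest) - 1L) %% 2L + 1L]
    label[rest] <- sprintf("ctx_%s_%s_%02d", lob, hemi,
                           ((seq_along(rest) - 1L) %/% 8L) + 1L)
    hemisphere[rest] <- hemi
    region_class[rest] <- paste0("cortical-", lob)
  }
  if (anyDuplicated(label)) stop("internal: node labels not unique")
  data.frame(node_id = node_id, label = label, hemisphere = hemisphere,
             region_class = region_class, epicenter_group = epicenter_group,
             stringsAsFactors = FALSE)
}

#' Generate a template network with planted subnetworks
#'
#' Builds a connected random graph at the requested density, assigns each
#' edge a baseline R1 weight (uniform in \code{weight_range}, an
#' R1-plausible band in s^-1), marks \code{n_affected_edges} edges as
#' carrying the PD effect (chosen preferentially among edges incident to
#' epicenter nodes), marks \code{n_behavior_edges} edges as the
#' behavior-coupled subnetwork (preferentially disjoint from the affected
#' set), and assigns per-edge presence probabilities (1 except a weak tail
#' that exercises the consensus rule).
#'
#' @param n_nodes node count (default 40).
#' @param density fraction of all node pairs realized as edges; the
#'   default yields 200 edges on 40 nodes.
#' @param epicenter_spec named list of 0-based node-id vectors; default
#'   [default_epicenters()] when \code{n_nodes >= 16}.
#' @param n_affected_edges,n_behavior_edges planted subnetwork sizes;
#'   \code{n_affected_edges = NA} plants on every epicenter-incident edge
#'   (a pure first-ring disease model).
#' @param seed integer RNG seed.
#' @param weight_range baseline R1 range in s^-1.
#' @param weak_edge_fraction fraction of edges given reduced presence.
#' @param weak_edge_presence presence probability of the weak tail.
#' @param max_tries connected-graph retry budget.
#' @return list of class \code{r1_template} with fields \code{nodes},
#'   \code{baseline_weight}, \code{presence_prob}, \code{affected_mask},
#'   \code{behavior_mask}, \code{edge_index}, \code{epicenters}.
#' @export
generate_template_network <- function(n_nodes = 40, density = 0.2564,
                                      epicenter_spec = NULL,
                                      n_affected_edges = 40,
                                      n_behavior_edges = 8, seed = 1,
                                      weight_range = c(0.55, 1.15),
                                      weak_edge_fraction = 0.05,
                                      weak_edge_presence = 0.7,
                                      max_tries = 50) {
  if (density <= 0 || density > 1) stop("`density` must lie in (0, 1]")
  if (is.null(epicenter_spec))
    epicenter_spec <- if (n_nodes >= 16) default_epicenters() else list()
  epi_nodes <- unique(unlist(epicenter_spec))
  if (length(epi_nodes) && any(epi_nodes < 0 | epi_nodes >= n_nodes))
    stop("epicenter node ids must lie in 0..", n_nodes - 1L)
  m <- round(density * n_nodes * (n_nodes - 1) / 2)
  if (m < n_nodes - 1)
    stop("density too low for a connected graph on ", n_nodes, " nodes")
  if ((!is.na(n_affected_edges) && n_affected_edges > m) ||
      n_behavior_edges > m)
    stop("planted subnetworks cannot exceed the edge count (", m, ")")
  set.seed(as.integer(seed))
  g <- NULL
  for (try in seq_len(max_tries)) {
    cand <- igraph::sample_gnm(n_nodes, m)
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g))
    stop("could not generate a connected graph at density ", density,
         " within ", max_tries, " tries")
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]

  nodes <- make_node_table(n_nodes, epicenter_spec)
  lab <- nodes$label
  sym <- function(vals, init = 0) {
    M <- matrix(init, n_nodes, n_nodes, dimnames = list(lab, lab))
    M[cbind(el[, 1] + 1L, el[, 2] + 1L)] <- vals
    M[cbind(el[, 2] + 1L, el[, 1] + 1L)] <- vals
    M
  }
  baseline <- sym(stats::runif(m, weight_range[1], weight_range[2]))

  incident <- which(el[, 1] %in% epi_nodes | el[, 2] %in% epi_nodes)
  if (is.na(n_affected_edges)) n_affected_edges <- length(incident)
  affected <- integer(0)
  if (n_affected_edges > 0) {
    if (length(incident) >= n_affected_edges) {
      affected <- sample(incident, n_affected_edges)
    } else {
      extra <- sample(setdiff(seq_len(m), incident),
                      n_affected_edges - length(incident))
      affected <- c(incident, extra)
    }
  }
  beh_pool <- setdiff(seq_len(m), affected)
  behavior <- integer(0)
  if (n_behavior_edges > 0) {
    if (length(beh_pool) >= n_behavior_edges) {
      behavior <- sample(beh_pool, n_behavior_edges)
    } else {
      behavior <- c(beh_pool, sample(affected, n_behavior_edges - length(beh_pool)))
    }
  }
  aff <- logical(m); aff[affected] <- TRUE
  beh <- logical(m); beh[behavior] <- TRUE

  pres <- rep(1, m)
  n_weak <- round(weak_edge_fraction * m)
  if (n_weak > 0) pres[sample(m, n_weak)] <- weak_edge_presence

  structure(
    list(nodes = nodes, baseline_weight = baseline,
         presence_prob = sym(pres), affected_mask = sym(aff, FALSE) > 0,
         behavior_mask = sym(beh, FALSE) > 0,
         edge_index = unname(el), epicenters = epicenter_spec),
    class = "r1_template"
  )
}

#' Simulate one subject's R1-weighted connectome
#'
#' For each template edge the subject weight is
#' \code{baseline * s * (1 - delta * affected * is_pd) + eps}, where
#' \code{s} is a subject-level lognormal scaling (meanlog 0, sdlog
#' \code{sigma_subject}) shared across edges, \code{eps} is independent
#' normal edge noise, and the multiplicative R1 reduction \code{delta}
#' applies only to affected edges of PD subjects (both PD subgroups).
#' Edges are present with the template's per-edge probability; weights are
#' clipped positive. Deterministic given the model seed and subject id.
#'
#' @param template an \code{r1_template}.
#' @param subject one manifest row (list or one-row data.frame with
#'   \code{subject_id} and \code{group}).
#' @param model an [effect_model()].
#' @return an [new_connectome()] object.
#' @export
generate_subject_edges <- function(template, subject, model) {
  stopifnot(inherits(template, "r1_template"),
            inherits(model, "r1_effect_model"))
  id <- as.character(subject$subject_id)
  grp <- as.character(subject$group)
  if (!grp %in% c("HC", "PDnonRBD", "PDRBD"))
    stop("unknown group label: ", grp)
  is_pd <- grp %in% c("PDnonRBD", "PDRBD")
  el <- template$edge_index
  m <- nrow(el)
  eidx <- cbind(el[, 1] + 1L, el[, 2] + 1L)
  base <- template$baseline_weight[eidx]
  aff <- template$affected_mask[eidx]
  prob <- template$presence_prob[eidx]

  set.seed(derive_seed(model$seed, id, salt = 0L))
  s_subj <- exp(stats::rnorm(1, 0, model$sigma_subject))
  eps <- stats::rnorm(m, 0, model$sigma_edge)
  present <- stats::runif(m) < prob

  w <- base * s_subj * (1 - model$delta * (aff & is_pd)) + eps
  w <- pmax(w, 1e-6)
  w[!present] <- 0

  n <- nrow(template$nodes)
  lab <- template$nodes$label
  W <- matrix(0, n, n, dimnames = list(lab, lab))
  P <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  W[eidx] <- w; W[eidx[, 2:1]] <- w
  P[eidx] <- present; P[eidx[, 2:1]] <- present
  new_connectome(W, P, template$nodes, subject_id = id)
}

#' Simulate connectomes for a whole manifest
#'
#' @param template an \code{r1_template}.
#' @param manifest data.frame from [generate_manifest()].
#' @param model an [effect_model()].
#' @return named list of connectomes keyed by subject id.
#' @export
generate_cohort_connectomes <- function(template, manifest, model) {
  out <- lapply(seq_len(nrow(manifest)), function(r)
    generate_subject_edges(template, manifest[r, ], model))
  stats::setNames(out, manifest$subject_id)
}

#' Simulate behavior scores coupled to the planted subnetwork
#'
#' Each subject's score is
#' \code{intercept + slope * deficit + noise}, where the deficit is the
#' mean over present behavior-mask edges of (template baseline - subject
#' weight): larger R1 loss on the planted subnetwork drives a higher
#' (worse) score, emulating a motor-severity scale.
#'
#' @param subject_edges named list of connectomes (keyed by subject id).
#' @param template an \code{r1_template} with a nonempty behavior mask.
#' @param model an [effect_model()].
#' @return named numeric vector of scores.
#' @export
generate_behavior_scores <- function(subject_edges, template, model) {
  beh <- edge_index_from_mask(template$behavior_mask)
  if (nrow(beh) == 0) stop("template behavior_mask is empty")
  eidx <- cbind(beh[, 1] + 1L, beh[, 2] + 1L)
  base <- template$baseline_weight[eidx]
  vapply(names(subject_edges), function(id) {
    cn <- subject_edges[[id]]
    pres <- cn$present[eidx]
    deficit <- if (any(pres)) mean(base[pres] - cn$weights[eidx][pres]) else 0
    set.seed(derive_seed(model$seed, id, salt = 1L))
    model$behavior_intercept + model$behavior_slope * deficit +
      stats::rnorm(1, 0, model$behavior_noise_sd)
  }, numeric(1))
}

#' Simulate per-subject epicenter-internal R1 medians
#'
#' The within-epicenter R1 of the original analysis is a voxelwise ROI
#' median, which needs volumes; the synthetic pathway draws it directly as
#' a per-subject scalar per epicenter:
#' \code{baseline * s * (1 - delta_epicenter * is_pd)} with the same
#' lognormal subject scaling as the edge generator. The default
#' \code{delta_epicenter = 0} reflects a null within-epicenter effect.
#'
#' @param manifest subject manifest.
#' @param epicenter_names character vector of epicenter names.
#' @param model an [effect_model()].
#' @param baseline epicenter R1 baseline in s^-1.
#' @param delta_epicenter fractional within-epicenter PD reduction.
#' @return long data.frame with columns \code{subject_id},
#'   \code{epicenter}, \code{value}.
#' @export
generate_epicenter_r1 <- function(manifest, epicenter_names, model,
                                  baseline = 0.9, delta_epicenter = 0) {
  rows <- lapply(seq_len(nrow(manifest)), function(r) {
    id <- manifest$subject_id[r]
    is_pd <- manifest$group[r] %in% c("PDnonRBD", "PDRBD")
    set.seed(derive_seed(model$seed, id, salt = 2L))
    s <- exp(stats::rnorm(length(epicenter_names), 0, model$sigma_subject))
    data.frame(subject_id = id, epicenter = epicenter_names,
               value = baseline * s * (1 - delta_epicenter * is_pd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
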