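# End-to-end orchestration on the synthetic cohort: simulate -> build ->
# consensus -> PLS (contrast + behavioral) -> rings -> demographics,
# writing all artifacts under an output directory.

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic end-to-end run. All
#' randomness derives from \code{seed}; two runs with the same
#' configuration produce identical artifacts.
#'
#' @param n_hc,n_pdnonrbd,n_pdrbd cohort sizes (defaults 35/59/22).
#' @param n_nodes,density template graph size and density.
#' @param n_affected_edges,n_behavior_edges planted subnetwork sizes.
#' @param delta,sigma_subject,sigma_edge effect-model parameters, see
#'   [effect_model()].
#' @param behavior_slope,behavior_noise_sd behavior coupling.
#' @param consensus_fraction consensus presence threshold.
#' @param n_perm,n_boot permutation and bootstrap counts.
#' @param bsr_threshold reliable-edge |BSR| cutoff.
#' @param fdr_alpha FDR significance level for reporting.
#' @param epicenter_spec named list of 0-based node-id sets; NULL uses
#'   [default_epicenters()].
#' @param seed master seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_hc = 35, n_pdnonrbd = 59, n_pdrbd = 22,
                            n_nodes = 40, density = 0.2564,
                            n_affected_edges = 40, n_behavior_edges = 8,
                            delta = 0.05, sigma_subject = 0.02,
                            sigma_edge = 0.02, behavior_slope = 250,
                            behavior_noise_sd = 4,
                            consensus_fraction = 0.5, n_perm = 500,
                            n_boot = 500, bsr_threshold = 2.56,
                            fdr_alpha = 0.05, epicenter_spec = NULL,
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a \code{pipeline_config} (or plain list).
#' @return the config, invisibly; errors list every violated constraint.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(all(c(config$n_hc, config$n_pdnonrbd, config$n_pdrbd) >= 0),
      "group sizes must be nonnegative")
  chk(config$n_hc >= 2 && (config$n_pdnonrbd + config$n_pdrbd) >= 2,
      "need >= 2 subjects in HC and in PD for the group analyses")
  chk(config$density > 0 && config$density <= 1,
      "density must lie in (0, 1]")
  chk(config$consensus_fraction > 0 && config$consensus_fraction <= 1,
      "consensus_fraction must lie in (0, 1]")
  chk(config$n_perm >= 1, "n_perm must be >= 1")
  chk(config$n_boot >= 2, "n_boot must be >= 2")
  chk(config$bsr_threshold > 0, "bsr_threshold must be positive")
  chk(config$delta >= 0 && config$delta < 1, "delta must lie in [0, 1)")
  chk(config$fdr_alpha > 0 && config$fdr_alpha < 1,
      "fdr_alpha must lie in (0, 1)")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(config)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  message("[", name, "] started")
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message("[", name, "] done in ",
          sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a cohort, builds consensus connectomes, runs the
#' mean-centering PLS contrast (HC vs pooled PD) with permutation and
#' bootstrap inference and confound checks, the behavioral PLS of PD
#' edges against the simulated motor score, the epicenter ring analysis,
#' and the demographics table. All artifacts are written under
#' \code{out_dir} along with a JSON run manifest of parameters and
#' package version; a re-run with the same config is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- stage("simulate", {
    manifest <- generate_manifest(config$n_hc, config$n_pdnonrbd,
                                  config$n_pdrbd, seed = config$seed)
    template <- generate_template_network(
      n_nodes = config$n_nodes, density = config$density,
      epicenter_spec = config$epicenter_spec,
      n_affected_edges = config$n_affected_edges,
      n_behavior_edges = config$n_behavior_edges, seed = config$seed + 1)
    model <- effect_model(delta = config$delta,
                          sigma_subject = config$sigma_subject,
                          sigma_edge = config$sigma_edge,
                          behavior_slope = config$behavior_slope,
                          behavior_noise_sd = config$behavior_noise_sd,
                          seed = config$seed + 2)
    connectomes <- generate_cohort_connectomes(template, manifest, model)
    behavior <- generate_behavior_scores(connectomes, template, model)
    manifest$mds_updrs_iii_off[manifest$group != "HC"] <-
      behavior[manifest$subject_id[manifest$group != "HC"]]
    epi_r1 <- generate_epicenter_r1(manifest, names(template$epicenters),
                                    model)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    write_node_table(template$nodes, file.path(out_dir, "nodes.tsv"))
    write_matrix_tsv(template$baseline_weight,
                     file.path(out_dir, "template_baseline.tsv"))
    list(manifest = manifest, template = template, model = model,
         connectomes = connectomes, behavior = behavior, epi_r1 = epi_r1)
  })

  cons <- stage("consensus", {
    is_hc <- sim$manifest$group == "HC"
    g_hc <- build_group_connectome(sim$connectomes[is_hc],
                                   config$consensus_fraction)
    g_pd <- build_group_connectome(sim$connectomes[!is_hc],
                                   config$consensus_fraction)
    g_all <- build_group_connectome(sim$connectomes,
                                    config$consensus_fraction)
    write_connectome(g_hc, file.path(out_dir, "group_HC"))
    write_connectome(g_pd, file.path(out_dir, "group_PD"))
    write_connectome(g_all, file.path(out_dir, "group_pooled"))
    list(hc = g_hc, pd = g_pd, pooled = g_all,
         edge_index = consensus_edge_index(g_all))
  })

  contrast <- stage("pls-contrast", {
    groups2 <- ifelse(sim$manifest$group == "HC", "HC", "PD")
    dm <- assemble_data_matrix(sim$connectomes, cons$edge_index,
                               groups = groups2)
    fit <- pls_svd(mean_center_by_group(dm$X, dm$groups), X = dm$X)
    perm <- permutation_pvalues(dm$X, groups = dm$groups,
                                n_perm = config$n_perm,
                                seed = config$seed + 3)
    boot <- bootstrap_ratios(dm$X, groups = dm$groups, lv = 1,
                             n_boot = config$n_boot,
                             seed = config$seed + 4)
    rel <- threshold_reliable_edges(boot$bsr, dm$edge_index,
                                    threshold = config$bsr_threshold,
                                    labels = sim$template$nodes$label)
    conf <- lv_confound_check(fit$subject_scores[, 1], sim$manifest$age,
                              sim$manifest$sex)
    sal <- data.frame(
      node_i = sim$template$nodes$label[dm$edge_index[, 1] + 1L],
      node_j = sim$template$nodes$label[dm$edge_index[, 2] + 1L],
      salience_lv1 = fit$edge_saliences[, 1], bsr_lv1 = boot$bsr)
    utils::write.table(sal, file.path(out_dir, "pls_contrast_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(rel, file.path(out_dir, "pls_contrast_reliable.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_json_report(
      list(singular_values = fit$singular_values, perm_p = perm$p,
           n_perm = perm$n_perm, confound = conf),
      file.path(out_dir, "pls_contrast.json"))
    list(fit = fit, perm = perm, boot = boot, reliable = rel,
         confound = conf)
  })

  behavioral <- stage("pls-behavior", {
    is_pd <- sim$manifest$group != "HC"
    dm <- assemble_data_matrix(sim$connectomes[is_pd], cons$edge_index)
    Y <- matrix(sim$manifest$mds_updrs_iii_off[is_pd],
                dimnames = list(NULL, "mds_updrs_iii_off"))
    fit <- pls_svd(behavior_cross_block(dm$X, Y), X = dm$X)
    perm <- permutation_pvalues(dm$X, Y = Y, n_perm = config$n_perm,
                                seed = config$seed + 5)
    boot <- bootstrap_ratios(dm$X, Y = Y, lv = 1, n_boot = config$n_boot,
                             seed = config$seed + 6)
    rel <- threshold_reliable_edges(boot$bsr, dm$edge_index,
                                    threshold = config$bsr_threshold,
                                    labels = sim$template$nodes$label)
    r_lv <- pearson_with_p(fit$subject_scores[, 1], Y[, 1])
    write_json_report(
      list(singular_values = fit$singular_values, perm_p = perm$p,
           lv1_score_r = r_lv$statistic, lv1_score_p = r_lv$p),
      file.path(out_dir, "pls_behavior.json"))
    utils::write.table(rel, file.path(out_dir, "pls_behavior_reliable.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(fit = fit, perm = perm, boot = boot, reliable = rel,
         lv1_score_r = r_lv$statistic)
  })

  rings <- stage("rings", {
    adj <- derive_reference_adjacency(sim$connectomes,
                                      config$consensus_fraction)
    rdefs <- lapply(names(sim$template$epicenters), function(nm)
      define_rings(adj, sim$template$epicenters[[nm]], name = nm))
    med <- ring_subject_medians(sim$connectomes, rdefs)
    stats_tab <- compare_ring_groups(med, sim$manifest)
    rd_names <- vapply(rdefs, function(r) r$epicenter_name, character(1))
    stats_tab$n_edges <- vapply(seq_len(nrow(stats_tab)), function(r) {
      rd <- rdefs[[match(stats_tab$epicenter[r], rd_names)]]
      nrow(if (stats_tab$ring[r] == "first") rd$first_ring_edges
           else rd$second_ring_edges)
    }, integer(1))
    internal <- epicenter_internal_comparison(sim$epi_r1, sim$manifest)
    utils::write.table(stats_tab, file.path(out_dir, "rings.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_json_report(
      list(ring_stats = stats_tab, epicenter_internal = internal,
           alpha = config$fdr_alpha),
      file.path(out_dir, "rings.json"))
    list(definitions = rdefs, medians = med, stats = stats_tab,
         internal = internal)
  })

  demo <- stage("demographics", {
    tab <- demographics_table(sim$manifest)
    utils::write.table(tab, file.path(out_dir, "demographics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  })

  write_json_report(
    list(package = "r1connectome",
         version = as.character(utils::packageVersion("r1connectome")),
         parameters = unclass(config)),
    file.path(out_dir, "run_manifest.json"))

  invisible(list(simulate = sim, consensus = cons, contrast = contrast,
                 behavioral = behavioral, rings = rings,
                 demographics = demo))
}
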