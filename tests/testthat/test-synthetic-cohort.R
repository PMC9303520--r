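test_that("manifest generation matches requested sizes, moments and determinism", {
  m <- generate_manifest(35, 59, 22, seed = 1)
  expect_equal(nrow(m), 116)
  expect_equal(as.vector(table(m$group)[c("HC", "PDnonRBD", "PDRBD")]),
               c(35, 59, 22))
  expect_true(all(m$age >= 35 & m$age <= 90))
  expect_true(all(m$sex %in% c("F", "M")))
  expect_true(all(m$hy[m$group == "HC"] == 0))
  expect_true(all(is.na(m$disease_duration_months[m$group == "HC"])))
  expect_true(all(is.finite(m$mmse)))
  expect_identical(m, generate_manifest(35, 59, 22, seed = 1))
  expect_false(identical(m$age, generate_manifest(35, 59, 22, seed = 2)$age))

  expect_equal(nrow(generate_manifest(0, 0, 0, seed = 1)), 0)
  expect_error(generate_manifest(-1, 0, 0, seed = 1), "nonnegative")
})

test_that("large-sample age mean approaches the configured group mean", {
  m <- generate_manifest(1000, 0, 0, seed = 2)
  # 3 SE of N(61.2, 9.16)/sqrt(1000) is ~0.87; 1.0 leaves truncation room
  expect_lt(abs(mean(m$age) - 61.2), 1.0)
  expect_gt(mean(m$sex == "F"), 12 / 35 - 0.05)
  expect_lt(mean(m$sex == "F"), 12 / 35 + 0.05)
})

test_that("template network honors density, connectivity and planted-edge placement", {
  tpl <- generate_template_network(n_nodes = 40, density = 0.2,
                                   epicenter_spec = list(E = c(0L, 1L)),
                                   n_affected_edges = 20,
                                   n_behavior_edges = 8, seed = 3)
  m <- nrow(tpl$edge_index)
  expect_equal(m, round(0.2 * 40 * 39 / 2))
  g <- igraph::graph_from_adjacency_matrix(
    (tpl$baseline_weight > 0) * 1, mode = "undirected")
  expect_true(igraph::is_connected(g))
  aff <- edge_index_from_mask(tpl$affected_mask)
  expect_equal(nrow(aff), 20)
  n_incident_avail <- sum(tpl$edge_index[, 1] %in% 0:1 |
                            tpl$edge_index[, 2] %in% 0:1)
  touches <- rowSums(cbind(aff[, 1] %in% 0:1, aff[, 2] %in% 0:1)) > 0
  expect_equal(sum(touches), min(20, n_incident_avail))
  w <- tpl$baseline_weight[tpl$baseline_weight > 0]
  expect_true(all(w >= 0.55 & w <= 1.15))

  cmpl <- generate_template_network(n_nodes = 10, density = 1,
                                    epicenter_spec = list(),
                                    n_affected_edges = 5,
                                    n_behavior_edges = 2, seed = 4)
  expect_equal(nrow(cmpl$edge_index), 45)

  t1 <- generate_template_network(seed = 9)
  t2 <- generate_template_network(seed = 9)
  expect_identical(t1$baseline_weight, t2$baseline_weight)
  expect_identical(t1$affected_mask, t2$affected_mask)

  expect_error(generate_template_network(n_nodes = 10, density = 0.5,
                                         epicenter_spec = list(E = 12L)),
               "node ids")
})

test_that("noise-free subject weights reproduce the multiplicative PD effect exactly", {
  tpl <- single_epicenter_template(seed = 12, n_nodes = 20, density = 0.4,
                                   n_affected = 8)
  mod <- effect_model(delta = 0.05, sigma_subject = 0, sigma_edge = 0,
                      seed = 1)
  pd <- generate_subject_edges(tpl, list(subject_id = "p1", group = "PDRBD"), mod)
  hc <- generate_subject_edges(tpl, list(subject_id = "h1", group = "HC"), mod)
  aff <- tpl$affected_mask
  pres <- tpl$presence_prob == 1
  expect_equal(pd$weights[aff & pres],
               0.95 * tpl$baseline_weight[aff & pres], tolerance = 1e-12)
  expect_equal(hc$weights[pres & tpl$baseline_weight > 0],
               tpl$baseline_weight[pres & tpl$baseline_weight > 0],
               tolerance = 1e-12)
  # PD effect only on affected edges
  unaff <- !aff & tpl$baseline_weight > 0 & pres
  expect_equal(pd$weights[unaff], tpl$baseline_weight[unaff],
               tolerance = 1e-12)
})

test_that("null cohorts (delta = 0) leave group labels exchangeable per edge", {
  tpl <- single_epicenter_template(seed = 13, n_nodes = 10, density = 0.6,
                                   n_affected = 5)
  mod <- effect_model(delta = 0, seed = 2)
  man <- generate_manifest(100, 100, 0, seed = 3)
  cns <- generate_cohort_connectomes(tpl, man, mod)
  ei <- tpl$edge_index
  X <- t(vapply(cns, function(cn) cn$weights[cbind(ei[, 1] + 1, ei[, 2] + 1)],
                numeric(nrow(ei))))
  is_hc <- man$group == "HC"
  p <- vapply(seq_len(ncol(X)), function(e)
    two_sample_t(X[is_hc, e], X[!is_hc, e])$p, numeric(1))
  # per-edge rejection close to alpha; loose binomial band over ~27 edges
  expect_lt(mean(p < 0.05), 0.2)
})

test_that("planted PD-minus-HC weight difference calibrates to -delta * baseline", {
  tpl <- single_epicenter_template(seed = 14, n_nodes = 15, density = 0.5,
                                   n_affected = 8)
  mod <- effect_model(delta = 0.05, seed = 4)
  man <- generate_manifest(200, 200, 0, seed = 5)
  cns <- generate_cohort_connectomes(tpl, man, mod)
  aff <- edge_index_from_mask(tpl$affected_mask)
  eidx <- cbind(aff[, 1] + 1, aff[, 2] + 1)
  A <- t(vapply(cns, function(cn) cn$weights[eidx], numeric(nrow(aff))))
  is_hc <- man$group == "HC"
  diff_mean <- mean(colMeans(A[!is_hc, ]) - colMeans(A[is_hc, ]))
  expected <- -0.05 * mean(tpl$baseline_weight[eidx])
  se <- sd(rowMeans(A)) * sqrt(1 / 200 + 1 / 200)
  expect_lt(abs(diff_mean - expected), 3 * se)
})

test_that("behavior scores are an exact affine readout in the noise-free case", {
  tpl <- single_epicenter_template(seed = 15, n_nodes = 12, density = 0.5,
                                   n_affected = 4)
  mod <- effect_model(delta = 0.05, sigma_subject = 0, sigma_edge = 0,
                      behavior_slope = 1, behavior_noise_sd = 0,
                      behavior_intercept = 10, seed = 6)
  man <- generate_manifest(2, 2, 0, seed = 7)
  cns <- generate_cohort_connectomes(tpl, man, mod)
  sc <- generate_behavior_scores(cns, tpl, mod)
  beh <- edge_index_from_mask(tpl$behavior_mask)
  eidx <- cbind(beh[, 1] + 1, beh[, 2] + 1)
  for (id in names(cns)) {
    deficit <- mean(tpl$baseline_weight[eidx] - cns[[id]]$weights[eidx])
    expect_equal(unname(sc[id]), 10 + deficit, tolerance = 1e-12)
  }
  # identical edge tables with zero noise give identical scores
  expect_equal(unname(sc[man$subject_id[man$group == "HC"][1]]),
               unname(sc[man$subject_id[man$group == "HC"][2]]),
               tolerance = 1e-12)
  tpl_nobeh <- tpl
  tpl_nobeh$behavior_mask[] <- FALSE
  expect_error(generate_behavior_scores(cns, tpl_nobeh, mod), "empty")
})

test_that("zero behavior slope decouples scores from edge weights", {
  tpl <- single_epicenter_template(seed = 16, n_nodes = 10, density = 0.6,
                                   n_affected = 4)
  mod <- effect_model(delta = 0, behavior_slope = 0, behavior_noise_sd = 5,
                      seed = 8)
  man <- generate_manifest(300, 0, 0, seed = 9)
  cns <- generate_cohort_connectomes(tpl, man, mod)
  sc <- generate_behavior_scores(cns, tpl, mod)
  ei <- tpl$edge_index
  X <- t(vapply(cns, function(cn) cn$weights[cbind(ei[, 1] + 1, ei[, 2] + 1)],
                numeric(nrow(ei))))
  r <- abs(cor(sc[rownames(X)], X))
  expect_lt(max(r), 0.2)
})

test_that("epicenter-internal R1 draws are deterministic and null by default", {
  man <- generate_manifest(10, 10, 0, seed = 10)
  mod <- effect_model(seed = 11)
  v1 <- generate_epicenter_r1(man, c("SN", "LC"), mod)
  v2 <- generate_epicenter_r1(man, c("SN", "LC"), mod)
  expect_identical(v1, v2)
  expect_true(all(v1$value > 0))
  mod2 <- effect_model(seed = 11)
  v3 <- generate_epicenter_r1(man, c("SN", "LC"), mod2, delta_epicenter = 0.1)
  pd_ids <- man$subject_id[man$group != "HC"]
  expect_equal(mean(v3$value[v3$subject_id %in% pd_ids]) /
                 mean(v1$value[v1$subject_id %in% pd_ids]), 0.9,
               tolerance = 1e-12)
})
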