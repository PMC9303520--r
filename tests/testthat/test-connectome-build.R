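phantom_fixture <- function(seed = 7) {
  tpl <- generate_template_network(n_nodes = 4, density = 1,
                                   epicenter_spec = list(),
                                   n_affected_edges = 0,
                                   n_behavior_edges = 0, seed = seed)
  list(tpl = tpl, ph = generate_phantom(tpl, c(24, 24, 24), seed = seed + 1))
}

test_that("streamline endpoints map to their constructed node pairs", {
  fx <- phantom_fixture()
  em <- assign_streamline_endpoints(fx$ph$streamlines, fx$ph$labels)
  expect_equal(em$n_discarded, 0)
  expect_equal(length(em$edges), nrow(fx$tpl$edge_index))
  keys <- sort(names(em$edges))
  want <- sort(paste0(fx$tpl$edge_index[, 1], "|", fx$tpl$edge_index[, 2]))
  expect_equal(keys, want)

  # reversing every streamline leaves the edge map unchanged
  rev_sl <- lapply(fx$ph$streamlines, function(s) s[nrow(s):1, ])
  em_rev <- assign_streamline_endpoints(rev_sl, fx$ph$labels)
  expect_equal(em_rev$edges[sort(names(em_rev$edges))],
               em$edges[sort(names(em$edges))])
})

test_that("streamlines with background or out-of-bounds endpoints are discarded", {
  fx <- phantom_fixture()
  labs <- fx$ph$labels
  # a free voxel (background) to end in
  bg <- which(labs == 0, arr.ind = TRUE)[1, ] - 1
  s_bg <- rbind(fx$ph$node_positions[1, ], as.numeric(bg))
  s_oob <- rbind(fx$ph$node_positions[1, ], c(500, 500, 500))
  expect_message(
    em <- assign_streamline_endpoints(list(s_bg, s_oob), labs),
    "out-of-bounds")
  expect_equal(em$n_assigned, 0)
  expect_equal(em$n_discarded, 2)
  expect_equal(em$n_out_of_bounds, 1)
})

test_that("volume sampling is exact on constants and monotone along a gradient", {
  vol <- array(0.8, c(6, 6, 6))
  v <- sample_metric_along_streamline(vol, rbind(c(0, 0, 0), c(5, 5, 5)))
  expect_true(all(v == 0.8))
  expect_gte(length(v), 2)

  half <- array(1, c(10, 4, 4))
  half[6:10, , ] <- 2
  v2 <- sample_metric_along_streamline(half, rbind(c(0, 1, 1), c(9, 1, 1)),
                                       step = 0.25)
  expect_true(all(diff(v2) >= -1e-12))
  expect_equal(v2[1], 1)
  expect_equal(v2[length(v2)], 2)

  expect_error(sample_metric_along_streamline(vol, rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero-length")
  expect_error(sample_metric_along_streamline(vol, rbind(c(1, 1, 1), c(2, 2, 2)),
                                              step = 0), "positive")
})

test_that("bundle weight follows the pooled-median convention", {
  expect_equal(compute_edge_weight(list(c(0.8, 1.0, 1.2))), 1.0)
  expect_equal(compute_edge_weight(list(1.0, 1.0, 3.0)), 1.0)
  expect_equal(compute_edge_weight(list(c(1.0, 2.0))), 1.5)
  # nested variant differs when streamline lengths are unbalanced
  sams <- list(c(1, 1, 1, 1), c(3))
  expect_equal(compute_edge_weight(sams), 1)
  expect_equal(compute_edge_weight(sams, method = "per_streamline"), 2)
  expect_error(compute_edge_weight(list()), "empty")
})

test_that("subject connectome recovers planted corridor medians and ignores order", {
  fx <- phantom_fixture()
  em <- assign_streamline_endpoints(fx$ph$streamlines, fx$ph$labels)
  cn <- build_subject_connectome(fx$ph$streamlines, em, fx$ph$r1,
                                 fx$tpl$nodes)
  ev <- fx$ph$edge_values
  for (r in seq_len(nrow(ev))) {
    expect_equal(cn$weights[ev$i[r] + 1, ev$j[r] + 1], ev$value[r],
                 tolerance = 1e-6)
  }
  expect_true(all(cn$present[cbind(ev$i + 1, ev$j + 1)]))

  # dense-resampling oracle: 10x finer step gives the same medians
  for (r in seq_len(nrow(ev))) {
    key <- paste0(ev$i[r], "|", ev$j[r])
    dense <- compute_edge_weight(lapply(em$edges[[key]], function(s)
      sample_metric_along_streamline(fx$ph$r1, fx$ph$streamlines[[s]],
                                     step = 0.05)))
    expect_equal(cn$weights[ev$i[r] + 1, ev$j[r] + 1], dense,
                 tolerance = 1e-6)
  }

  perm <- rev(seq_along(fx$ph$streamlines))
  em_p <- assign_streamline_endpoints(fx$ph$streamlines[perm], fx$ph$labels)
  cn_p <- build_subject_connectome(fx$ph$streamlines[perm], em_p, fx$ph$r1,
                                   fx$tpl$nodes)
  expect_equal(cn_p$weights, cn$weights)

  empty <- build_subject_connectome(list(), list(edges = list()),
                                    fx$ph$r1, fx$tpl$nodes)
  expect_false(any(empty$present))
})

test_that("consensus connectome applies the at-least rule with cross-subject medians", {
  n <- 3
  mk <- function(w01) connectome_from_edges(n, list(list(0, 1, w01),
                                                    list(0, 2, 1.0)))
  # edge 0-1 present in 2 of 5 subjects (0.4) -> dropped
  subs5 <- c(lapply(c(1.0, 1.2), mk), lapply(1:3, function(k)
    connectome_from_edges(n, list(list(0, 2, 1.0)))))
  g5 <- build_group_connectome(subs5, 0.5)
  expect_false(g5$present[1, 2])
  expect_true(g5$present[1, 3])

  # exactly 3 of 6 (0.5) retained with median of the present values
  subs6 <- c(lapply(c(1.0, 1.2, 1.4), mk), lapply(1:3, function(k)
    connectome_from_edges(n, list(list(0, 2, 1.0)))))
  g6 <- build_group_connectome(subs6, 0.5)
  expect_true(g6$present[1, 2])
  expect_equal(g6$weights[1, 2], 1.2)

  # retained edge set shrinks (or stays) as the threshold rises
  tpl <- single_epicenter_template(seed = 31, n_nodes = 12, density = 0.5,
                                   n_affected = 4)
  tpl$presence_prob[tpl$presence_prob == 1] <- 0.8
  mod <- effect_model(seed = 12)
  man <- generate_manifest(10, 10, 0, seed = 13)
  cns <- generate_cohort_connectomes(tpl, man, mod)
  dens <- vapply(c(0.3, 0.5, 0.8, 1.0), function(f)
    sum(build_group_connectome(cns, f)$present) / 2, numeric(1))
  expect_true(all(diff(dens) <= 0))

  expect_error(build_group_connectome(list()), "empty")
})

test_that("vectorization is ordered, invertible and marks absent edges", {
  cn <- connectome_from_edges(3, list(list(0, 1, 0.9), list(0, 2, 1.1),
                                      list(1, 2, 1.0)))
  ev <- vectorize_connectome(cn, all_node_pairs(3))
  expect_equal(ev$values, c(0.9, 1.1, 1.0))

  cn2 <- connectome_from_edges(3, list(list(0, 1, 0.9), list(1, 2, 1.0)))
  ev2 <- vectorize_connectome(cn2, all_node_pairs(3))
  expect_true(is.na(ev2$values[2]))
  back <- devectorize_connectome(ev2$values, ev2$edge_index, cn2$nodes)
  expect_equal(back$weights, cn2$weights)
  expect_equal(back$present, cn2$present)

  dup <- rbind(c(0L, 1L), c(0L, 1L))
  expect_error(vectorize_connectome(cn, dup), "duplicate")
})
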