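adj_from_edges <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  for (e in edges) {
    A[e[1] + 1, e[2] + 1] <- TRUE
    A[e[2] + 1, e[1] + 1] <- TRUE
  }
  A
}

test_that("ring definitions follow the direct / one-step-indirect rule", {
  # E(0)-A(1)-C(3), E(0)-B(2)-D(4)
  A <- adj_from_edges(5, list(c(0, 1), c(1, 3), c(0, 2), c(2, 4)))
  rd <- define_rings(A, 0L, "E")
  expect_equal(rd$first_ring_nodes, c(1L, 2L))
  expect_equal(rd$second_ring_nodes, c(3L, 4L))
  expect_equal(rd$first_ring_edges, rbind(c(0L, 1L), c(0L, 2L)))
  expect_equal(rd$second_ring_edges, rbind(c(1L, 3L), c(2L, 4L)))

  # complete graph: everyone is a direct neighbor, second ring empty
  K <- adj_from_edges(4, list(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(1, 3),
                              c(2, 3)))
  rdK <- define_rings(K, 0L)
  expect_equal(rdK$first_ring_nodes, 1:3)
  expect_equal(length(rdK$second_ring_nodes), 0)
  expect_equal(nrow(rdK$second_ring_edges), 0)

  # a node adjacent to both the epicenter and a first-ring node stays first
  A2 <- adj_from_edges(4, list(c(0, 1), c(0, 2), c(1, 2), c(2, 3)))
  rd2 <- define_rings(A2, 0L)
  expect_equal(rd2$first_ring_nodes, c(1L, 2L))
  expect_equal(rd2$second_ring_nodes, 3L)
  # 1-2 is an intra-first-ring edge: in neither ring edge set
  expect_false(any(rd2$first_ring_edges[, 1] == 1 &
                     rd2$first_ring_edges[, 2] == 2))
  expect_equal(rd2$second_ring_edges, rbind(c(2L, 3L)))

  # isolated epicenter: valid empty result, flagged
  A3 <- adj_from_edges(3, list(c(1, 2)))
  rd3 <- define_rings(A3, 0L)
  expect_equal(length(rd3$first_ring_nodes), 0)
  expect_match(rd3$note, "no neighbors")
})

test_that("ring node sets equal BFS depths 1 and 2 on random graphs", {
  set.seed(71)
  for (k in 1:30) {
    n <- sample(6:30, 1)
    A <- random_adjacency(n, p = runif(1, 0.1, 0.4))
    epi <- sample(0:(n - 1), sample(1:2, 1))
    rd <- define_rings(A, epi)
    ref <- oracle_rings_bfs(A, epi)
    expect_equal(rd$first_ring_nodes, ref$first)
    expect_equal(rd$second_ring_nodes, ref$second)
    # disjointness and edge-set consistency
    expect_equal(length(intersect(rd$first_ring_nodes,
                                  rd$second_ring_nodes)), 0)
    if (nrow(rd$first_ring_edges) && nrow(rd$second_ring_edges)) {
      k1 <- paste(rd$first_ring_edges[, 1], rd$first_ring_edges[, 2])
      k2 <- paste(rd$second_ring_edges[, 1], rd$second_ring_edges[, 2])
      expect_equal(length(intersect(k1, k2)), 0)
    }
  }
})

test_that("subject ring medians use present edges only and scale homogeneously", {
  cn <- connectome_from_edges(4, list(list(0, 1, 0.9), list(0, 2, 1.0),
                                      list(0, 3, 1.1)))
  ring <- rbind(c(0L, 1L), c(0L, 2L), c(0L, 3L))
  expect_equal(subject_ring_median(cn, ring), 1.0)

  cn2 <- connectome_from_edges(4, list(list(0, 1, 0.9), list(0, 3, 1.1)))
  expect_equal(subject_ring_median(cn2, ring), 1.0)  # absent edge dropped

  cn3 <- connectome_from_edges(4, list(list(0, 1, 1.8), list(0, 2, 2.0),
                                       list(0, 3, 2.2)))
  expect_equal(subject_ring_median(cn3, ring),
               2 * subject_ring_median(cn, ring))

  expect_warning(v <- subject_ring_median(cn, ring[0, , drop = FALSE]),
                 "empty ring")
  expect_true(is.na(v))
  cn4 <- connectomes <- connectome_from_edges(4, list(list(1, 2, 1.0)))
  expect_warning(v4 <- subject_ring_median(cn4, ring), "no ring edge")
  expect_true(is.na(v4))
})

test_that("reference adjacency follows the pooled consensus rule", {
  cn_a <- connectome_from_edges(3, list(list(0, 1, 1.0), list(1, 2, 1.0)))
  cn_b <- connectome_from_edges(3, list(list(0, 1, 1.1)))
  adj <- derive_reference_adjacency(list(cn_a, cn_a, cn_a))
  expect_equal(adj, cn_a$present, ignore_attr = TRUE)
  # edge 1-2 in 1 of 3 subjects (33%) < 50% -> excluded; 0-1 (3 of 3) kept
  adj2 <- derive_reference_adjacency(list(cn_a, cn_b, cn_b))
  expect_true(adj2[1, 2])
  expect_false(adj2[2, 3])
  expect_true(isSymmetric(adj2))
  expect_true(all(diag(adj2) == FALSE))
})

test_that("ring ANCOVA matches the brute-force nested-model F and controls the null", {
  tpl <- single_epicenter_template(seed = 81)
  mod <- effect_model(delta = 0.05, seed = 82)
  man <- generate_manifest(35, 59, 22, seed = 83)
  cns <- generate_cohort_connectomes(tpl, man, mod)
  adj <- derive_reference_adjacency(cns)
  rd <- define_rings(adj, tpl$epicenters$SN, "SN")
  med <- ring_subject_medians(cns, list(rd))
  st <- compare_ring_groups(med, man)

  sub <- merge(med[med$ring == "first", ], man, by = "subject_id")
  ref <- oracle_ancova_F(sub$value, ifelse(sub$group == "HC", "HC", "PD"),
                         cbind(sub$age, as.integer(sub$sex == "M")))
  expect_equal(st$F[st$ring == "first"], ref$F, tolerance = 1e-8)
  expect_equal(st$p[st$ring == "first"], ref$p, tolerance = 1e-8)
  expect_true(all(st$q >= st$p))

  # planted first-ring effect: first ring significant, second not
  expect_lt(st$q[st$ring == "first"], 0.05)
  expect_gt(st$q[st$ring == "second"], 0.05)

  # shuffled labels behave as a null
  set.seed(84)
  rej <- replicate(60, {
    man_s <- man
    man_s$group <- sample(man$group)
    s <- compare_ring_groups(med, man_s)
    s$p[s$ring == "first"] < 0.05
  })
  expect_lt(mean(rej), 0.18)
})

test_that("epicenter-internal comparison is a two-sample t with sign symmetry", {
  man <- generate_manifest(20, 20, 0, seed = 91)
  vals <- data.frame(subject_id = rep(man$subject_id, 2),
                     epicenter = rep(c("SN", "LC"), each = nrow(man)),
                     value = rnorm(2 * nrow(man), 0.9, 0.02))
  out <- epicenter_internal_comparison(vals, man)
  expect_equal(sort(out$epicenter), c("LC", "SN"))
  expect_true(all(out$p >= 0 & out$p <= 1))

  # identical distributions give t = 0
  v2 <- vals
  ref_vals <- rnorm(nrow(man) / 2 * 0 + 20, 0.9, 0.02)
  v2$value[v2$epicenter == "SN"] <- rep(ref_vals, length.out = nrow(man))
  hc_ids <- man$subject_id[man$group == "HC"]
  pd_ids <- man$subject_id[man$group != "HC"]
  v2$value[v2$epicenter == "SN" & v2$subject_id %in% pd_ids] <-
    v2$value[v2$epicenter == "SN" & v2$subject_id %in% hc_ids]
  out2 <- epicenter_internal_comparison(v2, man)
  expect_equal(out2$t[out2$epicenter == "SN"], 0, tolerance = 1e-12)

  # swapping the group labels flips the sign of t
  man_sw <- man
  man_sw$group <- ifelse(man$group == "HC", "PDnonRBD", "HC")
  out_sw <- epicenter_internal_comparison(vals, man_sw)
  expect_equal(out_sw$t, -out$t, tolerance = 1e-12)

  # a planted within-epicenter effect is detected at large n
  man_big <- generate_manifest(150, 150, 0, seed = 92)
  mod <- effect_model(seed = 93)
  v_eff <- generate_epicenter_r1(man_big, "SN", mod, delta_epicenter = 0.03)
  out_eff <- epicenter_internal_comparison(v_eff, man_big)
  expect_lt(out_eff$p, 0.001)
})
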