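# Independent oracles: hand-rolled reference computations kept separate
# from the implementation paths they check.

# BH step-up by its textbook definition: sort p ascending, q_(k) is the
# minimum over j >= k of n * p_(j) / j, clipped to 1, mapped back.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sp <- p[o]
  q <- numeric(n)
  for (k in seq_len(n)) {
    q[k] <- min(1, min(n * sp[k:n] / (k:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Kruskal-Wallis H from the rank formula with tie correction.
oracle_kw_H <- function(samples) {
  x <- unlist(samples)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(rr) length(rr) * (mean(rr) - (N + 1) / 2)^2))
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Pooled-variance two-sample t from the closed form.
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tt, p = 2 * pt(-abs(tt), df))
}

# ANCOVA group F as a full-vs-reduced model comparison via lm()/anova().
oracle_ancova_F <- function(y, group, covariates = NULL) {
  d <- data.frame(y = y, group = factor(group))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0("c", seq_along(covariates))
    d <- cbind(d, covariates)
    f_red <- stats::as.formula(paste("y ~", paste(names(covariates), collapse = "+")))
    f_full <- stats::as.formula(paste("y ~", paste(names(covariates), collapse = "+"), "+ group"))
  } else {
    f_red <- y ~ 1
    f_full <- y ~ group
  }
  a <- anova(lm(f_red, d), lm(f_full, d))
  list(F = a$F[2], p = a$`Pr(>F)`[2])
}

# Chi-square closed form for a 2x2 table.
oracle_chi2_2x2 <- function(tab) {
  N <- sum(tab)
  num <- N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  chi <- num / den
  list(chi2 = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# Ring membership by BFS depth from the epicenter set (igraph shortest
# paths): depth-1 nodes form the first ring, depth-2 the second.
oracle_rings_bfs <- function(adjacency, epicenter_nodes) {
  g <- igraph::graph_from_adjacency_matrix(adjacency * 1, mode = "undirected")
  d <- igraph::distances(g, v = epicenter_nodes + 1)
  depth <- apply(d, 2, min)
  list(first = sort(which(depth == 1) - 1L),
       second = sort(which(depth == 2) - 1L))
}

# Pearson r from the covariance formula.
oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

jaccard_pairs <- function(a, b) {
  ka <- paste(a[, 1], a[, 2]); kb <- paste(b[, 1], b[, 2])
  length(intersect(ka, kb)) / length(union(ka, kb))
}
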