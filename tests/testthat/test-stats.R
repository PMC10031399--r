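test_that("Kruskal-Wallis matches the textbook hand computation", {
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # identical value multisets in two groups: perfectly symmetric ranks
  kw0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(kw0$statistic, 0)
  # fully tied data: the tie-corrected denominator vanishes, H defined 0
  kwt <- kruskal_wallis(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(kwt$statistic, 0)
  expect_equal(kwt$p_value, 1)

  expect_error(kruskal_wallis(1:4, rep("a", 4)), "two groups")
  expect_error(kruskal_wallis(1:4, factor(rep("a", 4), levels = c("a", "b"))),
               "at least one observation")
})

test_that("tie-corrected KW agrees with stats::kruskal.test on tied data", {
  set.seed(29)
  for (k in 1:20) {
    x <- sample(1:6, 24, replace = TRUE)  # heavy ties
    g <- sample(rep(c("a", "b", "c"), each = 8))
    kw <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("KW is calibrated: null rejection rate near alpha (3 groups of 10)", {
  set.seed(31)
  g <- rep(c("a", "b", "c"), each = 10)
  rej <- vapply(seq_len(2000), function(i) {
    kruskal_wallis(rnorm(30), g)$p_value < 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("Dunn z matches the hand formula and degenerates sensibly", {
  tab <- dunn_posthoc(1:9, rep(c("g1", "g2", "g3"), each = 3))
  row <- tab[tab$group_a == "g1" & tab$group_b == "g3", ]
  expect_equal(abs(row$z_statistic), 6 / sqrt(5), tolerance = 1e-12)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adjusted >= tab$p_raw))

  same <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_raw, 1)
})

test_that("Dunn p-values agree with a permutation reference", {
  set.seed(37)
  x <- c(2.1, 5.3, 3.3, 7.8, 6.1, 9.0, 4.4, 8.2, 1.7, 5.9, 7.1, 3.9)
  g <- rep(c("a", "b", "c"), each = 4)
  tab <- dunn_posthoc(x, g)
  for (i in seq_len(nrow(tab))) {
    p_perm <- perm_dunn_p(x, g, tab$group_a[i], tab$group_b[i], n_perm = 4000)
    se <- sqrt(p_perm * (1 - p_perm) / 4000) + 1e-3
    expect_lt(abs(tab$p_raw[i] - p_perm), max(3 * se, 0.05))
  }
})

test_that("Holm adjustment follows the step-down recipe", {
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.02)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (k in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_identical(adj, stats::p.adjust(p, "holm"))  # independent oracle
    expect_true(all(adj >= p))
    # Holm is uniformly at least as powerful as Bonferroni
    expect_true(all(adj <= stats::p.adjust(p, "bonferroni") + 1e-15))
  }
})

test_that("compact letters cover the canonical cases", {
  groups <- c("A", "B", "C")
  none_sig <- data.frame(group_a = c("A", "A", "B"),
                         group_b = c("B", "C", "C"),
                         significant = FALSE)
  expect_equal(unname(compact_letters(none_sig, groups)), rep("a", 3))

  all_sig <- transform(none_sig, significant = TRUE)
  expect_equal(sort(unname(compact_letters(all_sig, groups))),
               c("a", "b", "c"))

  chain <- transform(none_sig, significant = c(FALSE, TRUE, FALSE))
  expect_equal(unname(compact_letters(chain, groups)), c("a", "ab", "b"))

  expect_error(compact_letters(none_sig[-2, ], groups), "missing")
})

test_that("letter displays satisfy the share-iff-not-significant invariant", {
  set.seed(43)
  for (k in 1:30) {
    n_groups <- sample(3:6, 1)
    groups <- LETTERS[seq_len(n_groups)]
    pairs <- t(combn(groups, 2))
    cmp <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                      significant = runif(nrow(pairs)) < 0.4)
    expect_true(letters_consistent(compact_letters(cmp, groups), cmp))
  }
})

test_that("Spearman correlation matches rank-formula and cor.test oracles", {
  x <- c(3.1, 4.7, 0.2, 9.9, 5.5, 6.1, 2.2, 8.8, 7.0, 1.3)
  y <- c(1.0, 5.2, 0.8, 9.1, 4.4, 7.7, 3.3, 6.6, 8.0, 2.1)
  sc <- spearman_correlation(x, y)
  # definitional: Pearson on ranks
  expect_equal(sc$r_s, cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(sc$r_s, unname(ref$estimate), tolerance = 1e-12)

  expect_equal(spearman_correlation(1:5, c(2, 4, 6, 8, 10))$r_s, 1)
  expect_equal(spearman_correlation(1:5, 5:1)$r_s, -1)
  expect_equal(spearman_correlation(1:5, c(2, 4, 6, 8, 10))$p_value, 0)
  expect_error(spearman_correlation(1:5, rep(1, 5)), "zero variance")
  expect_error(spearman_correlation(1:2, 1:2), "length >= 3")
})

test_that("independent subset keeps one system per sharing cluster", {
  # no sharing: everything retained
  sys <- pig_systems(make_systems_df(5))
  expect_equal(nrow(independent_subset(sys, seed = 1)), 5)

  # two systems share a breeding farm: 4 of 5 retained
  df <- make_systems_df(5)
  df$breeding_farm_id[2] <- df$breeding_farm_id[1]
  sub <- independent_subset(pig_systems(df), seed = 1)
  expect_equal(nrow(sub), 4)
  expect_equal(attr(sub, "n_clusters"), 4)

  # transitive cluster via breeding then rearing links
  df <- make_systems_df(3)
  df$breeding_farm_id[2] <- df$breeding_farm_id[1]
  df$rearing_farm_id[2:3] <- "R_shared"
  sub <- independent_subset(pig_systems(df), seed = 5)
  expect_equal(nrow(sub), 1)

  # deterministic under a fixed seed
  df <- make_systems_df(6)
  df$breeding_farm_id[1:3] <- "B_shared"
  sys <- pig_systems(df)
  expect_identical(independent_subset(sys, seed = 9),
                   independent_subset(sys, seed = 9))
})

test_that("cluster counts equal igraph connected components (oracle)", {
  skip_if_not_installed("igraph")
  set.seed(47)
  for (k in 1:15) {
    n <- sample(6:20, 1)
    df <- make_systems_df(n)
    df$breeding_farm_id <- sprintf("B%02d", sample(ceiling(n / 2), n,
                                                   replace = TRUE))
    df$rearing_farm_id <- ifelse(runif(n) < 0.5, NA_character_,
                                 sprintf("R%02d", sample(ceiling(n / 3), n,
                                                         replace = TRUE)))
    sub <- independent_subset(pig_systems(df), seed = k)
    # oracle: bipartite system-farm graph, components among system vertices
    edges <- c(rbind(df$system_id, paste0("bf:", df$breeding_farm_id)))
    has_r <- !is.na(df$rearing_farm_id)
    edges <- c(edges, c(rbind(df$system_id[has_r],
                              paste0("rf:", df$rearing_farm_id[has_r]))))
    gr <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                      directed = FALSE)
    memb <- igraph::components(gr)$membership
    n_comp <- length(unique(memb[df$system_id]))
    expect_equal(nrow(sub), n_comp)
  }
})

test_that("rank-correlation matrix is symmetric with unit diagonal", {
  sys <- pig_systems(make_systems_df(4, sp_health = c(10, 40, 60, 90)))
  g <- metric_grid(sys, canonical_metric_grid("standard"))
  wq <- stats::setNames(overall_wq_of(sys), sys$system_id)
  rc <- rank_correlation_matrix(g, wq)
  expect_equal(dim(rc$r_s), c(11, 11))  # 10 transitions + overall WQ
  expect_equal(unname(diag(rc$r_s)), rep(1, 11))
  expect_equal(rc$r_s, t(rc$r_s))
  expect_true(all(rc$r_s["overall_wq", colnames(rc$r_s) != "overall_wq"] < 0))

  expect_error(rank_correlation_matrix(g[-1, ], wq), "missing")
  expect_error(rank_correlation_matrix(g, unname(wq)), "named")
})

test_that("weighting comparison detects shifts and nothing else", {
  sys <- pig_systems(make_systems_df(8, sp_health = round(seq(5, 95, length.out = 8))))
  g <- metric_grid(sys)
  # identical costs across weightings: H = 0, p = 1
  g_same <- g
  for (wn in c("equal", "extreme")) {
    src <- g$cost[g$metric_id == "T100/standard"]
    g_same$cost[g_same$metric_id == paste0("T100/", wn)] <- src
  }
  same <- compare_weightings(g_same)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # one weighting shifted by a large constant: clearly significant
  g_shift <- g
  g_shift$cost[g_shift$metric_id == "T100/extreme"] <-
    g_shift$cost[g_shift$metric_id == "T100/extreme"] + 100
  expect_lt(compare_weightings(g_shift)$p_value, 0.01)
  expect_error(compare_weightings(g[g$metric_id == "T100/standard", ]),
               "two weighting")
})
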