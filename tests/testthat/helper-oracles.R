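# Independent oracles, written separately from the package code paths they
# check: an explicit 8-term welfare-cost summation, permutation references
# for the rank tests, and a brute-force letter-display checker.

# Eq.-style welfare cost, term by term. Own flag logic, own classification.
oracle_welfare_cost <- function(sp, fp, w, y_sp, y_fp,
                                kind, threshold = NULL, level = NULL) {
  meets_class <- function(p, lvl) {
    exc <- sum(p >= 55) == 4 && sum(p >= 80) >= 2
    enh <- sum(p >= 20) == 4 && sum(p >= 55) >= 2
    if (lvl == "excellent") exc else enh
  }
  stage_flags <- function(p) {
    if (kind == "numeric") p >= threshold
    else if (kind == "classification") rep(meets_class(p, level), 4)
    else c(FALSE, FALSE, TRUE, FALSE)  # behaviour is principle 3
  }
  total <- 0
  for (stage in c("sp", "fp")) {
    p <- if (stage == "sp") sp else fp
    y <- if (stage == "sp") y_sp else y_fp
    fl <- stage_flags(p)
    for (i in 1:4) {
      total <- total + if (fl[i]) -p[i] * w[i] * y else (100 - p[i]) * w[i] * y
    }
  }
  unname(total)
}

# Random single-system inputs for property tests (independent of the
# synthetic_farms generator).
random_metric_case <- function() {
  list(sp = runif(4, 0, 100), fp = runif(4, 0, 100),
       y_sp = runif(1, 1e-4, 5e-3), y_fp = runif(1, 1e-3, 1e-2))
}

# Two-sided permutation p-value for the Kruskal-Wallis statistic.
perm_kw_p <- function(values, groups, n_perm = 20000) {
  groups <- factor(groups)
  obs <- kruskal_wallis(values, groups)$statistic
  hits <- 0
  for (b in seq_len(n_perm)) {
    h <- kruskal_wallis(values, sample(groups))$statistic
    if (h >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# Permutation p-value for one Dunn pairwise z (two-sided, |z| as statistic).
perm_dunn_p <- function(values, groups, a, b, n_perm = 20000) {
  groups <- factor(groups)
  z_of <- function(g) {
    tab <- dunn_posthoc(values, g)
    row <- (tab$group_a == a & tab$group_b == b) |
      (tab$group_a == b & tab$group_b == a)
    abs(tab$z_statistic[row])
  }
  obs <- z_of(groups)
  hits <- 0
  for (k in seq_len(n_perm)) {
    if (z_of(sample(groups)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# LetterDisplay invariant: groups share a letter iff not significantly
# different.
letters_consistent <- function(letters, comparisons) {
  share <- function(a, b) {
    length(intersect(strsplit(letters[[a]], "")[[1]],
                     strsplit(letters[[b]], "")[[1]])) > 0
  }
  all(vapply(seq_len(nrow(comparisons)), function(i) {
    a <- comparisons$group_a[i]; b <- comparisons$group_b[i]
    share(a, b) == !comparisons$significant[i]
  }, logical(1)))
}
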