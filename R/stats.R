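# Nonparametric robustness machinery: tie-corrected Kruskal-Wallis, Dunn's
# post hoc z tests with Holm adjustment, compact letter displays, Spearman
# rank correlation and independent-subset selection over shared-farm
# clusters.

check_grouped <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0L)) {
    stop("every group must have at least one observation", call. = FALSE)
  }
  if (nlevels(groups) < 2L) {
    stop("omnibus tests require at least two groups", call. = FALSE)
  }
  groups
}

# Sum of (t^3 - t) over tied value groups, the shared tie-correction term.
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank sum test (tie-corrected)
#'
#' Omnibus test for a location difference among k groups, computed on
#' midranks with the standard tie correction
#' `H = [12 / (N (N + 1)) * sum R_j^2 / n_j - 3 (N + 1)] / (1 - sum(t^3 - t) / (N^3 - N))`
#' and referred to the chi-squared distribution with `k - 1` degrees of
#' freedom. Data in which every observation is tied (vanishing tie-corrected
#' denominator) are defined to give `H = 0`, `p = 1`.
#'
#' @param values Numeric vector of observations (welfare costs, WQ scores,
#'   life-years, ...).
#' @param groups Grouping vector (label types, husbandry types, ...), same
#'   length as `values`; coerced to factor.
#' @return List with `statistic` (H), `df`, `p_value`, and `n`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(c("a", "b", "c"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_grouped(values, groups)
  n <- length(values)
  r <- rank(values)
  rank_sums <- tapply(r, groups, sum)
  sizes <- tapply(r, groups, length)
  h_raw <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  correction <- 1 - tie_term(r) / (n^3 - n)
  h <- if (correction <= 0) 0 else h_raw / correction
  df <- nlevels(groups) - 1L
  list(statistic = h, df = df,
       p_value = stats::pchisq(h, df = df, lower.tail = FALSE),
       n = n)
}

#' Dunn's post hoc pairwise comparisons with Holm adjustment
#'
#' Follows a Kruskal-Wallis test with all pairwise z tests on group mean
#' ranks, using the pooled midranks of the full sample and the tie-corrected
#' variance:
#' `z_ab = (meanrank_a - meanrank_b) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_a + 1/n_b))`.
#' Two-sided p-values come from the standard normal and are adjusted across
#' the family of all pairwise comparisons with [holm_adjust()].
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return Data frame with one row per unordered group pair: `group_a`,
#'   `group_b`, `z_statistic`, `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- check_grouped(values, groups)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  var_unit <- n * (n + 1) / 12 - tie_term(r) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(var_unit * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- if (se > 0) (mean_ranks[[a]] - mean_ranks[[b]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- holm_adjust(p)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             z_statistic = z, p_raw = p, p_adjusted = p_adj,
             significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Holm step-down p-value adjustment
#'
#' Sort the m raw p-values ascending, multiply the i-th smallest by
#' `m - i + 1`, enforce a running maximum, cap at 1 and restore the input
#' order. Uniformly at least as powerful as Bonferroni while controlling the
#' family-wise error rate.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, in input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.02))  # 0.03 0.04 0.04
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  ord <- order(p_values)
  adj <- pmin(1, cummax(p_values[ord] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compact letter display from pairwise comparisons
#'
#' Encodes a set of pairwise significance results as letters over the groups
#' (the letters printed above boxplots): two groups share at least one letter
#' if and only if they are *not* significantly different. Uses the
#' insert-and-absorb construction: starting from one letter covering all
#' groups, each significant pair splits the letters containing both members,
#' and redundant letters (whose group set is contained in another's) are
#' absorbed. Deterministic given the group ordering.
#'
#' @param comparisons Data frame as returned by [dunn_posthoc()]; must cover
#'   every pair of `groups`.
#' @param groups Character vector of group names, in display order.
#' @return Named character vector mapping each group to its letter string.
#' @export
compact_letters <- function(comparisons, groups) {
  groups <- as.character(groups)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  have <- key(comparisons$group_a, comparisons$group_b)
  need <- utils::combn(groups, 2)
  need_keys <- key(need[1, ], need[2, ])
  if (!all(need_keys %in% have)) {
    stop("comparisons must cover all group pairs; missing: ",
         paste(gsub("\r", " vs ", setdiff(need_keys, have)), collapse = ", "),
         call. = FALSE)
  }
  sig <- comparisons$significant[match(need_keys, have)]

  # columns = letters, as logical membership vectors over groups
  cols <- list(rep(TRUE, length(groups)))
  for (k in which(sig)) {
    a <- match(need[1, k], groups); b <- match(need[2, k], groups)
    for (j in seq_along(cols)) {
      col <- cols[[j]]
      if (col[a] && col[b]) {
        col_a <- col; col_a[b] <- FALSE
        col_b <- col; col_b[a] <- FALSE
        cols[[j]] <- col_a
        cols[[length(cols) + 1L]] <- col_b
      }
    }
    # absorb columns contained in another column
    keep <- rep(TRUE, length(cols))
    for (j in seq_along(cols)) {
      for (l in seq_along(cols)) {
        if (j != l && keep[j] && keep[l] && all(cols[[j]] <= cols[[l]]) &&
            !identical(cols[[j]], cols[[l]])) {
          keep[j] <- FALSE
        }
      }
    }
    # drop exact duplicates too
    cols <- unique(cols[keep])
  }
  letters_seq <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_along(groups), function(i) {
    paste(letters_seq[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the p-value from the t
#' approximation `t = r_s sqrt((n - 2) / (1 - r_s^2))` on `n - 2` degrees of
#' freedom (p = 0 when `|r_s| = 1`).
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `r_s`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  }
  r_s <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(r_s) >= 1) 0 else {
    t_stat <- r_s * sqrt((n - 2) / (1 - r_s^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r_s = r_s, p_value = p, n = n)
}

#' Independent subset over shared breeding/rearing farms
#'
#' Systems that share a breeding and/or rearing farm are not independent data
#' points. This builds the graph linking systems that share a breeding or
#' rearing farm identifier, takes its connected components as clusters, and
#' retains exactly one uniformly-random system per cluster. Systems with no
#' sharing form singleton clusters and are always retained.
#'
#' @param systems A [pig_systems()] table (or any data frame with
#'   `breeding_farm_id` and `rearing_farm_id` columns; `NA` rearing ids mean
#'   no rearing farm).
#' @param seed Integer seed for the random within-cluster selection; recorded
#'   in the result's `"seed"` attribute.
#' @return The retained subset of `systems` (one row per cluster), with
#'   attributes `"seed"` and `"n_clusters"`.
#' @export
independent_subset <- function(systems, seed = NULL) {
  comp <- sharing_components(systems)
  rows <- if (is.null(seed)) {
    vapply(split(seq_len(nrow(systems)), comp), function(idx) {
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }, integer(1))
  } else {
    withr_seed(seed, vapply(split(seq_len(nrow(systems)), comp), function(idx) {
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }, integer(1)))
  }
  out <- systems[sort(rows), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "n_clusters") <- max(comp)
  out
}

# Evaluate expr under a local RNG state seeded with seed.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Connected components of the shared-farm graph, via union-find.
# Returns an integer component index per row, numbered by first appearance.
sharing_components <- function(systems) {
  n <- nrow(systems)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (col in c("breeding_farm_id", "rearing_farm_id")) {
    ids <- as.character(systems[[col]])
    ok <- !is.na(ids) & nzchar(ids)
    for (idx in split(which(ok), ids[ok])) {
      if (length(idx) > 1L) for (j in idx[-1]) union_(idx[1], j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Spearman correlation matrix of system rankings across metric variants
#'
#' Quantifies how robust the ranking of systems is to the choice of
#' welfare-cost metric: pairwise Spearman correlations between the per-system
#' costs of every metric variant, plus a column against the overall WQ score.
#' Because high WQ scores indicate good welfare while high costs indicate
#' poor welfare, the WQ column is expected to be negative throughout.
#'
#' @param grid Output of [metric_grid()] (must contain every system for every
#'   metric).
#' @param overall_wq Optional named numeric vector of overall WQ scores,
#'   names matching `system_id`.
#' @return List with matrices `r_s` and `p_value` (metrics x metrics, plus an
#'   `overall_wq` row/column when supplied); symmetric with unit diagonal.
#' @export
rank_correlation_matrix <- function(grid, overall_wq = NULL) {
  wide <- cost_matrix(grid)
  if (!is.null(overall_wq)) {
    if (is.null(names(overall_wq))) {
      stop("overall_wq must be named by system_id", call. = FALSE)
    }
    if (!all(rownames(wide) %in% names(overall_wq))) {
      stop("overall_wq is missing systems present in the grid", call. = FALSE)
    }
    wide <- cbind(wide, overall_wq = overall_wq[rownames(wide)])
  }
  k <- ncol(wide)
  r_s <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r_s) <- dimnames(p) <- list(colnames(wide), colnames(wide))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sc <- spearman_correlation(wide[, i], wide[, j])
      r_s[i, j] <- r_s[j, i] <- sc$r_s
      p[i, j] <- p[j, i] <- sc$p_value
    }
  }
  list(r_s = r_s, p_value = p)
}

# Long metric grid -> systems x metrics matrix, erroring on missing cells.
cost_matrix <- function(grid) {
  ids <- unique(grid$system_id)
  metrics <- unique(grid$metric_id)
  wide <- matrix(NA_real_, length(ids), length(metrics),
                 dimnames = list(ids, metrics))
  wide[cbind(match(grid$system_id, ids), match(grid$metric_id, metrics))] <-
    grid$cost
  if (anyNA(wide)) {
    stop("metric grid has missing system x metric cells", call. = FALSE)
  }
  wide
}

#' Sensitivity of welfare costs to the principle weighting
#'
#' Kruskal-Wallis test with the weighting scheme as the grouping factor over
#' per-system costs at a fixed transition, asking whether the choice among
#' standard/equal/extreme weightings shifts the cost distribution.
#'
#' @param grid Output of [metric_grid()].
#' @param transition_label Transition prefix selecting the metric variants to
#'   compare (e.g. `"T100"`, `"enhanced"`, `"behaviour"`); default `"T100"`.
#' @return As [kruskal_wallis()].
#' @export
compare_weightings <- function(grid, transition_label = "T100") {
  sel <- grid[startsWith(grid$metric_id, paste0(transition_label, "/")), ]
  weighting <- sub("^.*/", "", sel$metric_id)
  if (length(unique(weighting)) < 2L) {
    stop("need at least two weighting variants at transition '",
         transition_label, "'", call. = FALSE)
  }
  kruskal_wallis(sel$cost, weighting)
}
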