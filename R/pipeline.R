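# End-to-end analysis: life-years accounting -> overall WQ scores -> metric
# grid -> independent subset -> group tests and rank-robustness summary.

#' Run the full welfare-cost analysis pipeline
#'
#' Executes, in order: production accounting ([life_years_per_kg()]), overall
#' WQ scoring ([overall_wq_score()], standard weighting), the welfare-cost
#' metric grid ([metric_grid()]), independent-subset selection over shared
#' breeding/rearing farms ([independent_subset()]), and the robustness
#' statistics ([kruskal_wallis()], [dunn_posthoc()], [compact_letters()],
#' [rank_correlation_matrix()], [compare_weightings()]). Metric and score
#' tables cover all systems; inferential statistics are computed on the
#' independent subset only (one system per shared-farm cluster), since
#' systems sharing farms are not independent data points. Grouping factors
#' with fewer than two levels in the subset are skipped with a notice.
#'
#' @param systems A [pig_systems()] table (>= 2 systems for the statistics
#'   stages).
#' @param specs Metric grid to evaluate; default the canonical 30 variants.
#' @param alpha Significance level for post hoc flags (default 0.05).
#' @param seed Integer seed for the random within-cluster selection.
#' @param subset Logical; set `FALSE` to compute statistics on all systems
#'   (e.g. when no farms are shared).
#' @param mode Mortality assumption for the accounting stage.
#' @return A results bundle: list with `systems`, `life_years`, `overall_wq`
#'   (named vector), `grid`, `subset_ids`, `group_tests` (per grouping factor
#'   and response: omnibus result, pairwise table, letter display),
#'   `rank_correlations`, `weighting_sensitivity`,
#'   `quality_lifeyears` (WQ vs total life-years association, Pearson and
#'   Spearman), `notices`, and `meta` (seed, alpha, counts, package version).
#' @export
run_pipeline <- function(systems, specs = canonical_metric_grid(),
                         alpha = 0.05, seed = 1L, subset = TRUE,
                         mode = "average_slaughter_age") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  notices <- character(0)

  ly <- stage("production_accounting", life_years_per_kg(systems, mode = mode))
  wq <- stage("wq_aggregation", {
    scores <- overall_wq_score(as_score_matrix(systems, "sp"),
                               as_score_matrix(systems, "fp"),
                               t_sp = ly$t_sp)
    names(scores) <- as.character(systems$system_id)
    scores
  })
  grid <- stage("metric_family", metric_grid(systems, specs, mode = mode))

  sub <- if (subset) {
    stage("independent_subset", independent_subset(systems, seed = seed))
  } else systems
  sub_ids <- as.character(sub$system_id)
  if (nrow(sub) < 2L) {
    stop("pipeline stage 'stats_robustness': need >= 2 systems", call. = FALSE)
  }
  sub_grid <- grid[grid$system_id %in% sub_ids, , drop = FALSE]
  sub_ly <- ly[match(sub_ids, as.character(systems$system_id)), , drop = FALSE]

  responses <- c(list(overall_wq = wq[sub_ids],
                      lifeyears_sp = stats::setNames(sub_ly$y_sp, sub_ids),
                      lifeyears_fp = stats::setNames(sub_ly$y_fp, sub_ids)),
                 lapply(split(sub_grid, sub_grid$metric_id), function(g) {
                   stats::setNames(g$cost, g$system_id)[sub_ids]
                 }))
  groupings <- list(
    label = stats::setNames(as.character(sub$assigned_label), sub_ids),
    breeding_husbandry = stats::setNames(as.character(sub$breeding_husbandry),
                                         sub_ids),
    finishing_husbandry = stats::setNames(as.character(sub$finishing_husbandry),
                                          sub_ids))

  group_tests <- list()
  for (gname in names(groupings)) {
    gr <- groupings[[gname]]
    if (length(unique(gr)) < 2L) {
      notices <- c(notices, paste0(
        "omnibus tests by ", gname,
        " skipped: fewer than two groups in the analysis set"))
      next
    }
    for (rname in names(responses)) {
      om <- kruskal_wallis(responses[[rname]], gr)
      pw <- dunn_posthoc(responses[[rname]], gr, alpha = alpha)
      group_tests[[paste(gname, rname, sep = ".")]] <- list(
        grouping = gname, response = rname, omnibus = om, pairwise = pw,
        letters = compact_letters(pw, sort(unique(gr))))
    }
  }

  rank_cor <- stage("stats_robustness",
                    rank_correlation_matrix(sub_grid, wq[sub_ids]))
  weighting_sens <- tryCatch(compare_weightings(sub_grid),
                             error = function(e) NULL)

  y_total <- stats::setNames(sub_ly$y_sp + sub_ly$y_fp, sub_ids)
  quality_lifeyears <- if (stats::sd(y_total) == 0 ||
                           stats::sd(wq[sub_ids]) == 0) {
    notices <- c(notices, paste0(
      "quality/life-years association skipped: zero variance in the",
      " analysis set"))
    NULL
  } else {
    list(pearson = list(r = stats::cor(wq[sub_ids], y_total),
                        df = length(sub_ids) - 2L),
         spearman = spearman_correlation(wq[sub_ids], y_total))
  }

  list(systems = systems, life_years = ly, overall_wq = wq, grid = grid,
       subset_ids = sub_ids, group_tests = group_tests,
       rank_correlations = rank_cor,
       weighting_sensitivity = weighting_sens,
       quality_lifeyears = quality_lifeyears,
       notices = notices,
       meta = list(seed = seed, alpha = alpha,
                   n_systems = nrow(systems), n_subset = nrow(sub),
                   n_metrics = length(unique(grid$metric_id)),
                   mode = mode,
                   version = as.character(utils::packageVersion("welfareLCA")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Render a results bundle as a text report
#'
#' Group medians, compact letter displays and adjusted pairwise p-values per
#' response, plus the ranking-robustness summary: the textual analogue of the
#' study-style box plots and correlation heat map.
#'
#' @param bundle Output of [run_pipeline()].
#' @param file Optional path; default prints to the console.
#' @return The report lines, invisibly.
#' @export
report_bundle <- function(bundle, file = "") {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  m <- bundle$meta
  add("welfareLCA results (v", m$version, ", seed ", m$seed, ")")
  add(m$n_systems, " systems; statistics on independent subset of n = ",
      m$n_subset, "; alpha = ", m$alpha)
  add("")
  for (test in bundle$group_tests) {
    om <- test$omnibus
    add("[", test$response, " by ", test$grouping, "] KW chi2(", om$df,
        ") = ", signif(om$statistic, 4), ", p = ", signif(om$p_value, 3))
    gr_levels <- names(test$letters)
    for (g in gr_levels) add("  ", g, ": letters '", test$letters[[g]], "'")
    sig <- test$pairwise[test$pairwise$significant, , drop = FALSE]
    if (nrow(sig) > 0L) {
      for (i in seq_len(nrow(sig))) {
        add("  ", sig$group_a[i], " vs ", sig$group_b[i], ": p_adj = ",
            signif(sig$p_adjusted[i], 3))
      }
    }
  }
  add("")
  r <- bundle$rank_correlations$r_s
  off <- r[upper.tri(r)]
  add("rank-correlation summary over ", ncol(r), " columns: median r_s = ",
      signif(stats::median(off), 3), ", min = ", signif(min(off), 3))
  if (!is.null(bundle$weighting_sensitivity)) {
    ws <- bundle$weighting_sensitivity
    add("weighting sensitivity (T100): KW p = ", signif(ws$p_value, 3))
  }
  ql <- bundle$quality_lifeyears
  if (!is.null(ql)) {
    add("overall WQ vs total life-years: Pearson r = ",
        signif(ql$pearson$r, 3), ", Spearman r_s = ",
        signif(ql$spearman$r_s, 3))
  }
  if (nzchar(file)) writeLines(ln, file) else writeLines(ln)
  invisible(ln)
}
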