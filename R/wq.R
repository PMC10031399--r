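# Welfare Quality (WQ) score aggregation: principle weightings, the
# life-year-weighted overall score, classification levels and the
# indifference threshold.

#' WQ principle weighting schemes
#'
#' Weights over the four WQ principles (good health, good feeding, appropriate
#' behaviour, good housing), summing to one. Three presets reflect the lack of
#' consensus on the relative importance of the principles:
#' `standard` = (0.35, 0.25, 0.25, 0.15), emphasizing health;
#' `equal` = (0.25, 0.25, 0.25, 0.25); and
#' `extreme` = (0.50, 0.20, 0.20, 0.10), doubling down on health.
#'
#' @param name `"standard"`, `"equal"`, `"extreme"`, or `"custom"` (in which
#'   case `weights` must be supplied).
#' @param weights For `name = "custom"`: numeric vector of four non-negative
#'   weights summing to 1, in the order health, feeding, behaviour, housing.
#' @return Named numeric vector of length 4 with attribute `"name"`.
#' @examples
#' wq_weighting("standard")
#' @export
wq_weighting <- function(name = c("standard", "equal", "extreme", "custom"),
                         weights = NULL) {
  name <- match.arg(name)
  w <- switch(name,
              standard = c(0.35, 0.25, 0.25, 0.15),
              equal    = c(0.25, 0.25, 0.25, 0.25),
              extreme  = c(0.50, 0.20, 0.20, 0.10),
              custom   = weights)
  if (is.null(w) || length(w) != 4L || any(!is.finite(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-12) {
    stop("principle weights must be 4 non-negative numbers summing to 1",
         call. = FALSE)
  }
  w <- as.numeric(w)
  names(w) <- principle_names
  attr(w, "name") <- name
  w
}

# Coerce scores to an n x 4 matrix in principle order. Accepts a length-4
# vector, an n x 4 matrix, or a data frame carrying prefixed score columns.
as_score_matrix <- function(scores, prefix = NULL) {
  if (is.data.frame(scores)) {
    cols <- if (is.null(prefix)) principle_names else
      paste0(prefix, "_", principle_names)
    scores <- as.matrix(scores[, cols])
  } else if (is.null(dim(scores))) {
    if (length(scores) != 4L) {
      stop("expected 4 principle scores (health, feeding, behaviour, housing)",
           call. = FALSE)
    }
    scores <- matrix(scores, nrow = 1L)
  }
  scores <- as.matrix(scores)
  if (ncol(scores) != 4L) stop("expected 4 principle-score columns",
                               call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 100)) {
    stop("principle scores must lie in [0, 100]", call. = FALSE)
  }
  colnames(scores) <- principle_names
  scores
}

#' Weighted WQ score of a single production stage
#'
#' The weight-convex combination `sum_i w_i p_i` of the four principle scores
#' of one stage assessment; bounded by the smallest and largest principle
#' score.
#'
#' @param scores Length-4 numeric vector (health, feeding, behaviour,
#'   housing) or an n x 4 matrix of assessments.
#' @param weighting A weighting from [wq_weighting()] (default standard).
#' @return Numeric vector of stage scores in `[0, 100]`.
#' @examples
#' weighted_stage_score(c(60, 70, 80, 50))  # 66
#' @export
weighted_stage_score <- function(scores, weighting = wq_weighting("standard")) {
  drop(as_score_matrix(scores) %*% wq_weighting("custom", weighting))
}

#' Overall WQ score of a breed-to-finish system
#'
#' Combines the sows-and-piglets (SP) and fattening-pigs (FP) stage
#' assessments into one score by weighting each stage's weighted score by the
#' proportion of life-years required by that stage to produce a finished pig:
#'
#'   overall = t_sp * sum_i w_i p_i^SP + t_fp * sum_i w_i p_i^FP.
#'
#' The same principle weighting is applied to both stages by default; a
#' distinct `weighting_fp` may be supplied for sensitivity work.
#'
#' @param sp,fp Stage assessments (length-4 vectors or n x 4 matrices).
#' @param t_sp Proportion of life-years in the SP stage (scalar or vector);
#'   `t_fp = 1 - t_sp` unless given explicitly.
#' @param weighting,weighting_fp Principle weightings ([wq_weighting()]);
#'   `weighting_fp` defaults to `weighting`.
#' @param t_fp FP proportion; must satisfy `t_sp + t_fp = 1`.
#' @return Numeric vector of overall WQ scores in `[0, 100]`.
#' @examples
#' overall_wq_score(c(60, 70, 80, 50), c(40, 60, 70, 30), t_sp = 0.25)  # 54.75
#' @export
overall_wq_score <- function(sp, fp, t_sp,
                             weighting = wq_weighting("standard"),
                             weighting_fp = weighting, t_fp = 1 - t_sp) {
  if (any(abs(t_sp + t_fp - 1) > 1e-9) || any(t_sp < 0) || any(t_fp < 0)) {
    stop("stage proportions must be non-negative and sum to 1", call. = FALSE)
  }
  t_sp * weighted_stage_score(sp, weighting) +
    t_fp * weighted_stage_score(fp, weighting_fp)
}

#' WQ classification of a stage assessment
#'
#' The WQ framework classifies an assessment as `excellent` when all four
#' principle scores are at least 55 and at least two are at least 80, and as
#' `enhanced` when all are at least 20 and at least two are at least 55.
#' Every excellent assessment also satisfies the enhanced conditions, so the
#' returned factor is ordered `neither < enhanced < excellent`.
#'
#' @param scores Length-4 vector or n x 4 matrix of principle scores.
#' @return Ordered factor with levels `neither`, `enhanced`, `excellent`.
#' @examples
#' classify_wq(c(80, 80, 55, 55))   # excellent
#' classify_wq(c(55, 55, 20, 20))   # enhanced
#' classify_wq(c(100, 100, 100, 10))  # neither
#' @export
classify_wq <- function(scores) {
  m <- as_score_matrix(scores)
  excellent <- rowSums(m >= 55) == 4L & rowSums(m >= 80) >= 2L
  enhanced <- rowSums(m >= 20) == 4L & rowSums(m >= 55) >= 2L
  lev <- ifelse(excellent, "excellent", ifelse(enhanced, "enhanced", "neither"))
  factor(lev, levels = c("neither", "enhanced", "excellent"), ordered = TRUE)
}

#' Biological difference under the WQ indifference threshold
#'
#' WQ scores carry an indifference threshold of five points: two scores are
#' considered biologically different only when they differ by more than 5.
#' This is reporting metadata; it never alters the statistical tests.
#'
#' @param s1,s2 Scores in `[0, 100]` (vectors recycled as usual).
#' @return Logical: `TRUE` iff `|s1 - s2| > 5`.
#' @export
biologically_different <- function(s1, s2) {
  if (any(!is.finite(c(s1, s2))) || any(c(s1, s2) < 0) || any(c(s1, s2) > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  abs(s1 - s2) > 5
}
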