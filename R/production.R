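# Life-years per kg deadweight from annualized herd productivity records,
# with economic allocation of the cull-sow co-product.

DAYS_PER_YEAR <- 365

#' Effective deadweight output with economic allocation
#'
#' Breed-to-finish systems produce deadweight (DW) both from fattening pigs
#' and from cull sows. The two co-products are equated by economic allocation:
#' cull-sow DW is scaled by the ratio of its price to the fattening-pig price,
#' so that the functional unit remains 1 kg of fattening-pig-equivalent DW,
#'
#'   DW_eff = DW_fat + DW_cull * price_cull / price_fattening,
#'
#' with `DW_fat = slaughtered_per_year * deadweight_per_pig` and
#' `DW_cull = cull_sows_per_year * cull_sow_deadweight`.
#'
#' @param record Data frame with the production-record columns (one or more
#'   rows; see [systems_schema()]). A `pig_systems` table works directly.
#' @return Numeric vector, effective kg DW per year.
#' @examples
#' rec <- data.frame(slaughtered_per_year = 2100, deadweight_per_pig = 88,
#'                   cull_sows_per_year = 45, cull_sow_deadweight = 75,
#'                   price_fattening = 1.6, price_cull = 0.8)
#' effective_deadweight(rec)  # 186487.5
#' @export
effective_deadweight <- function(record) {
  if (any(!is.finite(record$price_fattening) | record$price_fattening <= 0)) {
    stop("economic allocation requires price_fattening > 0", call. = FALSE)
  }
  dw_fat <- record$slaughtered_per_year * record$deadweight_per_pig
  dw_cull <- record$cull_sows_per_year * record$cull_sow_deadweight
  dw <- dw_fat + dw_cull * record$price_cull / record$price_fattening
  if (any(dw <= 0)) {
    stop("degenerate production record: zero effective deadweight output",
         call. = FALSE)
  }
  dw
}

#' Life-years required per kg deadweight
#'
#' Converts an annualized production record into the life-years `y` needed to
#' produce 1 kg DW, separately for the sows-and-piglets (SP) stage and the
#' fattening-pigs (FP) stage, together with each stage's share `t` of the
#' life-years per finished pig.
#'
#' SP life-years per year comprise one full year per average breeding sow on
#' farm plus `weaning_age / 365` years for every piglet born alive (piglets
#' that die before weaning are credited the full pre-weaning period; the
#' questionnaire data carry no age at death). FP life-years per year are the
#' post-weaning period `(slaughter_age - weaning_age) / 365` credited, under
#' the default `"average_slaughter_age"` assumption, to every weaned pig:
#' fattening animals that died or were culled on farm are assumed to have
#' lived the average age of those that went to slaughter. The alternative
#' `"death_at_weaning"` mode credits the period only to slaughtered pigs,
#' bounding the sensitivity of `y` to that assumption from below. Both are
#' divided by [effective_deadweight()].
#'
#' @param record Production record(s), as for [effective_deadweight()].
#' @param mode Mortality assumption, `"average_slaughter_age"` (default) or
#'   `"death_at_weaning"`.
#' @return Data frame with columns `y_sp`, `y_fp` (life-years per kg DW) and
#'   `t_sp`, `t_fp` (stage proportions, summing to 1).
#' @examples
#' rec <- data.frame(sows_avg = 100, born_alive_per_year = 2400,
#'                   weaned_per_year = 2200, weaning_age = 28,
#'                   slaughtered_per_year = 2100, slaughter_age = 180,
#'                   deadweight_per_pig = 88, cull_sows_per_year = 45,
#'                   cull_sow_deadweight = 75, price_fattening = 1.6,
#'                   price_cull = 0.8)
#' life_years_per_kg(rec)
#' @export
life_years_per_kg <- function(record,
                              mode = c("average_slaughter_age",
                                       "death_at_weaning")) {
  mode <- match.arg(mode)
  dw <- effective_deadweight(record)
  sp_years <- record$sows_avg +
    record$born_alive_per_year * record$weaning_age / DAYS_PER_YEAR
  fp_head <- switch(mode,
                    average_slaughter_age = record$weaned_per_year,
                    death_at_weaning = record$slaughtered_per_year)
  fp_years <- fp_head *
    (record$slaughter_age - record$weaning_age) / DAYS_PER_YEAR
  y_sp <- sp_years / dw
  y_fp <- fp_years / dw
  t <- stage_proportions(y_sp, y_fp)
  data.frame(y_sp = y_sp, y_fp = y_fp, t_sp = t$t_sp, t_fp = t$t_fp)
}

#' Stage proportions of life-years
#'
#' The proportion of life-years needed to produce a finished pig that is spent
#' in each production stage: `t_sp = y_sp / (y_sp + y_fp)`, `t_fp = 1 - t_sp`.
#'
#' @param y_sp,y_fp Life-years per kg DW for each stage (vectors).
#' @return Data frame with columns `t_sp`, `t_fp`.
#' @export
stage_proportions <- function(y_sp, y_fp) {
  tot <- y_sp + y_fp
  if (any(!is.finite(tot) | tot <= 0)) {
    stop("degenerate life-years: y_sp + y_fp must be positive", call. = FALSE)
  }
  data.frame(t_sp = y_sp / tot, t_fp = y_fp / tot)
}
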