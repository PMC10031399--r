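# The welfare-cost metric family: life-years weighted by WQ principle scores,
# with a configurable cost/benefit transition, and its canonical 30-variant
# grid (10 transitions x 3 principle weightings).

#' Cost/benefit transition rules
#'
#' A transition decides, per principle and production stage, whether the
#' life-years carried by a principle score count as a welfare cost
#' (contribution `(100 - p) w y`) or as a welfare benefit (`-p w y`). Three
#' kinds are supported:
#'
#' * `numeric`: scores at or above a threshold `T` are benefits, evaluated
#'   independently per principle and stage. The canonical grid uses
#'   `T = 100, 90, 80, 70, 60, 50, 40`.
#' * `classification`: all four principles of a stage are benefits iff that
#'   stage's assessment meets a WQ classification level (`"excellent"` or
#'   `"enhanced"`); an excellent stage also meets the enhanced transition.
#' * `behaviour_benefit`: the appropriate-behaviour principle is always a
#'   benefit and the other three principles are always costs, in both stages,
#'   reflecting calls to treat behavioural indicators as positive welfare.
#'
#' @param kind One of `"numeric"`, `"classification"`, `"behaviour_benefit"`.
#' @param threshold Numeric transition score in `[0, 100]`; required iff
#'   `kind = "numeric"`.
#' @param level Classification level, `"excellent"` or `"enhanced"`; required
#'   iff `kind = "classification"`.
#' @return A `transition_spec` object.
#' @export
transition_spec <- function(kind = c("numeric", "classification",
                                     "behaviour_benefit"),
                            threshold = NULL, level = NULL) {
  kind <- match.arg(kind)
  if (kind == "numeric") {
    if (is.null(threshold) || !is.numeric(threshold) ||
        length(threshold) != 1L || !is.finite(threshold) ||
        threshold < 0 || threshold > 100) {
      stop("numeric transitions require a single threshold in [0, 100]",
           call. = FALSE)
    }
    if (!is.null(level)) stop("numeric transitions take no level", call. = FALSE)
  } else if (kind == "classification") {
    if (is.null(level) || !level %in% c("excellent", "enhanced")) {
      stop("classification transitions require level 'excellent' or 'enhanced'",
           call. = FALSE)
    }
    if (!is.null(threshold)) {
      stop("classification transitions take no threshold", call. = FALSE)
    }
  } else if (!is.null(threshold) || !is.null(level)) {
    stop("behaviour_benefit transitions take neither threshold nor level",
         call. = FALSE)
  }
  structure(list(kind = kind, threshold = threshold, level = level),
            class = "transition_spec")
}

transition_label <- function(transition) {
  switch(transition$kind,
         numeric = paste0("T", format(transition$threshold)),
         classification = transition$level,
         behaviour_benefit = "behaviour")
}

#' A metric variant: transition rule x principle weighting
#'
#' @param transition A [transition_spec()].
#' @param weighting A [wq_weighting()] or preset name.
#' @param metric_id Stable identifier; defaults to
#'   `"<transition>/<weighting>"`, e.g. `"T100/standard"`,
#'   `"enhanced/equal"`, `"behaviour/extreme"`.
#' @return A `metric_spec` object.
#' @export
metric_spec <- function(transition, weighting = "standard", metric_id = NULL) {
  if (!inherits(transition, "transition_spec")) {
    stop("transition must be a transition_spec", call. = FALSE)
  }
  if (is.character(weighting) && length(weighting) == 1L) {
    weighting <- wq_weighting(weighting)
  } else {
    weighting <- wq_weighting("custom", weighting)
  }
  if (is.null(metric_id)) {
    metric_id <- paste0(transition_label(transition), "/",
                        attr(weighting, "name"))
  }
  structure(list(transition = transition, weighting = weighting,
                 metric_id = metric_id),
            class = "metric_spec")
}

#' The canonical 30-variant metric grid
#'
#' Ten transitions (numeric `T` = 100, 90, 80, 70, 60, 50, 40; the two WQ
#' classifications excellent and enhanced; behaviour-as-benefit) crossed with
#' the three principle weightings (standard, equal, extreme).
#'
#' @param weightings Character vector of weighting preset names.
#' @return Named list of 30 [metric_spec()] objects, in grid order.
#' @export
canonical_metric_grid <- function(weightings = c("standard", "equal",
                                                 "extreme")) {
  transitions <- c(
    lapply(c(100, 90, 80, 70, 60, 50, 40),
           function(T) transition_spec("numeric", threshold = T)),
    list(transition_spec("classification", level = "excellent"),
         transition_spec("classification", level = "enhanced"),
         transition_spec("behaviour_benefit"))
  )
  specs <- list()
  for (tr in transitions) {
    for (wname in weightings) {
      spec <- metric_spec(tr, wname)
      specs[[spec$metric_id]] <- spec
    }
  }
  specs
}

#' Benefit flags per principle and stage under a transition rule
#'
#' @param sp,fp Stage assessments (length-4 vectors or n x 4 matrices).
#' @param transition A [transition_spec()].
#' @return List with logical matrices `sp` and `fp` (n x 4): `TRUE` where the
#'   principle's life-years count as a benefit (`p >= T` branch).
#' @export
resolve_benefit_flags <- function(sp, fp, transition) {
  sp <- as_score_matrix(sp)
  fp <- as_score_matrix(fp)
  if (nrow(sp) != nrow(fp)) stop("sp and fp must match in rows", call. = FALSE)
  flags <- switch(
    transition$kind,
    numeric = list(sp = sp >= transition$threshold,
                   fp = fp >= transition$threshold),
    classification = {
      meets <- function(m) classify_wq(m) >= transition$level
      list(sp = matrix(meets(sp), nrow(sp), 4L),
           fp = matrix(meets(fp), nrow(fp), 4L))
    },
    behaviour_benefit = {
      one <- matrix(rep(principle_names == "behaviour", each = nrow(sp)),
                    nrow(sp), 4L)
      list(sp = one, fp = one)
    })
  dimnames(flags$sp) <- dimnames(flags$fp) <-
    list(NULL, principle_names)
  flags
}

#' Contribution of one principle to the welfare cost
#'
#' The two branches of the welfare-cost summand: `(100 - p) * w * y` when the
#' principle's life-years are a cost (`p < T`) and `-p * w * y` when they are
#' a benefit (`p >= T`). The function is discontinuous at the transition by
#' construction: crossing `T` drops the contribution from `(100 - T) w y` to
#' `-T w y`.
#'
#' @param p Principle score(s) in `[0, 100]`.
#' @param w Principle weight(s), non-negative.
#' @param y Life-years per kg DW of the stage, non-negative.
#' @param is_benefit Logical, the branch selector.
#' @return Numeric cost contribution (negative values are benefits).
#' @export
principle_contribution <- function(p, w, y, is_benefit) {
  if (any(p < 0 | p > 100) || any(w < 0) || any(y < 0)) {
    stop("require p in [0,100], w >= 0, y >= 0", call. = FALSE)
  }
  ifelse(is_benefit, -p * w * y, (100 - p) * w * y)
}

#' Welfare cost of systems under one metric variant
#'
#' The headline quantity: welfare cost per kg deadweight, summing the eight
#' principle-by-stage contributions
#' `(100 - p) w y` (cost branch) or `-p w y` (benefit branch) with the
#' stage-specific life-years `y_sp`, `y_fp` and the branch chosen by the
#' metric's transition rule. Higher values indicate poorer welfare; negative
#' values indicate a net welfare benefit.
#'
#' @param sp,fp Stage assessments (length-4 vectors or n x 4 matrices).
#' @param spec A [metric_spec()].
#' @param y_sp,y_fp Life-years per kg DW for each stage (vectors).
#' @return Data frame with columns `cost`, `cost_sp`, `cost_fp`
#'   (`cost = cost_sp + cost_fp`).
#' @examples
#' spec <- metric_spec(transition_spec("numeric", threshold = 70), "standard")
#' welfare_cost(c(60, 70, 80, 50), c(40, 60, 70, 30), spec,
#'              y_sp = 1.5e-3, y_fp = 4.9e-3)
#' @export
welfare_cost <- function(sp, fp, spec, y_sp, y_fp) {
  sp <- as_score_matrix(sp)
  fp <- as_score_matrix(fp)
  flags <- resolve_benefit_flags(sp, fp, spec$transition)
  w <- matrix(spec$weighting, nrow(sp), 4L, byrow = TRUE)
  contrib_sp <- principle_contribution(sp, w, y_sp, flags$sp)
  contrib_fp <- principle_contribution(fp, w, y_fp, flags$fp)
  cost_sp <- rowSums(matrix(contrib_sp, nrow(sp), 4L))
  cost_fp <- rowSums(matrix(contrib_fp, nrow(fp), 4L))
  data.frame(cost = cost_sp + cost_fp, cost_sp = cost_sp, cost_fp = cost_fp)
}

#' Welfare costs of a population across a metric grid
#'
#' Evaluates every metric variant on every system, using each system's own
#' life-years profile from [life_years_per_kg()].
#'
#' @param systems A [pig_systems()] table.
#' @param specs List of [metric_spec()] objects; defaults to the canonical
#'   30-variant grid.
#' @param mode Mortality assumption passed to [life_years_per_kg()].
#' @return Data frame with one row per system x metric: `system_id`,
#'   `metric_id`, `cost`, `cost_sp`, `cost_fp`, ordered by
#'   (`system_id`, `metric_id`).
#' @export
metric_grid <- function(systems, specs = canonical_metric_grid(),
                        mode = "average_slaughter_age") {
  if (length(specs) == 0L) {
    stop("metric grid requires at least one metric_spec", call. = FALSE)
  }
  ids <- vapply(specs, function(s) s$metric_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate metric_id in grid: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ly <- life_years_per_kg(systems, mode = mode)
  sp <- as_score_matrix(systems, prefix = "sp")
  fp <- as_score_matrix(systems, prefix = "fp")
  out <- lapply(specs, function(spec) {
    cbind(data.frame(system_id = as.character(systems$system_id),
                     metric_id = spec$metric_id,
                     stringsAsFactors = FALSE),
          welfare_cost(sp, fp, spec, ly$y_sp, ly$y_fp))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out <- out[order(out$system_id, out$metric_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
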