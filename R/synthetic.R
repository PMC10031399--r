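# Synthetic breed-to-finish populations emulating a 74-system UK pig sector:
# six label types, husbandry structure, correlated WQ principle scores, a
# calibrated positive quality/life-years association, and clusters of systems
# sharing breeding and/or rearing farms (43 independent clusters).

#' Default generator configuration
#'
#' The paper-calibrated stated world: 74 systems split over six label types
#' (none = 4, red tractor = 31, RSPCA assured = 12, free range = 18,
#' woodland = 3, organic = 6); a sharing plan over breeding/rearing farms
#' yielding 43 independent clusters; a target correlation of 0.57 between
#' overall WQ score and total life-years per kg DW; and per-label mean WQ
#' scores and life-years multipliers ordered so that woodland systems have
#' the highest welfare (lowest welfare cost), followed by organic, then free
#' range / RSPCA assured, then red tractor, then unlabelled systems, with
#' outdoor breeding scoring above indoor and outdoor finishing above slatted.
#' Between-label differences exceed the 5-point WQ indifference threshold.
#'
#' All remaining quantities (noise standard deviations, husbandry mixes,
#' production baselines) are free parameters chosen as realistic for UK pig
#' production; see the package vignette for rationale.
#'
#' @return A `generator_config` list; see [generate_population()].
#' @export
default_config <- function() {
  label_score_means <- rbind(
    none          = c(42, 55, 30, 40),
    red_tractor   = c(52, 62, 38, 50),
    rspca_assured = c(60, 68, 55, 62),
    free_range    = c(62, 70, 65, 68),
    woodland      = c(82, 85, 88, 85),
    organic       = c(72, 76, 78, 76))
  colnames(label_score_means) <- principle_names

  cfg <- list(
    label_counts = c(none = 4L, red_tractor = 31L, rspca_assured = 12L,
                     free_range = 18L, woodland = 3L, organic = 6L),
    label_score_means = label_score_means,
    label_lifeyears_multiplier = c(none = 1.00, red_tractor = 1.00,
                                   rspca_assured = 1.08, free_range = 1.15,
                                   woodland = 1.30, organic = 1.25),
    husbandry_given_label = list(
      none          = list(breeding = c(indoor = 1),
                           finishing = c(slatted = 0.8, straw_yard = 0.2)),
      red_tractor   = list(breeding = c(indoor = 0.9, hybrid = 0.1),
                           finishing = c(slatted = 0.7, straw_yard = 0.3)),
      rspca_assured = list(breeding = c(indoor = 0.4, hybrid = 0.4,
                                        outdoor = 0.2),
                           finishing = c(straw_yard = 0.8, outdoor = 0.2)),
      free_range    = list(breeding = c(outdoor = 1),
                           finishing = c(outdoor = 1)),
      woodland      = list(breeding = c(hybrid = 0.3, outdoor = 0.7),
                           finishing = c(outdoor = 1)),
      organic       = list(breeding = c(outdoor = 1),
                           finishing = c(straw_yard = 0.1, outdoor = 0.9))),
    breeding_effect = c(indoor = 0, hybrid = 2, outdoor = 4),
    finishing_effect = c(slatted = 0, straw_yard = 2, outdoor = 4),
    quality_sd = 3.5,
    score_noise_sd = 5,
    quality_lifeyears_correlation = 0.57,
    lifeyears_noise_sd = 0.06,
    y_total_base = 6.4e-3,
    t_sp_mean = 0.237,
    t_sp_sd = 0.02,
    # cluster sizes per label; 74 systems in 43 clusters, size-3 clusters are
    # breeding-farm + rearing-farm chains
    sharing_plan = list(
      none          = c(2, 1, 1),
      red_tractor   = c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1),
      rspca_assured = c(3, 3, 2, 1, 1, 1, 1),
      free_range    = c(3, 3, 3, 2, 2, 1, 1, 1, 1, 1),
      woodland      = c(2, 1),
      organic       = c(2, 2, 1, 1)),
    # systems holding additional, less demanding labels (most-demanding rule)
    label_extras = list(
      rspca_assured = list(extras = "red_tractor", count = 10L),
      free_range    = list(extras = c("red_tractor", "rspca_assured"),
                           count = 15L),
      woodland      = list(extras = "free_range", count = 2L),
      organic       = list(extras = c("red_tractor", "rspca_assured",
                                      "free_range"), count = 6L)),
    production_baselines = list(
      sows_log_mean = log(150), sows_log_sd = 0.5,
      born_per_sow_indoor = 26, born_per_sow_outdoor = 22,
      born_per_sow_cv = 0.06,
      preweaning_mortality = 0.12, postweaning_mortality = 0.03,
      weaning_age_indoor = 27, weaning_age_outdoor = 40,
      weaning_age_jitter = 3,
      cull_rate = 0.45, cull_sow_deadweight = 75,
      price_fattening = 1.60, price_cull = 0.80, price_cull_sd = 0.08)
  )
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Modify a generator configuration
#'
#' Returns a new configuration with the named fields replaced and all
#' invariants revalidated. Useful for sensitivity scenarios, e.g. a null
#' configuration with no label effects for type-I-error studies.
#'
#' @param config A `generator_config` (see [default_config()]).
#' @param ... Named replacement values for existing fields.
#' @return A revalidated `generator_config`.
#' @examples
#' cfg <- perturb_config(default_config(), quality_lifeyears_correlation = 0)
#' @export
perturb_config <- function(config, ...) {
  overrides <- list(...)
  if (length(overrides) > 0L &&
      (is.null(names(overrides)) || any(!nzchar(names(overrides))))) {
    stop("overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(unclass(config)))
  if (length(unknown) > 0L) {
    stop("unknown generator_config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  # a counts override without a matching plan falls back to singletons
  if ("label_counts" %in% names(overrides) &&
      !"sharing_plan" %in% names(overrides)) {
    ok <- all(vapply(names(config$label_counts), function(l) {
      sum(config$sharing_plan[[l]]) == config$label_counts[[l]]
    }, logical(1)))
    if (!ok) {
      config$sharing_plan <- lapply(as.list(config$label_counts),
                                    function(n) rep(1L, n))
    }
  }
  validate_config(config)
  config
}

validate_config <- function(config) {
  counts <- config$label_counts
  if (!setequal(names(counts), label_levels)) {
    stop("label_counts must cover exactly the label vocabulary", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != as.integer(counts))) {
    stop("label_counts must be positive integers", call. = FALSE)
  }
  rho <- config$quality_lifeyears_correlation
  if (!is.finite(rho) || rho <= -1 || rho >= 1) {
    stop("quality_lifeyears_correlation must lie in (-1, 1)", call. = FALSE)
  }
  for (l in names(counts)) {
    plan <- config$sharing_plan[[l]]
    if (is.null(plan) || any(plan < 1) || sum(plan) != counts[[l]]) {
      stop("infeasible sharing_plan for label '", l,
           "': cluster sizes must be positive and sum to the label count",
           call. = FALSE)
    }
  }
  if (any(config$label_score_means < 0) || any(config$label_score_means > 100)) {
    stop("label_score_means must lie in [0, 100]", call. = FALSE)
  }
  if (any(config$label_lifeyears_multiplier <= 0)) {
    stop("label_lifeyears_multiplier must be positive", call. = FALSE)
  }
  invisible(config)
}

# Moment-match the loading of the latent quality factor on log life-years so
# that the population-level correlation between overall WQ score and total
# life-years per kg DW hits the configured target. Moments are computed on
# the linear (pre-truncation) model over label x husbandry strata.
solve_quality_loading <- function(config) {
  w0 <- wq_weighting("standard")
  t0 <- config$t_sp_mean
  strata <- list(w = numeric(0), m_wq = numeric(0), m_ly = numeric(0))
  for (l in names(config$label_counts)) {
    hl <- config$husbandry_given_label[[l]]
    base <- sum(w0 * config$label_score_means[l, ])
    # weight by the expected label composition of the independent subset
    # (one system per shared-farm cluster), the set on which the
    # quality/life-years association is reported
    n_eff <- length(config$sharing_plan[[l]])
    for (b in names(hl$breeding)) {
      for (f in names(hl$finishing)) {
        strata$w <- c(strata$w, n_eff *
                        hl$breeding[[b]] * hl$finishing[[f]])
        strata$m_wq <- c(strata$m_wq,
                         base + t0 * config$breeding_effect[[b]] +
                           (1 - t0) * config$finishing_effect[[f]])
        strata$m_ly <- c(strata$m_ly,
                         log(config$label_lifeyears_multiplier[[l]]))
      }
    }
  }
  wts <- strata$w / sum(strata$w)
  mu_wq <- sum(wts * strata$m_wq)
  var_w_wq <- config$quality_sd^2 +
    sum(w0^2) * (t0^2 + (1 - t0)^2) * config$score_noise_sd^2
  s2 <- sum(wts * (strata$m_wq - mu_wq)^2) + var_w_wq
  rho <- config$quality_lifeyears_correlation
  if (s2 <= 0) return(0)

  # Moments taken on the y scale: within each stratum the log multiplier is
  # normal with sd^2 = c^2 + noise^2, so y is lognormal; the within-stratum
  # covariance with the (normal) WQ score follows Stein's identity,
  # cov(WQ, e^L) = cov(WQ, L) E[e^L].
  f <- function(c) {
    sd2_w <- c^2 + config$lifeyears_noise_sd^2
    m_y <- exp(strata$m_ly + sd2_w / 2)
    mu_y <- sum(wts * m_y)
    var_y <- sum(wts * (m_y^2 * (exp(sd2_w) - 1) + (m_y - mu_y)^2))
    cov_wy <- sum(wts * (config$quality_sd * c * m_y +
                           (strata$m_wq - mu_wq) * (m_y - mu_y)))
    cov_wy / sqrt(s2 * var_y) - rho
  }
  if (config$quality_sd == 0) {
    # no within-system channel; accept the label-level correlation as-is
    return(0)
  }
  # f can have two roots (the correlation peaks in c); scan for sign changes
  # and take the root of smallest magnitude, i.e. the least within-system
  # coupling beyond the label-level structure needed to hit the target.
  grid <- seq(-3, 3, by = 0.05)
  fg <- vapply(grid, f, numeric(1))
  flips <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (length(flips) == 0L) {
    stop("infeasible quality_lifeyears_correlation target for this config",
         call. = FALSE)
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(f, grid[c(i, i + 1L)], tol = 1e-10)$root
  }, numeric(1))
  roots[which.min(abs(roots))]
}

#' Generate a synthetic breed-to-finish population
#'
#' Draws a population of breed-to-finish pig systems under a
#' `generator_config`. Per system, a latent farm-quality factor shifts all
#' four WQ principle scores of both stages (plus label and husbandry mean
#' effects and independent per-principle noise, truncated to `[0, 100]`) and,
#' through a loading solved by moment matching
#' (`quality_lifeyears_correlation`), the log of the system's life-years
#' multiplier. Production records are back-solved so that
#' [life_years_per_kg()] reproduces the drawn life-years exactly, and the
#' sharing plan is materialized as shared breeding/rearing-farm identifiers
#' (size-3 clusters are chains: two systems share a breeding farm, two a
#' rearing farm). Output is deterministic given `(config, seed)`.
#'
#' @param config A `generator_config` from [default_config()] /
#'   [perturb_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return A [pig_systems()] table with attributes `"config"` and `"seed"`.
#' @export
generate_population <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  withr_seed(seed, generate_population_impl(config, seed))
}

generate_population_impl <- function(config, seed) {
  counts <- config$label_counts[label_levels[label_levels %in%
                                               names(config$label_counts)]]
  labels <- rep(names(counts), counts)
  n <- length(labels)
  ids <- sprintf("S%03d", seq_len(n))

  # ---- sharing structure ----------------------------------------------------
  breeding_farm <- character(n)
  rearing_farm <- rep(NA_character_, n)
  cluster_of <- integer(n)
  n_breeding <- 0L; n_rearing <- 0L; n_cluster <- 0L
  for (l in names(counts)) {
    rows <- which(labels == l)
    pos <- 1L
    for (size in config$sharing_plan[[l]]) {
      n_cluster <- n_cluster + 1L
      members <- rows[pos:(pos + size - 1L)]
      pos <- pos + size
      cluster_of[members] <- n_cluster
      if (size == 1L) {
        n_breeding <- n_breeding + 1L
        breeding_farm[members] <- sprintf("B%03d", n_breeding)
      } else {
        # first two members share a breeding farm, the rest get their own
        n_breeding <- n_breeding + 1L
        breeding_farm[members[1:2]] <- sprintf("B%03d", n_breeding)
        for (m in members[-(1:2)]) {
          n_breeding <- n_breeding + 1L
          breeding_farm[m] <- sprintf("B%03d", n_breeding)
        }
        # chain the remaining members in via shared rearing farms
        if (size > 2L) {
          for (j in 2:(size - 1L)) {
            n_rearing <- n_rearing + 1L
            rearing_farm[members[c(j, j + 1L)]] <- sprintf("R%03d", n_rearing)
          }
        }
      }
    }
  }
  finishing_farm <- sprintf("F%03d", seq_len(n))

  # ---- husbandry: breeding type is a property of the breeding farm ----------
  draw1 <- function(probs) sample(names(probs), 1L, prob = probs)
  breeding_husbandry <- character(n)
  for (bf in unique(breeding_farm)) {
    members <- which(breeding_farm == bf)
    probs <- config$husbandry_given_label[[labels[members[1]]]]$breeding
    breeding_husbandry[members] <- draw1(probs)
  }
  finishing_husbandry <- vapply(labels, function(l) {
    draw1(config$husbandry_given_label[[l]]$finishing)
  }, character(1))

  # ---- WQ principle scores --------------------------------------------------
  z <- stats::rnorm(n)
  mean_sp <- config$label_score_means[labels, , drop = FALSE] +
    config$breeding_effect[breeding_husbandry]
  mean_fp <- config$label_score_means[labels, , drop = FALSE] +
    config$finishing_effect[finishing_husbandry]
  noise <- function() matrix(stats::rnorm(n * 4L, sd = config$score_noise_sd),
                             n, 4L)
  clip01 <- function(m) {
    out <- pmin(100, pmax(0, m))
    dim(out) <- dim(m)
    out
  }
  sp_scores <- clip01(mean_sp + config$quality_sd * z + noise())
  fp_scores <- clip01(mean_fp + config$quality_sd * z + noise())
  colnames(sp_scores) <- sp_score_cols
  colnames(fp_scores) <- fp_score_cols

  # ---- life-years, correlated with latent quality ---------------------------
  loading <- solve_quality_loading(config)
  log_mult <- log(config$label_lifeyears_multiplier[labels]) + loading * z +
    stats::rnorm(n, sd = config$lifeyears_noise_sd)
  y_total <- config$y_total_base * exp(log_mult)
  t_sp <- pmin(0.5, pmax(0.08,
                         stats::rnorm(n, config$t_sp_mean, config$t_sp_sd)))
  y_sp <- t_sp * y_total
  y_fp <- (1 - t_sp) * y_total

  # ---- production records back-solved from the drawn life-years -------------
  pb <- config$production_baselines
  outdoor_bred <- breeding_husbandry == "outdoor"
  sows <- pmax(20, round(stats::rlnorm(n, pb$sows_log_mean, pb$sows_log_sd)))
  born_rate <- ifelse(outdoor_bred, pb$born_per_sow_outdoor,
                      pb$born_per_sow_indoor) *
    (1 + stats::rnorm(n, sd = pb$born_per_sow_cv))
  born <- round(sows * pmax(born_rate, 5))
  weaned <- round(born * (1 - pb$preweaning_mortality))
  slaughtered <- round(weaned * (1 - pb$postweaning_mortality))
  weaning_age <- ifelse(outdoor_bred, pb$weaning_age_outdoor,
                        pb$weaning_age_indoor) +
    stats::runif(n, -pb$weaning_age_jitter, pb$weaning_age_jitter)
  cull_sows <- round(sows * pb$cull_rate)
  price_cull <- pmax(0.1, stats::rnorm(n, pb$price_cull, pb$price_cull_sd))

  sp_years <- sows + born * weaning_age / DAYS_PER_YEAR
  dw_eff <- sp_years / y_sp
  dw_cull_alloc <- cull_sows * pb$cull_sow_deadweight *
    price_cull / pb$price_fattening
  deadweight_per_pig <- (dw_eff - dw_cull_alloc) / slaughtered
  if (any(deadweight_per_pig <= 0)) {
    stop("infeasible production baselines: negative fattening deadweight",
         call. = FALSE)
  }
  slaughter_age <- weaning_age + DAYS_PER_YEAR * (y_fp * dw_eff) / weaned

  # ---- labels held ----------------------------------------------------------
  labels_held <- ifelse(labels == "none", "", labels)
  for (l in names(config$label_extras)) {
    plan <- config$label_extras[[l]]
    rows <- which(labels == l)
    take <- rows[seq_len(min(plan$count, length(rows)))]
    labels_held[take] <- paste(c(plan$extras, l), collapse = ";")
  }

  df <- data.frame(
    system_id = ids, labels_held = labels_held, assigned_label = labels,
    breeding_husbandry = breeding_husbandry,
    finishing_husbandry = finishing_husbandry,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(sp_scores), as.data.frame(fp_scores))
  df$sows_avg <- sows
  df$born_alive_per_year <- born
  df$weaned_per_year <- weaned
  df$weaning_age <- weaning_age
  df$slaughtered_per_year <- slaughtered
  df$slaughter_age <- slaughter_age
  df$deadweight_per_pig <- deadweight_per_pig
  df$cull_sows_per_year <- cull_sows
  df$cull_sow_deadweight <- pb$cull_sow_deadweight
  df$price_fattening <- pb$price_fattening
  df$price_cull <- price_cull
  df$breeding_farm_id <- breeding_farm
  df$rearing_farm_id <- rearing_farm
  df$finishing_farm_id <- finishing_farm

  out <- pig_systems(df)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "drawn_y") <- data.frame(y_sp = y_sp, y_fp = y_fp)
  out
}
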