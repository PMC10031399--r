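# Shared fixtures: hand-built systems tables and generator configs.

principles <- c("health", "feeding", "behaviour", "housing")

# A single fully consistent system row, with overridable fields.
make_system_row <- function(id = "sysA", ...) {
  row <- data.frame(
    system_id = id,
    labels_held = "red_tractor",
    assigned_label = "red_tractor",
    breeding_husbandry = "indoor",
    finishing_husbandry = "slatted",
    sp_health = 60, sp_feeding = 70, sp_behaviour = 80, sp_housing = 50,
    fp_health = 40, fp_feeding = 60, fp_behaviour = 70, fp_housing = 30,
    sows_avg = 100, born_alive_per_year = 2400, weaned_per_year = 2200,
    weaning_age = 28, slaughtered_per_year = 2100, slaughter_age = 180,
    deadweight_per_pig = 88, cull_sows_per_year = 45,
    cull_sow_deadweight = 75, price_fattening = 1.6, price_cull = 0.8,
    breeding_farm_id = paste0("B_", id), rearing_farm_id = NA_character_,
    finishing_farm_id = paste0("F_", id),
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

# Vector-valued overrides are recycled element-wise across rows.
make_systems_df <- function(n = 3, ...) {
  overrides <- list(...)
  do.call(rbind, lapply(seq_len(n), function(i) {
    row_overrides <- lapply(overrides, function(v) v[[((i - 1) %% length(v)) + 1]])
    do.call(make_system_row, c(list(id = sprintf("sys%02d", i)), row_overrides))
  }))
}

# Null generator config: no label or husbandry effects, equal life-years.
null_generator_config <- function() {
  cfg <- default_config()
  m <- cfg$label_score_means
  m[] <- rep(c(55, 65, 50, 55), each = nrow(m))
  perturb_config(
    cfg,
    label_score_means = m,
    label_lifeyears_multiplier = stats::setNames(
      rep(1, length(cfg$label_lifeyears_multiplier)),
      names(cfg$label_lifeyears_multiplier)),
    breeding_effect = c(indoor = 0, hybrid = 0, outdoor = 0),
    finishing_effect = c(slatted = 0, straw_yard = 0, outdoor = 0))
}

score_cols <- function(stage) paste0(stage, "_", principles)

# Drop provenance attributes for value comparisons.
plain_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  x
}

overall_wq_of <- function(systems, weighting = wq_weighting("standard")) {
  ly <- life_years_per_kg(systems)
  overall_wq_score(as.matrix(systems[, score_cols("sp")]),
                   as.matrix(systems[, score_cols("fp")]),
                   t_sp = ly$t_sp, weighting = weighting)
}
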