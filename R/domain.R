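# Shared data model: closed categorical vocabularies, label precedence,
# system-level validation.

#' Label-type vocabulary, ordered from least to most demanding
#'
#' Assurance-scheme and marketing categories for UK pig systems, in strict
#' precedence order: systems belonging to several labels are assigned to the
#' most demanding one. Quality Meat Scotland certification is treated as
#' `red_tractor`.
#'
#' @format Character vector of length 6; position encodes precedence
#'   (`none` = lowest, `organic` = highest).
#' @export
label_levels <- c("none", "red_tractor", "rspca_assured", "free_range",
                  "woodland", "organic")

#' Husbandry-type vocabularies
#'
#' Breeding husbandry is one of indoor, hybrid (indoor-outdoor) or outdoor;
#' finishing husbandry is one of slatted, straw yard or outdoor. The order is
#' a reporting convention only, no numeric coding is implied.
#'
#' @format Character vectors of length 3.
#' @export
breeding_husbandry_levels <- c("indoor", "hybrid", "outdoor")

#' @rdname breeding_husbandry_levels
#' @export
finishing_husbandry_levels <- c("slatted", "straw_yard", "outdoor")

#' Precedence rank of a label type
#'
#' @param label Character vector of label names.
#' @return Integer rank, `none` = 0 up to `organic` = 5.
#' @export
label_rank <- function(label) {
  idx <- match(label, label_levels)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown label type(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(label_levels, collapse = ", "), ")",
         call. = FALSE)
  }
  idx - 1L
}

#' Assign the most demanding label type
#'
#' A system that belongs to two or more labels is categorized under the most
#' demanding of them (e.g. a free-range system that is also RSPCA assured is
#' assigned `free_range`). An empty set of labels maps to `none`.
#'
#' @param labels_held Character vector (treated as a set) of label names held
#'   by the system, possibly empty. A single semicolon-separated string is
#'   also accepted (the on-disk encoding).
#' @return A single label name, the maximum-precedence member of
#'   `labels_held`, or `"none"` for an empty set.
#' @examples
#' assign_label_type(c("red_tractor", "rspca_assured", "free_range"))
#' assign_label_type(character(0))
#' @export
assign_label_type <- function(labels_held) {
  labels_held <- parse_labels_held(labels_held)
  if (length(labels_held) == 0L) return("none")
  label_levels[max(label_rank(labels_held)) + 1L]
}

# "a;b;c" -> c("a","b","c"); vectors pass through; whitespace trimmed.
parse_labels_held <- function(labels_held) {
  if (length(labels_held) == 1L && is.character(labels_held) &&
      grepl(";", labels_held, fixed = TRUE)) {
    labels_held <- strsplit(labels_held, ";", fixed = TRUE)[[1L]]
  }
  labels_held <- trimws(labels_held)
  unique(labels_held[nzchar(labels_held)])
}

principle_names <- c("health", "feeding", "behaviour", "housing")
sp_score_cols <- paste0("sp_", principle_names)
fp_score_cols <- paste0("fp_", principle_names)

production_cols <- c("sows_avg", "born_alive_per_year", "weaned_per_year",
                     "weaning_age", "slaughtered_per_year", "slaughter_age",
                     "deadweight_per_pig", "cull_sows_per_year",
                     "cull_sow_deadweight", "price_fattening", "price_cull")

farm_id_cols <- c("breeding_farm_id", "rearing_farm_id", "finishing_farm_id")

systems_columns <- function() {
  c("system_id", "labels_held", "assigned_label",
    "breeding_husbandry", "finishing_husbandry",
    sp_score_cols, fp_score_cols, production_cols, farm_id_cols)
}

#' Construct a table of breed-to-finish systems
#'
#' The canonical container for a population of breed-to-finish pig systems:
#' a data frame with one row per system carrying identifiers, label and
#' husbandry categorizations, the eight WQ principle scores (four for the
#' sows-and-piglets stage, prefix `sp_`, four for the fattening stage, prefix
#' `fp_`), the annualized production record and farm identifiers. Rows are
#' validated on construction.
#'
#' @param df Data frame holding all columns of the systems schema (see
#'   [systems_schema()]).
#' @return A `pig_systems` data frame.
#' @seealso [validate_systems()], [generate_population()]
#' @export
pig_systems <- function(df) {
  missing_cols <- setdiff(systems_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("systems table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, systems_columns()]
  violations <- validate_systems(df)
  if (length(violations) > 0L) {
    stop("invalid systems table:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  class(df) <- c("pig_systems", "data.frame")
  df
}

#' Column schema of the systems table
#'
#' @return Character vector of the column names, in canonical order.
#' @export
systems_schema <- function() systems_columns()

#' Validate a table of breed-to-finish systems
#'
#' Checks every type invariant of the data model and returns the violations
#' as human-readable strings rather than raising: vocabulary membership of
#' labels and husbandry types, the most-demanding-label assignment rule, WQ
#' score ranges, production-record consistency (non-negativity,
#' weaned <= born alive, slaughtered <= weaned, weaning before slaughter) and
#' uniqueness of finishing-farm identifiers.
#'
#' @param systems Data frame in the systems schema (class `pig_systems` not
#'   required).
#' @return Character vector of violation descriptions; empty when all
#'   invariants hold. Each entry names the row (by `system_id`), the field and
#'   the rule violated.
#' @export
validate_systems <- function(systems) {
  v <- character(0)
  note <- function(...) v <<- c(v, paste0(...))
  id <- as.character(systems$system_id)
  if (anyDuplicated(id)) {
    note("system_id: duplicated identifier(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }

  for (i in seq_len(nrow(systems))) {
    row <- systems[i, ]
    held <- tryCatch(parse_labels_held(row$labels_held),
                     error = function(e) NULL)
    bad_vocab <- !is.null(held) && !all(held %in% label_levels)
    if (bad_vocab) {
      note(id[i], ": labels_held: unknown label name(s): ",
           paste(setdiff(held, label_levels), collapse = ", "))
    }
    if (!row$assigned_label %in% label_levels) {
      note(id[i], ": assigned_label: unknown label '", row$assigned_label, "'")
    } else if (!is.null(held) && !bad_vocab &&
               !identical(assign_label_type(held), as.character(row$assigned_label))) {
      note(id[i], ": assigned_label: '", row$assigned_label,
           "' is not the most demanding label held (expected '",
           assign_label_type(held), "')")
    }
    if (!row$breeding_husbandry %in% breeding_husbandry_levels) {
      note(id[i], ": breeding_husbandry: unknown value '",
           row$breeding_husbandry, "'")
    }
    if (!row$finishing_husbandry %in% finishing_husbandry_levels) {
      note(id[i], ": finishing_husbandry: unknown value '",
           row$finishing_husbandry, "'")
    }
    for (col in c(sp_score_cols, fp_score_cols)) {
      p <- row[[col]]
      if (!is.finite(p) || p < 0 || p > 100) {
        note(id[i], ": ", col, ": principle score ", format(p),
             " outside [0, 100]")
      }
    }
    v <- c(v, validate_production_row(row, id[i]))
  }

  fin <- as.character(systems$finishing_farm_id)
  if (anyDuplicated(fin)) {
    note("finishing_farm_id: must be unique per system; duplicated: ",
         paste(unique(fin[duplicated(fin)]), collapse = ", "))
  }
  v
}

#' @rdname validate_systems
#' @param system A single-row data frame (one system).
#' @export
validate_system <- function(system) validate_systems(system[1, , drop = FALSE])

validate_production_row <- function(row, id) {
  v <- character(0)
  for (col in production_cols) {
    x <- row[[col]]
    if (!is.finite(x) || x < 0) {
      v <- c(v, paste0(id, ": ", col, ": must be a non-negative number, got ",
                       format(x)))
    }
  }
  if (length(v) > 0L) return(v)  # comparisons below need finite values
  if (row$weaned_per_year > row$born_alive_per_year) {
    v <- c(v, paste0(id, ": weaned_per_year: exceeds born_alive_per_year"))
  }
  if (row$slaughtered_per_year > row$weaned_per_year) {
    v <- c(v, paste0(id, ": slaughtered_per_year: exceeds weaned_per_year"))
  }
  if (row$weaning_age >= row$slaughter_age) {
    v <- c(v, paste0(id, ": weaning_age: must be below slaughter_age"))
  }
  v
}

#' @export
print.pig_systems <- function(x, ...) {
  cat("<pig_systems> ", nrow(x), " breed-to-finish system(s)\n", sep = "")
  tab <- table(factor(x$assigned_label, levels = label_levels))
  cat("  by label: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  NextMethod()
  invisible(x)
}
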