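#' Load diet-index scoring standards
#'
#' The scoring rules for each HEI-2015 and AHEI-2010 component ship as
#' editable CSV tables under `inst/extdata/`, defaulting to the published
#' values: 13 HEI-2015 components scored on per-1000-kcal densities (the
#' fatty-acid ratio and the two percent-of-energy components on their own
#' basis) and 10 AHEI-2010 components scored on daily amounts (trans fat
#' excluded). Keeping the standards in data rather than code makes the
#' modified-vs-original AHEI sensitivity analysis a table/flag swap.
#'
#' @param path Optional path to a replacement CSV with the same columns.
#' @return A tibble with one row per component: `component`, `direction`
#'   (`adequacy`, `moderation` or `special`), `max_points`, `zero_score`
#'   and `full_score` thresholds (with optional `_female` overrides),
#'   `basis` (`density_1000`, `per_day` or `as_is`), `units`, and the
#'   adult alcohol band columns for the special rule.
#' @export
hei2015_standards <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hei2015_standards.csv",
                                package = "dietfootprint", mustWork = TRUE)
  std <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_standards(std)
  std
}

#' @rdname hei2015_standards
#' @export
ahei2010_standards <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ahei2010_standards.csv",
                                package = "dietfootprint", mustWork = TRUE)
  std <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_standards(std)
  std
}

validate_standards <- function(std) {
  needed <- c("index", "component", "direction", "max_points",
              "zero_score", "full_score", "basis", "units", "special_rule")
  missing <- setdiff(needed, names(std))
  if (length(missing)) {
    abort(paste0("standards table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(std$max_points <= 0)) abort("standards: max_points must be > 0")
  plain <- std$special_rule == "none"
  if (any(!is.finite(std$zero_score[plain])) || any(!is.finite(std$full_score[plain]))) {
    abort("standards: thresholds must be finite for non-special components")
  }
  adequacy <- plain & std$direction == "adequacy"
  moderation <- plain & std$direction == "moderation"
  if (any(std$full_score[adequacy] <= std$zero_score[adequacy])) {
    abort("standards: adequacy components need full_score > zero_score")
  }
  if (any(std$full_score[moderation] >= std$zero_score[moderation])) {
    abort("standards: moderation components need full_score < zero_score")
  }
  invisible(std)
}

# Resolve sex-specific thresholds; `sex` is "male"/"female" (vector ok).
resolve_threshold <- function(male_value, female_value, sex) {
  out <- rep(male_value, length(sex))
  if (!is.na(female_value)) out[sex == "female"] <- female_value
  out
}
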