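# Core domain types: complaint hierarchy, patient cohort, triage
# discretization of age and vital signs.

# Canonical category labels. Vital bins follow the clinical triage cut points;
# printed ranges share endpoints ("49-59, 59-105"), so bins are half-open
# [lower, upper): a boundary value belongs to the upper bin. Every vital has an
# extra "missing" category.
AGE_BREAKS <- c(30, 40, 50, 60, 70, 80, 90)
AGE_LABELS <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79",
                "80-89", ">90")

VITAL_BINS <- list(
  temperature = list(
    breaks = c(94.8, 96.1, 99.2, 100.4),
    labels = c("<94.8", "94.8-96.1", "96.1-99.2", "99.2-100.4", ">100.4")
  ),
  pulse = list(
    breaks = c(49, 59, 105, 109, 119, 129),
    labels = c("<49", "49-59", "59-105", "105-109", "109-119", "119-129",
               ">129")
  ),
  respiratory_rate = list(
    breaks = c(13, 14, 19, 23),
    labels = c("<13", "13-14", "14-19", "19-23", ">23")
  ),
  blood_pressure = list(
    breaks = c(99, 106, 176, 199),
    labels = c("<99", "99-106", "106-176", "176-199", ">199")
  ),
  # "93-94" covers the integers 93 and 94, so its upper boundary is 95.
  oxygen_saturation = list(
    breaks = c(93, 95),
    labels = c("<93", "93-94", ">94")
  )
)

VITAL_NAMES <- names(VITAL_BINS)
GENDER_LEVELS <- c("female", "male")
ARRIVAL_LEVELS <- c("ambulance", "walk_in")

REQUIRED_COHORT_COLUMNS <- c("gender", "arrival_mode", VITAL_NAMES,
                             "complaint", "outcome")

#' Label set of a categorical predictor block
#'
#' @param block one of `"age_band"`, `"gender"`, `"arrival_mode"`, or a vital
#'   sign name (`"temperature"`, `"pulse"`, `"respiratory_rate"`,
#'   `"blood_pressure"`, `"oxygen_saturation"`).
#' @return Character vector of admissible labels (vitals include `"missing"`).
#' @export
predictor_levels <- function(block) {
  switch(block,
    age_band = AGE_LABELS,
    gender = GENDER_LEVELS,
    arrival_mode = ARRIVAL_LEVELS,
    if (block %in% VITAL_NAMES) {
      c(VITAL_BINS[[block]]$labels, "missing")
    } else {
      stop_unknown_block(block)
    }
  )
}

stop_unknown_block <- function(block) {
  stop_evospec(sprintf("unknown predictor block '%s'", block),
               "evospec_validation_error")
}

#' Discretize an adult age into a triage age band
#'
#' Bands are half-open decades (`18-29`, ..., `80-89`) with `>90` open above;
#' an age of exactly 90 falls in `>90` so the bands leave no gap.
#'
#' @param age_years numeric vector of ages in years; must be `>= 18`.
#' @return Character vector of age-band labels.
#' @examples
#' categorize_age(c(45, 95))
#' @export
categorize_age <- function(age_years) {
  if (!is.numeric(age_years) || any(!is.finite(age_years))) {
    stop_evospec("age_years must be finite numeric", "evospec_validation_error")
  }
  if (any(age_years < 18)) {
    stop_evospec(
      sprintf("age below the adult ED domain (>= 18): %s",
              paste(age_years[age_years < 18], collapse = ", ")),
      "evospec_domain_error"
    )
  }
  AGE_LABELS[findInterval(age_years, AGE_BREAKS) + 1L]
}

#' Discretize a raw vital-sign measurement into its triage category
#'
#' Bins are half-open `[lower, upper)`, open at the extremes; a missing
#' measurement (`NA`) maps to the dedicated `"missing"` category.
#'
#' @param vital_name one of `"temperature"`, `"pulse"`, `"respiratory_rate"`,
#'   `"blood_pressure"`, `"oxygen_saturation"`.
#' @param raw_value numeric vector, possibly containing `NA`.
#' @return Character vector of category labels.
#' @examples
#' categorize_vital("pulse", c(110, NA))
#' categorize_vital("oxygen_saturation", 95)
#' @export
categorize_vital <- function(vital_name, raw_value) {
  if (!vital_name %in% VITAL_NAMES) {
    stop_evospec(sprintf("unknown vital sign '%s'", vital_name),
                 "evospec_validation_error")
  }
  if (!is.numeric(raw_value)) {
    stop_evospec("raw_value must be numeric (NA allowed for missing)",
                 "evospec_validation_error")
  }
  if (any(is.nan(raw_value) | is.infinite(raw_value))) {
    stop_evospec(sprintf("non-finite %s value", vital_name),
                 "evospec_validation_error")
  }
  bins <- VITAL_BINS[[vital_name]]
  out <- rep_len("missing", length(raw_value))
  ok <- !is.na(raw_value)
  out[ok] <- bins$labels[findInterval(raw_value[ok], bins$breaks) + 1L]
  out
}

#' Construct a two-level complaint hierarchy
#'
#' @param parent either a named character vector mapping each specific
#'   complaint (name) to its complaint category (value), or a two-column
#'   data frame `(complaint, category)`.
#' @return An object of class `complaint_hierarchy` with elements
#'   `complaints` (ordered unique complaint identifiers), `categories`
#'   (unique category identifiers, in first-appearance order) and `parent`
#'   (named character vector, complaint -> category).
#' @details Identifiers are matched case-insensitively after trimming
#'   whitespace. Each complaint must map to exactly one category and the two
#'   identifier namespaces must be disjoint.
#' @examples
#' complaint_hierarchy(c("abdominal cramping" = "abdominal pain",
#'                       "abdominal mass"     = "abdominal pain",
#'                       "headache"           = "neurological"))
#' @export
complaint_hierarchy <- function(parent) {
  if (is.data.frame(parent)) {
    if (ncol(parent) < 2L) {
      stop_evospec("hierarchy table needs two columns (complaint, category)",
                   "evospec_schema_error")
    }
    map <- normalize_id(parent[[2L]])
    names(map) <- normalize_id(parent[[1L]])
    parent <- map
  } else {
    if (is.null(names(parent))) {
      stop_evospec("parent must be a named vector (complaint -> category)",
                   "evospec_schema_error")
    }
    val <- normalize_id(parent)
    names(val) <- normalize_id(names(parent))
    parent <- val
  }
  if (length(parent) < 1L) {
    stop_evospec("hierarchy must contain at least one complaint (n >= 1)",
                 "evospec_validation_error")
  }
  dup <- unique(names(parent)[duplicated(names(parent))])
  if (length(dup)) {
    conflicting <- vapply(dup, function(d) {
      length(unique(parent[names(parent) == d])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop_evospec(
        sprintf("complaint(s) listed under more than one category: %s",
                paste(dup[conflicting], collapse = ", ")),
        "evospec_validation_error"
      )
    }
    parent <- parent[!duplicated(names(parent))]
  }
  complaints <- names(parent)
  categories <- unique(unname(parent))
  clash <- intersect(complaints, categories)
  if (length(clash)) {
    stop_evospec(
      sprintf("identifier(s) used both as complaint and category: %s",
              paste(clash, collapse = ", ")),
      "evospec_validation_error"
    )
  }
  structure(
    list(complaints = complaints, categories = categories, parent = parent),
    class = "complaint_hierarchy"
  )
}

#' @export
print.complaint_hierarchy <- function(x, ...) {
  cat(sprintf("complaint hierarchy: %d complaints in %d categories\n",
              length(x$complaints), length(x$categories)))
  invisible(x)
}

#' Number of specific complaints in a hierarchy
#' @param hierarchy a [complaint_hierarchy()].
#' @return Integer, the mask length `n`.
#' @export
n_complaints <- function(hierarchy) length(hierarchy$complaints)

validate_cohort_records <- function(records, hierarchy) {
  needed <- c("age_band", REQUIRED_COHORT_COLUMNS)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_evospec(sprintf("cohort is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "evospec_schema_error")
  }
  for (block in c("age_band", "gender", "arrival_mode", VITAL_NAMES)) {
    lv <- predictor_levels(block)
    bad <- setdiff(unique(records[[block]]), lv)
    if (length(bad)) {
      stop_evospec(
        sprintf("invalid %s label(s): %s (expected one of: %s)",
                block, paste(bad, collapse = ", "), paste(lv, collapse = ", ")),
        "evospec_validation_error"
      )
    }
  }
  if (!all(records$outcome %in% c(0L, 1L))) {
    bad <- unique(records$outcome[!records$outcome %in% c(0L, 1L)])
    stop_evospec(sprintf("outcome must be 0 or 1; found: %s",
                         paste(bad, collapse = ", ")),
                 "evospec_validation_error")
  }
  orphan <- setdiff(unique(records$complaint), hierarchy$complaints)
  if (length(orphan)) {
    stop_evospec(
      sprintf("complaint(s) absent from the hierarchy: %s",
              paste(orphan, collapse = ", ")),
      "evospec_integrity_error"
    )
  }
  if (length(unique(records$outcome)) < 2L) {
    stop_evospec("cohort must contain both outcome classes",
                 "evospec_validation_error")
  }
  invisible(records)
}

#' Construct a validated ED cohort
#'
#' @param records data frame with one row per visit and columns `age_band`,
#'   `gender`, `arrival_mode`, the five vital-sign categories
#'   (`temperature`, `pulse`, `respiratory_rate`, `blood_pressure`,
#'   `oxygen_saturation`), `complaint` and binary `outcome`.
#' @param hierarchy a [complaint_hierarchy()] covering every complaint that
#'   occurs in `records`.
#' @return An object of class `ed_cohort`: list with `records`, `hierarchy`
#'   and an internal design cache.
#' @export
new_cohort <- function(records, hierarchy) {
  stopifnot(inherits(hierarchy, "complaint_hierarchy"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("age_band", "gender", "arrival_mode", VITAL_NAMES,
                "complaint")) {
    if (col %in% names(records)) records[[col]] <- normalize_id(records[[col]])
  }
  records$outcome <- suppressWarnings(as.integer(records$outcome))
  validate_cohort_records(records, hierarchy)
  rownames(records) <- NULL
  structure(
    list(records = records, hierarchy = hierarchy, cache = new.env()),
    class = "ed_cohort"
  )
}

#' @export
print.ed_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf(paste0(
    "ED cohort: %d visits, %d unique complaints (%d in hierarchy), ",
    "%d categories\n  critical-outcome prevalence: %.2f%%\n"),
    nrow(r), length(unique(r$complaint)), length(x$hierarchy$complaints),
    length(x$hierarchy$categories), 100 * mean(r$outcome)))
  invisible(x)
}

#' Load a cohort and its complaint hierarchy from CSV files
#'
#' The cohort file must contain `gender`, `arrival_mode`, the five vitals,
#' `complaint`, `outcome`, and either raw `age_years` or pre-binned
#' `age_band`. Vital columns may be raw numeric measurements (blank =
#' missing), which are discretized with [categorize_vital()], or pre-binned
#' labels. The hierarchy file has two columns, `complaint,category`.
#'
#' @param cohort_path path to the cohort CSV.
#' @param hierarchy_path path to the hierarchy CSV.
#' @return An [new_cohort()] object.
#' @export
load_cohort <- function(cohort_path, hierarchy_path) {
  hier_raw <- read.csv(hierarchy_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!all(c("complaint", "category") %in% names(hier_raw))) {
    stop_evospec("hierarchy CSV must have columns 'complaint' and 'category'",
                 "evospec_schema_error")
  }
  hierarchy <- complaint_hierarchy(hier_raw[, c("complaint", "category")])

  raw <- read.csv(cohort_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  missing_cols <- setdiff(REQUIRED_COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop_evospec(sprintf("cohort CSV is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "evospec_schema_error")
  }
  if (!("age_years" %in% names(raw)) && !("age_band" %in% names(raw))) {
    stop_evospec("cohort CSV needs an 'age_years' or 'age_band' column",
                 "evospec_schema_error")
  }

  records <- data.frame(row.names = seq_len(nrow(raw)))
  if ("age_band" %in% names(raw)) {
    records$age_band <- normalize_id(raw$age_band)
  } else {
    records$age_band <- categorize_age(as.numeric(raw$age_years))
  }
  records$gender <- normalize_id(raw$gender)
  arrival <- chartr(" -", "__", normalize_id(raw$arrival_mode))
  records$arrival_mode <- sub("^via_", "", arrival)
  for (v in VITAL_NAMES) {
    col <- trimws(raw[[v]])
    nonblank <- col[col != "" & !is.na(col)]
    numeric_ok <- length(nonblank) == 0L ||
      !anyNA(suppressWarnings(as.numeric(nonblank)))
    if (numeric_ok) {
      records[[v]] <- categorize_vital(v, suppressWarnings(as.numeric(col)))
    } else {
      lab <- normalize_id(col)
      lab[lab == ""] <- "missing"
      records[[v]] <- lab
    }
  }
  records$complaint <- normalize_id(raw$complaint)
  out <- suppressWarnings(as.integer(trimws(raw$outcome)))
  if (anyNA(out) | !all(out %in% c(0L, 1L))) {
    bad <- unique(raw$outcome[is.na(out) | !out %in% c(0L, 1L)])
    stop_evospec(sprintf("non-binary outcome value(s): %s",
                         paste(bad, collapse = ", ")),
                 "evospec_validation_error")
  }
  records$outcome <- out
  new_cohort(records, hierarchy)
}

#' Split a cohort into two disjoint sub-cohorts
#'
#' Records are partitioned by position (first `n_first` rows vs the rest),
#' which for exchangeable records - e.g. cohorts from [generate_cohort()] -
#' yields two independent cohorts sharing one hierarchy. Useful for
#' selection/evaluation designs where a specification is chosen on one
#' sample and assessed on records the search never saw.
#'
#' @param cohort an `ed_cohort`.
#' @param n_first number of records in the first sub-cohort.
#' @return List with `first` and `second` `ed_cohort`s.
#' @export
split_cohort <- function(cohort, n_first) {
  stopifnot(inherits(cohort, "ed_cohort"))
  n <- nrow(cohort$records)
  if (n_first < 1L || n_first >= n) {
    stop_evospec("n_first must leave at least one record in each part",
                 "evospec_validation_error")
  }
  idx <- seq_len(n) <= n_first
  list(first = new_cohort(cohort$records[idx, , drop = FALSE],
                          cohort$hierarchy),
       second = new_cohort(cohort$records[!idx, , drop = FALSE],
                           cohort$hierarchy))
}

#' Write a cohort (and optionally its hierarchy) to CSV
#'
#' Writes the pre-binned label representation, so a written cohort reloads
#' identically with [load_cohort()].
#'
#' @param cohort an `ed_cohort`.
#' @param cohort_path output path for the cohort CSV.
#' @param hierarchy_path optional output path for the hierarchy CSV.
#' @return Invisibly, `cohort_path`.
#' @export
write_cohort <- function(cohort, cohort_path, hierarchy_path = NULL) {
  stopifnot(inherits(cohort, "ed_cohort"))
  write.csv(cohort$records, cohort_path, row.names = FALSE, quote = TRUE)
  if (!is.null(hierarchy_path)) {
    h <- cohort$hierarchy
    write.csv(
      data.frame(complaint = h$complaints,
                 category = unname(h$parent[h$complaints])),
      hierarchy_path, row.names = FALSE, quote = TRUE
    )
  }
  invisible(cohort_path)
}
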