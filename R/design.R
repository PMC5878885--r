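# Indicator design construction under the four specification modes.
#
# The complaint/category encoding is the heart of the method:
#   complaints_only  - one indicator per specific complaint, no categories.
#   categories_only  - one indicator per complaint category, no complaints.
#   flattened        - one mutually exclusive combined level: a patient with a
#                      selected complaint carries that complaint indicator and
#                      is removed from its parent category; everyone else
#                      carries the parent-category indicator.
#   hierarchical     - every patient keeps the parent-category indicator; a
#                      selected complaint adds a second, supplementary
#                      indicator.

STATIC_BLOCKS <- c("age_band", "gender", "arrival_mode", VITAL_NAMES)
DESIGN_MODES <- c("flattened", "hierarchical", "complaints_only",
                  "categories_only")

# Precomputed per-cohort integer codes; cached inside the cohort object since
# they are mask-independent.
design_context <- function(cohort) {
  stopifnot(inherits(cohort, "ed_cohort"))
  if (!is.null(cohort$cache$ctx)) return(cohort$cache$ctx)
  records <- cohort$records
  h <- cohort$hierarchy
  static <- lapply(STATIC_BLOCKS, function(block) {
    levels <- predictor_levels(block)
    codes <- match(records[[block]], levels)
    counts <- tabulate(codes, nbins = length(levels))
    list(block = block, levels = levels, codes = codes, counts = counts,
         ref = which.max(counts))
  })
  names(static) <- STATIC_BLOCKS
  complaint_code <- match(records$complaint, h$complaints)
  category_of <- match(unname(h$parent[h$complaints]), h$categories)
  category_code <- category_of[complaint_code]
  ctx <- list(
    n_records = nrow(records),
    outcome = records$outcome,
    static = static,
    complaint_code = complaint_code,
    category_code = category_code,
    category_of = category_of,
    complaint_counts = tabulate(complaint_code, nbins = length(h$complaints)),
    hierarchy = h
  )
  cohort$cache$ctx <- ctx
  ctx
}

check_mask <- function(mask, n) {
  if (is.null(mask)) {
    stop_evospec("a specification mask is required for this mode",
                 "evospec_validation_error")
  }
  mask <- as.integer(mask)
  if (length(mask) != n) {
    stop_evospec(sprintf("mask length %d does not match n = %d complaints",
                         length(mask), n),
                 "evospec_validation_error")
  }
  if (anyNA(mask) || !all(mask %in% c(0L, 1L))) {
    stop_evospec("mask bits must be 0 or 1", "evospec_validation_error")
  }
  mask
}

# Column layout for one (mask, mode). Returns per-block level->column maps
# (0 = no column: dropped reference or absent), plus column names.
design_layout <- function(ctx, mask, mode, drop_reference) {
  h <- ctx$hierarchy
  n <- length(h$complaints)
  n_cat <- length(h$categories)

  col_names <- character(0)
  static_map <- vector("list", length(ctx$static))
  names(static_map) <- names(ctx$static)
  nextcol <- 0L
  for (block in names(ctx$static)) {
    s <- ctx$static[[block]]
    keep <- rep(TRUE, length(s$levels))
    if (drop_reference) keep[s$ref] <- FALSE
    map <- integer(length(s$levels))
    map[keep] <- nextcol + seq_len(sum(keep))
    nextcol <- nextcol + sum(keep)
    col_names <- c(col_names, paste0(block, "=", s$levels[keep]))
    static_map[[block]] <- map
  }

  sel <- if (mode %in% c("flattened", "hierarchical")) mask else NULL

  # Records mapped to each category under the mode (flattening extracts
  # selected-complaint patients from their category).
  cat_counts <- switch(mode,
    complaints_only = integer(n_cat),
    flattened = {
      keep_rec <- sel[ctx$complaint_code] == 0L
      tabulate(ctx$category_code[keep_rec], nbins = n_cat)
    },
    tabulate(ctx$category_code, nbins = n_cat)
  )
  cat_present <- cat_counts > 0L

  cplt_in <- switch(mode,
    complaints_only = rep(TRUE, n),
    categories_only = rep(FALSE, n),
    sel == 1L
  )

  # Reference level of the mutually exclusive complaint/category block.
  drop_cat <- drop_cplt <- 0L
  if (drop_reference) {
    if (mode == "categories_only" || mode == "hierarchical") {
      if (any(cat_present)) {
        drop_cat <- which(cat_present)[which.max(cat_counts[cat_present])]
      }
    } else if (mode == "complaints_only") {
      drop_cplt <- which.max(ctx$complaint_counts)
    } else if (mode == "flattened") {
      eff_cplt <- ifelse(cplt_in, ctx$complaint_counts, 0L)
      best_cat <- if (any(cat_present)) max(cat_counts) else 0L
      if (any(cplt_in) && max(eff_cplt) > best_cat) {
        drop_cplt <- which.max(eff_cplt)
      } else if (any(cat_present)) {
        drop_cat <- which(cat_present)[which.max(cat_counts[cat_present])]
      }
    }
  }

  cat_keep <- cat_present
  if (drop_cat > 0L) cat_keep[drop_cat] <- FALSE
  cat_map <- integer(n_cat)
  cat_map[cat_keep] <- nextcol + seq_len(sum(cat_keep))
  nextcol <- nextcol + sum(cat_keep)
  col_names <- c(col_names, h$categories[cat_keep])

  cplt_keep <- cplt_in
  if (drop_cplt > 0L) cplt_keep[drop_cplt] <- FALSE
  cplt_map <- integer(n)
  cplt_map[cplt_keep] <- nextcol + seq_len(sum(cplt_keep))
  nextcol <- nextcol + sum(cplt_keep)
  col_names <- c(col_names, h$complaints[cplt_keep])

  list(p = nextcol, col_names = col_names, static_map = static_map,
       cat_map = cat_map, cplt_map = cplt_map, mode = mode,
       selected = cplt_in & mode %in% c("flattened", "hierarchical"))
}

# Per-record column indices (0 = none) for the complaint/category slots.
complaint_slots <- function(ctx, layout, mask, mode) {
  cc <- ctx$complaint_code
  kc <- ctx$category_code
  n_rec <- ctx$n_records
  cplt_slot <- integer(n_rec)
  cat_slot <- integer(n_rec)
  if (mode == "complaints_only") {
    cplt_slot <- layout$cplt_map[cc]
  } else if (mode == "categories_only") {
    cat_slot <- layout$cat_map[kc]
  } else {
    sel_rec <- mask[cc] == 1L
    cplt_slot[sel_rec] <- layout$cplt_map[cc[sel_rec]]
    if (mode == "flattened") {
      cat_slot[!sel_rec] <- layout$cat_map[kc[!sel_rec]]
    } else {
      cat_slot <- layout$cat_map[kc]
    }
  }
  list(cplt = cplt_slot, cat = cat_slot)
}

#' Build the binary indicator design for a cohort under a specification mask
#'
#' @param cohort an [new_cohort()] object.
#' @param mask binary vector of length `n` (one bit per specific complaint in
#'   hierarchy order); ignored (may be `NULL`) for the two baseline modes.
#' @param mode one of `"flattened"`, `"hierarchical"`, `"complaints_only"`,
#'   `"categories_only"`.
#' @param drop_reference if `TRUE`, encode each mutually exclusive block
#'   one-of-K with its most frequent level dropped (full-rank design for
#'   fitting with an intercept). The default `FALSE` keeps the raw one
#'   indicator per level, which is where the structural identities between
#'   modes hold bit-exactly. In hierarchical mode the supplementary complaint
#'   indicators are never dropped.
#' @return A `design_matrix` object: list with `values` (patients x columns
#'   binary matrix), `column_names`, `outcome`, `row_ids`, `mode`, `mask`.
#' @details Unselected complaints contribute no column at all, and category
#'   columns to which no patient maps under the mode (e.g. a fully selected
#'   category in flattened mode) are dropped rather than kept as all-zero
#'   columns.
#' @export
build_design <- function(cohort, mask = NULL,
                         mode = c("flattened", "hierarchical",
                                  "complaints_only", "categories_only"),
                         drop_reference = FALSE) {
  mode <- match.arg(mode)
  ctx <- design_context(cohort)
  n <- length(ctx$hierarchy$complaints)
  if (mode %in% c("flattened", "hierarchical")) {
    mask <- check_mask(mask, n)
  } else {
    mask <- NULL
  }
  layout <- design_layout(ctx, mask, mode, drop_reference)
  values <- matrix(0L, nrow = ctx$n_records, ncol = layout$p,
                   dimnames = list(NULL, layout$col_names))
  rows <- seq_len(ctx$n_records)
  for (block in names(ctx$static)) {
    colidx <- layout$static_map[[block]][ctx$static[[block]]$codes]
    keep <- colidx > 0L
    values[cbind(rows[keep], colidx[keep])] <- 1L
  }
  slots <- complaint_slots(ctx, layout, mask, mode)
  keep <- slots$cat > 0L
  values[cbind(rows[keep], slots$cat[keep])] <- 1L
  keep <- slots$cplt > 0L
  values[cbind(rows[keep], slots$cplt[keep])] <- 1L
  structure(
    list(values = values, column_names = layout$col_names,
         outcome = ctx$outcome, row_ids = rows, mode = mode, mask = mask,
         drop_reference = drop_reference),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix (%s%s): %d rows x %d columns, %d events\n",
              x$mode, if (x$drop_reference) ", full rank" else "",
              nrow(x$values), ncol(x$values), sum(x$outcome)))
  invisible(x)
}

#' Export a design matrix to CSV
#'
#' Writes the indicator columns plus a final `outcome` column.
#'
#' @param design a `design_matrix`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
export_design <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  df <- as.data.frame(design$values)
  df$outcome <- design$outcome
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Fast path used by cv_fitness: index-coded full-rank design with one record
# per COLUMN (slots x records), so each record's indices are contiguous for
# the C++ accumulator. Design column 1 is the intercept; each record has at
# most 1 + #blocks + 2 active columns.
design_index <- function(ctx, mask, mode) {
  layout <- design_layout(ctx, mask, mode, drop_reference = TRUE)
  n_rec <- ctx$n_records
  m <- 1L + length(ctx$static) + 2L
  idx <- matrix(0L, nrow = m, ncol = n_rec)
  idx[1L, ] <- 1L
  j <- 1L
  shift <- function(colidx) colidx + (colidx > 0L)  # 1-based with intercept
  for (block in names(ctx$static)) {
    j <- j + 1L
    idx[j, ] <- shift(layout$static_map[[block]][ctx$static[[block]]$codes])
  }
  slots <- complaint_slots(ctx, layout, mask, mode)
  idx[j + 1L, ] <- shift(slots$cat)
  idx[j + 2L, ] <- shift(slots$cplt)
  list(idx = idx, p = layout$p + 1L,
       col_names = c("(Intercept)", layout$col_names))
}
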