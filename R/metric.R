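#' Load (or fetch the shipped) scoring-metric configuration
#'
#' The metric configuration declares, for each dosage type and category id,
#' the default points, the permissible range, whether the engine scores the
#' category automatically, and a short description. The shipped default
#' carries the 40 copy-number-loss and 40 copy-number-gain categories of the
#' 2019 ACMG/ClinGen CNV scoring metric, with 18 loss and 16 gain categories
#' flagged automated.
#'
#' @param path Optional path to a TSV (columns `dosage`, `category`,
#'   `default`, `min`, `max`, `automated`, `description`) or a JSON array of
#'   objects with the same fields. `NULL` loads the configuration shipped
#'   with the package.
#' @param adjustment_step Granularity for manual up/down adjustment away from
#'   a category's default, in points.
#' @return A `metric_config` object (data frame of categories plus the
#'   adjustment step).
#' @export
load_metric_config <- function(path = NULL, adjustment_step = 0.05) {
  if (is.null(path))
    path <- system.file("extdata", "metric_config.tsv", package = "cnvscore",
                        mustWork = TRUE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::fromJSON(path)
  } else {
    cfg <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  }
  required <- c("dosage", "category", "default", "min", "max", "automated",
                "description")
  missing_cols <- setdiff(required, names(cfg))
  if (length(missing_cols))
    cnv_abort(sprintf("metric config %s is missing column(s): %s",
                      basename(path), paste(missing_cols, collapse = ", ")),
              "cnvscore_schema_error")
  cfg$dosage <- toupper(cfg$dosage)
  cfg$automated <- as.logical(as.integer(cfg$automated))
  for (col in c("default", "min", "max")) cfg[[col]] <- as.numeric(cfg[[col]])

  bad <- which(cfg$min > cfg$default | cfg$default > cfg$max)
  if (length(bad))
    cnv_abort(sprintf("metric config: default outside [min, max] for %s",
                      paste(sprintf("%s/%s", cfg$dosage[bad],
                                    cfg$category[bad]), collapse = ", ")),
              "cnvscore_schema_error")
  dup <- duplicated(cfg[, c("dosage", "category")])
  if (any(dup))
    cnv_abort(sprintf("metric config: duplicate category id(s): %s",
                      paste(unique(cfg$category[dup]), collapse = ", ")),
              "cnvscore_schema_error")
  for (d in c("LOSS", "GAIN")) {
    n <- sum(cfg$dosage == d)
    if (n != 40L)
      cnv_abort(sprintf("metric config must define 40 %s categories, found %d",
                        d, n),
                "cnvscore_schema_error")
  }
  structure(list(categories = cfg, adjustment_step = adjustment_step),
            class = "metric_config")
}

#' Default points for one metric category
#'
#' @param cfg A `metric_config`.
#' @param dosage `"LOSS"` or `"GAIN"`.
#' @param category Category id.
#' @return The configured default points.
#' @export
metric_defaults <- function(cfg, dosage, category) {
  metric_row(cfg, dosage, category)$default
}

metric_row <- function(cfg, dosage, category) {
  df <- cfg$categories
  i <- which(df$dosage == dosage & df$category == category)
  if (length(i) != 1L)
    cnv_abort(sprintf("category %s is not defined for dosage %s",
                      category, dosage),
              "cnvscore_validation_error")
  df[i, ]
}

#' Points assigned per loss-of-function evidence strength
#'
#' Maps the graded PVS1 call from the intragenic evaluator to the point
#' value and range used by category 2E (intragenic deletion in an HI gene)
#' and category 2I (intragenic tandem duplication in an HI gene).
#'
#' @param dosage `"LOSS"` (category 2E) or `"GAIN"` (category 2I).
#' @param strength One of `"PVS1"`, `"PVS1_STRONG"`, `"PVS1_MODERATE"`,
#'   `"NONE"`.
#' @return List with `points`, `range_min`, `range_max`.
#' @export
pvs1_points <- function(dosage = c("LOSS", "GAIN"),
                        strength = c("PVS1", "PVS1_STRONG", "PVS1_MODERATE",
                                     "NONE")) {
  dosage <- match.arg(dosage)
  strength <- match.arg(strength)
  map <- if (dosage == "LOSS") {
    list(PVS1          = list(points = 0.9,  range_min = 0.45, range_max = 0.9),
         PVS1_STRONG   = list(points = 0.45, range_min = 0.3,  range_max = 0.9),
         PVS1_MODERATE = list(points = 0.3,  range_min = 0.15, range_max = 0.45),
         NONE          = list(points = 0,    range_min = 0,    range_max = 0))
  } else {
    # Duplications only grade PVS1 (tandem proven) / PVS1_Strong (assumed).
    list(PVS1          = list(points = 0.9,  range_min = 0,    range_max = 0.9),
         PVS1_STRONG   = list(points = 0.45, range_min = 0,    range_max = 0.9),
         PVS1_MODERATE = list(points = 0,    range_min = 0,    range_max = 0),
         NONE          = list(points = 0,    range_min = 0,    range_max = 0))
  }
  map[[strength]]
}

#' Merge manual evidence into automated evidence items
#'
#' Validates user-supplied points against the metric configuration (category
#' exists for the dosage, points within the configured range, and — in
#' strict mode — a whole multiple of the adjustment step away from the
#' default) and appends them as `MANUAL` items. A manual entry for a
#' category that was scored automatically replaces the automated points and
#' is flagged `user-adjusted`.
#'
#' @param auto_items Evidence data frame from the automated scorers.
#' @param manual Data frame (or list of lists) with columns `category`,
#'   `points` and optional `note`.
#' @param cfg A `metric_config`.
#' @param dosage `"LOSS"` or `"GAIN"` — the dosage of the query being scored.
#' @param strict Enforce that points differ from the default by a multiple
#'   of `cfg$adjustment_step`.
#' @return Merged evidence data frame.
#' @export
merge_manual <- function(auto_items, manual, cfg, dosage, strict = TRUE) {
  if (is.null(manual) || (is.data.frame(manual) && nrow(manual) == 0L))
    return(auto_items)
  if (!is.data.frame(manual))
    manual <- do.call(rbind, lapply(manual, function(m)
      data.frame(category = m$category, points = m$points,
                 note = m$note %||% "", stringsAsFactors = FALSE)))
  if (!"note" %in% names(manual)) manual$note <- ""
  manual$points <- as.numeric(manual$points)

  if (anyDuplicated(manual$category))
    cnv_abort(sprintf("duplicate manual evidence for category %s",
                      manual$category[duplicated(manual$category)][1]),
              "cnvscore_validation_error")

  items <- auto_items
  step_h <- to_hundredths(cfg$adjustment_step)
  for (i in seq_len(nrow(manual))) {
    cat_id <- manual$category[i]
    pts <- manual$points[i]
    row <- metric_row(cfg, dosage, cat_id)   # errors on wrong-dosage category
    if (pts < row$min || pts > row$max)
      cnv_abort(sprintf("manual points %.2f for category %s outside range [%.2f, %.2f]",
                        pts, cat_id, row$min, row$max),
                "cnvscore_validation_error")
    if (strict && (to_hundredths(pts) - to_hundredths(row$default)) %% step_h != 0L)
      cnv_abort(sprintf("manual points %.2f for category %s not a multiple of %.2f from default %.2f",
                        pts, cat_id, cfg$adjustment_step, row$default),
                "cnvscore_validation_error")
    prior <- which(items$category == cat_id & items$source == "AUTOMATED" &
                     items$contributes)
    flag_adjusted <- length(prior) > 0L
    if (flag_adjusted) items$contributes[prior] <- FALSE
    items <- rbind(items, evidence_item(
      category = cat_id, points = pts, range_min = row$min,
      range_max = row$max, source = "MANUAL", contributes = TRUE,
      rationale = paste0(if (flag_adjusted) "user-adjusted; " else "",
                         if (nzchar(manual$note[i])) manual$note[i]
                         else row$description),
      element_refs = ""))
  }
  items
}
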