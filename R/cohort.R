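# Column schema for the on-disk cohort CSV (one row per patient).
# Hematocrit columns are in percent on disk by default; internally every
# hematocrit is a fraction in (0, 1).
.cohort_csv_cols <- c(
  "patient_id", "sex", "age", "height_cm", "weight_kg",
  "stone_burden_mm2", "stone_type",
  "hct_preop", "hct_12h", "hct_24h", "hct_36h", "hct_72h",
  "crossmatched_ml", "transfused_intraop_ml", "transfused_postop_ml",
  "product_hct"
)

.hct_cols <- c("hct_preop", "hct_12h", "hct_24h", "hct_36h", "hct_72h")

.sex_levels <- c("male", "female")
.stone_levels <- c("staghorn", "non_staghorn", "unknown")

#' Construct a validated PCNL cohort
#'
#' A cohort is a plain `data.frame` with class `pcnl_cohort`, one row per
#' patient.  Hematocrits are stored internally as fractions in (0, 1): the
#' red-cell-mass chain (`EBV * Hct`) is dimensionally meaningful only on that
#' scale, and the transfused-volume addend in total RBC loss means a percent
#' scale would not cancel.  File I/O accepts percent (the clinical
#' convention) and converts at the boundary.
#'
#' @param data data.frame carrying the cohort columns (see
#'   [read_cohort()] for the schema).  Missing optional columns
#'   (`hct_12h`, `hct_24h`, `hct_36h`, `stone_type`, `product_hct`) are
#'   filled with `NA` / defaults.
#' @return `data` with class `pcnl_cohort`, validated.
#' @seealso [validate_cohort()], [read_cohort()]
#' @export
pcnl_cohort <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"stone_type" %in% names(data)) data$stone_type <- "unknown"
  if (!"product_hct" %in% names(data)) data$product_hct <- 1.0
  data$product_hct[is.na(data$product_hct)] <- 1.0
  for (h in .hct_cols) if (!h %in% names(data)) data[[h]] <- NA_real_
  missing <- setdiff(setdiff(.cohort_csv_cols, c("hct_12h", "hct_24h", "hct_36h")),
                     names(data))
  if (length(missing)) {
    stop(errorCondition(
      sprintf("cohort is missing mandatory column(s): %s",
              paste(missing, collapse = ", ")),
      class = c("pcnl_schema_error", "error", "condition")))
  }
  data <- data[, .cohort_csv_cols]
  data$patient_id <- as.character(data$patient_id)
  class(data) <- c("pcnl_cohort", "data.frame")
  validate_cohort(data)
}

#' Validate a PCNL cohort against its domain invariants
#'
#' Checks, per patient: height and weight positive; stone burden
#' non-negative; age at least 18 (adult inclusion criterion); cross-matched
#' and transfused volumes non-negative; every stored hematocrit a fraction
#' in (0, 1); the pre-operative hematocrit and at least one post-operative
#' draw present; sex and stone type among the known levels; product
#' hematocrit in (0, 1].  Violations are reported together, indexed by row
#' and patient id, as a classed `pcnl_validation_error`.
#'
#' @param cohort a `pcnl_cohort` (hematocrits already fractions).
#' @return the cohort, invisibly-valid (returned unchanged).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (n == 0L) {
    stop(errorCondition("cohort has no records",
                        class = c("pcnl_validation_error", "error", "condition")))
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      problems <<- c(problems, sprintf(
        "row %d (patient %s): %s", idx, cohort$patient_id[idx], what))
    }
  }
  note(!cohort$sex %in% .sex_levels, "sex must be 'male' or 'female'")
  note(!cohort$stone_type %in% .stone_levels,
       "stone_type must be staghorn/non_staghorn/unknown")
  note(is.na(cohort$height_cm) | cohort$height_cm <= 0, "height must be > 0")
  note(is.na(cohort$weight_kg) | cohort$weight_kg <= 0, "weight must be > 0")
  note(is.na(cohort$stone_burden_mm2) | cohort$stone_burden_mm2 < 0,
       "stone burden must be >= 0")
  note(is.na(cohort$age) | cohort$age < 18, "age must be >= 18 years")
  note(is.na(cohort$crossmatched_ml) | cohort$crossmatched_ml < 0,
       "cross-matched volume must be >= 0")
  note(is.na(cohort$transfused_intraop_ml) | cohort$transfused_intraop_ml < 0,
       "intra-operative transfused volume must be >= 0")
  note(is.na(cohort$transfused_postop_ml) | cohort$transfused_postop_ml < 0,
       "post-operative transfused volume must be >= 0")
  note(is.na(cohort$product_hct) | cohort$product_hct <= 0 | cohort$product_hct > 1,
       "product hematocrit must be in (0, 1]")
  for (h in .hct_cols) {
    note(!is.na(cohort[[h]]) & (cohort[[h]] <= 0 | cohort[[h]] >= 1),
         sprintf("%s must be a fraction in (0, 1)", h))
  }
  note(is.na(cohort$hct_preop), "pre-operative hematocrit is mandatory")
  post <- as.matrix(cohort[, c("hct_12h", "hct_24h", "hct_36h", "hct_72h")])
  note(rowSums(!is.na(post)) == 0,
       "at least one post-operative hematocrit is required")
  if (length(problems)) {
    stop(errorCondition(
      paste0("cohort validation failed:\n  ",
             paste(problems, collapse = "\n  ")),
      class = c("pcnl_validation_error", "error", "condition")))
  }
  cohort
}

#' Read a PCNL cohort from CSV
#'
#' Expects one row per patient with header columns `patient_id, sex {M,F},
#' age, height_cm, weight_kg, stone_burden_mm2, stone_type, hct_preop,
#' hct_12h, hct_24h, hct_36h, hct_72h, crossmatched_ml,
#' transfused_intraop_ml, transfused_postop_ml, product_hct`.
#' `stone_type` and `product_hct` are optional (defaults `unknown` and 1.0,
#' i.e. whole-blood accounting of the transfused product).  Hematocrit
#' columns are percent by default and converted to fractions on read; no
#' record with an out-of-range hematocrit ever escapes the reader.
#'
#' @param path CSV file path.
#' @param hct_unit `"percent"` (default) or `"fraction"` — the unit of the
#'   hematocrit columns on disk.
#' @return a validated [pcnl_cohort()], rows in file order.
#' @export
read_cohort <- function(path, hct_unit = c("percent", "fraction")) {
  hct_unit <- match.arg(hct_unit)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  # sex codes M/F must never be parsed as logicals
  char_cols <- c("patient_id", "sex", "stone_type")
  header <- names(utils::read.csv(path, nrows = 1))
  cc <- rep("character", length(intersect(char_cols, header)))
  names(cc) <- intersect(char_cols, header)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  mandatory <- setdiff(.cohort_csv_cols,
                       c("stone_type", "product_hct", "hct_12h", "hct_24h", "hct_36h"))
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop(errorCondition(
      sprintf("CSV is missing mandatory column(s): %s",
              paste(missing, collapse = ", ")),
      class = c("pcnl_schema_error", "error", "condition")))
  }
  raw$sex <- c(M = "male", F = "female", male = "male", female = "female")[
    as.character(raw$sex)]
  if (hct_unit == "percent") {
    for (h in intersect(.hct_cols, names(raw))) {
      bad <- !is.na(raw[[h]]) & (raw[[h]] <= 0 | raw[[h]] > 100)
      if (any(bad)) {
        stop(errorCondition(
          sprintf("hematocrit %s outside (0, 100] percent for patient(s): %s",
                  h, paste(raw$patient_id[bad], collapse = ", ")),
          class = c("pcnl_validation_error", "error", "condition")))
      }
      raw[[h]] <- raw[[h]] / 100
    }
  }
  pcnl_cohort(raw)
}

#' Write a PCNL cohort to CSV
#'
#' Inverse of [read_cohort()]: hematocrit fractions are written back in the
#' requested unit.  Extra columns beyond the cohort schema (e.g. the
#' synthetic generator's `tbl_true_ml`) are dropped.  Read-after-write
#' reproduces the cohort field-for-field to within 1e-9 on numeric fields.
#'
#' @param cohort a validated [pcnl_cohort()]; must be non-empty.
#' @param path output CSV path.
#' @param hct_unit unit for the hematocrit columns on disk.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, hct_unit = c("percent", "fraction")) {
  hct_unit <- match.arg(hct_unit)
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must contain at least one record")
  }
  cohort <- validate_cohort(pcnl_cohort(cohort))
  out <- as.data.frame(cohort)[, .cohort_csv_cols]
  out$sex <- c(male = "M", female = "F")[out$sex]
  if (hct_unit == "percent") {
    for (h in .hct_cols) out[[h]] <- out[[h]] * 100
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read pipeline configuration from a YAML file
#'
#' Recognised keys (all optional): `hct_unit` ("percent"/"fraction"),
#' `final_timepoint` (default `"hct_72h"`), `product_hct` (default 1.0),
#' `adequacy_threshold` (default 0.15, the under/over-transfusion band as a
#' fraction of total blood loss).
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return named list of settings with defaults filled in.
#' @export
read_pcnl_config <- function(path = NULL) {
  defaults <- list(hct_unit = "percent", final_timepoint = "hct_72h",
                   product_hct = 1.0, adequacy_threshold = 0.15)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.null(user$hct_unit) &&
      !user$hct_unit %in% c("percent", "fraction")) {
    stop("config: hct_unit must be 'percent' or 'fraction'")
  }
  utils::modifyList(defaults, user[intersect(names(user), names(defaults))])
}
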