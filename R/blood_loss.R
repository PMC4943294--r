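#' Body surface area from height and weight
#'
#' Power-law anthropometric formula
#' `BSA = 0.0235 * height^0.42246 * weight^0.51456` (height in cm, weight in
#' kg, BSA in m^2).
#'
#' @param height_cm height in centimetres, > 0.
#' @param weight_kg body weight in kilograms, > 0.
#' @return body surface area in m^2; vectorised.
#' @examples
#' body_surface_area(170, 70)
#' @export
body_surface_area <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive and finite")
  }
  0.0235 * height_cm^0.42246 * weight_kg^0.51456
}

#' Sex-specific estimated blood volume
#'
#' Total blood volume predicted from body surface area:
#' 2530 mL/m^2 for males, 2430 mL/m^2 for females.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param bsa_m2 body surface area in m^2, > 0.
#' @return estimated blood volume in mL.
#' @export
estimated_blood_volume <- function(sex, bsa_m2) {
  if (any(!sex %in% .sex_levels)) stop("sex must be 'male' or 'female'")
  if (any(!is.finite(bsa_m2)) || any(bsa_m2 <= 0)) stop("bsa must be > 0")
  ifelse(sex == "male", 2530, 2430) * bsa_m2
}

#' Red-cell-mass loss from the perioperative hematocrit shift
#'
#' The uncompensated red-cell loss is the red-cell volume reflected in the
#' pre-to-post hematocrit drop, `EBV * (hct_initial - hct_final)`; it may be
#' negative when the hematocrit rises.  The compensated loss is the
#' red-cell volume returned by transfusion.  The total is their sum.
#'
#' @param ebv_ml estimated blood volume, mL.
#' @param hct_initial,hct_final pre-operative and final (72-h post-operative)
#'   hematocrits as fractions in (0, 1).
#' @param transfused_rbc_ml red-cell volume transfused between the two
#'   draws, mL (>= 0); product volume times product hematocrit.
#' @return data.frame with columns `uncompensated_ml`, `compensated_ml`,
#'   `total_ml`; vectorised over its arguments.
#' @export
rbc_loss <- function(ebv_ml, hct_initial, hct_final, transfused_rbc_ml = 0) {
  .check_hct_fraction(hct_initial, "hct_initial")
  .check_hct_fraction(hct_final, "hct_final")
  if (any(transfused_rbc_ml < 0)) stop("transfused RBC volume must be >= 0")
  unc <- ebv_ml * (hct_initial - hct_final)
  data.frame(uncompensated_ml = unc,
             compensated_ml = transfused_rbc_ml + 0 * unc,
             total_ml = unc + transfused_rbc_ml)
}

#' Hemodilution-corrected total blood loss
#'
#' Converts total red-cell loss back to a whole-blood-equivalent volume by
#' dividing by the mean of the pre-operative and final hematocrits:
#' `TBL = total_rbc_loss / (0.5 * (hct_initial + hct_final))`.
#'
#' @param total_rbc_loss_ml total red-cell loss, mL.
#' @inheritParams rbc_loss
#' @return total blood loss in mL.
#' @export
total_blood_loss <- function(total_rbc_loss_ml, hct_initial, hct_final) {
  .check_hct_fraction(hct_initial, "hct_initial")
  .check_hct_fraction(hct_final, "hct_final")
  total_rbc_loss_ml / (0.5 * (hct_initial + hct_final))
}

.check_hct_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(errorCondition(
      sprintf("%s must be a hematocrit fraction in (0, 1)", name),
      class = c("pcnl_domain_error", "error", "condition")))
  }
  invisible(x)
}

#' Per-patient blood-loss estimates for a cohort
#'
#' Runs the full chain for every patient: body surface area, sex-adjusted
#' estimated blood volume, initial/final red-cell volumes, uncompensated and
#' compensated red-cell loss, and hemodilution-corrected total blood loss.
#' The initial hematocrit is the pre-operative draw and the final is the
#' 72-hour post-operative draw; the 12/24/36-h draws are carried for QC only.
#' The compensated (transfused) red-cell volume is
#' `(transfused_intraop_ml + transfused_postop_ml) * product_hct`.
#'
#' Patients without a 72-h hematocrit cannot be estimated.  With
#' `on_missing = "exclude"` (complete-case default) they are dropped with a
#' message and listed in the `excluded` attribute; `"error"` aborts naming
#' the patients.
#'
#' @param cohort a validated [pcnl_cohort()].
#' @param on_missing `"exclude"` (default) or `"error"`.
#' @return data.frame keyed by `patient_id` with columns `bsa_m2`, `ebv_ml`,
#'   `initial_rbc_ml`, `final_rbc_ml`, `uncompensated_rbc_loss_ml`,
#'   `compensated_rbc_loss_ml`, `total_rbc_loss_ml`, `tbl_ml`, and attribute
#'   `excluded` (character vector of patient ids without a final draw).
#' @examples
#' coh <- pcnl_cohort(data.frame(
#'   patient_id = "p1", sex = "female", age = 45, height_cm = 160,
#'   weight_kg = 55, stone_burden_mm2 = 900, hct_preop = 0.40,
#'   hct_72h = 0.35, crossmatched_ml = 400, transfused_intraop_ml = 0,
#'   transfused_postop_ml = 0))
#' estimate_blood_loss(coh)
#' @export
estimate_blood_loss <- function(cohort, on_missing = c("exclude", "error")) {
  on_missing <- match.arg(on_missing)
  cohort <- validate_cohort(cohort)
  no_final <- is.na(cohort$hct_72h)
  if (any(no_final)) {
    ids <- cohort$patient_id[no_final]
    if (on_missing == "error") {
      stop(errorCondition(
        sprintf("missing 72-h hematocrit for patient(s): %s",
                paste(ids, collapse = ", ")),
        class = c("pcnl_estimation_error", "error", "condition")))
    }
    message(sprintf("excluding %d record(s) without a 72-h hematocrit: %s",
                    length(ids), paste(ids, collapse = ", ")))
  }
  x <- cohort[!no_final, , drop = FALSE]
  bsa <- body_surface_area(x$height_cm, x$weight_kg)
  ebv <- estimated_blood_volume(x$sex, bsa)
  transfused_rbc <- (x$transfused_intraop_ml + x$transfused_postop_ml) *
    x$product_hct
  loss <- rbc_loss(ebv, x$hct_preop, x$hct_72h, transfused_rbc)
  out <- data.frame(
    patient_id = x$patient_id,
    bsa_m2 = bsa,
    ebv_ml = ebv,
    initial_rbc_ml = ebv * x$hct_preop,
    final_rbc_ml = ebv * x$hct_72h,
    uncompensated_rbc_loss_ml = loss$uncompensated_ml,
    compensated_rbc_loss_ml = loss$compensated_ml,
    total_rbc_loss_ml = loss$total_ml,
    tbl_ml = total_blood_loss(loss$total_ml, x$hct_preop, x$hct_72h),
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- cohort$patient_id[no_final]
  out
}
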