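#' Classify a patient's transfusion pattern
#'
#' Pattern is read off the two transfusion-volume fields: `none`,
#' `intra_only`, `post_only`, or `both`.
#'
#' @param transfused_intraop_ml,transfused_postop_ml transfused volumes, mL
#'   (vectorised, >= 0).
#' @return factor with levels `none`, `intra_only`, `post_only`, `both`.
#' @export
classify_transfusion_pattern <- function(transfused_intraop_ml,
                                         transfused_postop_ml) {
  if (any(transfused_intraop_ml < 0) || any(transfused_postop_ml < 0)) {
    stop("transfused volumes must be >= 0")
  }
  i <- transfused_intraop_ml > 0
  p <- transfused_postop_ml > 0
  out <- ifelse(i & p, "both",
                ifelse(i, "intra_only", ifelse(p, "post_only", "none")))
  factor(out, levels = c("none", "intra_only", "post_only", "both"))
}

#' Cross-match-to-transfusion (CT) ratio
#'
#' Blood-bank utilisation metric: amount cross-matched divided by amount
#' transfused.  At cohort level the numerator includes cross-matched blood
#' for patients never transfused — that is the point of the metric — so the
#' ratio exceeds 1 whenever preparation outstrips use.  Units cancel, so mL
#' or blood units work equally as long as both totals use the same unit.
#'
#' @param crossmatched_total total cross-matched amount (mL or units).
#' @param transfused_total total transfused amount, same unit; must be > 0.
#' @return the dimensionless ratio.
#' @export
ct_ratio <- function(crossmatched_total, transfused_total) {
  if (!is.finite(transfused_total) || transfused_total <= 0) {
    stop(errorCondition(
      "no transfusions; CT ratio undefined",
      class = c("pcnl_undefined_ratio_error", "error", "condition")))
  }
  if (crossmatched_total < 0) stop("cross-matched total must be >= 0")
  crossmatched_total / transfused_total
}

#' Classify transfusion adequacy against estimated blood loss
#'
#' A transfusion is adequate when the transfused volume is within
#' `threshold` (default 15%) of the estimated total blood loss;
#' `under` when the deficit exceeds the threshold, `over` when the excess
#' does.  A patient with zero estimated loss is `adequate` if untransfused
#' and `over` otherwise.
#'
#' @param tbl_ml estimated total blood loss, mL (>= 0; vectorised).
#' @param transfused_ml total transfused volume, mL (>= 0).
#' @param threshold tolerated relative deviation, fraction of TBL.
#' @return factor with levels `under`, `adequate`, `over`.
#' @export
classify_adequacy <- function(tbl_ml, transfused_ml, threshold = 0.15) {
  if (any(tbl_ml < 0) || any(transfused_ml < 0)) {
    stop(errorCondition("tbl and transfused volume must be >= 0",
                        class = c("pcnl_domain_error", "error", "condition")))
  }
  if (threshold < 0) stop("threshold must be >= 0")
  delta <- ifelse(tbl_ml > 0, (transfused_ml - tbl_ml) / tbl_ml,
                  ifelse(transfused_ml > 0, Inf, 0))
  out <- ifelse(delta > threshold, "over",
                ifelse(delta < -threshold, "under", "adequate"))
  factor(out, levels = c("under", "adequate", "over"))
}

#' Cohort-level transfusion audit
#'
#' Aggregates per-patient transfusion patterns and adequacy classes into a
#' cohort audit: transfusion rate, pattern proportions, the
#' cross-match-to-transfusion ratio over all cross-matched volume (including
#' never-transfused patients), mean cross-matched volume, and mean
#' transfused volume among transfused patients.  Adequacy counts are
#' reported both over transfused patients and over the whole cohort.
#'
#' @param cohort a validated [pcnl_cohort()].
#' @param estimates result of [estimate_blood_loss()] on the same cohort;
#'   computed if omitted.  Patients without an estimate (no 72-h draw) get
#'   `NA` adequacy but still count in the pattern table and CT ratio.
#' @param threshold adequacy band, fraction of TBL (default 0.15).
#' @return object of class `pcnl_audit`: list with `per_patient`
#'   (data.frame: patient_id, pattern, transfused_ml, tbl_ml, adequacy) and
#'   `summary` (n, n_transfused, transfusion_rate_pct, pattern_pct,
#'   ct_ratio, mean_crossmatched_ml, mean_transfused_ml, adequacy counts).
#' @export
audit_transfusion <- function(cohort, estimates = NULL, threshold = 0.15) {
  cohort <- validate_cohort(cohort)
  if (is.null(estimates)) {
    estimates <- suppressMessages(estimate_blood_loss(cohort))
  }
  n <- nrow(cohort)
  transfused_ml <- cohort$transfused_intraop_ml + cohort$transfused_postop_ml
  pattern <- classify_transfusion_pattern(cohort$transfused_intraop_ml,
                                          cohort$transfused_postop_ml)
  tbl <- estimates$tbl_ml[match(cohort$patient_id, estimates$patient_id)]
  adequacy <- factor(rep(NA_character_, n),
                     levels = c("under", "adequate", "over"))
  ok <- !is.na(tbl)
  if (any(ok)) {
    adequacy[ok] <- classify_adequacy(pmax(tbl[ok], 0), transfused_ml[ok],
                                      threshold)
  }
  per_patient <- data.frame(
    patient_id = cohort$patient_id, pattern = pattern,
    transfused_ml = transfused_ml, tbl_ml = tbl, adequacy = adequacy,
    stringsAsFactors = FALSE)

  is_transfused <- pattern != "none"
  pattern_pct <- 100 * as.vector(table(pattern)) / n
  names(pattern_pct) <- levels(pattern)
  total_transfused <- sum(transfused_ml)
  ctr <- if (total_transfused > 0) {
    ct_ratio(sum(cohort$crossmatched_ml), total_transfused)
  } else NA_real_
  summary <- list(
    n = n,
    n_transfused = sum(is_transfused),
    transfusion_rate_pct = 100 * mean(is_transfused),
    pattern_pct = pattern_pct,
    ct_ratio = ctr,
    mean_crossmatched_ml = mean(cohort$crossmatched_ml),
    mean_transfused_ml = if (any(is_transfused)) {
      mean(transfused_ml[is_transfused])
    } else NA_real_,
    adequacy_transfused = table(adequacy[is_transfused & ok]),
    adequacy_cohort = table(adequacy[ok]),
    threshold = threshold)
  structure(list(per_patient = per_patient, summary = summary),
            class = "pcnl_audit")
}

#' @export
print.pcnl_audit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PCNL transfusion audit (n = %d, adequacy band +/-%.0f%% of TBL)\n",
              s$n, 100 * s$threshold))
  cat(sprintf("  transfusion rate: %.1f%% (%d/%d)\n",
              s$transfusion_rate_pct, s$n_transfused, s$n))
  for (lev in names(s$pattern_pct)) {
    cat(sprintf("    %-11s %5.1f%%\n", lev, s$pattern_pct[[lev]]))
  }
  cat(sprintf("  mean cross-matched: %.2f mL\n", s$mean_crossmatched_ml))
  if (!is.na(s$mean_transfused_ml)) {
    cat(sprintf("  mean transfused (transfused patients): %.2f mL\n",
                s$mean_transfused_ml))
  }
  cat(sprintf("  CT ratio: %s\n",
              if (is.na(s$ct_ratio)) "undefined (no transfusions)"
              else sprintf("%.2f", s$ct_ratio)))
  ac <- s$adequacy_cohort
  cat(sprintf("  adequacy (whole cohort): under %d / adequate %d / over %d\n",
              ac[["under"]], ac[["adequate"]], ac[["over"]]))
  invisible(x)
}
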