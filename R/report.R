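#' Assemble the full pipeline report for a cohort
#'
#' Runs every stage on a cohort and collects the results into one object:
#' cohort characteristics; blood-loss summary (mean/sd/median and the
#' 2.5-97.5% range of total blood loss, mean hematocrit drop); bivariate
#' predictor screening; the stepwise model fitted to the screened-in
#' candidates next to the fixed published predictor; and the transfusion
#' audit.  Every number in the report is recomputable from the cohort and
#' the settings.
#'
#' @param cohort a validated [pcnl_cohort()].
#' @param threshold transfusion-adequacy band (fraction of TBL).
#' @param entry_p bivariate screening threshold for model entry.
#' @return object of class `pcnl_report` with elements `cohort_summary`,
#'   `blood_loss`, `screening`, `model`, `published`, `audit`, `excluded`.
#' @export
pipeline_report <- function(cohort, threshold = 0.15, entry_p = 0.25) {
  cohort <- validate_cohort(cohort)
  est <- suppressMessages(estimate_blood_loss(cohort))
  merged <- merge(as.data.frame(cohort), est, by = "patient_id")
  merged$baseline_hct_pct <- 100 * merged$hct_preop

  screening <- bivariate_screen(merged, outcome = "tbl_ml",
                                entry_p = entry_p, on_constant = "drop")
  candidates <- screening$variable[screening$passes_entry]
  model <- if (length(candidates)) {
    fit_stepwise(merged, outcome = "tbl_ml", candidates = candidates)
  } else NULL

  drop_pp <- 100 * (merged$hct_preop - merged$hct_72h)
  blood_loss <- list(
    n_estimated = nrow(est),
    mean_tbl_ml = mean(est$tbl_ml), sd_tbl_ml = stats::sd(est$tbl_ml),
    median_tbl_ml = stats::median(est$tbl_ml),
    tbl_range_95 = stats::quantile(est$tbl_ml, c(0.025, 0.975), names = FALSE),
    mean_hct_drop_pp = mean(drop_pp), sd_hct_drop_pp = stats::sd(drop_pp))

  cohort_summary <- list(
    n = nrow(cohort),
    n_male = sum(cohort$sex == "male"),
    n_female = sum(cohort$sex == "female"),
    mean_age = mean(cohort$age), sd_age = stats::sd(cohort$age),
    staghorn_pct = 100 * mean(cohort$stone_type == "staghorn"),
    mean_stone_burden_mm2 = mean(cohort$stone_burden_mm2))

  structure(list(cohort_summary = cohort_summary, blood_loss = blood_loss,
                 screening = screening, model = model,
                 published = published_model(),
                 audit = audit_transfusion(cohort, est, threshold),
                 excluded = attr(est, "excluded")),
            class = "pcnl_report")
}

#' Render a pipeline report as Markdown
#'
#' Percentages are printed to 1 decimal, volumes to 2, coefficients to 3,
#' mirroring conventional clinical reporting.
#'
#' @param report a [pipeline_report()] result.
#' @return character vector of Markdown lines.
#' @export
format_report_md <- function(report) {
  stopifnot(inherits(report, "pcnl_report"))
  cs <- report$cohort_summary; bl <- report$blood_loss
  a <- report$audit$summary
  lines <- c(
    "# PCNL blood-loss and transfusion report", "",
    "## Cohort",
    sprintf("- n = %d (%d male / %d female)", cs$n, cs$n_male, cs$n_female),
    sprintf("- age: %.2f +/- %.2f years", cs$mean_age, cs$sd_age),
    sprintf("- staghorn calculi: %.1f%%", cs$staghorn_pct),
    sprintf("- mean stone burden: %.2f mm2", cs$mean_stone_burden_mm2), "",
    "## Blood loss",
    sprintf("- estimated patients: %d%s", bl$n_estimated,
            if (length(report$excluded)) {
              sprintf(" (%d excluded, no 72-h hematocrit)",
                      length(report$excluded))
            } else ""),
    sprintf("- total blood loss: %.2f +/- %.2f mL, median %.2f (95%% range %.2f-%.2f) mL",
            bl$mean_tbl_ml, bl$sd_tbl_ml, bl$median_tbl_ml,
            bl$tbl_range_95[1], bl$tbl_range_95[2]),
    sprintf("- mean hematocrit drop: %.2f +/- %.2f percentage points",
            bl$mean_hct_drop_pp, bl$sd_hct_drop_pp), "",
    "## Predictor screening (entry p < 0.25)",
    "| variable | method | r | p | enters |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3f | %s |",
            report$screening$variable, report$screening$method,
            report$screening$r, report$screening$p,
            ifelse(report$screening$passes_entry, "yes", "no")), "",
    "## Fitted model")
  lines <- c(lines,
    if (is.null(report$model)) {
      "- no candidate passed screening; no model fitted"
    } else {
      c(paste0("- ", .equation_text(report$model)),
        sprintf("- R^2 = %.3f, n = %d", report$model$r_squared,
                report$model$n))
    },
    paste0("- published comparator: ", .equation_text(report$published)), "",
    "## Transfusion audit",
    sprintf("- transfusion rate: %.1f%% (%d/%d)", a$transfusion_rate_pct,
            a$n_transfused, a$n),
    sprintf("- pattern: none %.1f%%, intra-only %.1f%%, post-only %.1f%%, both %.1f%%",
            a$pattern_pct[["none"]], a$pattern_pct[["intra_only"]],
            a$pattern_pct[["post_only"]], a$pattern_pct[["both"]]),
    sprintf("- mean cross-matched: %.2f mL", a$mean_crossmatched_ml),
    if (!is.na(a$mean_transfused_ml)) {
      sprintf("- mean transfused (among transfused): %.2f mL",
              a$mean_transfused_ml)
    } else "- no transfusions given",
    sprintf("- CT ratio: %s",
            if (is.na(a$ct_ratio)) "undefined (no transfusions)"
            else sprintf("%.2f", a$ct_ratio)),
    sprintf("- adequacy (whole cohort): under %d / adequate %d / over %d",
            a$adequacy_cohort[["under"]], a$adequacy_cohort[["adequate"]],
            a$adequacy_cohort[["over"]]))
  lines
}

.equation_text <- function(model) {
  co <- model$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  eq <- sprintf("TBL (mL) = %.3f", co[["(Intercept)"]])
  for (v in terms) eq <- paste0(eq, sprintf(" + %.3f x %s", co[[v]], v))
  eq
}

#' @export
print.pcnl_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
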