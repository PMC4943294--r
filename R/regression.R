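# Fixed coefficients of the published blood-loss predictor.
# TBL (mL) = -153.379 + 0.229 * stone burden (mm^2)
#                     + 0.203 * baseline serum hematocrit (%)
.published_coef <- c(`(Intercept)` = -153.379,
                     stone_burden_mm2 = 0.229,
                     baseline_hct_pct = 0.203)

#' Predict total blood loss from the published linear model
#'
#' Evaluates the fixed-coefficient predictor
#' `TBL = -153.379 + 0.229 * stone_burden + 0.203 * baseline_hct` with stone
#' burden in mm^2 and baseline hematocrit in PERCENT (the equation's scale).
#' The estimator chain elsewhere in this package carries hematocrits as
#' fractions, so this boundary is explicit: a hematocrit below 1 is rejected
#' as a probable unit mix-up rather than silently mispredicted.
#'
#' @param stone_burden_mm2 stone burden (length x width) in mm^2, >= 0.
#' @param baseline_hct_pct baseline serum hematocrit in percent, in (1, 100).
#' @return predicted total blood loss in mL (full precision; reports round
#'   to 2 decimals).  Vectorised.
#' @examples
#' predict_published(1000, 40)  # 83.741
#' @export
predict_published <- function(stone_burden_mm2, baseline_hct_pct) {
  if (any(stone_burden_mm2 < 0)) stop("stone burden must be >= 0")
  if (any(baseline_hct_pct < 1 & baseline_hct_pct != 0)) {
    stop(errorCondition(
      "baseline hematocrit looks like a fraction; supply PERCENT (e.g. 40)",
      class = c("pcnl_unit_error", "error", "condition")))
  }
  if (any(baseline_hct_pct < 0 | baseline_hct_pct >= 100)) {
    stop("baseline hematocrit percent must be in [0, 100)")
  }
  .published_coef[[1]] +
    .published_coef[[2]] * stone_burden_mm2 +
    .published_coef[[3]] * baseline_hct_pct
}

#' The published blood-loss model as a fitted-model object
#'
#' @return a `pcnl_tbl_model` carrying the published intercept and slopes
#'   (stone burden in mL per mm^2, baseline hematocrit in mL per percentage
#'   point); per-term p-values and R^2 are `NA` (not reported for the
#'   final equation).
#' @export
published_model <- function() {
  structure(list(coefficients = .published_coef,
                 p_values = c(`(Intercept)` = NA_real_,
                              stone_burden_mm2 = NA_real_,
                              baseline_hct_pct = NA_real_),
                 n = 85L, r_squared = NA_real_,
                 excluded = character(0), source = "published"),
            class = "pcnl_tbl_model")
}

#' Bivariate screening of candidate predictors against blood loss
#'
#' Correlates each candidate column with the outcome using Pearson or
#' Spearman correlation (two-sided tests, no multiplicity correction) and
#' flags candidates passing the liberal model-entry screen p < 0.25.  The
#' default method map mirrors clinical practice for these variables:
#' Pearson for baseline hematocrit and age, Spearman (rank-based) for the
#' skewed counts and chemistry values.
#'
#' @param data data.frame holding the candidate columns and the outcome.
#' @param outcome outcome column name (default `"tbl_ml"`).
#' @param variables candidate column names; defaults to every default-map
#'   variable present in `data`.
#' @param methods named character vector mapping variable -> "pearson" or
#'   "spearman"; unmapped variables default to "spearman".
#' @param entry_p screening threshold (default 0.25).
#' @param on_constant `"error"` (default) raises a classed
#'   `pcnl_constant_variable_error` naming any constant candidate (its
#'   correlation is undefined); `"drop"` removes such candidates with a
#'   warning.
#' @return data.frame: `variable`, `method`, `r`, `p`, `passes_entry`
#'   (`p < entry_p`), `n` complete pairs, ordered as given.
#' @export
bivariate_screen <- function(data, outcome = "tbl_ml", variables = NULL,
                             methods = NULL, entry_p = 0.25,
                             on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  default_map <- c(stone_burden_mm2 = "spearman", n_stones = "spearman",
                   creatinine_mgdl = "spearman", rbc_count = "spearman",
                   hct_preop = "pearson", hemoglobin_gdl = "spearman",
                   bmi = "spearman", age = "pearson",
                   operative_time_min = "spearman")
  if (is.null(variables)) {
    variables <- intersect(names(default_map), names(data))
  }
  missing <- setdiff(c(outcome, variables), names(data))
  if (length(missing)) {
    stop("column(s) not in data: ", paste(missing, collapse = ", "))
  }
  map <- default_map
  if (!is.null(methods)) map[names(methods)] <- methods
  y <- data[[outcome]]
  constant <- vapply(variables, function(v) {
    x <- data[[v]][stats::complete.cases(data[[v]], y)]
    length(unique(x)) < 2L
  }, logical(1))
  if (any(constant)) {
    msg <- sprintf("correlation undefined for constant variable(s): %s",
                   paste(variables[constant], collapse = ", "))
    if (on_constant == "error") {
      stop(errorCondition(msg, class = c("pcnl_constant_variable_error",
                                         "error", "condition")))
    }
    warning(msg)
    variables <- variables[!constant]
  }
  rows <- lapply(variables, function(v) {
    m <- if (v %in% names(map)) map[[v]] else "spearman"
    keep <- stats::complete.cases(data[[v]], y)
    if (sum(keep) < 3L) stop("fewer than 3 complete pairs for ", v)
    ct <- suppressWarnings(
      stats::cor.test(data[[v]][keep], y[keep], method = m, exact = FALSE))
    data.frame(variable = v, method = m, r = unname(ct$estimate),
               p = ct$p.value, passes_entry = ct$p.value < entry_p,
               n = sum(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Forward stepwise ordinary least squares with p-value entry/removal
#'
#' Builds a linear model for the outcome by forward selection over
#' pre-screened candidates: at each step the candidate with the smallest
#' partial p-value enters if it clears `alpha_enter`; after each entry,
#' included terms whose p-value has drifted above `alpha_remove` are
#' dropped (worst first).  Candidates are typically the variables passing
#' [bivariate_screen()]; the fit never contains a variable outside the
#' caller's candidate set.  With no candidate clearing entry the result is
#' the intercept-only model.
#'
#' @param data data.frame with outcome and candidate columns (complete
#'   cases used).
#' @param outcome outcome column name.
#' @param candidates character vector of candidate column names, non-empty.
#' @param alpha_enter entry threshold on the partial p-value (default 0.05).
#' @param alpha_remove removal threshold (default 0.10).
#' @return a `pcnl_tbl_model`: `coefficients`, `p_values` (t-tests), `n`,
#'   `r_squared`, `excluded` (candidates not selected), and the underlying
#'   `lm` fit (`NULL` for the published model).
#' @export
fit_stepwise <- function(data, outcome = "tbl_ml", candidates,
                         alpha_enter = 0.05, alpha_remove = 0.10) {
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  missing <- setdiff(c(outcome, candidates), names(data))
  if (length(missing)) {
    stop("column(s) not in data: ", paste(missing, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, c(outcome, candidates)]), ,
               drop = FALSE]
  if (nrow(data) <= length(candidates) + 1L) {
    stop("need n > number of candidates + 1")
  }
  X <- as.matrix(data[, candidates, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    drop1rank <- vapply(seq_along(candidates), function(j) {
      qr(cbind(1, X[, -j, drop = FALSE]))$rank
    }, integer(1))
    offenders <- candidates[drop1rank == qr(cbind(1, X))$rank]
    stop(errorCondition(
      sprintf("collinear candidate design; offending variable(s): %s",
              paste(offenders, collapse = ", ")),
      class = c("pcnl_rank_deficiency_error", "error", "condition")))
  }

  term_p <- function(fit) {
    ct <- stats::coef(summary(fit))
    p <- ct[, "Pr(>|t|)"]
    p[setdiff(rownames(ct), "(Intercept)")]
  }
  included <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break  # cycling guard; classic stepwise can oscillate
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      entry_p <- vapply(pool, function(v) {
        f <- stats::lm(stats::reformulate(c(included, v), outcome), data)
        term_p(f)[[v]]
      }, numeric(1))
      best <- names(which.min(entry_p))
      if (entry_p[[best]] <= alpha_enter) {
        included <- c(included, best)
        changed <- TRUE
      }
    }
    if (length(included)) {
      repeat {
        f <- stats::lm(stats::reformulate(included, outcome), data)
        p <- term_p(f)
        if (max(p) > alpha_remove && length(p) > 0L) {
          worst <- names(which.max(p))
          included <- setdiff(included, worst)
          changed <- changed || TRUE
          if (!length(included)) break
        } else break
      }
    }
    if (!changed) break
  }
  form <- if (length(included)) stats::reformulate(included, outcome)
          else stats::as.formula(paste(outcome, "~ 1"))
  fit <- stats::lm(form, data)
  ct <- stats::coef(summary(fit))
  structure(list(coefficients = stats::coef(fit),
                 p_values = ct[, "Pr(>|t|)"],
                 n = nrow(data),
                 r_squared = summary(fit)$r.squared,
                 excluded = setdiff(candidates, included),
                 source = "stepwise", fit = fit),
            class = "pcnl_tbl_model")
}

#' Predict from a fitted or published blood-loss model
#'
#' @param object a `pcnl_tbl_model`.
#' @param newdata data.frame carrying the model's predictor columns; for the
#'   published model, `stone_burden_mm2` and `baseline_hct_pct` (percent).
#' @param ... unused.
#' @return predicted TBL in mL.
#' @export
predict.pcnl_tbl_model <- function(object, newdata, ...) {
  if (identical(object$source, "published")) {
    return(predict_published(newdata$stone_burden_mm2,
                             newdata$baseline_hct_pct))
  }
  vars <- setdiff(names(object$coefficients), "(Intercept)")
  missing <- setdiff(vars, names(newdata))
  if (length(missing)) {
    stop("newdata lacks column(s): ", paste(missing, collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(newdata)[, vars, drop = FALSE]))
  drop(X %*% object$coefficients[colnames(X)])
}

#' @export
print.pcnl_tbl_model <- function(x, digits = 3, ...) {
  cat(sprintf("Blood-loss linear model (%s, n = %d)\n", x$source, x$n))
  co <- x$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  eq <- sprintf("TBL (mL) = %.*f", digits, co[["(Intercept)"]])
  for (v in terms) eq <- paste0(eq, sprintf(" + %.*f x %s", digits, co[[v]], v))
  cat("  ", eq, "\n", sep = "")
  if (!all(is.na(x$p_values))) {
    for (v in terms) {
      cat(sprintf("    %-20s p = %.4f\n", v, x$p_values[[v]]))
    }
    cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  }
  if (length(x$excluded)) {
    cat("  not selected:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
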