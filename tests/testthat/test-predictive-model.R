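test_that("the published predictor reproduces its worked example", {
  expect_equal(round(predict_published(1000, 40), 2), 83.74)
  expect_equal(predict_published(0, 0), -153.379)  # bare intercept
  expect_equal(predict_published(2000, 30), 310.711, tolerance = 1e-9)
})

test_that("the published predictor is affine in its inputs", {
  a <- c(500, 35); b <- c(700, 42)
  expect_equal(predict_published(a[1], a[2]) + predict_published(b[1], b[2]) -
                 predict_published(0, 0),
               predict_published(a[1] + b[1], a[2] + b[2]),
               tolerance = 1e-12)
})

test_that("fraction-scale hematocrit is rejected as a unit mix-up", {
  expect_error(predict_published(1000, 0.40), class = "pcnl_unit_error")
  expect_error(predict_published(-5, 40), ">= 0")
  expect_error(predict_published(1000, 120), "percent")
})

test_that("published_model() predicts identically to predict_published", {
  m <- published_model()
  nd <- data.frame(stone_burden_mm2 = c(100, 1000, 2500),
                   baseline_hct_pct = c(30, 40, 50))
  expect_equal(predict(m, nd),
               predict_published(nd$stone_burden_mm2, nd$baseline_hct_pct))
  expect_equal(unname(m$coefficients),
               c(-153.379, 0.229, 0.203))
})

test_that("screening correlations match definitional computation", {
  set.seed(21)
  n <- 40
  d <- data.frame(x_p = rnorm(n), x_s = rexp(n), tbl_ml = rnorm(n))
  res <- bivariate_screen(d, variables = c("x_p", "x_s"),
                          methods = c(x_p = "pearson", x_s = "spearman"))
  # Pearson by the covariance-ratio definition
  r_def <- sum((d$x_p - mean(d$x_p)) * (d$tbl_ml - mean(d$tbl_ml))) /
    sqrt(sum((d$x_p - mean(d$x_p))^2) * sum((d$tbl_ml - mean(d$tbl_ml))^2))
  expect_equal(res$r[res$variable == "x_p"], r_def, tolerance = 1e-9)
  t_def <- r_def * sqrt((n - 2) / (1 - r_def^2))
  expect_equal(res$p[res$variable == "x_p"], 2 * pt(-abs(t_def), n - 2),
               tolerance = 1e-9)
  # Spearman = Pearson on ranks
  rx <- rank(d$x_s); ry <- rank(d$tbl_ml)
  rho_def <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$r[res$variable == "x_s"], rho_def, tolerance = 1e-9)
})

test_that("self-correlation passes the entry screen trivially", {
  d <- data.frame(tbl_ml = rnorm(30))
  d$self <- d$tbl_ml
  res <- bivariate_screen(d, variables = "self",
                          methods = c(self = "pearson"))
  expect_equal(res$r, 1)
  expect_true(res$passes_entry)
})

test_that("a null variable fails the 0.25 entry screen about 75% of the time", {
  set.seed(31)
  fails <- replicate(300, {
    d <- data.frame(x = rnorm(120), tbl_ml = rnorm(120))
    !bivariate_screen(d, variables = "x",
                      methods = c(x = "pearson"))$passes_entry
  })
  expect_gt(mean(fails), 0.67)
  expect_lt(mean(fails), 0.83)
})

test_that("constant candidates raise an undefined-correlation error", {
  d <- data.frame(flat = rep(3, 20), ok = rnorm(20), tbl_ml = rnorm(20))
  err <- tryCatch(bivariate_screen(d, variables = c("flat", "ok")),
                  error = identity)
  expect_s3_class(err, "pcnl_constant_variable_error")
  expect_match(conditionMessage(err), "flat")
  expect_silent(res <- suppressWarnings(
    bivariate_screen(d, variables = c("flat", "ok"), on_constant = "drop")))
  expect_identical(res$variable, "ok")
})

test_that("a noiseless linear candidate is recovered exactly with R^2 = 1", {
  set.seed(5)
  d <- data.frame(x = runif(40, 0, 10))
  d$tbl_ml <- 12 + 3.5 * d$x
  # a perfect fit trips summary.lm's reliability warning; that is the point
  m <- suppressWarnings(fit_stepwise(d, candidates = "x"))
  expect_equal(unname(m$coefficients["x"]), 3.5, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["(Intercept)"]), 12, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
})

test_that("stepwise recovers the generating model from a low-noise fixture", {
  # at sd 1 mL both generating terms are detectable at n = 85
  fx <- generate_regression_fixture(n = 85, noise_sd = 1, seed = 42)
  m <- fit_stepwise(fx$data, candidates = c("stone_burden_mm2",
                                            "baseline_hct_pct"))
  expect_setequal(names(m$coefficients),
                  c("(Intercept)", "stone_burden_mm2", "baseline_hct_pct"))
  se <- sqrt(diag(vcov(m$fit)))[names(fx$truth)]
  expect_true(all(abs(m$coefficients[names(fx$truth)] - fx$truth) <=
                    3 * se))
  # at sd 10 the hematocrit term (partial t ~ 0.75) is correctly screened
  # out while the stone-burden slope is still recovered
  fx10 <- generate_regression_fixture(n = 85, noise_sd = 10, seed = 42)
  m10 <- fit_stepwise(fx10$data, candidates = c("stone_burden_mm2",
                                                "baseline_hct_pct"))
  expect_true("stone_burden_mm2" %in% names(m10$coefficients))
  se10 <- sqrt(diag(vcov(m10$fit)))[["stone_burden_mm2"]]
  expect_lt(abs(m10$coefficients[["stone_burden_mm2"]] -
                  fx10$truth[["stone_burden_mm2"]]), 3 * se10)
})

test_that("pure-noise candidates mostly yield the intercept-only model", {
  set.seed(77)
  picked <- replicate(100, {
    d <- data.frame(a = rnorm(50), b = rnorm(50), tbl_ml = rnorm(50))
    m <- fit_stepwise(d, candidates = c("a", "b"))
    length(m$coefficients) > 1
  })
  # with entry alpha 0.05 over two candidates the false-entry rate is ~0.1
  expect_lt(mean(picked), 0.25)
})

test_that("the fit never contains a variable outside the candidate set", {
  fx <- generate_regression_fixture(n = 85, noise_sd = 50, seed = 9)
  fx$data$decoy <- fx$data$tbl_ml + rnorm(85, 0, 1)  # strong but not offered
  m <- fit_stepwise(fx$data, candidates = "stone_burden_mm2")
  expect_true(all(names(m$coefficients) %in%
                    c("(Intercept)", "stone_burden_mm2")))
  expect_true(all(m$excluded %in% "stone_burden_mm2" | length(m$excluded) == 0))
})

test_that("collinear designs abort naming the offending variables", {
  set.seed(3)
  d <- data.frame(x = rnorm(30))
  d$y <- 2 * d$x
  d$tbl_ml <- d$x + rnorm(30)
  err <- tryCatch(fit_stepwise(d, candidates = c("x", "y")),
                  error = identity)
  expect_s3_class(err, "pcnl_rank_deficiency_error")
  expect_match(conditionMessage(err), "x")
})

test_that("coefficient bias shrinks as the fixture grows", {
  errs <- function(n, seeds) {
    vapply(seeds, function(s) {
      fx <- generate_regression_fixture(n = n, noise_sd = 400, seed = s)
      f <- lm(tbl_ml ~ stone_burden_mm2 + baseline_hct_pct, fx$data)
      coef(f)[["stone_burden_mm2"]] - fx$truth[["stone_burden_mm2"]]
    }, numeric(1))
  }
  e_small <- errs(85, 1:150)
  e_big <- errs(850, 151:300)
  expect_lt(mean(abs(e_big)), mean(abs(e_small)))
  expect_lt(abs(mean(e_big)), 0.006)
})
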