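# Independent straight-line recomputation of the blood-loss chain for one
# patient, written as plain scalar arithmetic so it shares no code path
# with estimate_blood_loss().
oracle_chain <- function(sex, height_cm, weight_kg, hct_pre, hct_final,
                         transfused_ml = 0, product_hct = 1) {
  bsa <- 0.0235 * height_cm^0.42246 * weight_kg^0.51456
  ebv <- if (sex == "male") bsa * 2530 else bsa * 2430
  initial_rbc <- ebv * hct_pre
  final_rbc <- ebv * hct_final
  uncompensated <- initial_rbc - final_rbc
  compensated <- transfused_ml * product_hct
  total_rbc <- uncompensated + compensated
  tbl <- total_rbc / ((hct_pre + hct_final) / 2)
  list(bsa = bsa, ebv = ebv, initial_rbc = initial_rbc,
       final_rbc = final_rbc, uncompensated = uncompensated,
       compensated = compensated, total_rbc = total_rbc, tbl = tbl)
}

# A random but always-valid cohort for property tests, with varied sexes,
# anthropometrics, hematocrit shifts (including occasional rises) and
# transfusion volumes.
make_random_cohort <- function(n, seed = 1) {
  set.seed(seed)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  hct_pre <- runif(n, 0.30, 0.50)
  hct_72 <- pmin(pmax(hct_pre - runif(n, -0.03, 0.12), 0.15), 0.55)
  transfused <- ifelse(runif(n) < 0.2, runif(n, 100, 700), 0)
  intra_share <- runif(n)
  pcnl_cohort(data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    sex = sex,
    age = runif(n, 18, 80),
    height_cm = runif(n, 145, 185),
    weight_kg = runif(n, 40, 95),
    stone_burden_mm2 = rlnorm(n, log(900), 0.6),
    stone_type = sample(c("staghorn", "non_staghorn", "unknown"), n,
                        replace = TRUE),
    hct_preop = hct_pre,
    hct_12h = pmin(pmax(hct_pre - runif(n, 0, 0.05), 0.10), 0.60),
    hct_24h = pmin(pmax(hct_pre - runif(n, 0, 0.08), 0.10), 0.60),
    hct_36h = pmin(pmax(hct_pre - runif(n, 0, 0.10), 0.10), 0.60),
    hct_72h = hct_72,
    crossmatched_ml = runif(n, 200, 800),
    transfused_intraop_ml = transfused * intra_share,
    transfused_postop_ml = transfused * (1 - intra_share),
    product_hct = sample(c(1, 0.6, 0.35), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Minimal single-patient cohort with overridable fields.
one_patient <- function(...) {
  base <- list(
    patient_id = "p1", sex = "female", age = 45, height_cm = 160,
    weight_kg = 55, stone_burden_mm2 = 900, stone_type = "unknown",
    hct_preop = 0.40, hct_12h = NA_real_, hct_24h = NA_real_,
    hct_36h = NA_real_, hct_72h = 0.35, crossmatched_ml = 400,
    transfused_intraop_ml = 0, transfused_postop_ml = 0, product_hct = 1)
  args <- list(...)
  base[names(args)] <- args
  as.data.frame(base, stringsAsFactors = FALSE)
}
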