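test_that("percent change is exact arithmetic", {
  expect_equal(percent_change(10, 8), -20)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 5), class = "pahburden_data_error")
  set.seed(51)
  b <- runif(200, 1, 50); p <- runif(200, 0.5, 60)
  expect_equal(percent_change(b, p), (p - b) / b * 100, tolerance = 1e-12)
})

test_that("the PAH diagnostic rule uses the correct boundaries", {
  expect_true(validate_pah_diagnosis(list(mPAP = 55, PAWP = 7.7, PVR = 14.2)))
  expect_false(validate_pah_diagnosis(list(mPAP = 24, PAWP = 7, PVR = 5)))
  # boundary cases: mPAP >= 25 and PAWP <= 15 inclusive, PVR > 3 strict
  expect_true(validate_pah_diagnosis(list(mPAP = 25, PAWP = 15, PVR = 3.1)))
  expect_false(validate_pah_diagnosis(list(mPAP = 30, PAWP = 15, PVR = 3)))
  expect_error(validate_pah_diagnosis(list(mPAP = 30, PAWP = 10)),
               class = "pahburden_data_error")
})

test_that("matching returns ratio-for-one same-sex nearest-age controls", {
  carriers <- data.frame(subject_id = sprintf("X%02d", 1:12),
                         age = c(20, 25, 30, 35, 40, 45, 50, 55, 60, 18, 22, 70),
                         sex = rep(c("F", "M"), 6), stringsAsFactors = FALSE)
  set.seed(52)
  pool <- data.frame(subject_id = sprintf("Y%03d", 1:120),
                     age = round(runif(120, 15, 75)),
                     sex = rep(c("F", "M"), 60), stringsAsFactors = FALSE)
  m <- match_controls(carriers, pool, ratio = 3)
  expect_equal(nrow(m), 36)
  expect_equal(anyDuplicated(m$subject_id), 0)
  for (i in seq_len(nrow(m))) {
    expect_equal(m$sex[i],
                 carriers$sex[carriers$subject_id == m$matched_to[i]])
  }
  # exact-copy pool at ratio 1 reproduces carrier ages
  pool2 <- carriers; pool2$subject_id <- sub("X", "Z", pool2$subject_id)
  m2 <- match_controls(carriers, pool2, ratio = 1)
  expect_setequal(m2$age, carriers$age)
  # insufficient pool errors with the per-sex deficit
  err <- expect_error(match_controls(carriers, pool[1:10, ], ratio = 3),
                      class = "pahburden_data_error")
  expect_match(conditionMessage(err), "deficit per sex")
})

test_that("greedy matching is near-optimal on exhaustive instances", {
  # enumerate all injective 1:1 assignments on a 5 x 10 single-sex instance
  set.seed(53)
  for (r in 1:5) {
    ages_c <- round(runif(5, 18, 70))
    ages_p <- round(runif(10, 15, 75))
    carriers <- data.frame(subject_id = sprintf("C%d", 1:5), age = ages_c,
                           sex = "F", stringsAsFactors = FALSE)
    pool <- data.frame(subject_id = sprintf("P%02d", 1:10), age = ages_p,
                       sex = "F", stringsAsFactors = FALSE)
    m <- match_controls(carriers, pool, ratio = 1)
    greedy_mean <- mean(abs(m$age -
      carriers$age[match(m$matched_to, carriers$subject_id)]))
    combos <- utils::combn(10, 5)
    best <- Inf
    for (k in seq_len(ncol(combos))) {
      # optimal pairing within a chosen subset: sort both sides
      d <- mean(abs(sort(ages_p[combos[, k]]) - sort(ages_c)))
      best <- min(best, d)
    }
    expect_lte(greedy_mean, best + 2)
  }
})

test_that("the ANCOVA coefficient matches a residualization oracle", {
  set.seed(54)
  n <- 48
  g <- c(rep(TRUE, 12), rep(FALSE, 36))
  b <- rnorm(n, 15, 5)
  y <- -15 - 21.7 * g - 0.4 * b + rnorm(n, 0, 10)
  fit <- genotype_response_model(y, g, b)
  # Frisch-Waugh: residualize outcome and genotype on baseline, regress
  ry <- resid(lm(y ~ b)); rg <- resid(lm(as.numeric(g) ~ b))
  oracle <- sum(ry * rg) / sum(rg^2)
  expect_equal(fit$ls_mean_difference, oracle, tolerance = 1e-8)
  expect_true(fit$ci_low <= fit$ls_mean_difference &
                fit$ls_mean_difference <= fit$ci_high)
  expect_equal(fit$n_carriers, 12)
  expect_equal(fit$n_noncarriers, 36)
})

test_that("the genotype coefficient is the adjusted-means difference", {
  set.seed(55)
  g <- rep(c(TRUE, FALSE), times = c(10, 30))
  b <- rnorm(40, 15, 4)
  y <- -10 - 20 * g - 0.5 * b + rnorm(40, 0, 8)
  fit <- genotype_response_model(y, g, b)
  # shifting every baseline by a constant moves the intercept only
  fit_shift <- genotype_response_model(y, g, b + 100)
  expect_equal(fit$ls_mean_difference, fit_shift$ls_mean_difference,
               tolerance = 1e-8)
  expect_equal(fit$p_value, fit_shift$p_value, tolerance = 1e-8)
  # without the baseline term the coefficient is the raw mean difference
  raw <- genotype_response_model(y, g, b, adjust_baseline = FALSE)
  expect_equal(raw$ls_mean_difference, mean(y[g]) - mean(y[!g]))
  # cross-check against the estimated marginal means machinery
  if (requireNamespace("emmeans", quietly = TRUE)) {
    d <- data.frame(y = y, g = factor(g), b = b)
    em <- emmeans::emmeans(lm(y ~ g + b, data = d), "g")
    diff_em <- summary(emmeans::contrast(em, list(d = c(-1, 1))))$estimate
    expect_equal(fit$ls_mean_difference, diff_em, tolerance = 1e-8)
  }
  # degenerate groups are refused
  expect_error(genotype_response_model(y, rep(TRUE, 40), b),
               class = "pahburden_data_error")
  expect_error(genotype_response_model(y, g, rep(3, 40)),
               class = "pahburden_data_error")
})

test_that("cohort-level vasoreactivity analysis recovers planted effects", {
  cfg <- small_config(seed = 56, n_discovery_cases = 80L,
                      n_replication_cases = 80L, n_controls = 20L,
                      case_carrier_freq = 0.12, noise_sd = 8)
  co <- generate_cohort(cfg)
  res <- vasoresponse_analysis(co, cfg$causal_gene)
  expect_named(res$models, c("PVR", "cardiac_index"))
  m <- res$models$PVR
  expect_equal(m$n_noncarriers, 3 * m$n_carriers)
  # the planted effect lies inside (or near) the interval; sign must match
  expect_lt(m$ls_mean_difference, 0)
  expect_gt(res$models$cardiac_index$ls_mean_difference, 0)
  # matched subjects are case subjects with paired hemodynamics
  expect_true(all(res$subjects$group == "case"))
})
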