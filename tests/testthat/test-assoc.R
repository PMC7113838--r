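test_that("carrier tables tabulate the truth roster exactly", {
  co <- generate_cohort(small_config(seed = 41, n_discovery_cases = 30L,
                                     n_replication_cases = 30L,
                                     n_controls = 60L,
                                     case_carrier_freq = 0.2,
                                     control_carrier_freq = 0.05))
  gene <- co$config$causal_gene
  tab <- carrier_table(co, gene = gene,
                       level_order = c("case", "control"))
  tc <- co$truth$carriers
  expect_equal(tab$a, sum(tc$group == "case"))
  expect_equal(tab$b, 60 - sum(tc$group == "case"))
  expect_equal(tab$c, sum(tc$group == "control"))
  expect_equal(tab$d, 60 - sum(tc$group == "control"))
  expect_error(carrier_table(co, gene = "NOSUCH"),
               class = "pahburden_data_error")
  # empty roster tabulates as (0, n, 0, n)
  co0 <- generate_cohort(small_config(seed = 42, case_carrier_freq = 0,
                                      control_carrier_freq = 0))
  tab0 <- carrier_table(co0, gene = gene, level_order = c("case", "control"))
  expect_equal(c(tab0$a, tab0$b, tab0$c, tab0$d), c(0, 25, 0, 25))
  expect_false(odds_ratio_wald(tab0)$estimable)
})

test_that("Wald odds ratios reproduce printed case-control contrasts", {
  # combined burden: 14/230 cases vs 8/968 controls
  res <- odds_ratio_wald(contingency_table(14, 216, 8, 960))
  expect_equal(round(res$or_estimate, 1), 7.8)
  expect_equal(round(res$ci_low, 1), 3.2)
  expect_equal(round(res$ci_high, 1), 18.8)
  expect_equal(signif(res$p_value, 1), 5e-6)
  # recurrent missense variants
  res2 <- odds_ratio_wald(contingency_table(5, 225, 2, 966))
  expect_equal(round(c(res2$or_estimate, res2$ci_low, res2$ci_high), 1),
               c(10.7, 2.1, 55.7))
  res3 <- odds_ratio_wald(contingency_table(8, 222, 6, 962))
  expect_equal(round(c(res3$or_estimate, res3$ci_low, res3$ci_high), 1),
               c(5.8, 2.0, 16.8))
  # zero cell: not estimable unless the Haldane correction is requested
  ne <- odds_ratio_wald(contingency_table(1, 229, 0, 968))
  expect_false(ne$estimable)
  expect_true(is.na(ne$or_estimate))
  hal <- odds_ratio_wald(contingency_table(1, 229, 0, 968), haldane = TRUE)
  expect_true(hal$estimable)
  expect_error(contingency_table(-1, 2, 3, 4),
               class = "pahburden_data_error")
})

test_that("logistic slope equals the cross-product ratio on 2x2 tables", {
  set.seed(43)
  for (r in 1:300) {
    cells <- sample(1:2000, 4, replace = TRUE)
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    lg <- logistic_single_predictor(tab)
    expect_true(lg$estimable)
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_lt(abs(lg$or_estimate - or) / or, 1e-6)
  }
  # symmetric table: OR exactly 1
  for (k in c(1, 7, 50)) {
    expect_equal(logistic_single_predictor(
      contingency_table(k, k, k, k))$or_estimate, 1, tolerance = 1e-9)
  }
  # separation mirrors the NE policy
  expect_false(logistic_single_predictor(
    contingency_table(1, 229, 0, 968))$estimable)
})

test_that("OR invariances: row scaling and exposure transposition", {
  tab <- contingency_table(8, 222, 6, 962)
  base <- odds_ratio_wald(tab)$or_estimate
  scaled <- odds_ratio_wald(contingency_table(8 * 7, 222 * 7, 6, 962))
  expect_equal(scaled$or_estimate, base)
  flipped <- odds_ratio_wald(contingency_table(222, 8, 962, 6))
  expect_equal(flipped$or_estimate, 1 / base)
})

test_that("continuity-adjusted chi-square truncates and bounds Pearson", {
  # discovery vs replication recurrent-variant carriers
  res <- yates_chi2(contingency_table(2, 40, 6, 182,
                                      groups = c("discovery", "replication")))
  expect_equal(round(res$statistic, 4), 0.0013)
  expect_equal(round(res$p_value, 2), 0.97)
  # pediatric vs adult: |O-E| < 0.5 everywhere -> statistic exactly 0
  ped <- yates_chi2(contingency_table(2, 35, 12, 181,
                                      groups = c("pediatric", "adult")))
  expect_identical(ped$statistic, 0)
  expect_identical(ped$p_value, 1)
  # perfectly proportional table
  prop <- yates_chi2(contingency_table(10, 30, 20, 60))
  expect_identical(prop$statistic, 0)
  # agreement with the standard implementation, and Yates <= Pearson
  set.seed(44)
  for (r in 1:200) {
    cells <- sample(1:80, 4, replace = TRUE)
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    mine <- yates_chi2(tab)
    ref <- suppressWarnings(stats::chisq.test(
      matrix(cells[c(1, 3, 2, 4)], 2), correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    pearson <- suppressWarnings(stats::chisq.test(
      matrix(cells[c(1, 3, 2, 4)], 2), correct = FALSE))
    expect_lte(mine$statistic, unname(pearson$statistic))
    # joint swap of group and exposure labels leaves the statistic unchanged
    swapped <- yates_chi2(contingency_table(cells[4], cells[3],
                                            cells[2], cells[1]))
    expect_equal(swapped$statistic, mine$statistic, tolerance = 1e-12)
  }
  expect_error(yates_chi2(contingency_table(0, 0, 5, 5)),
               class = "pahburden_data_error")
})

test_that("Fisher exact agrees with the reference implementation", {
  set.seed(45)
  expect_equal(fisher_exact(contingency_table(0, 10, 0, 10)), 1)
  tab <- contingency_table(14, 216, 8, 960)
  expect_equal(fisher_exact(tab),
               stats::fisher.test(as.matrix(rbind(c(14, 216), c(8, 960))))$p.value,
               tolerance = 1e-12)
  # transposition symmetry
  expect_equal(fisher_exact(contingency_table(14, 8, 216, 960)),
               fisher_exact(tab), tolerance = 1e-15)
  for (r in 1:150) {
    cells <- sample(0:60, 4, replace = TRUE)
    if (sum(cells) == 0) next
    p_mine <- fisher_exact(contingency_table(cells[1], cells[2],
                                             cells[3], cells[4]))
    p_ref <- stats::fisher.test(matrix(cells[c(1, 3, 2, 4)], 2))$p.value
    expect_equal(p_mine, p_ref, tolerance = 1e-12)
  }
})

test_that("carrier percentages report at printed precision", {
  expect_equal(carrier_percent(14, 230), 6.1)
  expect_equal(carrier_percent(8, 968), 0.8)
  expect_equal(carrier_percent(0, 50), 0.0)
  expect_equal(frequency_report(contingency_table(8, 222, 6, 962)),
               c(case = 3.5, control = 0.6))
  # exact-rational oracle at higher precision
  expect_equal(carrier_percent(8, 230, digits = 6), round(800 / 230, 6))
  expect_error(carrier_percent(1, 0), class = "pahburden_data_error")
})
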