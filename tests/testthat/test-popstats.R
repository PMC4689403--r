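test_that("carrier counting sums het plus hom individuals once", {
  calls <- data.frame(AC = 3L, hom_count = 1L)
  expect_identical(carriers_from_calls(calls), 2L)
  expect_identical(carriers_from_calls(calls[0, ]), 0L)
  expect_error(carriers_from_calls(data.frame(AC = 1L, hom_count = 1L)),
               class = "carrier_invariant_error")
  # simulator forbids double carriers, so truth allele counts are exact
  sim <- simulate_cohort(test_sim_config(seed = 71))
  tv <- sim$truth[!sim$truth$fp &
                    sim$truth$class %in% c("nonsense", "frameshift",
                                           "essential_splice"), ]
  recs <- sim$records_by_dataset$EXAC
  calls2 <- recs[paste(recs$chrom, recs$pos, recs$ref, recs$alt, sep = ":")
                 %in% tv$key, ]
  expect_identical(carriers_from_calls(calls2), sum(tv$AC))
})

test_that("prevalence reproduces the published worked examples", {
  expect_equal(round(prevalence(219, 60706), 2), 0.36)
  expect_equal(round(prevalence(10, 2504), 3), 0.399)
  expect_equal(round(prevalence(19, 6504), 3), 0.292)
  # exactness before display rounding
  for (k in c(0, 1, 7, 219)) {
    expect_equal(prevalence(k, 60706) * 60706 / 100, k)
  }
  expect_error(prevalence(5, 0), class = "prevalence_error")
})

test_that("one-in-N conversion and display rounding behave as documented", {
  expect_identical(one_in_n(0.36), 278)
  expect_identical(one_in_n(0.196), 510)
  expect_identical(one_in_n(0.057), 1754)
  expect_identical(format_one_in(510, nearest = 100), "1 in 500")
  expect_identical(format_one_in(1754, nearest = 50), "1 in 1750")
  expect_error(one_in_n(0), class = "one_in_n_error")
})

test_that("Wilson intervals invert the score test to 1e-6", {
  for (case in list(c(219, 60706), c(10, 2504), c(19, 6504), c(1, 5000),
                    c(3, 100), c(50, 60))) {
    ci <- binomial_ci(case[1], case[2], "wilson")
    oracle <- wilson_oracle(case[1], case[2])
    expect_equal(unname(ci), oracle, tolerance = 1e-6,
                 info = paste(case, collapse = "/"))
  }
  expect_identical(unname(binomial_ci(0, 100, "wilson")["ci_low"]), 0)
  expect_identical(unname(binomial_ci(0, 100, "clopper_pearson")["ci_low"]), 0)
  expect_error(binomial_ci(5, 100, level = 1.5), class = "ci_level_error")
})

test_that("both interval methods bracket the published headline interval", {
  for (method in c("wilson", "clopper_pearson")) {
    ci <- binomial_ci(219, 60706, method)
    est <- prevalence(219, 60706)
    expect_true(ci["ci_low"] <= est && est <= ci["ci_high"])
    # agrees with the printed 0.315 - 0.413 within rounding
    expect_equal(unname(ci["ci_low"]), 0.315, tolerance = 0.02)
    expect_equal(unname(ci["ci_high"]), 0.413, tolerance = 0.02)
  }
})

test_that("Clopper-Pearson contains Wilson across a (k, n) grid", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(10:100000, 1)
    k <- sample(0:n, 1)
    w <- binomial_ci(k, n, "wilson")
    cp <- binomial_ci(k, n, "clopper_pearson")
    expect_lte(cp["ci_low"], w["ci_low"] + 1e-9)
    expect_gte(cp["ci_high"], w["ci_high"] - 1e-9)
  }
})

test_that("95% Wilson intervals cover the true rate in >= 93% of cohorts", {
  set.seed(1234)
  p_true <- 0.004
  n <- 5000
  k <- stats::rbinom(1000, n, p_true)
  covered <- vapply(k, function(ki) {
    ci <- binomial_ci(ki, n, "wilson") / 100
    ci["ci_low"] <= p_true && p_true <= ci["ci_high"]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("the group chi-square test matches its algebra and oracles", {
  same <- data.frame(label = c("a", "b"), size = c(1000L, 2000L),
                     carriers = c(10L, 20L))
  res <- group_chi_square(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # 2x2 equals the squared two-proportion z statistic
  g2 <- data.frame(label = c("a", "b"), size = c(500L, 800L),
                   carriers = c(12L, 40L))
  res2 <- group_chi_square(g2)
  p_pool <- sum(g2$carriers) / sum(g2$size)
  z <- (g2$carriers[1] / g2$size[1] - g2$carriers[2] / g2$size[2]) /
    sqrt(p_pool * (1 - p_pool) * (1 / g2$size[1] + 1 / g2$size[2]))
  expect_equal(res2$statistic, z^2, tolerance = 1e-10)
  # random tables against the Pearson formula
  set.seed(8)
  for (i in 1:25) {
    g <- data.frame(label = letters[1:4],
                    size = sample(500:5000, 4),
                    carriers = sample(5:50, 4))
    res_g <- group_chi_square(g)
    m <- cbind(g$carriers, g$size - g$carriers)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - e)^2 / e)
    expect_equal(res_g$statistic, stat, tolerance = 1e-10)
    expect_equal(res_g$p_value, stats::pchisq(stat, 3, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(group_chi_square(same[1, ]), class = "group_test_error")
})

test_that("pairwise proportion tests are exact and symmetric", {
  expect_equal(pairwise_prop_test(5, 100, 5, 100), 1)
  p <- pairwise_prop_test(1, 10, 9, 10)
  # full enumeration oracle
  oracle <- local({
    logp <- function(x) lchoose(10, x) + lchoose(10, 10 - x) - lchoose(20, 10)
    p_obs <- exp(logp(1))
    xs <- 0:10
    sum(exp(logp(xs))[exp(logp(xs)) <= p_obs * (1 + 1e-7)])
  })
  expect_equal(p, oracle, tolerance = 1e-9)
  expect_equal(pairwise_prop_test(9, 10, 1, 10), p, tolerance = 1e-12)
})

test_that("Hardy-Weinberg het:hom expectation follows 2(1-q)/q", {
  expect_equal(hwe_het_hom_ratio(0.5), 2)
  expect_equal(hwe_het_hom_ratio(2 / 3), 1)
  q <- hwe_q_from_hom(1, 60706)
  expect_equal(q, sqrt(1 / 60706))
  # one observed homozygote in the reference cohort implies ~491 hets per hom
  expect_equal(hwe_het_hom_ratio(q), 490.76, tolerance = 0.01)
  expect_error(hwe_het_hom_ratio(0), class = "hwe_input_error")
  expect_error(hwe_q_from_hom(0, 10), class = "hwe_input_error")
})

test_that("coverage fractions tally depths at a threshold", {
  cov <- data.frame(chrom = "c", pos = 1:10,
                    mean_depth = c(rep(60, 8), 10, 20))
  expect_equal(coverage_fraction(cov, depth_threshold = 50)$fraction, 0.8)
  expect_equal(coverage_fraction(cov, depth_threshold = 1000)$fraction, 0)
  keys <- data.frame(chrom = "c", pos = c(1L, 9L, 99L))
  cf <- coverage_fraction(cov, keys, 50)
  expect_equal(cf$fraction, 0.5)
  expect_identical(cf$missing, "c:99")
  # simulated depths: fraction matches the truth tally
  sim <- simulate_cohort(test_sim_config(seed = 72))
  cf_sim <- coverage_fraction(sim$coverage, depth_threshold = 15)
  expect_equal(cf_sim$fraction, mean(sim$coverage$mean_depth >= 15))
})
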