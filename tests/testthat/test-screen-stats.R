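test_that("robust Z-score uses the negative-control median and unscaled MAD", {
  cs <- control_stats(c(0.50, 0.52, 0.54, 0.56, 0.58))
  expect_equal(cs$median_n, 0.54)
  expect_equal(cs$mad_n, 0.02)
  expect_equal(robust_z(0.44, cs), -5)          # hand-computed oracle
  expect_equal(robust_z(cs$median_n, cs), 0)    # identity

  # location invariance: shifting controls and x leaves Z unchanged
  cs2 <- control_stats(c(0.50, 0.52, 0.54, 0.56, 0.58) + 0.2)
  expect_equal(robust_z(0.44 + 0.2, cs2), -5)

  # optional normal-consistency scaling
  cs3 <- control_stats(c(0.50, 0.52, 0.54, 0.56, 0.58), mad_scale = 1.4826)
  expect_equal(robust_z(0.44, cs3), -5 / 1.4826)

  degenerate <- control_stats(rep(0.5, 5))
  expect_error(robust_z(0.4, degenerate), class = "degenerate_control_error")
  expect_error(control_stats(0.5), class = "degenerate_control_error")
})

test_that("composite Z averages valid replicates and goes absent below the floor", {
  expect_equal(composite_z(c(-1.2, -1.4, -1.0)), -1.2)
  expect_equal(composite_z(c(-2.0, NA, -1.0)), -1.5)
  expect_true(is.na(composite_z(c(-2.0, NA, NA))))
  expect_equal(composite_z(c(-2.0, NA, NA), min_valid = 1), -2.0)
})

test_that("hit calling is inclusive, independent per condition, and monotone", {
  tab <- data.frame(
    compound = c("A", "A", "B", "REF", "C"),
    concentration = c(1, 10, 1, 1, 1),
    composite_z = c(-2.0, -0.5, -1.0, -1.0, NA)
  )
  called <- call_hits(tab, c("REF", 1))
  expect_equal(attr(called, "reference_z"), -1.0)
  # A@1 hit, A@10 not (conditions judged independently); B ties the
  # reference and is a hit (inclusive rule); NA rows never hits
  expect_equal(called$hit, c(TRUE, FALSE, TRUE, TRUE, FALSE))

  # empty table: zero hits
  expect_equal(sum(call_hits(tab[0, ], c("REF", 1))$hit), 0)
  expect_error(call_hits(tab, c("MISSING", 1)), class = "config_error")

  # monotone: a more negative reference never adds hits
  tab2 <- tab
  tab2$composite_z[tab2$compound == "REF"] <- -2.0
  called2 <- call_hits(tab2, c("REF", 1))
  expect_true(all(called$hit | !called2$hit))
})

test_that("ranking is ascending with documented lexicographic tie-breaks", {
  tab <- data.frame(
    compound = c("Z", "A", "M"), concentration = c(1, 10, 1),
    composite_z = c(-1.0, -2.0, -1.0)
  )
  rk <- rank_conditions(tab)
  expect_equal(rk$compound, c("A", "M", "Z"))   # tie at -1.0: M before Z
  expect_equal(rk$rank, 1:3)
  single <- rank_conditions(tab[2, ])
  expect_equal(single$rank, 1L)
})

test_that("sign counts split promoted and suppressed conditions", {
  sc <- sign_counts(c(-1, -0.5, 0.2, NA, 0, 1.5))
  expect_equal(sc$n_negative, 2)
  expect_equal(sc$n_positive, 2)
  expect_equal(sc$n_zero, 1)
  expect_equal(sc$n_excluded, 1)
})

test_that("Z'-factor closed forms and invariances hold", {
  # perfect assay limit: zero spread
  expect_equal(z_prime(c(1, 1, 1), c(0, 0, 0)), 1)
  # mu gap 1, sd 0.1 each: 1 - 3 * 0.2 / 1 = 0.4 (constructed so sample sd
  # is exactly 0.1)
  pos <- 1 + c(-0.1, 0, 0.1) / sqrt(sum(c(-0.1, 0, 0.1)^2) / 2) * 0.1
  neg <- 0 + c(-0.1, 0, 0.1) / sqrt(sum(c(-0.1, 0, 0.1)^2) / 2) * 0.1
  expect_equal(sd(pos), 0.1)
  expect_equal(z_prime(pos, neg), 0.4)

  # affine invariance applied jointly to both groups
  set.seed(2)
  p <- rnorm(8, 1, 0.05); n <- rnorm(8, 0, 0.05)
  expect_equal(z_prime(3 * p + 2, 3 * n + 2), z_prime(p, n))

  expect_error(z_prime(c(1, 1), c(1, 1)), class = "undefined_separation_error")
  expect_error(z_prime(1, c(0, 0)), class = "parameter_error")
})

test_that("coefficient of variation is scale-invariant sample SD over mean", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(9, 10, 11)), 10)   # sd 1, mean 10
  x <- c(2, 3, 5, 7)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), class = "parameter_error")
})

test_that("the library-skew test flags skewed composite distributions", {
  # exact normal quantiles: no evidence against normality
  qn <- qnorm(ppoints(50))
  expect_gt(distribution_skew_test(qn)$p_value, 0.05)
  # heavily left-skewed: negated exponential
  set.seed(5)
  expect_lt(distribution_skew_test(-rexp(100))$p_value, 0.01)
  expect_error(distribution_skew_test(c(1, 2)), class = "parameter_error")
})

test_that("labeled-protein calculators implement the absorbance formulas", {
  # no-dye case: concentration = A280 / epsilon * dilution
  r0 <- absorbance_reading(A280 = 0.6778, A494 = 0)
  expect_equal(protein_concentration(r0)$molar, 1e-6)
  # epsilon = 677800 forces 1 umol/L at A280 = 0.6778
  expect_equal(protein_concentration(r0, molecular_weight = 440000)$mg_per_ml,
               0.44, tolerance = 1e-12)

  # boundary: A280 exactly CF * A494
  rb <- absorbance_reading(A280 = 0.3 * 0.5, A494 = 0.5)
  expect_equal(protein_concentration(rb)$molar, 0)
  rneg <- absorbance_reading(A280 = 0.1, A494 = 0.5)
  expect_error(protein_concentration(rneg), class = "parameter_error")

  # dye correction and dilution both enter linearly
  r2 <- absorbance_reading(A280 = 0.6778 + 0.3 * 0.2, A494 = 0.2, dilution = 3)
  expect_equal(protein_concentration(r2)$molar, 3e-6)

  # degree of labeling: 0.068 / (68000 * 1e-6) = 1
  rd <- absorbance_reading(A280 = 1, A494 = 0.068)
  expect_equal(degree_of_labeling(rd, 1e-6), 1)
  expect_equal(degree_of_labeling(absorbance_reading(1, 0), 1e-6), 0)
  rd2 <- absorbance_reading(A280 = 1, A494 = 0.136)
  expect_equal(degree_of_labeling(rd2, 1e-6), 2)   # linear in A494
  expect_error(degree_of_labeling(rd, 0), class = "contract_error")
})

test_that("negative-control robust Z-scores center at zero by construction", {
  set.seed(9)
  vals <- runif(9, 0.4, 0.6)
  cs <- control_stats(vals)
  expect_equal(median(robust_z(vals, cs)), 0)
})
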