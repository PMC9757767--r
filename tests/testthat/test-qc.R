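# Shared end-to-end fixture: a small simulated screen with one planted
# fibrillogenesis-failure (holes) condition and one planted toxicity
# condition, analyzed once and reused across the QC tests.
qc_sim_result <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      eff <- data.frame(
        compound = c("CPD-01", "CPD-02"), concentration = 1,
        kappa_mult = 1, nuclei_mult = c(1, 0.25), hole_fraction = c(0.5, 0)
      )
      cfg <- sim_screen_config(
        n_compounds = 2, concentrations = 1, effects = eff, replicates = 3,
        n_negative = 4, n_positive = 1, shape = c(256L, 256L),
        nuclei_baseline = 40, master_seed = 21L
      )
      res <<- analyze_screen(simulate_screen(cfg))
    }
    res
  }
})

test_that("background fraction counts pixels at or below the threshold", {
  expect_equal(background_fraction(matrix(0, 10, 10)), 1)
  expect_equal(background_fraction(matrix(101, 10, 10), 100), 0)
  expect_equal(background_fraction(matrix(100, 10, 10), 100), 1)  # "at or below"
  expect_equal(background_fraction(matrix(c(50, 150), 10, 10), 100), 0.5)
  expect_error(background_fraction(matrix(numeric(0), 0, 0)),
               class = "contract_error")
})

test_that("FOV, well and treatment flags follow the literal boundary rules", {
  cfg <- qc_config()
  # FOV: strict > 10 percent
  expect_equal(flag_fov(0.15, cfg)$reason, "insufficient_matrix")
  expect_null(flag_fov(0.10, cfg))
  expect_null(flag_fov(0, cfg))

  # well: >= 2 flagged FOV of 4 excludes; < 40 percent nuclei excludes
  f <- flag_well(c(TRUE, TRUE, FALSE, FALSE), 100, cfg)
  expect_equal(f[[1]]$reason, "too_few_fov")
  expect_length(flag_well(c(TRUE, FALSE, FALSE, FALSE), 100, cfg), 0L)
  expect_equal(flag_well(c(FALSE, FALSE, FALSE, FALSE), 39, cfg)[[1]]$reason,
               "toxicity")
  expect_length(flag_well(rep(FALSE, 4), 40, cfg), 0L)   # strict < 40
  both <- flag_well(c(TRUE, TRUE, TRUE, FALSE), 10, cfg)
  expect_setequal(vapply(both, `[[`, "", "reason"),
                  c("too_few_fov", "toxicity"))
  expect_error(flag_well(logical(0), 100, cfg), class = "contract_error")

  # treatment: >= 2 excluded replicate wells drops the condition
  expect_null(flag_treatment(c(TRUE, TRUE, FALSE), cfg))
  expect_equal(flag_treatment(c(TRUE, FALSE, FALSE), cfg)$reason,
               "too_few_wells")
  expect_equal(flag_treatment(c(FALSE, FALSE, FALSE), cfg)$value, 0)
})

test_that("qc_config rejects degenerate thresholds", {
  expect_error(qc_config(background_level = 0), class = "parameter_error")
  expect_error(qc_config(max_background_fraction = 1), class = "parameter_error")
})

test_that("loosening any threshold never increases exclusions", {
  set.seed(33)
  bg <- matrix(runif(40 * 4), 40, 4)          # per-FOV background fractions
  nuc <- runif(40, 0, 120)                    # per-well nuclei percent
  exclusions <- function(max_bg, min_nuc) {
    sum(vapply(seq_len(40), function(i) {
      cfg <- qc_config(max_background_fraction = max_bg,
                       min_nuclei_percent = min_nuc)
      fl <- vapply(bg[i, ], function(f) !is.null(flag_fov(f, cfg)), logical(1))
      length(flag_well(fl, nuc[i], cfg)) > 0
    }, logical(1)))
  }
  strict <- exclusions(0.10, 40)
  expect_lte(exclusions(0.20, 40), strict)    # looser background rule
  expect_lte(exclusions(0.10, 30), strict)    # looser toxicity rule
  expect_lte(exclusions(0.20, 30), strict)
})

test_that("qc_report buckets every excluded well exactly once", {
  wt <- data.frame(
    plate = "p1", well = sprintf("A%d", 1:6),
    matrix_fail = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    toxicity_fail = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  rep <- qc_report(wt)
  expect_equal(rep$total_wells, 6)
  expect_equal(rep$matrix_only, 1)
  expect_equal(rep$toxicity_only, 1)
  expect_equal(rep$both, 2)
  expect_equal(rep$excluded, rep$matrix_only + rep$toxicity_only + rep$both)

  none <- qc_report(data.frame(matrix_fail = rep(FALSE, 3),
                               toxicity_fail = rep(FALSE, 3)))
  expect_equal(none$excluded, 0)
  all_out <- qc_report(data.frame(matrix_fail = rep(TRUE, 3),
                                  toxicity_fail = rep(TRUE, 3)))
  expect_equal(all_out$excluded, all_out$total_wells)
})

test_that("planted hole and toxicity conditions are excluded for the right reasons", {
  res <- qc_sim_result()
  wt <- res$well_table

  # hole-planted condition: all replicate wells fail matrix QC
  holes <- wt[wt$compound == "CPD-01", ]
  expect_true(all(holes$matrix_fail))
  expect_true(all(holes$n_valid_fov == 0))

  # toxicity-planted condition: wells fail the < 40 percent nuclei rule
  tox <- wt[wt$compound == "CPD-02", ]
  expect_true(all(tox$toxicity_fail))
  expect_true(all(tox$nuclei_percent < 40))

  # report counts equal the planted condition counts
  expect_equal(res$qc$matrix_only, nrow(holes))
  expect_equal(res$qc$toxicity_only, nrow(tox))
  expect_equal(res$qc$both, 0)
  expect_equal(res$qc$excluded,
               res$qc$matrix_only + res$qc$toxicity_only + res$qc$both)

  # both planted conditions drop from the composite table
  ct <- res$condition_table
  expect_true(is.na(ct$composite_z[ct$compound == "CPD-01"]))
  expect_true(is.na(ct$composite_z[ct$compound == "CPD-02"]))
})

test_that("negative controls are never excluded by the toxicity rule", {
  res <- qc_sim_result()
  neg <- res$well_table[res$well_table$role == "negative-control", ]
  expect_false(any(neg$toxicity_fail))
  # percent of control averages 100 for the controls themselves
  expect_equal(mean(neg$nuclei_percent), 100, tolerance = 1e-9)
})
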