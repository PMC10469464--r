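test_that("trophic_position is the linear delta15N transform", {
  expect_equal(trophic_position(8, 8, baseline_tp = 2), 2)
  expect_equal(trophic_position(8 + 2.88, 8, baseline_tp = 2), 3)
  expect_equal(trophic_position(8 + 2 * 2.88, 8, baseline_tp = 2), 4)
  expect_equal(trophic_position(10, 8, baseline_tp = 1, enrichment = 4), 1.5)
  expect_error(trophic_position(8, 8, enrichment = 0), "enrichment")
})

test_that("detection_filter reads 'more than 60%' strictly", {
  meas <- function(n_det, n_tot) data.frame(
    sample_id = sprintf("S%03d", seq_len(n_tot)), analyte = "A",
    conc_ng_g_ww = 1, censored = rep(c(0L, 1L), c(n_det, n_tot - n_det)),
    mloq_ng_g_ww = 1)
  expect_true(detection_filter(meas(61, 100), "A")$include)
  expect_false(detection_filter(meas(60, 100), "A")$include)
  g <- detection_filter(meas(100, 100), "A")
  expect_true(g$include)
  expect_equal(g$frequency, 1.0)
  expect_error(detection_filter(meas(5, 10), "B"), "unknown analyte")
  expect_error(detection_filter(meas(5, 10), "A", threshold = 1.2), "threshold")
})

test_that("noiseless exponential data yields TMF = 2 within 1e-6", {
  ds <- handmade_dataset(tp = seq(1, 4, length.out = 12), m = log(2), b0 = 1)
  chems <- list(toy_chem())
  fit <- compute_tmf(ds$samples, ds$measurements, chems, "TOY", "wet")
  expect_equal(fit$tmf, 2, tolerance = 1e-6)
  fit_a <- compute_tmf(ds$samples, ds$measurements, chems, "TOY", "activity")
  expect_equal(fit_a$tmf, 2, tolerance = 1e-6)
})

test_that("identical composition makes all six schemes agree to 1e-9", {
  fw <- generate_foodweb(constant_comp_config(seed = 71))
  for (an in c("PFNA", "PFOS")) {
    res <- compute_tmf_all(fw$samples, fw$measurements, fw$chemicals,
                           analytes = an)
    expect_identical(sort(res$scheme), sort(tmf_schemes))
    expect_lt(max(res$tmf) - min(res$tmf), 1e-9)
  }
})

test_that("null analyte gives TMF near 1 with p > 0.05 at large n", {
  cfg <- synthetic_config(n_samples = 300, seed = 72,
                          analytes = data.frame(name = "PFOA", true_tmf = 1,
                                                baseline_activity = 1e-8,
                                                sigma = 0.6, mloq = NA_real_))
  fw <- generate_foodweb(cfg)
  fit <- compute_tmf(fw$samples, fw$measurements, fw$chemicals, "PFOA",
                     "activity")
  expect_lt(abs(log(fit$tmf)), 0.15)
  expect_gt(fit$p_value, 0.05)
})

test_that("detection gate and scheme exclusions are enforced in compute_tmf", {
  ds <- handmade_dataset(tp = seq(1, 4, length.out = 10), m = 0.5)
  ds$measurements$censored[1:5] <- 1L  # 50% detection <= 60%
  ds$measurements$conc_ng_g_ww[1:5] <- ds$measurements$mloq_ng_g_ww[1:5]
  chems <- list(toy_chem())
  expect_error(compute_tmf(ds$samples, ds$measurements, chems, "TOY", "wet"),
               "detection-frequency")

  # zero polar-lipid samples are dropped per-scheme with a warning and counted
  ds2 <- handmade_dataset(tp = seq(1, 4, length.out = 10), m = 0.5,
                          comp = tissue_composition(phi_NL = 0.02,
                                                    phi_ALB = 0.03,
                                                    phi_SP = 0.02,
                                                    phi_W = 0.9))
  expect_error(
    suppressWarnings(
      compute_tmf(ds2$samples, ds2$measurements, chems, "TOY", "polar_lipid")),
    "insufficient data")
  fit_w <- compute_tmf(ds2$samples, ds2$measurements, chems, "TOY", "wet")
  expect_identical(fit_w$n_excluded, 0L)
})

test_that("delta15N-derived trophic positions feed the regression", {
  ds <- handmade_dataset(tp = seq(1, 4, length.out = 10), m = log(2))
  # recode TP as delta15N with the default enrichment of 2.88 per level
  ds$samples$delta15N <- (ds$samples$trophic_position - 1) * 2.88 + 8
  ds$samples$trophic_position <- NA_real_
  chems <- list(toy_chem())
  fit <- compute_tmf(ds$samples, ds$measurements, chems, "TOY", "wet",
                     baseline_delta15N = 8, baseline_tp = 1)
  expect_equal(fit$tmf, 2, tolerance = 1e-6)
})

test_that("compare_tmfs: overlap logic and ratios", {
  mk <- function(tmf, lo, hi) structure(
    list(analyte = "A", scheme = "wet", tmf = tmf, ci95 = c(lo, hi)),
    class = "tmf_result")
  r <- compare_tmfs(list(mk(1.5, 1.1, 2.0), mk(1.5, 1.1, 2.0)))
  expect_true(all(r$overlap))
  expect_true(all(r$ratio == 1))
  r2 <- compare_tmfs(list(mk(1.5, 1.1, 2.0), mk(2.5, 2.1, 3.0)))
  expect_false(r2$overlap[1, 2])
  r3 <- compare_tmfs(list(mk(1.6, 1.1, 2.2), mk(2.5, 2.1, 3.0)))
  expect_true(r3$overlap[1, 2])
  expect_equal(r3$ratio[2, 1], 2.5 / 1.6)
  expect_error(compare_tmfs(list(mk(1, 1, 1))), "at least 2")
})
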