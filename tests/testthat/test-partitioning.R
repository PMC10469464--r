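test_that("sorptive_capacity: closed-form cases and structure", {
  chem <- toy_chem()
  # pure water has unit relative capacity whatever the chemical
  expect_equal(sorptive_capacity(comp_water, chem), 1)

  # direct arithmetic: 0.05 * 10^4 + 0.95
  chem4 <- toy_chem(logd = c(NLW = -9, PLW = -9, ALBW = 4, SPW = -9))
  comp <- tissue_composition(phi_ALB = 0.05, phi_W = 0.95)
  expect_equal(sorptive_capacity(comp, chem4), 0.05 * 1e4 + 0.95,
               tolerance = 1e-12)

  # increasing any phi_i with D_i > 1 strictly increases capacity
  base <- sorptive_capacity(comp_avian, chem)
  for (ph in c("phi_NL", "phi_PL", "phi_ALB", "phi_SP")) {
    args <- list(phi_NL = 0.04, phi_PL = 0.010, phi_ALB = 0.039,
                 phi_SP = 0.021, phi_W = 0.75)
    args[[ph]] <- args[[ph]] + 0.01
    chem_hi <- toy_chem(logd = c(NLW = 1, PLW = 3.5, ALBW = 4.5, SPW = 2.5))
    expect_gt(sorptive_capacity(do.call(tissue_composition, args), chem_hi),
              sorptive_capacity(comp_avian, chem_hi))
  }

  # linearity in each phi holding the others fixed
  c0 <- tissue_composition(phi_ALB = 0.01, phi_W = 0.5)
  c1 <- tissue_composition(phi_ALB = 0.03, phi_W = 0.5)
  c2 <- tissue_composition(phi_ALB = 0.02, phi_W = 0.5)
  expect_equal(sorptive_capacity(c2, chem),
               (sorptive_capacity(c0, chem) + sorptive_capacity(c1, chem)) / 2,
               tolerance = 1e-12)
})

test_that("mass_distribution conserves mass and honors limits", {
  # equal phi*D products -> 0.2 each
  chem_eq <- toy_chem(logd = c(NLW = 1, PLW = 1, ALBW = 1, SPW = 1))
  comp_eq <- tissue_composition(0.02, 0.02, 0.02, 0.02, 0.2)
  md <- mass_distribution(comp_eq, chem_eq)
  expect_equal(unclass(md), setNames(rep(0.2, 5), c("NL", "PL", "ALB", "SP", "W")),
               tolerance = 1e-12)

  # randomized compositions and D values: fractions in [0,1], sum 1 to 1e-12
  set.seed(21)
  for (r in 1:50) {
    phi <- runif(5); phi <- phi / sum(phi) * runif(1, 0.5, 1)
    comp <- tissue_composition(phi[1], phi[2], phi[3], phi[4], phi[5])
    chem <- toy_chem(logd = c(NLW = runif(1, -3, 2), PLW = runif(1, 0, 6),
                              ALBW = runif(1, 0, 6), SPW = runif(1, -1, 4)))
    md <- mass_distribution(comp, chem)
    expect_true(all(md >= 0 & md <= 1))
    expect_equal(sum(md), 1, tolerance = 1e-12)
  }

  # water fraction -> 1 as all D -> 0
  chem_lo <- toy_chem(logd = c(NLW = -30, PLW = -30, ALBW = -30, SPW = -30))
  expect_equal(unname(mass_distribution(comp_avian, chem_lo)[["W"]]), 1,
               tolerance = 1e-12)
  # albumin fraction -> 1 as D_ALBW -> Inf with phi_ALB > 0
  chem_hi <- toy_chem(logd = c(NLW = 0, PLW = 3, ALBW = 30, SPW = 2))
  expect_equal(unname(mass_distribution(comp_avian, chem_hi)[["ALB"]]), 1,
               tolerance = 1e-10)

  expect_error(mass_distribution(tissue_composition(), toy_chem()),
               "degenerate")
})

test_that("avian composition + bundled albumin-binding chemical: ~90% in albumin", {
  chems <- synthetic_chem_table()
  tab <- as.data.frame(chems)
  pfos <- tab[tab$name == "PFOS", ]
  # brute-force oracle straight from the table row
  num <- c(NL = comp_avian[["NL"]] * 10^pfos$logD_NLW,
           PL = comp_avian[["PL"]] * 10^pfos$logD_PLW,
           ALB = comp_avian[["ALB"]] * 10^pfos$logD_ALBW,
           SP = comp_avian[["SP"]] * 10^pfos$logD_SPW,
           W = comp_avian[["W"]])
  oracle_alb <- unname(num[["ALB"]] / sum(num))
  md <- mass_distribution(comp_avian, chem_get(chems, "PFOS"))
  expect_equal(unname(md[["ALB"]]), oracle_alb, tolerance = 1e-12)
  expect_lt(abs(oracle_alb - 0.9), 0.05)
})

test_that("mass_distribution_table emits the long format", {
  cfg <- synthetic_config(n_samples = 4, seed = 5)
  fw <- generate_foodweb(cfg)
  long <- mass_distribution_table(fw$samples, fw$chemicals,
                                  analytes = c("PFOS", "PFOA"))
  expect_identical(names(long), c("sample_id", "analyte", "phase", "fraction"))
  expect_equal(nrow(long), 4 * 2 * 5)
  sums <- tapply(long$fraction, paste(long$sample_id, long$analyte), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("logd_sensitivity matches brute-force recomputation", {
  cfg <- constant_comp_config(seed = 13)
  fw <- generate_foodweb(cfg)
  chems <- fw$chemicals
  ref_ld <- as.numeric(chems$records[["PFOS"]]$logd[["ALBW"]])
  sweep <- c(ref_ld - 1, ref_ld, ref_ld + 1)
  sens <- logd_sensitivity(fw$samples, fw$measurements, chems, "PFOS",
                           "ALBW", sweep)
  # reference row first, 0% change by construction
  expect_equal(sens$logd[1], ref_ld)
  expect_equal(sens$pct_change[1], 0)
  expect_true(sens$overlaps_reference[1])

  # brute force: substitute each value and recompute via compute_tmf
  for (i in seq_len(nrow(sens))) {
    mod <- chems$records
    mod$PFOS$logd[["ALBW"]] <- sens$logd[i]
    fit <- compute_tmf(fw$samples, fw$measurements, mod, "PFOS", "activity")
    expect_equal(sens$tmf[i], fit$tmf, tolerance = 1e-10)
    expect_equal(sens$pct_change[i],
                 100 * (fit$tmf - sens$tmf[1]) / sens$tmf[1],
                 tolerance = 1e-8)
  }
})
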