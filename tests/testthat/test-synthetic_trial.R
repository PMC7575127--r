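test_that("generation is deterministic and keyed by animal substreams", {
  cfg <- generator_config(seed = 5)
  d1 <- generate_trial(cfg)
  d2 <- generate_trial(cfg)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$marker_series[[3]]$conc_dm,
                   d2$marker_series[[3]]$conc_dm)
  # a smaller trial reuses the same per-animal streams
  d4 <- generate_trial(generator_config(seed = 5, n_animals = 4))
  r8 <- d1$records[d1$records$animal_id == "deer01", ]
  r4 <- d4$records[d4$records$animal_id == "deer01", ]
  expect_equal(r4$offered_fresh, r8$offered_fresh)
  expect_equal(r4$urine_mass, r8$urine_mass)
})

test_that("generated datasets validate and are balanced", {
  for (seed in c(2, 13)) {
    ds <- generate_trial(generator_config(seed = seed))
    expect_s3_class(ds, "trial_dataset")   # constructor validates
    lay <- ds$layout
    expect_equal(nrow(lay), 16)
    seqs <- unique(lay[c("animal_id", "sequence")])
    expect_equal(sort(as.vector(table(seqs$sequence))), c(4, 4))
    expect_equal(length(ds$marker_series), 16)
    expect_equal(length(ds$doses), 16)
  }
})

test_that("the noise-free pipeline reproduces the configured chain exactly", {
  cfg <- generator_config(seed = 1, noise_scale = 0)
  b <- trial_budgets(generate_trial(cfg))
  for (dd in c("PL", "RG")) {
    comp <- cfg$compositions[[dd]]
    m <- b[b$diet == dd, ]
    d0 <- unname(cfg$dmi_mean[dd])
    water0 <- d0 * (100 / comp$dm_pct - 1) + unname(cfg$trough_mean[dd])
    urine0 <- unname(cfg$urine_intercept[dd]) + cfg$urine_slope * water0
    ni0 <- n_intake(d0, comp$cp_pct)
    fn0 <- cfg$fn_intercept + cfg$fn_slope * ni0
    un0 <- unname(cfg$un_intercept[dd]) + cfg$un_slope * ni0
    expect_equal(m$dmi, rep(d0, 8), tolerance = 1e-9)
    expect_equal(m$water_intake_total, rep(water0, 8), tolerance = 1e-9)
    expect_equal(m$water_urine, rep(urine0, 8), tolerance = 1e-9)
    expect_equal(m$n_intake, rep(ni0, 8), tolerance = 1e-9)
    expect_equal(m$fecal_n, rep(fn0, 8), tolerance = 1e-9)
    expect_equal(m$urine_n, rep(un0, 8), tolerance = 1e-9)
    expect_equal(m$urine_n_conc, rep(un0 / urine0, 8), tolerance = 1e-9)
    expect_equal(m$app_dmd, rep(unname(cfg$dmd_pct[dd]), 8),
                 tolerance = 1e-9)
  }
})

test_that("marker curve generation is exact at cv = 0 and linear in dose", {
  truth <- list(dose = 3.72, gif = 6.44, rate = 0.0855, tau = 8.79,
                fecal_dm_pct = 25.2)
  s <- generate_marker_curve(truth, protocol_times, cv = 0, seed = 3,
                             fecal_dm_sd = 0)
  expect_equal(dm_to_water_basis(s$conc_dm, s$fecal_dm_pct),
               model_conc(protocol_times, 1000 * 3.72 / 6.44, 0.0855, 8.79))
  truth2 <- truth; truth2$dose <- 2 * truth$dose
  s2 <- generate_marker_curve(truth2, protocol_times, cv = 0.05, seed = 3)
  expect_equal(s2$conc_dm, 2 * generate_marker_curve(truth, protocol_times,
                                                     cv = 0.05,
                                                     seed = 3)$conc_dm,
               tolerance = 1e-12)
})

test_that("fit_curve closes the loop on noise-free generated curves", {
  truth <- list(dose = 3.72, gif = 3.93, rate = 1 / 11.58, tau = 8.92,
                fecal_dm_pct = 24.2)
  s <- generate_marker_curve(truth, protocol_times, cv = 0, seed = 4)
  fit <- fit_curve(s)
  expect_equal(fit$rate, truth$rate, tolerance = 1e-6)
  expect_equal(fit$c0 * exp(fit$rate * fit$tau),
               1000 * truth$dose / truth$gif * exp(truth$rate * truth$tau),
               tolerance = 1e-6)
})

test_that("impossible configurations fail with a named constraint", {
  expect_error(generator_config(n_animals = 7), "even")
  expect_error(generate_trial(generator_config(
    urine_intercept = c(PL = -30, RG = 0.88))), "urine output for diet PL")
  expect_error(generate_trial(generator_config(
    un_intercept = c(PL = 6.58, RG = -100))), "urinary N for diet RG")
})

test_that("generated diet contrasts carry the configured directions", {
  hits <- vapply(default_budgets(200)[1:50], function(b) {
    m <- stats::aggregate(cbind(dmi, water_urine, urine_n_conc,
                                n_intake) ~ diet, b, mean)
    pl <- m[m$diet == "PL", ]; rg <- m[m$diet == "RG", ]
    pl$dmi > rg$dmi && pl$water_urine > rg$water_urine &&
      pl$urine_n_conc < rg$urine_n_conc && pl$n_intake < rg$n_intake
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
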