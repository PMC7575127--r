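test_that("composition validates ranges and the ash/OM complement", {
  comp <- pl_comp()
  expect_equal(comp$ash_pct, 100 - 88.36)
  expect_error(composition("x", dm_pct = 0, cp_pct = 10, ndf_pct = 30,
                           adf_pct = 20, wsc_pct = 10, om_pct = 90),
               "in \\(0, 100\\)")
  expect_error(composition("x", dm_pct = 12, cp_pct = 10, ndf_pct = 30,
                           adf_pct = 20, wsc_pct = 10, om_pct = 90,
                           ash_pct = 15), "complementary")
  # either complement alone suffices
  c2 <- composition("x", 12, 10, 30, 20, 10, ash_pct = 11)
  expect_equal(c2$om_pct, 89)
})

test_that("dmi computes offer minus refusal dry mass with refusal DM default", {
  comp <- pl_comp()
  rec <- make_record(offered_fresh = 15.0, refused_fresh = 0.48)
  expect_equal(dmi(rec, comp), (15.0 - 0.48) * 0.1095)
  # refusal equal to offer gives zero intake
  expect_equal(dmi(make_record(offered_fresh = 10, refused_fresh = 10), comp), 0)
  # pure-DM identity
  c100 <- composition("dry", 99.99, 10, 30, 20, 10, om_pct = 90)
  expect_equal(dmi(make_record(diet = "dry", offered_fresh = 10,
                               refused_fresh = 0), c100), 10 * 0.9999)
  # refusal DM% override changes the refusal term only
  expect_equal(dmi(rec, comp, refusal_dm_pct = 20),
               15.0 * 0.1095 - 0.48 * 0.20)
  # diet mismatch is caught
  expect_error(dmi(make_record(diet = "RG"), comp), "does not match")
})

test_that("dmi is monotone in refusals and linear in the offer", {
  comp <- pl_comp()
  refused <- seq(0, 5, by = 0.5)
  vals <- dmi(make_record(offered_fresh = 10, refused_fresh = refused), comp)
  expect_true(all(diff(vals) < 0))
  offered <- seq(5, 15, by = 1)
  vals <- dmi(make_record(offered_fresh = offered, refused_fresh = 0), comp)
  expect_equal(diff(vals), rep(comp$dm_pct / 100, length(offered) - 1))
})

test_that("feed water closes the fresh-mass budget and handles edge DM", {
  comp <- pl_comp()
  d <- dmi(make_record(offered_fresh = 15, refused_fresh = 0.48), comp)
  expect_equal(feed_water(d, comp), d * (100 / 10.95 - 1))
  # water + DM = fresh intake under the density-1 convention
  expect_equal(feed_water(d, comp) + d, (15 - 0.48), tolerance = 1e-9)
  # at 50% DM the water equals the dry matter
  c50 <- composition("half", 50, 10, 30, 20, 10, om_pct = 90)
  expect_equal(feed_water(2.7, c50), 2.7)
  expect_equal(feed_water(0, comp), 0)
})

test_that("co_dose_mass multiplies mass by fraction with validation", {
  expect_equal(co_dose_mass(dose_record("a1", 1, 17.98, 0.207)),
               17.98 * 0.207)
  expect_equal(co_dose_mass(dose_record("a1", 1, 10, 0.999)), 9.99)
  expect_error(dose_record("a1", 1, 0, 0.2), "licoedta_mass")
  expect_error(dose_record("a1", 1, 10, 1.2), "co_fraction")
})

test_that("trial_dataset enforces record invariants and crossover layout", {
  comps <- list(PL = pl_comp(), RG = rg_comp())
  expect_s3_class(tiny_dataset(), "trial_dataset")

  bad <- tiny_records()
  bad$refused_fresh[1] <- bad$offered_fresh[1] + 1
  expect_error(trial_dataset(bad, comps), "refused_fresh exceeds")

  # missing phase 2 for one animal
  expect_error(trial_dataset(tiny_records()[-2, ], comps),
               "exactly two phases")

  # same diet in both phases
  swap <- tiny_records()
  swap$diet[2] <- "PL"
  expect_error(trial_dataset(swap, comps), "both diets")

  # duplicate day
  dup <- rbind(tiny_records(), make_record("a1", 1L, "PL"))
  expect_error(trial_dataset(dup, comps), "duplicate")

  # diet without composition
  expect_error(trial_dataset(tiny_records(), comps["PL"]),
               "without a composition")

  # missing measurement-day value
  nav <- tiny_records()
  nav$urine_mass[1] <- NA
  expect_error(trial_dataset(nav, comps), "missing value")

  # acclimation days may carry the same columns but are flagged
  acc <- rbind(tiny_records(),
               make_record("a1", 1L, "PL", day = 5L, measurement = FALSE))
  ds <- trial_dataset(acc, comps)
  expect_equal(sum(!ds$records$measurement), 1)
})

test_that("save and load round-trip a dataset through CSV", {
  ds <- generate_trial(generator_config(seed = 7, n_animals = 4))
  dir <- tempfile("trial")
  write_trial(ds, dir)
  ds2 <- load_trial(dir)
  expect_equal(ds2$records$animal_id, ds$records$animal_id)
  num <- vapply(ds$records, is.numeric, logical(1))
  for (col in names(ds$records)[num])
    expect_equal(ds2$records[[col]], ds$records[[col]], tolerance = 1e-12,
                 label = col)
  expect_equal(length(ds2$marker_series), length(ds$marker_series))
  s1 <- ds$marker_series[[1]]; s2 <- ds2$marker_series[[1]]
  expect_equal(s2$conc_dm, s1$conc_dm, tolerance = 1e-12)
  expect_equal(ds2$compositions$PL$cp_pct, ds$compositions$PL$cp_pct)
  unlink(dir, recursive = TRUE)
})

test_that("load_trial reports schema problems by name", {
  dir <- tempfile("badtrial")
  dir.create(dir)
  utils::write.csv(data.frame(x = 1), file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(diet = "PL", dm_pct = 11, cp_pct = 16,
                              ndf_pct = 30, adf_pct = 26, wsc_pct = 14,
                              om_pct = 88),
                   file.path(dir, "compositions.csv"), row.names = FALSE)
  expect_error(load_trial(dir), "missing column")
  expect_error(load_trial(tempfile()), "required")
  unlink(dir, recursive = TRUE)
})
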