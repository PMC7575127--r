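protocol_times <- c(0, 4, 8, 12, 24, 36, 48, 60, 72)

pl_comp <- function() composition("PL", dm_pct = 10.95, cp_pct = 15.87,
                                  ndf_pct = 30.33, adf_pct = 25.84,
                                  wsc_pct = 14.33, om_pct = 88.36)
rg_comp <- function() composition("RG", dm_pct = 14.88, cp_pct = 22.79,
                                  ndf_pct = 42.86, adf_pct = 23.88,
                                  wsc_pct = 12.60, om_pct = 89.46)

make_record <- function(animal_id = "a1", phase = 1L, diet = "PL",
                        day = 10L, offered_fresh = 15, refused_fresh = 0.48,
                        trough_water = 0.2, urine_mass = 8,
                        urine_n_conc = 3, fecal_fresh = 2,
                        fecal_dm_pct = 25, fecal_n_conc = 25,
                        urine_urea = NA_real_, measurement = TRUE) {
  data.frame(animal_id = animal_id, phase = phase, diet = diet, day = day,
             measurement = measurement, offered_fresh = offered_fresh,
             refused_fresh = refused_fresh, refusal_dm_pct = NA_real_,
             trough_water = trough_water, urine_mass = urine_mass,
             urine_n_conc = urine_n_conc, urine_urea = urine_urea,
             fecal_fresh = fecal_fresh, fecal_dm_pct = fecal_dm_pct,
             fecal_n_conc = fecal_n_conc, stringsAsFactors = FALSE)
}

# minimal balanced 2-animal crossover record set (one day per phase)
tiny_records <- function() {
  rbind(make_record("a1", 1L, "PL"),
        make_record("a1", 2L, "RG", offered_fresh = 12, refused_fresh = 1),
        make_record("a2", 1L, "RG", offered_fresh = 12, refused_fresh = 1),
        make_record("a2", 2L, "PL"))
}

tiny_dataset <- function() {
  trial_dataset(tiny_records(), list(PL = pl_comp(), RG = rg_comp()))
}

# random balanced crossover response table for estimator equivalence checks
random_crossover <- function(n_animals = 8) {
  animals <- sprintf("a%02d", seq_len(n_animals))
  first_pl <- seq_len(n_animals) <= n_animals / 2
  layout <- data.frame(
    animal_id = rep(animals, each = 2), phase = rep(1:2, n_animals),
    diet = as.vector(vapply(first_pl, function(f)
      if (f) c("PL", "RG") else c("RG", "PL"), character(2))),
    stringsAsFactors = FALSE)
  layout$y <- stats::rnorm(nrow(layout), mean = 10, sd = 2)
  layout
}

# independent normal-equations least squares (intercept prepended)
ols_oracle <- function(design, y) {
  X <- cbind(1, as.matrix(design))
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# memoized per-seed budget tables from the default generator, shared by the
# stochastic recovery tests
.trial_cache <- new.env(parent = emptyenv())
default_budgets <- function(n_seeds = 200) {
  key <- paste0("b", n_seeds)
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- lapply(seq_len(n_seeds), function(i)
      trial_budgets(generate_trial(generator_config(seed = i))))
  .trial_cache[[key]]
}
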