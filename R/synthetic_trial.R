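default_compositions <- function() {
  list(
    PL = composition("PL", dm_pct = 10.95, cp_pct = 15.87, ndf_pct = 30.33,
                     adf_pct = 25.84, wsc_pct = 14.33, om_pct = 88.36),
    RG = composition("RG", dm_pct = 14.88, cp_pct = 22.79, ndf_pct = 42.86,
                     adf_pct = 23.88, wsc_pct = 12.60, om_pct = 89.46))
}

#' Configuration of the synthetic crossover trial generator
#'
#' Collects every "truth" the generator builds a dataset from: the two diet
#' compositions, target intake and water means per diet, the structural
#' regression coefficients linking water intake to urine output and N intake
#' to N excretion, the liquid-phase kinetic truths per diet, and the noise
#' scales. Defaults encode a plantain (PL) vs ryegrass (RG) crossover in
#' 8 red deer: DMI 1.59/1.43 kg DM/d, trough water 0.18/1.00 L/d, apparent
#' DMD 67.30/73.43 \%, urine output = intercept (2.94 PL / 0.88 RG) + 0.42 x
#' water intake, fecal N = 6.38 + 0.15 x N intake, urinary N = intercept
#' (6.58 PL / 15.65 RG) + 0.45 x N intake, and per-diet kinetic truths
#' (GIF 6.44/3.93 L, RRT 11.69/11.58 h, ITT 8.79/8.92 h).
#'
#' Between-animal standard deviations default to the published standard
#' errors of diet means scaled by \code{sqrt(8)} (SD = SEM x sqrt(n));
#' day-to-day residual SDs default to half the between-animal SD; marker
#' concentrations carry 5\% multiplicative lognormal noise. All noise scales
#' multiply by \code{noise_scale}, so \code{noise_scale = 0} gives a
#' noise-free dataset whose analysis reproduces the configured chain
#' exactly.
#'
#' @param n_animals Even number of animals (default 8, half per sequence,
#'   alternating gender).
#' @param seed Base RNG seed; every draw is keyed by (seed, animal, phase,
#'   day, channel) so subsets are reproducible.
#' @param compositions Named list of two \code{\link{composition}}s.
#' @param dmi_mean,dmi_sem Per-diet DMI mean (kg DM/d) and its SEM.
#' @param trough_mean,trough_sem Per-diet trough water (L/d) and SEM.
#' @param dmd_pct Per-diet apparent DM digestibility truth, \%.
#' @param fecal_dm_truth Per-diet fecal DM truth, \%.
#' @param urine_slope,urine_intercept,urine_resid_sd Urine output (L/d) as a
#'   linear function of total water intake; per-diet intercepts; residual SD.
#' @param fn_intercept,fn_slope,fn_resid_sd Fecal N (g/d) vs N intake.
#' @param un_slope,un_intercept,un_resid_sd Urinary N (g/d) vs N intake;
#'   per-diet intercepts.
#' @param urea_per_un Urine urea (mmol/L) per unit urinary N concentration
#'   (g/L); default 34, matching the observed urea/N ratio.
#' @param kinetics Per-diet list of \code{gif} (L), \code{rate} (/h),
#'   \code{tau} (h); \code{gif_sem} scales between-animal GIF spread.
#' @param licoedta_mass,co_fraction Marker dose: 17.98 g of LiCoEDTA at
#'   20.7\% Co (3.72 g Co).
#' @param marker_times Sampling protocol, h post-dose.
#' @param marker_cv Multiplicative CV of marker concentrations (default
#'   0.05).
#' @param fecal_dm_sd SD of per-sample fecal DM\% around the diet truth.
#' @param refusal_range Daily refusal fraction range (uniform; ad libitum
#'   feeding targets >= 10\% refusals).
#' @param n_meas_days Measurement days per phase (default 3).
#' @param n_acclim_days Acclimation days generated per phase, flagged
#'   \code{measurement = FALSE} (default 0).
#' @param day_sd_frac Day-level SD as a fraction of the between-animal SD.
#' @param gender_effect Additive DMI shift for males, kg DM/d (default 0; no
#'   gender effect size is assumed).
#' @param noise_scale Global multiplier on all noise SDs/CVs.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_animals = 8, seed = 1,
                             compositions = default_compositions(),
                             dmi_mean = c(PL = 1.59, RG = 1.43),
                             dmi_sem = 0.11,
                             trough_mean = c(PL = 0.18, RG = 1.00),
                             trough_sem = 0.22,
                             dmd_pct = c(PL = 67.30, RG = 73.43),
                             fecal_dm_truth = c(PL = 25.2, RG = 24.2),
                             urine_slope = 0.42,
                             urine_intercept = c(PL = 2.94, RG = 0.88),
                             urine_resid_sd = 1.0,
                             fn_intercept = 6.38, fn_slope = 0.15,
                             fn_resid_sd = 3.0,
                             un_slope = 0.45,
                             un_intercept = c(PL = 6.58, RG = 15.65),
                             un_resid_sd = 7.5,
                             urea_per_un = 34,
                             kinetics = list(
                               PL = list(gif = 6.44, rate = 1 / 11.69,
                                         tau = 8.79),
                               RG = list(gif = 3.93, rate = 1 / 11.58,
                                         tau = 8.92)),
                             gif_sem = 0.60,
                             licoedta_mass = 17.98, co_fraction = 0.207,
                             marker_times = c(0, 4, 8, 12, 24, 36, 48, 60,
                                              72),
                             marker_cv = 0.05, fecal_dm_sd = 1.5,
                             refusal_range = c(0.08, 0.16),
                             n_meas_days = 3, n_acclim_days = 0,
                             day_sd_frac = 0.5, gender_effect = 0,
                             noise_scale = 1) {
  if (n_animals < 2 || n_animals %% 2 != 0)
    stop("n_animals must be an even count >= 2")
  if (!all(vapply(compositions, inherits, logical(1), "composition")))
    stop("compositions must be composition objects")
  diets <- names(compositions)
  if (length(diets) != 2) stop("exactly two diets are required")
  for (nm in c("dmi_mean", "trough_mean", "dmd_pct", "fecal_dm_truth",
               "urine_intercept", "un_intercept"))
    if (!all(diets %in% names(get(nm))))
      stop(nm, " must be named by diet (", paste(diets, collapse = ", "), ")")
  sds <- c(dmi_sem, trough_sem, urine_resid_sd, fn_resid_sd, un_resid_sd,
           gif_sem, marker_cv, fecal_dm_sd, noise_scale)
  if (any(sds < 0)) stop("noise scales must be >= 0")
  if (any(dmd_pct <= 0 | dmd_pct >= 100))
    stop("dmd_pct truths must lie in (0, 100)")
  structure(list(n_animals = n_animals, seed = seed,
                 compositions = compositions, diets = diets,
                 dmi_mean = dmi_mean, dmi_sem = dmi_sem,
                 trough_mean = trough_mean, trough_sem = trough_sem,
                 dmd_pct = dmd_pct, fecal_dm_truth = fecal_dm_truth,
                 urine_slope = urine_slope,
                 urine_intercept = urine_intercept,
                 urine_resid_sd = urine_resid_sd,
                 fn_intercept = fn_intercept, fn_slope = fn_slope,
                 fn_resid_sd = fn_resid_sd, un_slope = un_slope,
                 un_intercept = un_intercept, un_resid_sd = un_resid_sd,
                 urea_per_un = urea_per_un, kinetics = kinetics,
                 gif_sem = gif_sem, licoedta_mass = licoedta_mass,
                 co_fraction = co_fraction, marker_times = marker_times,
                 marker_cv = marker_cv, fecal_dm_sd = fecal_dm_sd,
                 refusal_range = refusal_range, n_meas_days = n_meas_days,
                 n_acclim_days = n_acclim_days, day_sd_frac = day_sd_frac,
                 gender_effect = gender_effect, noise_scale = noise_scale),
            class = "generator_config")
}

draw <- function(config, a, p, d, channel, fn) {
  with_preserved_seed(substream_seed(config$seed, a, p, d, channel), fn())
}

#' Generate one noisy fecal marker excretion curve
#'
#' Evaluates \code{\link{model_conc}} at the sampling times for a kinetic
#' truth (\code{dose} g Co, \code{gif} L, \code{rate} /h, \code{tau} h;
#' \code{c0 = 1000 dose / gif}), multiplies by lognormal noise with the
#' given CV (unit mean), draws each sample's fecal DM\% around the truth,
#' and returns the series on the DM basis that a laboratory would report.
#'
#' @param truth List with \code{dose}, \code{gif}, \code{rate}, \code{tau},
#'   optional \code{model} (default \code{"exp_delay"}) and
#'   \code{fecal_dm_pct} (default 25).
#' @param times Sampling times, h post-dose.
#' @param cv Multiplicative coefficient of variation (>= 0).
#' @param seed RNG seed for this curve.
#' @param fecal_dm_sd SD of the per-sample fecal DM\% (default 1.5).
#' @param animal_id,phase Labels for the resulting series.
#' @return A \code{\link{marker_series}}.
#' @export
generate_marker_curve <- function(truth, times, cv = 0.05, seed = 1,
                                  fecal_dm_sd = 1.5, animal_id = "sim",
                                  phase = 1) {
  stopifnot(cv >= 0, truth$gif > 0, truth$dose > 0)
  model <- if (is.null(truth$model)) "exp_delay" else truth$model
  fdm <- if (is.null(truth$fecal_dm_pct)) 25 else truth$fecal_dm_pct
  c0 <- 1000 * truth$dose / truth$gif
  conc_w <- model_conc(times, c0, truth$rate, truth$tau, model = model)
  with_preserved_seed(seed, {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      conc_w <- conc_w * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog)
    }
    dm <- rnorm_trunc(length(times), fdm, fecal_dm_sd, lower = 5)
    dm <- pmin(dm, 95)
    marker_series(animal_id, phase, times,
                  conc_w * (100 - dm) / dm, dm)
  })
}

#' Generate a complete synthetic crossover trial
#'
#' Builds a balanced 2-diet, 2-phase crossover dataset (half the animals on
#' each sequence) by chaining the configured structural equations: daily DMI
#' around the diet mean with between-animal and day effects; feed water from
#' the diet DM\%; trough water around the diet mean; urine output from the
#' water-intake regression; N intake from DMI and crude protein; fecal and
#' urinary N from the N-partitioning regressions; fecal output from the
#' digestibility truth; and per-animal-phase marker curves from the kinetic
#' truths. Every generated dataset passes \code{\link{trial_dataset}}
#' validation, and all randomness derives from the config seed.
#'
#' @param config A \code{\link{generator_config}}.
#' @return A \code{\link{trial_dataset}} with attribute \code{"truth"}: the
#'   config plus a per-animal-phase table of the latent values (realized
#'   DMI, water intake, urine output, N intake, FN, UN, GIF, c0) for
#'   recovery tests.
#' @export
generate_trial <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  ns <- config$noise_scale
  diets <- config$diets
  n <- config$n_animals
  sd_dmi_a <- config$dmi_sem * sqrt(8) * ns
  sd_trough_a <- config$trough_sem * sqrt(8) * ns
  sd_gif_a <- config$gif_sem * sqrt(8) * ns
  dose_g <- config$licoedta_mass * config$co_fraction

  # noise-free feasibility of the configured chain
  for (dd in diets) {
    comp <- config$compositions[[dd]]
    w0 <- config$dmi_mean[dd] * (100 / comp$dm_pct - 1) +
      config$trough_mean[dd]
    u0 <- config$urine_intercept[dd] + config$urine_slope * w0
    if (u0 <= 0)
      stop("config implies non-positive urine output for diet ", dd)
    ni0 <- n_intake(config$dmi_mean[dd], comp$cp_pct)
    if (config$un_intercept[dd] + config$un_slope * ni0 <= 0)
      stop("config implies non-positive urinary N for diet ", dd)
    if (config$fn_intercept + config$fn_slope * ni0 <= 0)
      stop("config implies non-positive fecal N for diet ", dd)
  }

  animals <- sprintf("deer%02d", seq_len(n))
  gender <- rep(c("M", "F"), length.out = n)
  # first half treatment-first, balanced for gender by alternation
  seq_first <- rep(diets, each = n / 2)
  days_meas <- seq_len(config$n_meas_days) + 9L
  days_acc <- if (config$n_acclim_days > 0)
    9L + 1L - rev(seq_len(config$n_acclim_days)) else integer(0)

  records <- list(); truth_rows <- list(); doses <- list(); series <- list()
  for (a in seq_len(n)) {
    a_dmi <- draw(config, a, 0, 0, 1, function()
      stats::rnorm(1, 0, sd_dmi_a))
    for (p in 1:2) {
      diet <- if (p == 1) seq_first[a] else setdiff(diets, seq_first[a])
      comp <- config$compositions[[diet]]
      base_dmi <- config$dmi_mean[diet] + a_dmi +
        if (gender[a] == "M") config$gender_effect else 0
      trough_ap <- draw(config, a, p, 0, 2, function()
        rnorm_trunc(1, config$trough_mean[diet], sd_trough_a, lower = 0))

      all_days <- c(days_acc, days_meas)
      nd <- length(all_days)
      dmi_d <- vapply(seq_len(nd), function(i) draw(config, a, p,
                                                    all_days[i], 3,
        function() rnorm_trunc(1, base_dmi, sd_dmi_a * config$day_sd_frac,
                               lower = 0.05)), numeric(1))
      trough_d <- vapply(seq_len(nd), function(i) draw(config, a, p,
                                                       all_days[i], 4,
        function() rnorm_trunc(1, trough_ap,
                               sd_trough_a * config$day_sd_frac,
                               lower = 0)), numeric(1))
      rf_d <- vapply(seq_len(nd), function(i) draw(config, a, p,
                                                   all_days[i], 5,
        function() stats::runif(1, config$refusal_range[1],
                                config$refusal_range[2])), numeric(1))
      fdm_d <- vapply(seq_len(nd), function(i) draw(config, a, p,
                                                    all_days[i], 6,
        function() rnorm_trunc(1, config$fecal_dm_truth[diet],
                               config$fecal_dm_sd * ns, lower = 5)),
        numeric(1))

      meas <- all_days %in% days_meas
      phase_dmi <- mean(dmi_d[meas])
      water_realized <- mean(dmi_d[meas] * (100 / comp$dm_pct - 1) +
                               trough_d[meas])
      eps_u <- draw(config, a, p, 0, 8, function()
        stats::rnorm(1, 0, config$urine_resid_sd * ns))
      urine_phase <- max(config$urine_intercept[diet] +
                           config$urine_slope * water_realized + eps_u, 0.5)
      urine_d <- vapply(seq_len(nd), function(i) draw(config, a, p,
                                                      all_days[i], 7,
        function() rnorm_trunc(1, urine_phase,
                               config$urine_resid_sd * config$day_sd_frac *
                                 ns, lower = 0.1)), numeric(1))

      ni <- n_intake(phase_dmi, comp$cp_pct)
      eps_fn <- draw(config, a, p, 0, 9, function()
        stats::rnorm(1, 0, config$fn_resid_sd * ns))
      fn <- max(config$fn_intercept + config$fn_slope * ni + eps_fn, 0.5)
      eps_un <- draw(config, a, p, 0, 10, function()
        stats::rnorm(1, 0, config$un_resid_sd * ns))
      un <- max(config$un_intercept[diet] + config$un_slope * ni + eps_un,
                0.5)

      fecal_dm_d <- dmi_d * (1 - config$dmd_pct[diet] / 100)
      fecal_fresh_d <- fecal_dm_d / (fdm_d / 100)
      fecal_n_conc <- fn / mean(fecal_dm_d[meas])
      urine_n_conc <- un / mean(urine_d[meas])
      urea <- config$urea_per_un * urine_n_conc

      offered_d <- (dmi_d / (1 - rf_d)) / (comp$dm_pct / 100)
      refused_d <- offered_d - dmi_d / (comp$dm_pct / 100)

      records[[length(records) + 1]] <- data.frame(
        animal_id = animals[a], phase = p, diet = diet, day = all_days,
        measurement = meas, offered_fresh = offered_d,
        refused_fresh = refused_d, refusal_dm_pct = NA_real_,
        trough_water = trough_d, urine_mass = urine_d,
        urine_n_conc = urine_n_conc, urine_urea = urea,
        fecal_fresh = fecal_fresh_d, fecal_dm_pct = fdm_d,
        fecal_n_conc = fecal_n_conc, stringsAsFactors = FALSE)

      kin <- config$kinetics[[diet]]
      gif_ap <- draw(config, a, p, 0, 11, function()
        rnorm_trunc(1, kin$gif, sd_gif_a, lower = 1))
      mseed <- substream_seed(config$seed, a, p, 0, 12)
      series[[length(series) + 1]] <- generate_marker_curve(
        list(dose = dose_g, gif = gif_ap, rate = kin$rate, tau = kin$tau,
             fecal_dm_pct = unname(config$fecal_dm_truth[diet])),
        config$marker_times, cv = config$marker_cv * ns, seed = mseed,
        fecal_dm_sd = config$fecal_dm_sd * ns, animal_id = animals[a],
        phase = p)
      doses[[length(doses) + 1]] <- dose_record(animals[a], p,
                                                config$licoedta_mass,
                                                config$co_fraction)

      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        animal_id = animals[a], phase = p, diet = diet, gender = gender[a],
        dmi = phase_dmi, water_intake = water_realized,
        urine = urine_phase, ni = ni, fn = fn, un = un,
        gif = gif_ap, c0 = 1000 * dose_g / gif_ap, rate = kin$rate,
        tau = kin$tau, stringsAsFactors = FALSE)
    }
  }
  dataset <- trial_dataset(do.call(rbind, records), config$compositions,
                           doses, series)
  attr(dataset, "truth") <- list(config = config,
                                 per_phase = do.call(rbind, truth_rows))
  dataset
}
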