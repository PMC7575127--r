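#' Fit liquid-phase kinetics for every marker series in a trial
#'
#' Runs \code{\link{fit_curve}} and \code{\link{derive_params}} on each
#' fecal marker series, using the matching dose record's cobalt mass.
#'
#' @param dataset A \code{\link{trial_dataset}} with marker series and
#'   doses.
#' @param model Model family passed to \code{\link{fit_curve}}.
#' @return Data frame, one row per animal-phase: fit parameters
#'   (\code{c0}, \code{rate}, \code{tau}, \code{rss}, \code{converged}) and
#'   derived kinetics (\code{fractional_outflow}, \code{gif}, \code{rrt},
#'   \code{itt}, \code{gmrt}).
#' @export
trial_kinetics <- function(dataset, model = c("exp_delay", "gamma2_delay")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  model <- match.arg(model)
  if (!length(dataset$marker_series))
    stop("dataset has no marker series")
  dose_key <- vapply(dataset$doses, function(d)
    paste(d$animal_id, d$phase, sep = "/"), character(1))
  rows <- lapply(dataset$marker_series, function(s) {
    i <- match(paste(s$animal_id, s$phase, sep = "/"), dose_key)
    if (is.na(i))
      stop("no dose record for marker series ", s$animal_id, "/", s$phase)
    fit <- fit_curve(s, model = model)
    kp <- derive_params(fit, co_dose_mass(dataset$doses[[i]]))
    data.frame(animal_id = s$animal_id, phase = s$phase,
               model = fit$model, c0 = fit$c0, rate = fit$rate,
               tau = fit$tau, rss = fit$rss, converged = fit$converged,
               fractional_outflow = kp$fractional_outflow, gif = kp$gif,
               rrt = kp$rrt, itt = kp$itt, gmrt = kp$gmrt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  lay <- dataset$layout
  out$diet <- lay$diet[match(paste(out$animal_id, out$phase, sep = "/"),
                             paste(lay$animal_id, lay$phase, sep = "/"))]
  out
}

qq_table <- function(fit) {
  r <- sort(fit$residuals)
  s <- sqrt(fit$rss / max(fit$n - length(fit$coefficients), 1))
  data.frame(theoretical = stats::qnorm(stats::ppoints(length(r))),
             sample = if (s > 0) r / s else r)
}

regression_summary <- function(fit, diet_term = "diet") {
  co <- fit$coefficients
  out <- list(terms = fit$terms, coefficients = as.list(co), n = fit$n,
              rss = fit$rss, r2_adj = fit$r2_adj, bic = fit$bic,
              selected_candidate = attr(fit, "selected"))
  if (diet_term %in% names(co)) {
    out$intercept_control <- unname(co["(Intercept)"])
    out$intercept_treatment <- unname(co["(Intercept)"] + co[diet_term])
  }
  out$qq <- qq_table(fit)
  out
}

#' Full analysis of a crossover metabolism trial
#'
#' Runs the complete pipeline on a validated dataset:
#' \enumerate{
#'   \item per animal-phase budgets (\code{\link{trial_budgets}});
#'   \item liquid-phase kinetics (\code{\link{trial_kinetics}}), when marker
#'     series are present;
#'   \item crossover diet contrasts (\code{\link{diet_effect}}) for every
#'     budget and kinetic response;
#'   \item mechanism regressions with BIC selection
#'     (\code{\link{select_model}}): urine output on water intake with
#'     candidate diet-intercept, ash-intake and diet-slope terms; fecal,
#'     urinary and total N on N intake with candidate diet terms;
#'   \item the Pearson correlation of urine output with urinary N
#'     concentration;
#'   \item the environmental translation: the fractional urinary-N
#'     concentration reduction (control to treatment) applied to the
#'     baseline urine-patch loading and the leaching power law.
#' }
#' Diets are coded treatment = 1, control = 0 in the regressions, so the
#' reported intercepts are per-diet.
#'
#' @param dataset A \code{\link{trial_dataset}}.
#' @param treatment,control Diet labels (default \code{"PL"}, \code{"RG"}).
#' @param model Kinetic model family.
#' @param leach A \code{\link{leaching_model}} (exponent and baseline
#'   loading).
#' @return An object of class \code{"trial_analysis"}: \code{budgets},
#'   \code{kinetics}, \code{effects} (one row per response),
#'   \code{regressions} (named list of fitted-model summaries),
#'   \code{correlation}, \code{environment}.
#' @export
analyze_trial <- function(dataset, treatment = "PL", control = "RG",
                          model = c("exp_delay", "gamma2_delay"),
                          leach = leaching_model()) {
  stopifnot(inherits(dataset, "trial_dataset"))
  model <- match.arg(model)
  budgets <- trial_budgets(dataset)
  kin <- if (length(dataset$marker_series))
    trial_kinetics(dataset, model = model) else NULL

  tab <- budgets
  if (!is.null(kin))
    tab <- merge(budgets, kin[c("animal_id", "phase", "fractional_outflow",
                                "gif", "rrt", "itt", "gmrt")],
                 by = c("animal_id", "phase"), sort = FALSE)
  tab <- tab[order(tab$animal_id, tab$phase), ]

  responses <- c("dmi", "fecal_dm_output", "app_dmd", "fecal_n_conc",
                 "urine_n_conc", "urine_urea", "water_trough", "water_feed",
                 "water_intake_total", "water_urine", "water_feces",
                 "water_excret_total", "water_balance", "prop_urine",
                 "prop_fecal", "prop_balance", "n_intake", "fecal_n",
                 "urine_n", "total_n", "app_n_digestibility", "n_retention",
                 "fractional_outflow", "gif", "rrt", "itt", "gmrt")
  responses <- responses[responses %in% names(tab)]
  responses <- responses[vapply(responses, function(r) !anyNA(tab[[r]]),
                                logical(1))]
  effects <- do.call(rbind, lapply(responses, function(r) {
    ee <- diet_effect(tab[[r]], tab, treatment, control)
    data.frame(response = r, lsmean_treatment = unname(ee$lsmeans[1]),
               lsmean_control = unname(ee$lsmeans[2]),
               diet_effect = ee$diet_effect, se = ee$se, df = ee$df,
               t_stat = ee$t_stat, p_value = ee$p_value,
               stringsAsFactors = FALSE)
  }))

  design <- data.frame(water = tab$water_intake_total,
                       ash = tab$ash_intake,
                       diet = as.numeric(tab$diet == treatment),
                       ni = tab$n_intake)
  design$water_diet <- design$water * design$diet
  design$ni_diet <- design$ni * design$diet

  # candidates that are rank deficient on this dataset (e.g. a noise-free
  # trial, where water intake is constant within diet) are not comparable
  # and are skipped before BIC selection
  select_feasible <- function(candidates, y) {
    ok <- vapply(candidates, function(tt)
      !inherits(tryCatch(ols(design[, tt, drop = FALSE], y),
                         error = function(e) e), "error"), logical(1))
    cand <- candidates[ok]
    if (!length(cand)) stop("no full-rank regression candidate")
    if (length(cand) == 1) {
      out <- ols(design[, cand[[1]], drop = FALSE], y)
      attr(out, "selected") <- which(ok)
      return(out)
    }
    out <- select_model(cand, design, y)
    attr(out, "selected") <- which(ok)[attr(out, "selected")]
    out
  }
  urine_fit <- select_feasible(list(c("water"),
                                    c("water", "diet"),
                                    c("water", "diet", "ash"),
                                    c("water", "diet", "water_diet")),
                               tab$water_urine)
  n_cands <- list(c("ni"), c("ni", "diet"), c("ni", "diet", "ni_diet"))
  fn_fit <- select_feasible(n_cands, tab$fecal_n)
  un_fit <- select_feasible(n_cands, tab$urine_n)
  tn_fit <- select_feasible(n_cands, tab$total_n)
  regressions <- list(urine_output = regression_summary(urine_fit),
                      fecal_n = regression_summary(fn_fit),
                      urine_n = regression_summary(un_fit),
                      total_n = regression_summary(tn_fit))

  correlation <- pearson_r(tab$water_urine, tab$urine_n_conc)

  unc <- effects[effects$response == "urine_n_conc", ]
  conc_reduction <- (unc$lsmean_control - unc$lsmean_treatment) /
    unc$lsmean_control
  env <- list(baseline_load = leach$baseline_load,
              exponent_b = leach$exponent_b,
              conc_reduction = conc_reduction,
              loading = if (conc_reduction >= 0 && conc_reduction <= 1)
                loading_rate(leach$baseline_load, conc_reduction)
              else NA_real_,
              leach_reduction = if (conc_reduction >= 0 &&
                                      conc_reduction < 1)
                leaching_reduction(max(conc_reduction, 0), leach)
              else NA_real_)

  structure(list(budgets = budgets, kinetics = kin, analysis_table = tab,
                 effects = effects, regressions = regressions,
                 correlation = correlation, environment = env,
                 treatment = treatment, control = control),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("Crossover trial analysis (%s vs %s), %d animal-phases\n",
              x$treatment, x$control, nrow(x$budgets)))
  key <- x$effects[x$effects$response %in%
                     c("dmi", "water_urine", "urine_n_conc", "n_intake",
                       "urine_n", "gif"), ]
  cat("Key diet contrasts (treatment vs control):\n")
  for (i in seq_len(nrow(key)))
    cat(sprintf("  %-14s %8.3f vs %8.3f (P = %.3g)\n", key$response[i],
                key$lsmean_treatment[i], key$lsmean_control[i],
                key$p_value[i]))
  uf <- x$regressions$urine_output
  cat(sprintf("Urine output model: %s (BIC %.2f)\n",
              paste(uf$terms, collapse = " + "), uf$bic))
  cat(sprintf("r(urine output, urinary N conc) = %.3f\n", x$correlation))
  if (!is.na(x$environment$loading))
    cat(sprintf("Urine-patch loading %.0f -> %.0f kg N/ha (%.1f%% conc. reduction); leaching -%.1f%%\n",
                x$environment$baseline_load, x$environment$loading,
                100 * x$environment$conc_reduction,
                100 * x$environment$leach_reduction))
  invisible(x)
}

#' Write analysis results to CSV and JSON files
#'
#' Emits \code{budgets.csv} (per animal-phase), \code{kinetics.csv},
#' \code{effects.csv} (response, per-diet least-squares means, SE, P),
#' \code{regressions.json} (terms, coefficients, BIC and Q-Q diagnostic
#' data per model) and \code{environment.json}.
#'
#' @param results A \code{\link{analyze_trial}} result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the files written.
#' @export
write_analysis <- function(results, dir) {
  stopifnot(inherits(results, "trial_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE, na = "")
    files <<- c(files, f)
  }
  wr(results$budgets, "budgets.csv")
  if (!is.null(results$kinetics)) wr(results$kinetics, "kinetics.csv")
  wr(results$effects, "effects.csv")
  f <- file.path(dir, "regressions.json")
  jsonlite::write_json(results$regressions, f, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- c(files, f)
  f <- file.path(dir, "environment.json")
  jsonlite::write_json(results$environment, f, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Simulate a trial and write it to disk
#'
#' Generates a synthetic trial (\code{\link{generate_trial}}) and writes
#' the CSV quartet plus \code{truth.json}, which records every generator
#' truth (structural coefficients, per-diet means, kinetic parameters and
#' the realized per-animal-phase latent values) for recovery testing.
#'
#' @param dir Output directory.
#' @param config A \code{\link{generator_config}}.
#' @return Invisibly, the files written.
#' @export
simulate_trial <- function(dir, config = generator_config()) {
  dataset <- generate_trial(config)
  files <- write_trial(dataset, dir)
  truth <- attr(dataset, "truth")
  cfg <- unclass(truth$config)
  cfg$compositions <- lapply(cfg$compositions, unclass)
  tr <- list(config = cfg, per_phase = truth$per_phase)
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(tr, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, f))
}
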