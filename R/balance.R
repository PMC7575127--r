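#' Apparent digestibility
#'
#' \code{100 * (intake - output) / intake}, the fraction of intake that does
#' not reappear in the feces. Applies to dry matter (kg DM/d) or nitrogen
#' (g N/d) alike. An output exceeding intake is legal (it flags a data
#' issue) and returns a negative-complement value with a warning.
#'
#' @param intake Daily intake (> 0); vectorized.
#' @param output Daily fecal output (>= 0), same units; vectorized.
#' @return Apparent digestibility, \%.
#' @examples
#' apparent_digestibility(1.59, 0.52)  # 67.30
#' @export
apparent_digestibility <- function(intake, output) {
  if (any(intake <= 0)) stop("intake must be > 0")
  if (any(output < 0)) stop("output must be >= 0")
  if (any(output > intake))
    warning("fecal output exceeds intake; digestibility is negative")
  100 * (intake - output) / intake
}

#' Nitrogen intake from dry matter intake and crude protein
#'
#' Crude protein is taken as 6.25 x N, so N intake (g/d) is
#' \code{1000 * dmi * (cp/100) / 6.25}.
#'
#' @param dmi_val Dry matter intake, kg DM/d.
#' @param cp_pct Crude protein, \% of DM.
#' @return Nitrogen intake, g N/d.
#' @export
n_intake <- function(dmi_val, cp_pct) {
  if (any(cp_pct < 0)) stop("cp_pct must be >= 0")
  1000 * dmi_val * (cp_pct / 100) / 6.25
}

#' Percent difference between two quantities
#'
#' \code{100 * (a - b) / b}: the relative change of \code{a} with respect to
#' \code{b}, as used for diet contrasts (e.g. plantain vs ryegrass mean).
#'
#' @param a,b Quantities in the same units; \code{b} must be nonzero.
#' @return Percent difference.
#' @examples
#' percent_difference(1.59, 1.43)  # +11.2
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) stop("reference value must be nonzero")
  100 * (a - b) / b
}

#' Daily water budget for one animal-phase
#'
#' Averages the measurement-period days and assembles the water ledger
#' (density-1 convention, kg = L): intake from the trough and from the feed
#' (via \code{\link{feed_water}} on each day's DMI), excretion in urine
#' (urine mass) and feces (\code{fecal_fresh * (1 - dm/100)}), the balance
#' (intake - excretion, interpreted as evaporative loss indoors), and each
#' component as a proportion of total intake.
#'
#' @param records Data frame of daily records for one animal-phase;
#'   acclimation days (\code{measurement == FALSE}) are dropped.
#' @param comp \code{\link{composition}} of the diet fed.
#' @return An object of class \code{"water_budget"}: \code{intake_trough},
#'   \code{intake_feed}, \code{intake_total}, \code{excret_urine},
#'   \code{excret_feces}, \code{excret_total}, \code{balance} (all L/d) and
#'   \code{prop_urine}, \code{prop_fecal}, \code{prop_balance} (\% of
#'   intake, summing to 100).
#' @export
water_budget <- function(records, comp) {
  stopifnot(inherits(comp, "composition"))
  if (!is.null(records$measurement))
    records <- records[records$measurement, , drop = FALSE]
  if (nrow(records) == 0) stop("no measurement-period days supplied")
  d <- dmi(records, comp)
  intake_trough <- mean(records$trough_water)
  intake_feed <- mean(feed_water(d, comp))
  intake_total <- intake_trough + intake_feed
  excret_urine <- mean(records$urine_mass)
  excret_feces <- mean(records$fecal_fresh * (1 - records$fecal_dm_pct / 100))
  excret_total <- excret_urine + excret_feces
  balance <- intake_total - excret_total
  structure(list(intake_trough = intake_trough, intake_feed = intake_feed,
                 intake_total = intake_total, excret_urine = excret_urine,
                 excret_feces = excret_feces, excret_total = excret_total,
                 balance = balance,
                 prop_urine = 100 * excret_urine / intake_total,
                 prop_fecal = 100 * excret_feces / intake_total,
                 prop_balance = 100 * balance / intake_total),
            class = "water_budget")
}

#' @export
print.water_budget <- function(x, ...) {
  cat(sprintf("Water budget (L/d): intake %.2f (trough %.2f + feed %.2f)\n",
              x$intake_total, x$intake_trough, x$intake_feed))
  cat(sprintf("  excretion %.2f (urine %.2f + feces %.2f); balance %.2f\n",
              x$excret_total, x$excret_urine, x$excret_feces, x$balance))
  cat(sprintf("  %% of intake: urine %.1f, fecal %.1f, balance %.1f\n",
              x$prop_urine, x$prop_fecal, x$prop_balance))
  invisible(x)
}

#' Daily nitrogen budget for one animal-phase
#'
#' Averages the measurement-period days: N intake from DMI and diet crude
#' protein (\code{\link{n_intake}}), fecal N as daily fecal DM output times
#' its N concentration, urinary N as urine mass times urine N concentration,
#' total excretion, apparent N digestibility
#' (\code{\link{apparent_digestibility}} on N) and N retention
#' (intake - total excretion). Urinary urea (mmol/L), when present, can be
#' cross-checked against urine N with \code{urea_n = TRUE}, converting at
#' 0.028 g N/mmol urea (2 N atoms of 14 g/mol per urea molecule).
#'
#' @param records Data frame of daily records for one animal-phase.
#' @param comp \code{\link{composition}} of the diet fed.
#' @param urea_n If \code{TRUE}, also report urea-derived urinary N
#'   (g/d) as \code{urine_urea_n}.
#' @return An object of class \code{"nitrogen_budget"}: \code{n_intake},
#'   \code{fecal_n}, \code{urine_n}, \code{total_n}, \code{n_retention}
#'   (g N/d), \code{app_n_digestibility} (\%).
#' @export
nitrogen_budget <- function(records, comp, urea_n = FALSE) {
  stopifnot(inherits(comp, "composition"))
  if (!is.null(records$measurement))
    records <- records[records$measurement, , drop = FALSE]
  if (nrow(records) == 0) stop("no measurement-period days supplied")
  d <- dmi(records, comp)
  ni <- mean(n_intake(d, comp$cp_pct))
  fecal_dm_out <- records$fecal_fresh * records$fecal_dm_pct / 100
  fn <- mean(fecal_dm_out * records$fecal_n_conc)
  un <- mean(records$urine_mass * records$urine_n_conc)
  out <- list(n_intake = ni, fecal_n = fn, urine_n = un, total_n = fn + un,
              app_n_digestibility = apparent_digestibility(ni, fn),
              n_retention = ni - (fn + un))
  if (urea_n) {
    if (all(is.na(records$urine_urea)))
      stop("urea cross-check requested but urine_urea is missing")
    out$urine_urea_n <- mean(records$urine_mass * records$urine_urea * 0.028)
  }
  structure(out, class = "nitrogen_budget")
}

#' @export
print.nitrogen_budget <- function(x, ...) {
  cat(sprintf("N budget (g/d): intake %.2f | fecal %.2f | urine %.2f | total %.2f\n",
              x$n_intake, x$fecal_n, x$urine_n, x$total_n))
  cat(sprintf("  apparent N digestibility %.2f%%; retention %.2f g/d\n",
              x$app_n_digestibility, x$n_retention))
  invisible(x)
}

#' Per animal-phase analysis table for a crossover trial
#'
#' Computes, for every animal-phase, the measurement-period means feeding
#' the crossover contrasts and mechanism regressions: DMI, fecal DM output,
#' apparent DM digestibility, the full water budget, the full nitrogen
#' budget, urine N and urea concentrations, fecal N concentration, and ash
#' intake (g/d, from the diet ash fraction).
#'
#' @param dataset A \code{\link{trial_dataset}}.
#' @return Data frame with one row per animal-phase, carrying
#'   \code{animal_id}, \code{phase}, \code{diet}, \code{sequence} and the
#'   response columns.
#' @export
trial_budgets <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  lay <- dataset$layout
  rows <- lapply(seq_len(nrow(lay)), function(i) {
    rec <- dataset$records[dataset$records$animal_id == lay$animal_id[i] &
                             dataset$records$phase == lay$phase[i] &
                             dataset$records$measurement, , drop = FALSE]
    comp <- dataset$compositions[[lay$diet[i]]]
    d <- mean(dmi(rec, comp))
    fecal_dm_out <- mean(rec$fecal_fresh * rec$fecal_dm_pct / 100)
    wb <- water_budget(rec, comp)
    nb <- nitrogen_budget(rec, comp)
    data.frame(
      animal_id = lay$animal_id[i], phase = lay$phase[i], diet = lay$diet[i],
      sequence = lay$sequence[i],
      dmi = d, fecal_dm_output = fecal_dm_out,
      app_dmd = apparent_digestibility(d, fecal_dm_out),
      water_trough = wb$intake_trough, water_feed = wb$intake_feed,
      water_intake_total = wb$intake_total,
      water_urine = wb$excret_urine, water_feces = wb$excret_feces,
      water_excret_total = wb$excret_total, water_balance = wb$balance,
      prop_urine = wb$prop_urine, prop_fecal = wb$prop_fecal,
      prop_balance = wb$prop_balance,
      n_intake = nb$n_intake, fecal_n = nb$fecal_n, urine_n = nb$urine_n,
      total_n = nb$total_n, app_n_digestibility = nb$app_n_digestibility,
      n_retention = nb$n_retention,
      urine_n_conc = mean(rec$urine_n_conc),
      urine_urea = mean(rec$urine_urea),
      fecal_n_conc = mean(rec$fecal_n_conc),
      ash_intake = 1000 * d * comp$ash_pct / 100,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
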