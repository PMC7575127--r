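#' Urine-patch nitrate-leaching response model
#'
#' A one-parameter power law standing in for the curvilinear relationship
#' between urine-patch N loading and nitrate-N leaching: relative leaching
#' scales as (relative loading)^b. The default exponent is calibrated
#' (\code{\link{calibrate_exponent}}) so that a 64.5\% loading reduction
#' maps to a 56.1\% leaching reduction; substitute your own exponent to use
#' a different calibration.
#'
#' @param exponent_b Power-law exponent (> 0); default the calibrated value
#'   (about 0.795).
#' @param baseline_load Reference urine-patch loading, kg urinary N/ha
#'   (> 0); default 400, a loading rate typical of sheep-sized grazers.
#' @return An object of class \code{"leaching_model"}.
#' @export
leaching_model <- function(exponent_b = calibrate_exponent(0.645, 0.561),
                           baseline_load = 400) {
  if (!is.numeric(exponent_b) || exponent_b <= 0)
    stop("exponent_b must be > 0")
  if (!is.numeric(baseline_load) || baseline_load <= 0)
    stop("baseline_load must be > 0")
  structure(list(exponent_b = exponent_b, baseline_load = baseline_load),
            class = "leaching_model")
}

#' Urine-patch N loading after a concentration reduction
#'
#' With urine volume per urination unchanged, patch loading scales with
#' urinary N concentration, so a fractional concentration reduction maps
#' directly onto the loading rate: \code{baseline * (1 - conc_reduction)}.
#'
#' @param baseline Baseline loading, kg urinary N/ha.
#' @param conc_reduction Fractional reduction in urinary N concentration,
#'   in [0, 1].
#' @return Loading rate, kg urinary N/ha.
#' @examples
#' loading_rate(400, 0.645)  # 142
#' @export
loading_rate <- function(baseline, conc_reduction) {
  if (any(conc_reduction < 0 | conc_reduction > 1))
    stop("conc_reduction must lie in [0, 1]")
  baseline * (1 - conc_reduction)
}

#' Calibrate the leaching power-law exponent
#'
#' Back-solves the exponent from one (loading reduction, leaching reduction)
#' pair: \code{b = log(1 - leach_reduction) / log(1 - load_reduction)}.
#'
#' @param load_reduction Fractional loading reduction, in (0, 1).
#' @param leach_reduction Fractional leaching reduction, in (0, 1).
#' @return The exponent b.
#' @examples
#' calibrate_exponent(0.645, 0.561)  # about 0.795
#' @export
calibrate_exponent <- function(load_reduction, leach_reduction) {
  if (any(load_reduction <= 0 | load_reduction >= 1) ||
      any(leach_reduction <= 0 | leach_reduction >= 1))
    stop("reductions must lie strictly in (0, 1)")
  log(1 - leach_reduction) / log(1 - load_reduction)
}

#' Relative nitrate-leaching reduction from a loading reduction
#'
#' Under the power-law response, a fractional loading reduction r maps to a
#' leaching reduction \code{1 - (1 - r)^b}.
#'
#' @param load_reduction Fractional loading reduction, in [0, 1).
#' @param model A \code{\link{leaching_model}}, or a bare numeric exponent.
#' @return Fractional leaching reduction.
#' @examples
#' leaching_reduction(0.645)  # about 0.561
#' @export
leaching_reduction <- function(load_reduction, model = leaching_model()) {
  if (is.numeric(model)) model <- leaching_model(exponent_b = model)
  stopifnot(inherits(model, "leaching_model"))
  if (any(load_reduction < 0 | load_reduction >= 1))
    stop("load_reduction must lie in [0, 1)")
  1 - (1 - load_reduction)^model$exponent_b
}
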