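#' Nutritive composition of a diet
#'
#' Constructs a validated per-diet nutritive profile on a dry-matter (DM)
#' basis. All fractions are percentages; \code{dm_pct} is the fraction of
#' fresh (as-fed) mass that is dry matter, the remaining fields are fractions
#' of the dry matter itself. Organic matter and ash are complementary
#' (\code{ash_pct = 100 - om_pct}); either may be omitted and is then filled
#' in from the other.
#'
#' @param diet_name Diet label (e.g. \code{"PL"} for plantain).
#' @param dm_pct Dry matter, \% of fresh mass.
#' @param cp_pct Crude protein, \% of DM.
#' @param ndf_pct Neutral detergent fiber, \% of DM.
#' @param adf_pct Acid detergent fiber, \% of DM.
#' @param wsc_pct Water-soluble carbohydrates, \% of DM.
#' @param om_pct Organic matter, \% of DM (optional if \code{ash_pct} given).
#' @param ash_pct Ash, \% of DM (optional if \code{om_pct} given).
#' @return An object of class \code{"composition"} (a named list).
#' @examples
#' composition("PL", dm_pct = 10.95, cp_pct = 15.87, ndf_pct = 30.33,
#'             adf_pct = 25.84, wsc_pct = 14.33, om_pct = 88.36)
#' @export
composition <- function(diet_name, dm_pct, cp_pct, ndf_pct, adf_pct, wsc_pct,
                        om_pct = NULL, ash_pct = NULL) {
  if (is.null(om_pct) && is.null(ash_pct))
    stop("one of 'om_pct' or 'ash_pct' must be supplied")
  if (is.null(ash_pct)) ash_pct <- 100 - om_pct
  if (is.null(om_pct)) om_pct <- 100 - ash_pct
  vals <- c(dm_pct = dm_pct, om_pct = om_pct, cp_pct = cp_pct,
            ndf_pct = ndf_pct, adf_pct = adf_pct, wsc_pct = wsc_pct,
            ash_pct = ash_pct)
  bad <- vals <= 0 | vals >= 100
  if (any(bad))
    stop("composition percentages must lie in (0, 100); offending: ",
         paste(names(vals)[bad], collapse = ", "))
  if (abs(ash_pct - (100 - om_pct)) > 0.1)
    stop("ash_pct and om_pct are not complementary (|ash - (100 - om)| > 0.1)")
  structure(list(diet_name = as.character(diet_name), dm_pct = dm_pct,
                 om_pct = om_pct, cp_pct = cp_pct, ndf_pct = ndf_pct,
                 adf_pct = adf_pct, wsc_pct = wsc_pct, ash_pct = ash_pct),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("Diet composition:", x$diet_name, "\n")
  cat(sprintf("  DM %.2f%% as fed | OM %.2f | CP %.2f | NDF %.2f | ADF %.2f | WSC %.2f | ash %.2f (%% DM)\n",
              x$dm_pct, x$om_pct, x$cp_pct, x$ndf_pct, x$adf_pct, x$wsc_pct,
              x$ash_pct))
  invisible(x)
}

#' Marker dose record
#'
#' A pulse dose of LiCoEDTA given to one animal at the start of one phase.
#' \code{dose_time} fixes the clock origin of the corresponding fecal marker
#' series (hours post-dose).
#'
#' @param animal_id Animal label.
#' @param phase Phase index (1 or 2).
#' @param licoedta_mass Mass of LiCoEDTA dosed, g.
#' @param co_fraction Mass fraction of cobalt in the dosed material, in (0, 1).
#' @param dose_time Clock origin, h (default 0).
#' @return An object of class \code{"dose_record"}.
#' @export
dose_record <- function(animal_id, phase, licoedta_mass, co_fraction,
                        dose_time = 0) {
  if (!is.numeric(licoedta_mass) || licoedta_mass <= 0)
    stop("licoedta_mass must be > 0")
  if (!is.numeric(co_fraction) || co_fraction <= 0 || co_fraction >= 1)
    stop("co_fraction must lie in (0, 1)")
  structure(list(animal_id = as.character(animal_id),
                 phase = as.integer(phase),
                 licoedta_mass = licoedta_mass, co_fraction = co_fraction,
                 dose_time = dose_time),
            class = "dose_record")
}

#' Cobalt mass delivered by a dose
#'
#' @param dose A \code{\link{dose_record}}.
#' @return Cobalt mass, g.
#' @examples
#' co_dose_mass(dose_record("d1", 1, 17.98, 0.207))  # 3.72 g
#' @export
co_dose_mass <- function(dose) {
  stopifnot(inherits(dose, "dose_record"))
  dose$licoedta_mass * dose$co_fraction
}

record_columns <- c("animal_id", "phase", "diet", "day", "measurement",
                    "offered_fresh", "refused_fresh", "refusal_dm_pct",
                    "trough_water", "urine_mass", "urine_n_conc",
                    "urine_urea", "fecal_fresh", "fecal_dm_pct",
                    "fecal_n_conc")

# columns that must be complete (non-missing) on measurement-period days
record_required <- setdiff(record_columns, c("refusal_dm_pct", "urine_urea"))

validate_records <- function(records) {
  missing_cols <- setdiff(setdiff(record_columns, c("refusal_dm_pct",
                                                    "urine_urea",
                                                    "measurement")),
                          names(records))
  if (length(missing_cols))
    stop("records table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(records$measurement)) records$measurement <- TRUE
  if (is.null(records$refusal_dm_pct)) records$refusal_dm_pct <- NA_real_
  if (is.null(records$urine_urea)) records$urine_urea <- NA_real_
  records <- records[record_columns]
  records$animal_id <- as.character(records$animal_id)
  records$phase <- as.integer(records$phase)
  records$measurement <- as.logical(records$measurement)
  records$refusal_dm_pct <- as.numeric(records$refusal_dm_pct)
  records$urine_urea <- as.numeric(records$urine_urea)

  key <- paste(records$animal_id, records$phase, records$day, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (animal, phase, day) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  meas <- records[records$measurement, , drop = FALSE]
  incomplete <- !stats::complete.cases(meas[setdiff(record_required,
                                                    "measurement")])
  if (any(incomplete))
    stop("missing value(s) in measurement-period record(s): ",
         paste(paste(meas$animal_id[incomplete], meas$phase[incomplete],
                     meas$day[incomplete], sep = "/"), collapse = ", "))

  nonneg <- c("offered_fresh", "refused_fresh", "trough_water", "urine_mass",
              "urine_n_conc", "fecal_fresh", "fecal_n_conc")
  for (col in nonneg) {
    bad <- which(!is.na(records[[col]]) & records[[col]] < 0)
    if (length(bad))
      stop("negative ", col, " in record ", key[bad[1]])
  }
  bad <- which(!is.na(records$refused_fresh) & !is.na(records$offered_fresh) &
                 records$refused_fresh > records$offered_fresh +
                 sqrt(.Machine$double.eps))
  if (length(bad))
    stop("refused_fresh exceeds offered_fresh in record ", key[bad[1]])
  bad <- which(!is.na(records$fecal_dm_pct) &
                 (records$fecal_dm_pct <= 0 | records$fecal_dm_pct >= 100))
  if (length(bad))
    stop("fecal_dm_pct outside (0, 100) in record ", key[bad[1]])
  records
}

validate_layout <- function(records, compositions) {
  ap <- unique(records[c("animal_id", "phase", "diet")])
  dup <- ap[duplicated(ap[c("animal_id", "phase")]), , drop = FALSE]
  if (nrow(dup))
    stop("more than one diet recorded for animal/phase: ",
         paste(dup$animal_id, dup$phase, sep = "/", collapse = ", "))
  counts <- table(ap$animal_id)
  if (any(counts != 2))
    stop("each animal must appear in exactly two phases; offending: ",
         paste(names(counts)[counts != 2], collapse = ", "))
  diets_per_animal <- tapply(ap$diet, ap$animal_id,
                             function(d) length(unique(d)))
  if (any(diets_per_animal != 2))
    stop("each animal must receive both diets across phases; offending: ",
         paste(names(diets_per_animal)[diets_per_animal != 2],
               collapse = ", "))
  unknown <- setdiff(unique(ap$diet), names(compositions))
  if (length(unknown))
    stop("diet(s) without a composition entry: ",
         paste(unknown, collapse = ", "))
  n_meas <- tapply(records$measurement, paste(records$animal_id,
                                              records$phase, sep = "/"), sum)
  if (any(n_meas == 0))
    stop("no measurement-period days for animal/phase: ",
         paste(names(n_meas)[n_meas == 0], collapse = ", "))
  p1 <- ap[ap$phase == min(ap$phase), ]
  layout <- data.frame(animal_id = ap$animal_id, phase = ap$phase,
                       diet = ap$diet, stringsAsFactors = FALSE)
  layout$sequence <- paste0(p1$diet[match(layout$animal_id, p1$animal_id)],
                            "-first")
  layout[order(layout$animal_id, layout$phase), ]
}

#' Assemble a crossover trial dataset
#'
#' Bundles daily records, diet compositions, marker doses and fecal marker
#' series into a validated trial dataset. Validation enforces the crossover
#' layout (one diet per animal-phase, both diets per animal across phases, at
#' least one measurement-period day per animal-phase) and the per-record
#' constraints (non-negative masses, refusals not exceeding the offer, fecal
#' DM\% within (0, 100), no missing values on measurement days).
#'
#' @param records Data frame of daily records; required columns
#'   \code{animal_id, phase, diet, day, offered_fresh, refused_fresh,
#'   trough_water, urine_mass, urine_n_conc, fecal_fresh, fecal_dm_pct,
#'   fecal_n_conc}; optional \code{measurement} (logical, default
#'   \code{TRUE}; acclimation days are flagged \code{FALSE} and excluded from
#'   budgets), \code{refusal_dm_pct}, \code{urine_urea}.
#' @param compositions Named list of \code{\link{composition}} objects, one
#'   per diet label used in \code{records}.
#' @param doses List of \code{\link{dose_record}} objects (may be empty).
#' @param marker_series List of \code{\link{marker_series}} objects (may be
#'   empty).
#' @return An object of class \code{"trial_dataset"} with elements
#'   \code{records}, \code{compositions}, \code{doses}, \code{marker_series}
#'   and a derived \code{layout} table (animal, phase, diet, sequence).
#' @export
trial_dataset <- function(records, compositions, doses = list(),
                          marker_series = list()) {
  stopifnot(is.data.frame(records), is.list(compositions))
  if (!all(vapply(compositions, inherits, logical(1), "composition")))
    stop("'compositions' must be a named list of composition objects")
  records <- validate_records(records)
  layout <- validate_layout(records, compositions)
  structure(list(records = records, compositions = compositions,
                 doses = doses, marker_series = marker_series,
                 layout = layout),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Crossover trial dataset: %d animals x %d phases, %d daily records\n",
              length(unique(x$layout$animal_id)),
              length(unique(x$layout$phase)), nrow(x$records)))
  cat("  diets:", paste(names(x$compositions), collapse = ", "),
      "| marker series:", length(x$marker_series),
      "| doses:", length(x$doses), "\n")
  invisible(x)
}

#' Daily dry matter intake
#'
#' DMI is the dry mass of the offer minus the dry mass of the refusal:
#' \code{offered_fresh * dm/100 - refused_fresh * refusal_dm/100}. The
#' refusal DM\% defaults to the offered diet's DM\% (overridable per record
#' via a \code{refusal_dm_pct} column or the argument).
#'
#' @param record Data frame of one or more daily records (see
#'   \code{\link{trial_dataset}} for columns).
#' @param comp The \code{\link{composition}} of the offered diet.
#' @param refusal_dm_pct Optional refusal DM\% overriding both the record
#'   column and the diet default.
#' @return Numeric vector, kg DM/d, one value per record row.
#' @examples
#' pl <- composition("PL", 10.95, 15.87, 30.33, 25.84, 14.33, om_pct = 88.36)
#' dmi(data.frame(offered_fresh = 15, refused_fresh = 0.48), pl)  # 1.59
#' @export
dmi <- function(record, comp, refusal_dm_pct = NULL) {
  stopifnot(inherits(comp, "composition"))
  if (!is.null(record$diet) && any(record$diet != comp$diet_name))
    stop("composition '", comp$diet_name,
         "' does not match the record diet")
  rdm <- if (!is.null(refusal_dm_pct)) refusal_dm_pct
         else if (!is.null(record$refusal_dm_pct)) record$refusal_dm_pct
         else NA_real_
  rdm <- ifelse(is.na(rdm), comp$dm_pct, rdm)
  out <- record$offered_fresh * comp$dm_pct / 100 -
    record$refused_fresh * rdm / 100
  if (any(out < -sqrt(.Machine$double.eps)))
    stop("negative dry matter intake implied; check refusal DM%")
  pmax(out, 0)
}

#' Water ingested with the feed
#'
#' The fresh herbage carries \code{(100/dm - 1)} kg of water per kg of DM
#' eaten; with water density 1 kg/L this is returned in L/d.
#'
#' @param dmi_val Dry matter intake, kg DM/d.
#' @param comp The \code{\link{composition}} of the diet consumed.
#' @return Feed water intake, L/d.
#' @export
feed_water <- function(dmi_val, comp) {
  stopifnot(inherits(comp, "composition"))
  if (comp$dm_pct <= 0) stop("dm_pct must be > 0")
  dmi_val * (100 / comp$dm_pct - 1)
}

#' Read a trial dataset from CSV tables
#'
#' Expects the four-file layout written by \code{\link{write_trial}}:
#' \code{records.csv}, \code{compositions.csv}, \code{doses.csv} and
#' \code{marker.csv} (UTF-8, one header row, period decimal separator,
#' missing values as empty fields). \code{doses.csv} and \code{marker.csv}
#' may be absent.
#'
#' @param dir Directory containing the CSV files.
#' @return A validated \code{\link{trial_dataset}}.
#' @export
load_trial <- function(dir) {
  pth <- function(f) file.path(dir, f)
  if (!file.exists(pth("records.csv")) || !file.exists(pth("compositions.csv")))
    stop("records.csv and compositions.csv are required in ", dir)
  records <- utils::read.csv(pth("records.csv"), stringsAsFactors = FALSE)
  ctab <- utils::read.csv(pth("compositions.csv"), stringsAsFactors = FALSE)
  need <- c("diet", "dm_pct", "cp_pct", "ndf_pct", "adf_pct", "wsc_pct",
            "om_pct")
  miss <- setdiff(need, names(ctab))
  if (length(miss))
    stop("compositions.csv is missing column(s): ", paste(miss, collapse = ", "))
  compositions <- lapply(seq_len(nrow(ctab)), function(i)
    composition(ctab$diet[i], ctab$dm_pct[i], ctab$cp_pct[i], ctab$ndf_pct[i],
                ctab$adf_pct[i], ctab$wsc_pct[i], om_pct = ctab$om_pct[i]))
  names(compositions) <- ctab$diet

  doses <- list()
  if (file.exists(pth("doses.csv"))) {
    dtab <- utils::read.csv(pth("doses.csv"), stringsAsFactors = FALSE)
    doses <- lapply(seq_len(nrow(dtab)), function(i)
      dose_record(dtab$animal_id[i], dtab$phase[i], dtab$licoedta_mass[i],
                  dtab$co_fraction[i],
                  if (is.null(dtab$dose_time)) 0 else dtab$dose_time[i]))
  }

  series <- list()
  if (file.exists(pth("marker.csv"))) {
    mtab <- utils::read.csv(pth("marker.csv"), stringsAsFactors = FALSE)
    need_m <- c("animal_id", "phase", "time_h", "conc_mg_per_kg_dm",
                "fecal_dm_pct")
    miss <- setdiff(need_m, names(mtab))
    if (length(miss))
      stop("marker.csv is missing column(s): ", paste(miss, collapse = ", "))
    keys <- unique(mtab[c("animal_id", "phase")])
    series <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- mtab[mtab$animal_id == keys$animal_id[i] &
                    mtab$phase == keys$phase[i], ]
      sub <- sub[order(sub$time_h), ]
      marker_series(keys$animal_id[i], keys$phase[i], sub$time_h,
                    sub$conc_mg_per_kg_dm, sub$fecal_dm_pct)
    })
  }
  trial_dataset(records, compositions, doses, series)
}

#' Write a trial dataset as CSV tables
#'
#' Inverse of \code{\link{load_trial}}; numeric columns are written at full
#' precision (15 significant digits) so a save/load round trip reproduces the
#' dataset.
#'
#' @param dataset A \code{\link{trial_dataset}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_trial <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) {
      out <- formatC(x, digits = 15, format = "g")
      out[is.na(x)] <- NA
      out
    })
    df
  }
  files <- character(0)
  f <- file.path(dir, "records.csv")
  utils::write.csv(fmt(dataset$records), f, row.names = FALSE, na = "")
  files <- c(files, f)

  ctab <- do.call(rbind, lapply(dataset$compositions, function(cc)
    data.frame(diet = cc$diet_name, dm_pct = cc$dm_pct, om_pct = cc$om_pct,
               cp_pct = cc$cp_pct, ndf_pct = cc$ndf_pct, adf_pct = cc$adf_pct,
               wsc_pct = cc$wsc_pct, ash_pct = cc$ash_pct)))
  f <- file.path(dir, "compositions.csv")
  utils::write.csv(fmt(ctab), f, row.names = FALSE, na = "")
  files <- c(files, f)

  if (length(dataset$doses)) {
    dtab <- do.call(rbind, lapply(dataset$doses, function(d)
      data.frame(animal_id = d$animal_id, phase = d$phase,
                 licoedta_mass = d$licoedta_mass,
                 co_fraction = d$co_fraction, dose_time = d$dose_time)))
    f <- file.path(dir, "doses.csv")
    utils::write.csv(fmt(dtab), f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  if (length(dataset$marker_series)) {
    mtab <- do.call(rbind, lapply(dataset$marker_series, function(s)
      data.frame(animal_id = s$animal_id, phase = s$phase, time_h = s$times,
                 conc_mg_per_kg_dm = s$conc_dm,
                 fecal_dm_pct = s$fecal_dm_pct)))
    f <- file.path(dir, "marker.csv")
    utils::write.csv(fmt(mtab), f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  invisible(files)
}
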