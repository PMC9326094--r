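#' Build a serial-dilution standard series
#'
#' Concentrations of a k-fold serial dilution starting at `top`. The default
#' 8-point 2-fold series from 0.4 ug/ml ends at 3.125e-3 ug/ml, the span
#' used for PicoGreen dsDNA calibration.
#'
#' @param top top concentration (ug/ml), default 0.4.
#' @param fold dilution factor, default 2.
#' @param n number of points, default 8.
#' @return Numeric vector of concentrations, decreasing.
#' @export
dilution_series <- function(top = 0.4, fold = 2, n = 8L) {
  stopifnot(top > 0, fold > 1, n >= 2)
  top / fold^(seq_len(n) - 1L)
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of readout on concentration,
#' `readout = slope * conc + intercept`. The PicoGreen response is linear
#' over the calibrated range, so no sigmoidal (4PL) model is fitted. A
#' warning is raised when r-squared falls below 0.98.
#'
#' @param concentration standard concentrations (ug/ml), at least two
#'   distinct, all > 0.
#' @param readout matching fluorescence readouts (arbitrary units).
#' @return Object of class `standard_curve`: `points` (data frame),
#'   `fit_slope`, `fit_intercept`, `r_squared`.
#' @export
fit_standard_curve <- function(concentration, readout) {
  if (length(concentration) != length(readout)) {
    stop("concentration and readout lengths differ", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("need at least two distinct standard concentrations", call. = FALSE)
  }
  if (any(concentration <= 0)) {
    stop("standard concentrations must be > 0", call. = FALSE)
  }
  fit <- stats::lm(readout ~ concentration)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((readout - mean(readout))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (r2 < 0.98) {
    warning(sprintf("standard curve r-squared is %.4f (< 0.98)", r2),
            call. = FALSE)
  }
  structure(list(
    points = data.frame(concentration = concentration, readout = readout),
    fit_slope = unname(stats::coef(fit)[2]),
    fit_intercept = unname(stats::coef(fit)[1]),
    r_squared = r2
  ), class = "standard_curve")
}

#' Interpolate cell-free DNA concentration from a standard curve
#'
#' Inverts the fitted line: `(readout - intercept) / slope`. Estimates
#' falling outside the calibrated concentration span are still returned but
#' flagged `"below_range"` / `"above_range"`.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param readout numeric readouts of unknown samples.
#' @return Data frame with `readout`, `concentration` (ug/ml) and `flag`
#'   (`"ok"`, `"below_range"` or `"above_range"`).
#' @export
interpolate_cfdna <- function(curve, readout) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$fit_slope == 0) {
    stop("standard curve has zero slope; cannot interpolate", call. = FALSE)
  }
  conc <- (readout - curve$fit_intercept) / curve$fit_slope
  lo <- min(curve$points$concentration)
  hi <- max(curve$points$concentration)
  tol <- 1e-8 * (hi - lo) # guard against round-trip float error at the ends
  flag <- ifelse(conc < lo - tol, "below_range",
                 ifelse(conc > hi + tol, "above_range", "ok"))
  data.frame(readout = readout, concentration = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Blank-correct ELISA optical densities
#'
#' Subtracts the mean blank OD from every sample well and floors the result
#' at zero (unstimulated wells read at background level; negative corrected
#' ODs carry no signal).
#'
#' @param plate data frame with columns `well`, `role`
#'   (`"blank"`, `"sample"`, or `"standard"`) and `value`; samples may carry
#'   an id in `sample_id`.
#' @return The plate data frame restricted to sample wells, with a
#'   `corrected` column added.
#' @export
elisa_blank_correct <- function(plate) {
  need_cols(plate, c("well", "role", "value"), "elisa_blank_correct")
  blanks <- plate$value[plate$role == "blank"]
  if (!length(blanks)) {
    stop("elisa_blank_correct: plate has no blank well", call. = FALSE)
  }
  out <- plate[plate$role == "sample", , drop = FALSE]
  out$corrected <- pmax(0, out$value - mean(blanks))
  out
}

#' Select the DNase activity at the OD plateau
#'
#' In the MPO-DNA ELISA, limited DNase digestion increases epitope
#' accessibility: OD rises with activity, plateaus, then collapses as the
#' complexes themselves degrade. This picks the lowest activity whose OD is
#' within `plateau_tolerance` (relative) of the maximum OD — the most
#' effective activity that does not risk degrading the analyte.
#'
#' @param activity DNase activities (UI per well), strictly increasing.
#' @param od matching mean optical densities, all >= 0.
#' @param plateau_tolerance relative tolerance, default 0.05.
#' @return The selected activity (UI).
#' @export
#' @examples
#' select_dnase_plateau(c(62.5, 125, 250, 500, 1000),
#'                      c(0.80, 1.00, 1.02, 0.60, 0.30)) # 125
select_dnase_plateau <- function(activity, od, plateau_tolerance = 0.05) {
  if (length(activity) != length(od)) {
    stop("activity and od lengths differ", call. = FALSE)
  }
  if (length(activity) < 3L) {
    stop("need at least 3 titration points", call. = FALSE)
  }
  if (any(diff(activity) <= 0)) {
    stop("activities must be strictly increasing", call. = FALSE)
  }
  if (any(od < 0)) stop("ODs must be >= 0", call. = FALSE)
  cut <- (1 - plateau_tolerance) * max(od)
  activity[which(od >= cut)[1]]
}

#' Read a plate-layout CSV
#'
#' Format: `well,role,value[,concentration[,sample_id]]`; `role` is one of
#' `standard`, `blank`, `sample`. Standards must carry a concentration.
#'
#' @param path file path.
#' @return Data frame with the plate columns.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("well", "role", "value"), "read_plate_csv")
  bad <- !df$role %in% c("standard", "blank", "sample")
  if (any(bad)) {
    stop("read_plate_csv: unknown role in row ", which(bad)[1], call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  if ("concentration" %in% names(df)) {
    df$concentration <- as.numeric(df$concentration)
    miss <- df$role == "standard" & !is.finite(df$concentration)
    if (any(miss)) {
      stop("read_plate_csv: standard well without concentration in row ",
           which(miss)[1], call. = FALSE)
    }
  } else if (any(df$role == "standard")) {
    stop("read_plate_csv: standards present but no concentration column",
         call. = FALSE)
  }
  df
}

#' Quantify cf DNA for a whole PicoGreen plate
#'
#' Fits the standard curve from the plate's standard wells (blank-subtracted
#' when blanks are present; the zero-DNA blank is not a calibration point)
#' and interpolates every sample well.
#'
#' @param plate plate data frame as from [read_plate_csv()].
#' @return List with `curve` (the [fit_standard_curve()] result) and
#'   `samples` (data frame `well`, `sample_id` if present, `readout`,
#'   `concentration`, `flag`).
#' @export
quantify_cfdna_plate <- function(plate) {
  std <- plate[plate$role == "standard", , drop = FALSE]
  if (nrow(std) < 2L) {
    stop("quantify_cfdna_plate: need at least two standard wells",
         call. = FALSE)
  }
  blanks <- plate$value[plate$role == "blank"]
  offset <- if (length(blanks)) mean(blanks) else 0
  if (length(blanks)) {
    message("PicoGreen: subtracting mean blank readout (",
            signif(offset, 4), ") before fitting")
  }
  curve <- fit_standard_curve(std$concentration, std$value - offset)
  smp <- plate[plate$role == "sample", , drop = FALSE]
  est <- interpolate_cfdna(curve, smp$value - offset)
  res <- data.frame(well = smp$well, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(smp)) res$sample_id <- smp$sample_id
  res$readout <- smp$value
  res$concentration <- est$concentration
  res$flag <- est$flag
  list(curve = curve, samples = res)
}
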