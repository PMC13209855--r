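#' Fit an external-standard calibration line
#'
#' Ordinary (unweighted) least squares of detector area on injected
#' amount, `area = slope * amount + intercept`, with the squared Pearson
#' correlation as R^2 and the relative SD of response factors
#' (`RF = area / amount` over non-zero amounts) as a linearity
#' diagnostic.
#'
#' @param levels data frame with columns `amount` (ng/injection, >= 0)
#'   and `area` (detector units)
#' @return an object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (min/max amount), `n_levels`, `rf_rsd`
#'   (percent), and `lod`/`loq` slots (NA until set by
#'   [detection_limits()])
#' @export
fit_calibration <- function(levels) {
  stopifnot(is.data.frame(levels),
            all(c("amount", "area") %in% names(levels)))
  if (any(levels$amount < 0)) stop_cap("amounts must be >= 0")
  if (length(unique(levels$amount)) < 3) {
    stop_cap("calibration needs at least 3 distinct amounts")
  }
  fit <- stats::lm(area ~ amount, data = levels)
  co <- stats::coef(fit)
  rf <- levels$area[levels$amount > 0] / levels$amount[levels$amount > 0]
  structure(list(
    slope = unname(co["amount"]),
    intercept = unname(co["(Intercept)"]),
    r_squared = stats::cor(levels$amount, levels$area)^2,
    range = range(levels$amount),
    n_levels = length(unique(levels$amount)),
    rf_rsd = 100 * stats::sd(rf) / mean(rf),
    lod = NA_real_, loq = NA_real_
  ), class = "calibration_curve")
}

#' Construct a calibration curve from known coefficients
#'
#' For working with a previously reported line rather than raw levels.
#'
#' @param slope area per ng
#' @param intercept area at zero amount
#' @param range amount range (ng/injection), length 2
#' @param r_squared,n_levels,rf_rsd optional diagnostics
#' @param lod,loq optional detection limits (ng/injection)
#' @return a `calibration_curve`
#' @export
calibration_curve <- function(slope, intercept, range = c(2.45, 122.5),
                              r_squared = NA_real_, n_levels = NA_integer_,
                              rf_rsd = NA_real_, lod = NA_real_,
                              loq = NA_real_) {
  if (slope <= 0) stop_cap("slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, range = range,
                 n_levels = n_levels, rf_rsd = rf_rsd,
                 lod = lod, loq = loq),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> area = %.2f * ng + %.2f | R^2 = %s | range %.3g-%.4g ng\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", format(x$r_squared, digits = 7)),
              x$range[1], x$range[2]))
  if (!is.na(x$lod)) {
    cat(sprintf("  LOD %.3g ng, LOQ %.3g ng per injection\n", x$lod, x$loq))
  }
  invisible(x)
}

#' Match a chromatographic peak to the reference retention time
#'
#' @param retention_time observed retention time (min)
#' @param reference_rt reference standard retention time (min, default
#'   3.85)
#' @param window maximum allowed drift (min, default 0.1)
#' @return `TRUE` iff `|rt - reference| <= window`
#' @export
match_peak <- function(retention_time, reference_rt = 3.85, window = 0.1) {
  if (window <= 0) stop_cap("window must be positive")
  # a peak exactly at the drift limit matches; guard the float boundary
  abs(retention_time - reference_rt) <= window + 1e-9
}

#' Signal-to-noise detection limits
#'
#' LOD at S/N = 3:1 and LOQ at S/N = 10:1, converted from area noise to
#' amount through the calibration slope: `LOD = 3 * noise / slope`,
#' `LOQ = 10 * noise / slope` (their ratio is exactly 10/3).
#'
#' @param noise_sd baseline noise SD in area units
#' @param curve a `calibration_curve`
#' @return the curve with `lod` and `loq` (ng/injection) filled in
#' @export
detection_limits <- function(noise_sd, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (noise_sd <= 0) stop_cap("noise_sd must be positive")
  if (curve$slope <= 0) stop_cap("slope must be positive")
  curve$lod <- 3 * noise_sd / curve$slope
  curve$loq <- 10 * noise_sd / curve$slope
  curve
}

#' Quantify one injection against the calibration line
#'
#' Inverts the line, `amount = (area - intercept) / slope`, and flags the
#' result relative to the detection limits and the calibrated range. An
#' area below the intercept would give a negative amount and is floored
#' at zero with the `below_lod` flag.
#'
#' @param area peak area (detector units)
#' @param curve a `calibration_curve`; if its `lod`/`loq` are `NA` the
#'   censoring flags fall back to `quantified`/`extrapolated` only
#' @return data frame with `amount` (ng/injection) and `flag`
#'   (`below_lod`, `between_lod_loq`, `quantified`, `extrapolated`)
#' @export
quantify_injection <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  amount <- (area - curve$intercept) / curve$slope
  flag <- rep("quantified", length(amount))
  neg <- amount < 0
  amount[neg] <- 0
  if (!is.na(curve$lod)) {
    flag[amount < curve$loq] <- "between_lod_loq"
    flag[amount < curve$lod] <- "below_lod"
  }
  flag[amount <= 0] <- "below_lod"  # zero signal is below any detection limit
  flag[amount > curve$range[2]] <- "extrapolated"
  data.frame(amount = amount, flag = flag)
}

#' Sample-preparation parameters for powder quantification
#'
#' @param sample_mass powder mass extracted (g, default 0.2)
#' @param reconstitution_volume final reconstitution volume (mL, default 2)
#' @param injection_volume injected volume (uL, default 10; instrument
#'   setting, required for per-gram conversion)
#' @return a `sample_prep` list
#' @export
sample_prep <- function(sample_mass = 0.2, reconstitution_volume = 2,
                        injection_volume = 10) {
  if (sample_mass <= 0 || reconstitution_volume <= 0 ||
      injection_volume <= 0) {
    stop_cap("sample-prep quantities must be positive")
  }
  structure(list(sample_mass = sample_mass,
                 reconstitution_volume = reconstitution_volume,
                 injection_volume = injection_volume),
            class = "sample_prep")
}

#' Convert an injected amount to a powder concentration
#'
#' `c_extract = amount / injection_volume` (ng/uL = ug/mL), scaled to the
#' full reconstitution volume and divided by the extracted powder mass:
#' `c_powder = amount * reconstitution_volume / (injection_volume *
#' sample_mass)` in ug/g.
#'
#' @param amount_ng injected amount (ng)
#' @param prep a [sample_prep]
#' @return concentration in the powder, ug/g
#' @export
powder_concentration <- function(amount_ng, prep = sample_prep()) {
  stopifnot(inherits(prep, "sample_prep"))
  # ng/uL == ug/mL; ug/mL * mL / g == ug/g
  amount_ng / prep$injection_volume * prep$reconstitution_volume /
    prep$sample_mass
}
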