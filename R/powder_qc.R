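#' Moisture content of a spray-dried powder
#'
#' Gravimetric oven-drying moisture: `MC = (m_i - m_d) / m_i * 100`.
#'
#' @param m_i initial sample mass (g)
#' @param m_d dried sample mass (g)
#' @return moisture content, percent
#' @export
moisture_content <- function(m_i, m_d) {
  if (any(m_i <= 0)) stop_cap("initial mass must be positive")
  if (any(m_d <= 0)) stop_cap("dried mass must be positive")
  if (any(m_d > m_i)) {
    stop_cap("dried mass exceeds initial mass: inconsistent assay")
  }
  (m_i - m_d) / m_i * 100
}

#' Water solubility of a powder
#'
#' A powder mass is dispersed in water, an aliquot of the supernatant is
#' dried, and the residue mass is scaled by the dispersion/aliquot ratio
#' (2.5 for the standard 25 g dispersion / 10 g aliquot):
#' `S = (m_solut - blank) * (dispersion/aliquot) / m_powder * 100`.
#' Blank correction is applied to the aliquot residue before the dilution
#' factor.
#'
#' @param m_solut dry residue mass from the aliquot (g)
#' @param m_powder powder mass added to the dispersion (g, nominal 0.100)
#' @param dispersion_mass total dispersion mass (g, default 25)
#' @param aliquot_mass analyzed aliquot mass (g, default 10)
#' @param blank_residue residue of the distilled-water blank (g)
#' @return solubility, percent; a negative blank-corrected residue is
#'   floored at zero with a warning
#' @export
solubility <- function(m_solut, m_powder = 0.100, dispersion_mass = 25,
                       aliquot_mass = 10, blank_residue = 0) {
  if (any(c(m_powder, dispersion_mass, aliquot_mass) <= 0)) {
    stop_cap("masses must be positive")
  }
  if (aliquot_mass > dispersion_mass) {
    stop_cap("aliquot cannot exceed the dispersion mass")
  }
  resid <- m_solut - blank_residue
  if (any(resid < 0)) {
    warning("blank residue exceeds sample residue; flooring at 0",
            call. = FALSE)
    resid <- pmax(resid, 0)
  }
  resid * (dispersion_mass / aliquot_mass) / m_powder * 100
}

#' Encapsulation efficiency
#'
#' Fraction of the oil load retained inside the capsules rather than
#' extractable from the powder surface:
#' `EE = (total - surface) / total * 100`.
#'
#' @param surface_oil surface (unencapsulated) oil, g/100 g powder
#' @param total_oil total oil, g/100 g powder
#' @return encapsulation efficiency, percent
#' @export
encapsulation_efficiency <- function(surface_oil, total_oil) {
  if (any(total_oil <= 0)) stop_cap("total oil must be positive")
  if (any(surface_oil < 0)) stop_cap("surface oil cannot be negative")
  if (any(surface_oil > total_oil)) {
    stop_cap("surface oil exceeds total oil: inconsistent assay")
  }
  (total_oil - surface_oil) / total_oil * 100
}

#' Bulk density
#'
#' Mass of gently poured powder per cylinder volume, `rho_b = m / V`.
#'
#' @param m powder mass (g)
#' @param V poured volume (mL)
#' @return bulk density, g/mL (multiply by 1000 for kg/m^3)
#' @export
bulk_density <- function(m, V) {
  if (any(V <= 0)) stop_cap("volume must be positive")
  if (any(m < 0)) stop_cap("mass cannot be negative")
  m / V
}

#' Tapped density with tapping-convergence check
#'
#' The cylinder is tapped until successive volume readings change by less
#' than 1%; the density uses the final settled volume. A series whose last
#' two readings still differ by 1% or more has not converged and is
#' rejected.
#'
#' @param m powder mass (g)
#' @param volume_series successive volume readings (mL), non-increasing,
#'   at least two
#' @param tol relative convergence tolerance (default 0.01)
#' @return tapped density, g/mL
#' @export
tapped_density <- function(m, volume_series, tol = 0.01) {
  if (length(volume_series) < 2) stop_cap("need at least two volume readings")
  if (any(volume_series <= 0)) stop_cap("volumes must be positive")
  if (any(diff(volume_series) > 0)) {
    stop_cap("tapping volumes must be non-increasing")
  }
  n <- length(volume_series)
  rel <- abs(volume_series[n] - volume_series[n - 1]) / volume_series[n - 1]
  if (rel >= tol) {
    stop_cap(sprintf(
      "tapping has not converged: last relative volume change %.2f%% >= %.0f%%",
      rel * 100, tol * 100))
  }
  m / volume_series[n]
}

#' Carr's Compressibility Index and Hausner Ratio
#'
#' Flowability indices from bulk and tapped density:
#' `CI = (rho_t - rho_b) / rho_t * 100` and `HR = rho_t / rho_b`.
#' Units cancel, so both densities may be g/mL or kg/m^3 as long as they
#' match. A tapped density below the bulk density is physically suspect
#' (mis-read tapping series) and warns but still returns values.
#'
#' @param rho_b bulk density
#' @param rho_t tapped density
#' @return list of class `flowability` with `rho_b`, `rho_t`, `ci`
#'   (percent), `hr`
#' @export
flowability_indices <- function(rho_b, rho_t) {
  if (any(rho_b <= 0) || any(rho_t <= 0)) {
    stop_cap("densities must be positive")
  }
  if (any(rho_t < rho_b)) {
    warning("tapped density below bulk density; indices returned as-is",
            call. = FALSE)
  }
  structure(list(rho_b = rho_b, rho_t = rho_t,
                 ci = (rho_t - rho_b) / rho_t * 100,
                 hr = rho_t / rho_b),
            class = "flowability")
}

#' Formulation recipe
#'
#' One emulsion batch: carrier oil and emulsifier masses plus any number
#' of wall-material solutions, each with its dissolved-solid fraction.
#'
#' @param oil_mass carrier oil mass (g)
#' @param emulsifier_mass emulsifier mass (g)
#' @param solutions data frame with columns `mass` (g) and
#'   `solid_fraction` (0-1), one row per wall-material solution
#' @return a `formulation_recipe` list
#' @export
formulation_recipe <- function(oil_mass, emulsifier_mass, solutions) {
  stopifnot(is.data.frame(solutions),
            all(c("mass", "solid_fraction") %in% names(solutions)))
  if (oil_mass < 0 || emulsifier_mass < 0 || any(solutions$mass < 0)) {
    stop_cap("masses cannot be negative")
  }
  if (any(solutions$solid_fraction < 0 | solutions$solid_fraction > 1)) {
    stop_cap("solid fractions must be in [0, 1]")
  }
  structure(list(oil_mass = oil_mass, emulsifier_mass = emulsifier_mass,
                 solutions = solutions),
            class = "formulation_recipe")
}

#' Feed mass balance of a formulation
#'
#' Total dry solids (wall-material solids + oil + emulsifier), total feed
#' mass (everything including solution water), the feed solids fraction,
#' and the oil mass fraction of the dry matrix (`m_oil`), which links the
#' powder analyte concentration to the lipid-core concentration.
#'
#' @param recipe a [formulation_recipe]
#' @return a `mass_balance` list: `dry_solids` (g), `total_feed_mass` (g),
#'   `feed_solids_fraction`, `m_oil`
#' @export
formulation_mass_balance <- function(recipe) {
  stopifnot(inherits(recipe, "formulation_recipe"))
  sol <- recipe$solutions
  dry <- recipe$oil_mass + recipe$emulsifier_mass +
    sum(sol$mass * sol$solid_fraction)
  total <- recipe$oil_mass + recipe$emulsifier_mass + sum(sol$mass)
  if (total <= 0) stop_cap("recipe has zero total mass")
  structure(list(dry_solids = dry,
                 total_feed_mass = total,
                 feed_solids_fraction = dry / total,
                 m_oil = if (dry > 0) recipe$oil_mass / dry else NA_real_),
            class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("<mass_balance> dry solids %.4g g of %.4g g feed (%.2f%% w/w), oil fraction of dry matrix %.4f\n",
              x$dry_solids, x$total_feed_mass,
              100 * x$feed_solids_fraction, x$m_oil))
  invisible(x)
}

#' Analyte concentration in the lipid core
#'
#' For a lipophilic analyte assumed confined to the dispersed oil phase,
#' the core concentration follows from the powder concentration and the
#' oil mass fraction of the dry matrix: `c_core = c_powder / m_oil`.
#'
#' @param c_powder analyte concentration in the powder (ug/g powder)
#' @param m_oil oil mass fraction of the dry matrix, in (0, 1]
#' @return core concentration, ug/g oil
#' @export
core_concentration <- function(c_powder, m_oil) {
  if (any(m_oil <= 0) || any(m_oil > 1)) {
    stop_cap("m_oil must be in (0, 1]")
  }
  if (any(c_powder < 0)) stop_cap("c_powder cannot be negative")
  c_powder / m_oil
}

#' Per-replicate QC table for one metric
#'
#' Applies a calculator to each replicate row and reports mean and SD per
#' formulation — the bench reporting convention (each analytical replicate
#' evaluated through the formula, then averaged), which for nonlinear
#' metrics differs from evaluating the formula at mean inputs.
#'
#' @param replicates data frame with columns `formulation`, `value` (one
#'   row per replicate, `value` already passed through the calculator), or
#'   raw columns plus `f` to apply
#' @param f optional function applied rowwise to `replicates` (receives
#'   the data frame row-split); if `NULL`, `value` is used as-is
#' @return data frame `formulation`, `mean`, `sd`, `n`
#' @export
replicate_summary <- function(replicates, f = NULL) {
  stopifnot(is.data.frame(replicates), "formulation" %in% names(replicates))
  vals <- if (is.null(f)) {
    replicates$value
  } else {
    vapply(seq_len(nrow(replicates)),
           function(i) f(replicates[i, , drop = FALSE]), numeric(1))
  }
  agg <- split(vals, replicates$formulation)
  out <- data.frame(
    formulation = names(agg),
    mean = vapply(agg, mean, numeric(1)),
    sd = vapply(agg, stats::sd, numeric(1)),
    n = vapply(agg, length, integer(1))
  )
  rownames(out) <- NULL
  out[order(match(out$formulation, unique(replicates$formulation))), ,
      drop = FALSE]
}
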