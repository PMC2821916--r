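#' Cell constants for abundance-to-molarity conversion
#'
#' Mean cell volume and molecular masses used when converting per-cell
#' protein mass (fg/cell) to molar concentration. Defaults: 80 fL mean cell
#' volume; 40 kDa for the indirect-pathway Rabex-5 truncation (residues
#' 135-480), 45 kDa for the direct-pathway truncation (1-399), 24 kDa for
#' Rab5 (canonical sequence), 51 kDa for GFP-Rab5. All overridable.
#'
#' @param volume_fl Mean cell volume (fL).
#' @param masses_kda Named numeric vector of molecular masses (kDa).
#' @return A `rab5_cell_constants` list.
#' @export
cell_constants <- function(volume_fl = 80,
                           masses_kda = c(rabex5_135_480 = 40,
                                          rabex5_1_399 = 45,
                                          rab5 = 24,
                                          gfp_rab5 = 51)) {
  if (!is.numeric(volume_fl) || length(volume_fl) != 1L || volume_fl <= 0) {
    stop("volume_fl must be a single positive number", call. = FALSE)
  }
  if (length(masses_kda) == 0 || any(masses_kda <= 0) ||
      is.null(names(masses_kda))) {
    stop("masses_kda must be a named vector of positive masses",
         call. = FALSE)
  }
  structure(list(volume_fl = volume_fl, masses_kda = masses_kda),
            class = "rab5_cell_constants")
}

#' Fit a densitometry standard curve
#'
#' Ordinary least-squares linear fit of background-corrected band intensity
#' against known protein amount (a dilution series of purified protein run on
#' the same blot). Inverse prediction (intensity to amount) is defined on the
#' fitted intensity range; extrapolation is refused by default.
#'
#' @param amounts_ng Known protein amounts (ng); at least 3 distinct positive
#'   values.
#' @param intensities Background-corrected densitometry signal (arbitrary
#'   units), same length.
#' @return A `rab5_standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, the data, and the calibrated intensity range.
#' @examples
#' sc <- fit_standard_curve(c(10, 25, 50, 100, 250), c(21, 49, 101, 199, 502))
#' intensity_to_amount(sc, 100)
#' @export
fit_standard_curve <- function(amounts_ng, intensities) {
  if (length(amounts_ng) != length(intensities)) {
    stop("amounts and intensities must have the same length", call. = FALSE)
  }
  if (length(unique(amounts_ng)) < 3L) {
    stop("calibration requires at least 3 distinct amounts", call. = FALSE)
  }
  if (any(amounts_ng <= 0)) {
    stop("calibration amounts must be strictly positive", call. = FALSE)
  }
  fit <- stats::lm(intensities ~ amounts_ng)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failed: fitted slope is not positive (",
         format(slope), ")", call. = FALSE)
  }
  tss <- sum((intensities - mean(intensities))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1,
    amounts_ng = amounts_ng,
    intensities = intensities,
    intensity_range = range(stats::fitted(fit))
  ), class = "rab5_standard_curve")
}

#' @rdname fit_standard_curve
#' @param curve A `rab5_standard_curve`.
#' @param intensity Background-corrected intensity to invert (a.u.).
#' @param allow_extrapolation Permit inverse prediction outside the
#'   calibrated intensity range.
#' @return `intensity_to_amount()` returns the inverse-predicted amount (ng).
#' @export
intensity_to_amount <- function(curve, intensity,
                                allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "rab5_standard_curve"))
  rng <- curve$intensity_range
  # zero signal reads as zero protein regardless of the fitted intercept
  out_of_range <- intensity > rng[2L] |
    (intensity < rng[1L] & intensity != 0)
  if (!allow_extrapolation && any(out_of_range)) {
    stop("intensity ", format(intensity[out_of_range][1L]),
         " is outside the calibrated range [", format(rng[1L]), ", ",
         format(rng[2L]), "]; set allow_extrapolation = TRUE to override",
         call. = FALSE)
  }
  ifelse(intensity == 0, 0,
         pmax((intensity - curve$intercept) / curve$slope, 0))
}

#' Convert a band intensity to protein mass per cell
#'
#' Inverse-predicts the loaded amount (ng) from the standard curve, converts
#' to femtograms, and corrects by the number of cells in the lysate and the
#' transfection efficiency (only the transfected fraction of cells
#' contributes the protein): `fg/cell = ng * 1e6 / (cells * efficiency)`.
#'
#' @param curve A `rab5_standard_curve`.
#' @param intensity Background-corrected band intensity (a.u.).
#' @param cells Number of cells in the lysate.
#' @param efficiency Transfection efficiency, in (0, 1]; 0.8 for BHK cells,
#'   0.2 for the Rabex-5-deficient NF73 fibroblasts.
#' @inheritParams intensity_to_amount
#' @return Protein abundance (fg/cell).
#' @export
intensity_to_fg_per_cell <- function(curve, intensity, cells, efficiency,
                                     allow_extrapolation = FALSE) {
  if (any(cells <= 0)) stop("cell count must be positive", call. = FALSE)
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop("transfection efficiency must lie in (0, 1]", call. = FALSE)
  }
  ng <- intensity_to_amount(curve, intensity, allow_extrapolation)
  ng * 1e6 / (cells * efficiency)
}

#' Convert per-cell protein mass to molar concentration (and back)
#'
#' `M = (mass * 1e-15 g) / (mw * 1e3 g/mol) / (volume * 1e-15 L)`.
#'
#' @param fg_per_cell Protein mass per cell (fg).
#' @param mw_kda Molecular mass (kDa).
#' @param volume_fl Cell volume (fL).
#' @return Concentration (M).
#' @examples
#' fg_per_cell_to_molar(32, 40, 80)  # 1e-5 M
#' @export
fg_per_cell_to_molar <- function(fg_per_cell, mw_kda, volume_fl) {
  if (any(mw_kda <= 0) || any(volume_fl <= 0)) {
    stop("molecular mass and cell volume must be positive", call. = FALSE)
  }
  if (any(fg_per_cell < 0)) {
    stop("mass per cell must be non-negative", call. = FALSE)
  }
  (fg_per_cell * 1e-15) / (mw_kda * 1e3) / (volume_fl * 1e-15)
}

#' @rdname fg_per_cell_to_molar
#' @param molar Concentration (M).
#' @export
molar_to_fg_per_cell <- function(molar, mw_kda, volume_fl) {
  if (any(mw_kda <= 0) || any(volume_fl <= 0)) {
    stop("molecular mass and cell volume must be positive", call. = FALSE)
  }
  molar * (mw_kda * 1e3) * (volume_fl * 1e-15) / 1e-15
}

#' Effective GAP-driven hydrolysis rate constant
#'
#' The intrinsic Rab5 GTP hydrolysis rate (2e-3 s^-1 at 37C) times the
#' fold-enhancement by cellular GAPs (at least two orders of magnitude),
#' giving the default beta = 0.2 s^-1. A stronger GAP scales beta up and the
#' downstream affinity estimate lambda/gamma down proportionally.
#'
#' @param intrinsic_rate Intrinsic hydrolysis rate constant (s^-1).
#' @param gap_enhancement Fold-enhancement by GAP (dimensionless).
#' @return Effective hydrolysis rate constant (s^-1).
#' @export
estimate_beta <- function(intrinsic_rate = 2e-3, gap_enhancement = 100) {
  if (intrinsic_rate <= 0 || gap_enhancement <= 0) {
    stop("both rate and enhancement must be positive", call. = FALSE)
  }
  intrinsic_rate * gap_enhancement
}

#' Affinity of the tripartite complex from the onset threshold
#'
#' Inverts the delayed-onset relation `x_threshold = lam*beta/(gamma*alpha*
#' z_tot)`: `lambda/gamma = x_threshold * z_tot / (beta/alpha)`. The result
#' is the dissociation constant (M) of the Rabex-5/Rabaptin-5/Rab5-GTP
#' complex in the cell, with the Rabaptin-5 concentration absorbed in gamma.
#'
#' @param x_threshold Total Rabex-5 concentration at onset (M).
#' @param z_tot Total Rab5 concentration (M).
#' @param beta_over_alpha Ratio of hydrolysis to exchange rate constants (M);
#'   1e-5 M from beta = 0.2 s^-1 and alpha = 2e4 M^-1 s^-1.
#' @return The affinity ratio lambda/gamma (M).
#' @examples
#' estimate_affinity_ratio(3.75e-6, 2.5e-5, 1e-5)  # ~9.4e-6, i.e. ~1e-5 M
#' @export
estimate_affinity_ratio <- function(x_threshold, z_tot,
                                    beta_over_alpha = 1e-5) {
  if (any(x_threshold < 0)) {
    stop("threshold concentration must be non-negative", call. = FALSE)
  }
  if (z_tot <= 0 || beta_over_alpha <= 0) {
    stop("z_tot and beta_over_alpha must be positive", call. = FALSE)
  }
  x_threshold * z_tot / beta_over_alpha
}

# printed-precision rounding helpers: reported cellular concentrations carry
# one significant figure; order-of-magnitude rounding is used when a value is
# quoted as a power of ten.
round_one_sig <- function(x) signif(x, 1)
order_of_magnitude <- function(x) 10^round(log10(x))
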