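#' Kinetic parameters of the Rab5 activation model
#'
#' Container for the rate constants and total concentrations of the
#' two-pathway Rab5 activation model. Internally the package works in molar
#' (M) and seconds throughout; femtograms per cell and hours appear only at
#' the quantification / data boundary.
#'
#' @param alpha GEF catalytic rate constant per unit Rabex-5 concentration
#'   (M^-1 s^-1).
#' @param beta Effective GAP-driven GTP hydrolysis rate constant (s^-1); the
#'   GAP concentration is absorbed into this first-order constant.
#' @param gamma Formation rate constant of the Rabex-5/Rabaptin-5/Rab5-GTP
#'   tripartite complex (M^-1 s^-1); the cytosolic Rabaptin-5 concentration is
#'   absorbed into it. `gamma = 0` disables the indirect pathway.
#' @param lam Dissociation rate constant of the tripartite complex (s^-1).
#' @param sigma Dimensionless equilibrium constant of direct membrane
#'   targeting. `sigma = 0` disables the direct pathway.
#' @param z_tot Total Rab5 concentration (M). Must be positive for any
#'   steady-state analysis.
#' @param x_tot Total Rabex-5 concentration (M).
#'
#' @return An object of class `rab5_params` (a named list with the seven
#'   fields above).
#' @examples
#' # Reference constants used for the model's illustration curves
#' p <- kinetic_params(alpha = 1, beta = 1, gamma = 1, lam = 100,
#'                     sigma = 0.1, z_tot = 10, x_tot = 20)
#' @export
kinetic_params <- function(alpha, beta, gamma, lam, sigma, z_tot, x_tot = 0) {
  vals <- list(alpha = alpha, beta = beta, gamma = gamma, lam = lam,
               sigma = sigma, z_tot = z_tot, x_tot = x_tot)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) {
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
    }
  }
  structure(vals, class = "rab5_params")
}

#' @export
print.rab5_params <- function(x, ...) {
  cat("Rab5 activation model parameters\n")
  cat(sprintf("  alpha = %g M^-1 s^-1 (GEF catalysis)\n", x$alpha))
  cat(sprintf("  beta  = %g s^-1     (GAP hydrolysis)\n", x$beta))
  cat(sprintf("  gamma = %g M^-1 s^-1 (complex formation)\n", x$gamma))
  cat(sprintf("  lam   = %g s^-1     (complex dissociation)\n", x$lam))
  cat(sprintf("  sigma = %g           (direct-targeting equilibrium)\n",
              x$sigma))
  cat(sprintf("  z_tot = %g M (total Rab5), x_tot = %g M (total Rabex-5)\n",
              x$z_tot, x$x_tot))
  invisible(x)
}

as_rab5_params <- function(x) {
  if (inherits(x, "rab5_params")) return(x)
  if (is.list(x)) {
    need <- c("alpha", "beta", "gamma", "lam", "sigma", "z_tot")
    if (all(need %in% names(x))) {
      return(kinetic_params(x$alpha, x$beta, x$gamma, x$lam, x$sigma,
                            x$z_tot, if (is.null(x$x_tot)) 0 else x$x_tot))
    }
  }
  stop("cannot interpret object as kinetic parameters; expected fields ",
       "alpha, beta, gamma, lam, sigma, z_tot[, x_tot]", call. = FALSE)
}

set_x_tot <- function(params, x_tot) {
  params$x_tot <- x_tot
  params
}

#' Read and write parameter sets as JSON
#'
#' Parameter sets are serialized with the exact keys `alpha`, `beta`, `gamma`,
#' `lam`, `sigma`, `z_tot`, `x_tot`, in SI units (M, s).
#'
#' @param params A [kinetic_params()] object.
#' @param path File path.
#' @return `read_params()` returns a `rab5_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  params <- as_rab5_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  as_rab5_params(jsonlite::fromJSON(path))
}
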