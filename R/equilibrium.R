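#' Steady-state Rab5-GTP via the direct pathway only
#'
#' With the indirect pathway absent (`x2 = 0`), the steady state is the
#' Michaelis-Menten-like hyperbola
#' `z = alpha * x1 * z_tot / (alpha * x1 + beta)` with
#' `x1 = sigma * x_tot / (1 + sigma)`. With `sigma = 0` no enzyme reaches the
#' membrane and the function returns 0 (documented behaviour, not an error).
#'
#' @param params A [kinetic_params()] object (its `x_tot` is used).
#' @return Steady-state Rab5-GTP concentration (M).
#' @export
steady_state_direct_only <- function(params) {
  params <- as_rab5_params(params)
  x1 <- params$sigma * params$x_tot / (1 + params$sigma)
  num <- params$alpha * x1
  if (num == 0) return(0)
  num * params$z_tot / (num + params$beta)
}

#' Midpoint of the direct-pathway response curve
#'
#' The total Rabex-5 concentration at which the direct-only steady state
#' reaches half of `z_tot`: `beta * (1 + sigma) / (alpha * sigma)`.
#'
#' @inheritParams steady_state_direct_only
#' @return Midpoint concentration (M).
#' @export
midpoint_direct <- function(params) {
  params <- as_rab5_params(params)
  if (params$sigma <= 0) {
    stop("midpoint of the direct-pathway response is undefined for sigma = 0",
         call. = FALSE)
  }
  if (params$alpha <= 0) {
    stop("midpoint undefined for alpha = 0", call. = FALSE)
  }
  params$beta * (1 + params$sigma) / (params$alpha * params$sigma)
}

#' Steady-state Rab5-GTP via the indirect (positive-feedback) pathway only
#'
#' With `sigma = 0` the nonzero steady-state branch is
#' `z = (gamma*alpha*x_tot*z_tot - lam*beta) / (gamma*(alpha*x_tot + beta))`.
#' Below the onset threshold this branch is negative (unphysical) and the
#' stable state is `z = 0`, so the returned value is clamped to the stable
#' branch (see [find_steady_states()] for the full root structure).
#'
#' @inheritParams steady_state_direct_only
#' @return Steady-state Rab5-GTP concentration (M).
#' @export
steady_state_indirect_only <- function(params) {
  params <- as_rab5_params(params)
  denom <- params$gamma * (params$alpha * params$x_tot + params$beta)
  if (denom == 0) return(0)
  z <- (params$gamma * params$alpha * params$x_tot * params$z_tot -
          params$lam * params$beta) / denom
  min(max(z, 0), params$z_tot)
}

#' Delayed-onset threshold of the positive feedback loop
#'
#' The total Rabex-5 concentration below which the indirect-only steady state
#' is exactly zero: `lam * beta / (gamma * alpha * z_tot)`. Inversely
#' proportional to total Rab5, so doubling `z_tot` halves the threshold.
#'
#' @inheritParams steady_state_direct_only
#' @return Threshold Rabex-5 concentration (M).
#' @export
onset_threshold <- function(params) {
  params <- as_rab5_params(params)
  if (params$z_tot <= 0) {
    stop("onset threshold undefined for z_tot = 0", call. = FALSE)
  }
  if (params$gamma <= 0 || params$alpha <= 0) {
    stop("onset threshold requires positive gamma and alpha", call. = FALSE)
  }
  params$lam * params$beta / (params$gamma * params$alpha * params$z_tot)
}

# Coefficients of the steady-state quadratic A z^2 + B z + C = 0, obtained by
# eliminating x2 = gamma * x_tot * z / (lam*(1+sigma) + gamma*z) from dz/dt=0.
steady_state_poly <- function(params) {
  with(params, c(
    A = -gamma * (alpha * x_tot + beta),
    B = alpha * x_tot * (gamma * z_tot - sigma * lam) -
      beta * lam * (1 + sigma),
    C = alpha * x_tot * sigma * lam * z_tot
  ))
}

# All real roots of the steady-state polynomial in z (degenerates handled).
steady_state_roots <- function(params) {
  co <- steady_state_poly(params)
  a <- co[["A"]]; b <- co[["B"]]; cc <- co[["C"]]
  if (a == 0) {
    if (b == 0) return(0)          # fully degenerate: origin only
    return(-cc / b)                # linear case (gamma = 0)
  }
  disc <- b * b - 4 * a * cc
  if (disc < 0) stop("steady-state quadratic has no real root; ",
                     "internal inconsistency", call. = FALSE)
  # numerically stable quadratic formula
  q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
  roots <- c(q / a, if (q != 0) cc / q else 0)
  sort(unique(roots))
}

#' Steady-state Rab5-GTP with both pathways active
#'
#' Returns the stable non-negative root of the full steady-state system
#' (both time derivatives zero). Reduces to [steady_state_direct_only()] when
#' `gamma = 0` and to [steady_state_indirect_only()] when `sigma = 0`;
#' continuous and non-decreasing in `x_tot`.
#'
#' @inheritParams steady_state_direct_only
#' @return Steady-state Rab5-GTP concentration (M).
#' @export
steady_state_general <- function(params) {
  params <- as_rab5_params(params)
  if (params$x_tot == 0) return(0)
  if (params$gamma == 0) return(steady_state_direct_only(params))
  roots <- steady_state_roots(params)
  phys <- roots[roots >= 0 & roots <= params$z_tot * (1 + 1e-12)]
  if (length(phys) == 0L) {
    stop("no non-negative steady-state root found; internal inconsistency",
         call. = FALSE)
  }
  # the largest physical root is the stable one (origin loses stability
  # exactly when a positive root appears; transcritical exchange)
  min(max(phys), params$z_tot)
}

#' Steady-state response curve of Rab5 activation vs total Rabex-5
#'
#' Element-wise application of the selected steady-state solution over a grid
#' of total Rabex-5 concentrations.
#'
#' @param params A [kinetic_params()] object (its `x_tot` field is ignored;
#'   the grid supplies it).
#' @param x_grid Increasing, non-negative vector of total Rabex-5
#'   concentrations (M).
#' @param mode One of `"direct_only"`, `"indirect_only"`, `"combined"`.
#' @return A `rab5_response_curve`: data frame with columns `x_tot_M`, `z_M`,
#'   with `mode` and `params` attached as attributes.
#' @examples
#' p <- kinetic_params(1, 1, 1, 100, 0.1, z_tot = 10)
#' rc <- response_curve(p, 10^seq(-2, 4, length.out = 200), "indirect_only")
#' hill_coefficient(rc)
#' @export
response_curve <- function(params, x_grid,
                           mode = c("direct_only", "indirect_only",
                                    "combined")) {
  params <- as_rab5_params(params)
  mode <- match.arg(mode)
  if (length(x_grid) > 0) {
    if (any(!is.finite(x_grid)) || any(x_grid < 0) ||
        any(diff(x_grid) <= 0)) {
      stop("x_grid must be increasing and non-negative", call. = FALSE)
    }
  }
  fn <- switch(mode,
               direct_only = steady_state_direct_only,
               indirect_only = steady_state_indirect_only,
               combined = steady_state_general)
  z <- vapply(x_grid, function(x) fn(set_x_tot(params, x)), numeric(1))
  curve <- data.frame(x_tot_M = as.numeric(x_grid), z_M = z)
  attr(curve, "mode") <- mode
  attr(curve, "params") <- params
  class(curve) <- c("rab5_response_curve", "data.frame")
  curve
}

# Interpolate the x at which the curve crosses level, linearly in log(x).
interp_crossing <- function(curve, level) {
  x <- curve$x_tot_M; z <- curve$z_M
  keep <- x > 0
  x <- x[keep]; z <- z[keep]
  above <- which(z >= level)
  if (length(above) == 0L || above[1L] == 1L) return(NA_real_)
  i <- above[1L]
  lx <- log(x[i - 1L]) + (level - z[i - 1L]) / (z[i] - z[i - 1L]) *
    (log(x[i]) - log(x[i - 1L]))
  exp(lx)
}

#' Generalized Hill coefficient of a response curve (10-90% rule)
#'
#' `n_H = ln(81) / ln(x90 / x10)`, where `x10` and `x90` are the total
#' Rabex-5 concentrations at which the steady-state Rab5-GTP reaches 10% and
#' 90% of `z_tot`, interpolated linearly in `log(x)` (response curves span
#' decades). For the direct-pathway hyperbola this is exactly 1; for the
#' indirect pathway it lies in (1, 2] and tends to 2 as
#' `lam/gamma >> z_tot`.
#'
#' @param curve A `rab5_response_curve` from [response_curve()]; it must
#'   bracket both the 10% and 90% levels of `z_tot`.
#' @return The Hill coefficient (dimensionless).
#' @export
hill_coefficient <- function(curve) {
  stopifnot(inherits(curve, "rab5_response_curve"))
  z_tot <- attr(curve, "params")$z_tot
  x10 <- interp_crossing(curve, 0.1 * z_tot)
  x90 <- interp_crossing(curve, 0.9 * z_tot)
  if (is.na(x10) || is.na(x90)) {
    stop("response curve does not bracket the 10% and 90% activation ",
         "levels; widen the x_tot grid", call. = FALSE)
  }
  log(81) / log(x90 / x10)
}

#' Normalized-slope sensitivity of a response curve
#'
#' Secondary sensitivity diagnostic: the slope of `z/z_tot` with respect to
#' `log(x_tot)` evaluated at the midpoint (`z = z_tot/2`), times 4 — i.e.
#' the slope normalized by the location of the midpoint. For an exact Hill
#' function this equals the Hill exponent. Delayed-onset curves are steepest
#' at the threshold rather than at the midpoint, so this midpoint measure
#' and [hill_coefficient()] (the 10-90% rule, the package's primary measure)
#' need not coincide.
#'
#' @inheritParams hill_coefficient
#' @return Dimensionless sensitivity.
#' @export
normalized_slope <- function(curve) {
  stopifnot(inherits(curve, "rab5_response_curve"))
  z_tot <- attr(curve, "params")$z_tot
  keep <- curve$x_tot_M > 0
  x <- curve$x_tot_M[keep]; z <- curve$z_M[keep] / z_tot
  if (length(x) < 3L) stop("curve too short", call. = FALSE)
  i <- which(z >= 0.5)
  if (length(i) == 0L || i[1L] <= 1L) {
    stop("curve does not bracket the midpoint; widen the x_tot grid",
         call. = FALSE)
  }
  i <- i[1L]
  4 * (z[i] - z[i - 1L]) / (log(x[i]) - log(x[i - 1L]))
}

#' Write a response curve as CSV plus a JSON sidecar
#'
#' The CSV has columns `x_tot_M,z_M`; the sidecar (same path with extension
#' `.json`) records the mode, parameters, onset threshold and midpoint (where
#' defined) and the Hill coefficient (where the grid brackets 10-90%).
#'
#' @param curve A `rab5_response_curve`.
#' @param path CSV output path.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rab5_response_curve"))
  utils::write.csv(as.data.frame(curve)[c("x_tot_M", "z_M")], path,
                   row.names = FALSE, quote = FALSE)
  params <- attr(curve, "params")
  side <- list(
    mode = attr(curve, "mode"),
    params = unclass(params),
    threshold_M = if (params$gamma > 0 && params$alpha > 0 &&
                      params$z_tot > 0) onset_threshold(params) else NULL,
    midpoint_M = if (params$sigma > 0 && params$alpha > 0)
      midpoint_direct(params) else NULL,
    hill_coefficient = tryCatch(hill_coefficient(curve),
                                error = function(e) NULL)
  )
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
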