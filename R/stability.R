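#' Jacobian of the two-variable system at a state
#'
#' Analytic 2x2 Jacobian of [time_derivatives()] with respect to `(z, x2)`.
#'
#' @param params A [kinetic_params()] object.
#' @param state Named numeric vector `c(z = , x2 = )`.
#' @return 2x2 numeric matrix.
#' @export
jacobian_at <- function(params, state) {
  params <- as_rab5_params(params)
  z <- state[["z"]]; x2 <- state[["x2"]]
  s1 <- 1 + params$sigma
  x0 <- (params$x_tot - x2) / s1
  x1 <- params$sigma * x0
  matrix(c(
    -params$alpha * (x1 + x2) - params$beta,       # d f / d z
    params$gamma * x0,                             # d g / d z
    params$alpha * (params$z_tot - z) / s1,        # d f / d x2
    -params$gamma * z / s1 - params$lam            # d g / d x2
  ), nrow = 2L)
}

#' Classify the stability of a steady state
#'
#' Classification by the sign of the maximal real part of the Jacobian
#' eigenvalues: negative = `"stable"`, positive = `"unstable"`, and
#' `"marginal"` when the magnitude is below `marginal_tol` times a
#' characteristic rate (the GAP rate `beta`, falling back to the fastest rate
#' in the set when `beta = 0`) — the signature of the transcritical exchange
#' point.
#'
#' @param params A [kinetic_params()] object.
#' @param state Named vector `c(z = , x2 = )`; must be a steady state (the
#'   residual of [time_derivatives()] is checked).
#' @param marginal_tol Relative tolerance for a zero leading eigenvalue.
#' @param residual_tol Relative tolerance for accepting `state` as a root.
#' @return One of `"stable"`, `"unstable"`, `"marginal"`.
#' @export
classify_stability <- function(params, state, marginal_tol = 1e-9,
                               residual_tol = 1e-6) {
  params <- as_rab5_params(params)
  rate0 <- max(params$beta, params$lam, params$alpha * params$z_tot,
               params$gamma * params$z_tot, .Machine$double.xmin)
  d <- rab5_rhs(0, c(state[["z"]], state[["x2"]]), params)[[1L]]
  scale <- rate0 * max(abs(params$z_tot), abs(params$x_tot),
                       abs(state[["z"]]), abs(state[["x2"]]), 1e-300)
  if (max(abs(d)) > residual_tol * scale) {
    stop("state is not a steady state: residual (", format(d[1L]), ", ",
         format(d[2L]), ") exceeds tolerance", call. = FALSE)
  }
  ev <- eigen(jacobian_at(params, state), only.values = TRUE)$values
  m <- max(Re(ev))
  char_rate <- if (params$beta > 0) params$beta else rate0
  if (abs(m) < marginal_tol * char_rate) return("marginal")
  if (m < 0) "stable" else "unstable"
}

#' Enumerate all steady states of the system
#'
#' Solves the steady-state polynomial in `z` (a quadratic after eliminating
#' the complex variable through its own steady-state relation), reconstructs
#' `x2` for each root, flags unphysical (negative or out-of-range) roots, and
#' classifies stability of physical roots via the Jacobian. For `sigma = 0`
#' the origin is always a root; the companion root is negative exactly when
#' `x_tot` is below the onset threshold.
#'
#' @param params A [kinetic_params()] object.
#' @return A `rab5_steady_states` object: data frame with columns `z_M`,
#'   `x2_M`, `physical`, `stability` (`NA` for unphysical roots), plus
#'   attribute `"params"`.
#' @export
find_steady_states <- function(params) {
  params <- as_rab5_params(params)
  z_roots <- steady_state_roots(params)
  x2_of_z <- function(z) {
    den <- params$lam * (1 + params$sigma) + params$gamma * z
    if (den == 0) 0 else params$gamma * params$x_tot * z / den
  }
  x2 <- vapply(z_roots, x2_of_z, numeric(1))
  physical <- z_roots >= -1e-15 & z_roots <= params$z_tot * (1 + 1e-12) &
    x2 >= -1e-15 & x2 <= params$x_tot * (1 + 1e-12)
  stability <- rep(NA_character_, length(z_roots))
  for (i in seq_along(z_roots)) {
    if (physical[i]) {
      stability[i] <- classify_stability(
        params, c(z = max(z_roots[i], 0), x2 = max(x2[i], 0)))
    }
  }
  out <- data.frame(z_M = z_roots, x2_M = x2, physical = physical,
                    stability = stability)
  attr(out, "params") <- params
  class(out) <- c("rab5_steady_states", "data.frame")
  out
}

# Value of the nonzero (companion) steady-state branch at a given x_tot;
# its sign change locates the transcritical crossing for sigma = 0.
companion_branch_value <- function(params, x_tot) {
  p <- set_x_tot(params, x_tot)
  roots <- steady_state_roots(p)
  roots <- roots[abs(roots) > 0 | length(roots) == 1L]
  nz <- roots[which.max(abs(roots))]
  nz
}

#' Scan total Rabex-5 for branch structure and bifurcations
#'
#' Tracks all steady-state roots (with stability) over a grid of total
#' Rabex-5 concentrations. For `sigma = 0` the zero branch and the companion
#' branch cross and exchange stability at the onset threshold — a
#' transcritical bifurcation — which is located by bisection to relative
#' precision `crossing_rtol`. A saddle-node (fold), the signature of
#' bistability, would appear as a sign change of `dz/dx_tot` along the stable
#' branch; its absence is asserted and reported.
#'
#' @param params A [kinetic_params()] object (`x_tot` supplied by the grid).
#' @param x_range Length-2 positive numeric: scan limits (M).
#' @param n_points Number of grid points (>= 10).
#' @param log_spacing Logical; space the grid logarithmically (default) or
#'   linearly.
#' @param crossing_rtol Relative bisection precision for the transcritical
#'   point.
#' @return A `rab5_bifurcation` object: list with `diagram` (data frame
#'   `x_tot_M`, `branch`, `z_M`, `physical`, `stability`), `crossing`
#'   (transcritical point, M, or `NA`), `bistable` (logical), `n_folds`
#'   (saddle-node count along the stable branch), and `params`.
#' @export
bifurcation_scan <- function(params, x_range, n_points = 50L,
                             log_spacing = TRUE, crossing_rtol = 1e-6) {
  params <- as_rab5_params(params)
  if (length(x_range) != 2L || any(x_range <= 0) || diff(x_range) <= 0) {
    stop("x_range must be two increasing positive values", call. = FALSE)
  }
  if (n_points < 10L) stop("n_points must be >= 10", call. = FALSE)
  grid <- if (log_spacing) {
    exp(seq(log(x_range[1L]), log(x_range[2L]), length.out = n_points))
  } else {
    seq(x_range[1L], x_range[2L], length.out = n_points)
  }
  rows <- vector("list", n_points)
  n_stable_physical <- integer(n_points)
  for (i in seq_len(n_points)) {
    ss <- find_steady_states(set_x_tot(params, grid[i]))
    ord <- order(ss$z_M)
    rows[[i]] <- data.frame(x_tot_M = grid[i], branch = seq_along(ord),
                            z_M = ss$z_M[ord], physical = ss$physical[ord],
                            stability = ss$stability[ord])
    n_stable_physical[i] <-
      sum(ss$physical & !is.na(ss$stability) & ss$stability == "stable")
  }
  diagram <- do.call(rbind, rows)
  if (any(n_stable_physical > 1L)) {
    stop("more than one stable physical steady state detected at x_tot = ",
         grid[which(n_stable_physical > 1L)[1L]],
         "; this contradicts the model's transcritical structure",
         call. = FALSE)
  }

  # transcritical crossing (sigma = 0): companion branch changes sign
  crossing <- NA_real_
  if (params$sigma == 0 && params$gamma > 0) {
    f <- function(x) companion_branch_value(params, x)
    flo <- f(grid[1L]); fhi <- f(grid[n_points])
    if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0) {
      lo <- grid[1L]; hi <- grid[n_points]
      while ((hi - lo) / hi > crossing_rtol) {
        mid <- sqrt(lo * hi)
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      crossing <- sqrt(lo * hi)
    }
  }

  # fold detection along the stable branch
  z_stable <- vapply(grid,
                     function(x) steady_state_general(set_x_tot(params, x)),
                     numeric(1))
  dz <- diff(z_stable)
  n_folds <- sum(dz[-1L] * dz[-length(dz)] < 0 & abs(dz[-1L]) >
                   1e-12 * params$z_tot)
  structure(list(diagram = diagram, crossing = crossing,
                 bistable = any(n_stable_physical > 1L),
                 n_folds = n_folds, params = params),
            class = "rab5_bifurcation")
}

#' @export
print.rab5_bifurcation <- function(x, ...) {
  cat("Rab5 activation bifurcation scan\n")
  cat(sprintf("  grid: %d points over [%g, %g] M\n",
              length(unique(x$diagram$x_tot_M)), min(x$diagram$x_tot_M),
              max(x$diagram$x_tot_M)))
  if (is.na(x$crossing)) {
    cat("  no transcritical crossing in range (single stable branch)\n")
  } else {
    cat(sprintf("  transcritical crossing at x_tot = %g M\n", x$crossing))
  }
  cat(sprintf("  bistable: %s; saddle-node folds: %d\n", x$bistable,
              x$n_folds))
  invisible(x)
}

#' Write a bifurcation diagram as CSV plus a JSON summary
#'
#' CSV columns `x_tot_M,branch,z_M,stability`; the JSON summary records the
#' crossing location and the bistability flag.
#'
#' @param scan A `rab5_bifurcation` from [bifurcation_scan()].
#' @param path CSV output path.
#' @export
write_bifurcation <- function(scan, path) {
  stopifnot(inherits(scan, "rab5_bifurcation"))
  utils::write.csv(scan$diagram[c("x_tot_M", "branch", "z_M", "stability")],
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(crossing_M = if (is.na(scan$crossing)) NULL else scan$crossing,
         bistable = scan$bistable, n_folds = scan$n_folds,
         params = unclass(scan$params)),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}
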