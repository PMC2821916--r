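#' Partition total Rabex-5 into cytosolic, membrane-bound and complexed pools
#'
#' Under rapid equilibrium of direct membrane targeting, the directly
#' membrane-bound pool is `x1 = sigma * x0`, so the conservation law
#' `x0 + x1 + x2 = x_tot` gives `x0 = (x_tot - x2) / (1 + sigma)`.
#'
#' @param params A [kinetic_params()] object.
#' @param x2 Tripartite-complex concentration (M); must lie in
#'   `[0, params$x_tot]`.
#' @return Named numeric vector `c(x0 = , x1 = )`: cytosolic and directly
#'   membrane-bound Rabex-5 (M).
#' @export
partition_enzyme <- function(params, x2) {
  params <- as_rab5_params(params)
  if (!is.numeric(x2) || length(x2) != 1L || !is.finite(x2)) {
    stop("x2 must be a single finite number", call. = FALSE)
  }
  if (x2 < 0) {
    stop("complex concentration x2 = ", x2, " is negative", call. = FALSE)
  }
  if (x2 > params$x_tot) {
    stop("complex concentration x2 = ", x2,
         " exceeds total Rabex-5 x_tot = ", params$x_tot, call. = FALSE)
  }
  x0 <- (params$x_tot - x2) / (1 + params$sigma)
  c(x0 = x0, x1 = params$sigma * x0)
}

#' Time derivatives of the two-variable Rab5 activation system
#'
#' The dynamical variables are `z` (Rab5-GTP, M) and `x2` (tripartite
#' complex, M); the enzyme pools `x0`, `x1` are algebraic via
#' [partition_enzyme()]. The kinetics are
#' `dz/dt = alpha * (x1 + x2) * (z_tot - z) - beta * z` and
#' `dx2/dt = gamma * x0 * z - lam * x2`.
#'
#' @param params A [kinetic_params()] object.
#' @param state Named numeric vector `c(z = , x2 = )` (M).
#' @return Named numeric vector `c(dz_dt = , dx2_dt = )` (M/s).
#' @export
time_derivatives <- function(params, state) {
  params <- as_rab5_params(params)
  z <- state[["z"]]
  x2 <- state[["x2"]]
  pools <- partition_enzyme(params, x2)
  dz <- params$alpha * (pools[["x1"]] + x2) * (params$z_tot - z) -
    params$beta * z
  dx2 <- params$gamma * pools[["x0"]] * z - params$lam * x2
  c(dz_dt = dz, dx2_dt = dx2)
}

# RHS in the calling convention of deSolve (no input validation: hot path).
rab5_rhs <- function(t, y, parms) {
  x0 <- (parms$x_tot - y[2L]) / (1 + parms$sigma)
  dz <- parms$alpha * (parms$sigma * x0 + y[2L]) * (parms$z_tot - y[1L]) -
    parms$beta * y[1L]
  dx2 <- parms$gamma * x0 * y[1L] - parms$lam * y[2L]
  list(c(dz, dx2))
}

#' Simulate the Rab5 activation kinetics
#'
#' Integrates the two-variable system with a stiff-capable solver
#' (`deSolve::ode`, method `lsoda`). The complex dissociation rate `lam` can
#' exceed the other rates by orders of magnitude, hence the stiff solver and
#' tight default tolerances. Negative excursions smaller than `10 * atol` are
#' clamped to zero; larger ones raise an integration-failure error.
#'
#' @param params A [kinetic_params()] object.
#' @param init Named numeric vector `c(z = , x2 = )`; default `c(0, 0)`,
#'   mirroring a suppressed (pre-induction) start.
#' @param times Strictly increasing numeric vector of output times (s).
#' @param rtol,atol Relative and absolute solver tolerances (atol in M).
#' @return A `rab5_trajectory`: a data frame with columns `time_s`, `z_M`,
#'   `x2_M`, `x0_M`, `x1_M` and the parameters attached as attribute
#'   `"params"`.
#' @examples
#' p <- kinetic_params(1, 1, 1, 100, 0.1, z_tot = 1, x_tot = 50)
#' tr <- simulate_activation(p, times = seq(0, 50, by = 0.5))
#' tail(tr, 2)
#' @export
simulate_activation <- function(params, init = c(z = 0, x2 = 0), times,
                                rtol = 1e-8, atol = 1e-12) {
  params <- as_rab5_params(params)
  if (!is.numeric(times) || length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be a strictly increasing numeric vector of length >= 2",
         call. = FALSE)
  }
  z0 <- init[["z"]]; x20 <- init[["x2"]]
  if (z0 < 0 || z0 > params$z_tot || x20 < 0 || x20 > params$x_tot) {
    stop("initial state out of bounds: need 0 <= z <= z_tot and ",
         "0 <= x2 <= x_tot", call. = FALSE)
  }
  out <- deSolve::ode(y = c(z0, x20), times = times, func = rab5_rhs,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  di <- deSolve::diagnostics(out)
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1L],
         "); solver diagnostics: ", paste(di$message, collapse = " "),
         call. = FALSE)
  }
  z <- out[, 2L]; x2 <- out[, 3L]
  clamp <- function(v, lo, hi, what) {
    slack <- 10 * atol + rtol * max(hi, 1e-300)
    if (any(v < lo - slack) || any(v > hi + slack)) {
      stop("trajectory violates bounds for ", what,
           " beyond solver tolerance (max excursion ",
           format(max(pmax(lo - v, v - hi))), ")", call. = FALSE)
    }
    pmin(pmax(v, lo), hi)
  }
  z <- clamp(z, 0, params$z_tot, "z")
  x2 <- clamp(x2, 0, params$x_tot, "x2")
  x0 <- (params$x_tot - x2) / (1 + params$sigma)
  traj <- data.frame(time_s = out[, 1L], z_M = z, x2_M = x2,
                     x0_M = x0, x1_M = params$sigma * x0)
  attr(traj, "params") <- params
  class(traj) <- c("rab5_trajectory", "data.frame")
  traj
}

#' Integrate to steady state
#'
#' Runs the kinetics over successively doubled horizons until both time
#' derivatives are below `tol` times a characteristic rate scale, returning
#' the final state. Used as the dynamic (independent) route to the steady
#' state; the closed forms live in [steady_state_general()].
#'
#' @inheritParams simulate_activation
#' @param tol Convergence tolerance on the scaled derivatives.
#' @param t0 Initial horizon (s); defaults to ten times the slowest
#'   characteristic time of the parameter set.
#' @param max_doublings Give up (with an error) after this many doublings.
#' @return Named vector `c(z = , x2 = )` at convergence.
#' @export
simulate_to_steady <- function(params, init = c(z = 0, x2 = 0), tol = 1e-10,
                               t0 = NULL, max_doublings = 40L,
                               rtol = 1e-10, atol = 1e-14) {
  params <- as_rab5_params(params)
  rates <- c(params$beta, params$lam, params$alpha * params$z_tot,
             params$gamma * params$z_tot, params$alpha * params$x_tot)
  rates <- rates[rates > 0]
  if (length(rates) == 0L) return(c(z = init[["z"]], x2 = init[["x2"]]))
  if (is.null(t0)) t0 <- 10 / min(rates)
  scale_z <- max(params$z_tot, 1e-300)
  scale_x <- max(params$x_tot, 1e-300)
  state <- c(z = init[["z"]], x2 = init[["x2"]])
  horizon <- t0
  for (i in seq_len(max_doublings)) {
    out <- deSolve::ode(y = unname(state), times = c(0, horizon),
                        func = rab5_rhs, parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    state <- c(z = min(max(out[2L, 2L], 0), params$z_tot),
               x2 = min(max(out[2L, 3L], 0), params$x_tot))
    d <- time_derivatives(params, state)
    r0 <- max(rates)
    if (abs(d[["dz_dt"]]) <= tol * r0 * scale_z &&
        abs(d[["dx2_dt"]]) <= tol * r0 * max(scale_x, scale_z)) {
      return(state)
    }
    horizon <- horizon * 2
  }
  stop("steady-state integration did not converge after ", max_doublings,
       " horizon doublings (final derivatives ",
       paste(format(time_derivatives(params, state)), collapse = ", "), ")",
       call. = FALSE)
}

#' Write a trajectory as CSV
#'
#' Columns `time_s,z_M,x2_M,x0_M,x1_M`.
#'
#' @param traj A `rab5_trajectory` from [simulate_activation()].
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rab5_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
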