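# Independent oracles and fixture builders used across the test files.

# Random kinetic parameter sets, log-uniform over 10^-2 .. 10^2 per the
# model-structure property checks.
random_params <- function(n, sigma = NULL, gamma = NULL) {
  draw <- function() 10^stats::runif(1, -2, 2)
  lapply(seq_len(n), function(i) {
    kinetic_params(
      alpha = draw(), beta = draw(),
      gamma = if (is.null(gamma)) draw() else gamma,
      lam = draw(),
      sigma = if (is.null(sigma)) draw() else sigma,
      z_tot = draw(), x_tot = draw())
  })
}

# Brute-force steady-state finder, independent of the package's quadratic
# closed form: eliminates the complex variable through its own equilibrium
# and scans/bisects the remaining scalar equation in z.
brute_force_steady_z <- function(params, n_scan = 4000) {
  with(params, {
    h <- function(z) {
      e <- if (lam * (1 + sigma) + gamma * z > 0) {
        x_tot * (sigma * lam + gamma * z) / (lam * (1 + sigma) + gamma * z)
      } else {
        x_tot
      }
      alpha * e * (z_tot - z) - beta * z
    }
    zg <- seq(0, z_tot, length.out = n_scan)
    hv <- vapply(zg, h, numeric(1))
    roots <- c()
    if (abs(hv[1]) < 1e-300) roots <- c(roots, 0)
    for (i in seq_len(n_scan - 1)) {
      if (hv[i] == 0) roots <- c(roots, zg[i])
      if (hv[i] * hv[i + 1] < 0) {
        roots <- c(roots, stats::uniroot(h, c(zg[i], zg[i + 1]),
                                         tol = 1e-14)$root)
      }
    }
    if (length(roots) == 0) 0 else max(roots)
  })
}

# Analytic 10-90% Hill coefficient of the indirect-only branch, from
# inverting its closed form: x(z) = beta*(lam + gamma*z)/(alpha*gamma*
# (z_tot - z)); the x90/x10 ratio reduces to
# 9*(lam/gamma + 0.9*z_tot)/(lam/gamma + 0.1*z_tot).
analytic_hill_indirect <- function(lam_over_gamma, z_tot) {
  log(81) / log(9 * (lam_over_gamma + 0.9 * z_tot) /
                  (lam_over_gamma + 0.1 * z_tot))
}

# Convenience: steady state by long-time ODE integration from a small
# positive seed (the origin is invariant for sigma = 0, so a perturbed start
# is needed to find the attracting branch).
ode_steady_z <- function(params) {
  init <- c(z = min(1e-3 * params$z_tot, params$z_tot),
            x2 = 0)
  simulate_to_steady(params, init = init, tol = 1e-11)[["z"]]
}

fig2_params <- function(sigma = 0.1, z_tot = 10, x_tot = 0) {
  kinetic_params(alpha = 1, beta = 1, gamma = 1, lam = 100, sigma = sigma,
                 z_tot = z_tot, x_tot = x_tot)
}
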