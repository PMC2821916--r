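#' Tet-Off induction profile
#'
#' Saturating-exponential rise of enzyme abundance after doxycycline removal:
#' `x(t) = baseline + (plateau - baseline) * (1 - 2^(-t / half_time))`. The
#' leaky pre-induction baseline is about one tenth of the plateau (an
#' order-of-magnitude induction), and the plateau is reached (>= 95%) at
#' about 7 h in BHK-like cells and about 12 h in the Rabex-5-deficient
#' NF73-like fibroblasts.
#'
#' @param baseline Leaky pre-induction enzyme level (fg/cell); `0 <= baseline
#'   < plateau`.
#' @param plateau Steady-state enzyme level (fg/cell).
#' @param half_time Time to half-plateau (h).
#' @param plateau_time Approximate saturation time (h); must exceed
#'   `half_time`, and the profile must reach 95% of plateau by then.
#' @return A `rab5_induction_profile` list.
#' @export
induction_profile <- function(baseline, plateau, half_time, plateau_time) {
  if (baseline < 0 || plateau <= baseline) {
    stop("need 0 <= baseline < plateau", call. = FALSE)
  }
  if (half_time <= 0 || plateau_time <= half_time) {
    stop("need 0 < half_time < plateau_time", call. = FALSE)
  }
  prof <- structure(list(baseline = baseline, plateau = plateau,
                         half_time = half_time,
                         plateau_time = plateau_time),
                    class = "rab5_induction_profile")
  if (induction_timecourse(prof, plateau_time) < 0.95 * plateau) {
    stop("profile does not reach 95% of plateau by plateau_time; ",
         "shorten half_time or extend plateau_time", call. = FALSE)
  }
  prof
}

#' Enzyme abundance along an induction time course
#'
#' @param profile A [induction_profile()].
#' @param times_h Non-negative, non-decreasing times (h).
#' @return Enzyme abundance (fg/cell) at each time.
#' @export
induction_timecourse <- function(profile, times_h) {
  if (!inherits(profile, "rab5_induction_profile")) {
    stop("profile must be a rab5_induction_profile", call. = FALSE)
  }
  if (any(times_h < 0) || any(diff(times_h) < 0)) {
    stop("times must be non-negative and non-decreasing", call. = FALSE)
  }
  profile$baseline + (profile$plateau - profile$baseline) *
    (1 - 2^(-times_h / profile$half_time))
}

#' Time (h) at which the induction profile crosses a given level
#'
#' Inverts [induction_timecourse()]; `NA` if the level is never reached.
#'
#' @inheritParams induction_timecourse
#' @param level Enzyme level (fg/cell).
#' @return Crossing time (h) or `NA`.
#' @export
induction_crossing_time <- function(profile, level) {
  if (level <= profile$baseline) return(0)
  if (level >= profile$plateau) return(NA_real_)
  frac <- (level - profile$baseline) / (profile$plateau - profile$baseline)
  -profile$half_time * log2(1 - frac)
}

#' Preset experimental scenarios
#'
#' Bundled study conditions for the synthetic induction experiments:
#'
#' * `"nf73"` — Rabex-5-deficient fibroblasts, indirect pathway only
#'   (`sigma = 0`), total Rab5 2.5e-5 M (endogenous plus GFP-Rab5),
#'   induction from 1.5 to 15 fg/cell with 95% plateau at ~12 h; the enzyme
#'   level crosses the 12 fg/cell onset threshold at 6 h.
#' * `"bhk_gfp_rab5"` — BHK cells with GFP-Rab5 doubling total Rab5 to
#'   1.2e-5 M and an active direct pathway (`sigma = 0.1`); induction from
#'   3.2 to 32 fg/cell with 95% plateau at ~7 h.
#' * `"bhk_endogenous"` — BHK cells at endogenous Rab5 (6e-6 M), induced
#'   enzyme acting through the indirect pathway only; the 32 fg/cell plateau
#'   stays below the onset threshold, so no activation is expected.
#'
#' Kinetic constants common to all scenarios: `alpha = 2e4` M^-1 s^-1 (GEF
#' catalysis measured in vitro), `beta = 0.2` s^-1 ([estimate_beta()]),
#' `gamma = 1e4` M^-1 s^-1 and `lam = 9.375e-2` s^-1, i.e. a complex affinity
#' `lam/gamma = 9.375e-6` M — the value implied by an onset threshold of
#' 12 fg/cell at `z_tot = 2.5e-5` M.
#'
#' @param name Scenario name.
#' @return A `rab5_scenario` list: `params` ([kinetic_params()], `x_tot`
#'   unused), `profile`, `constants` ([cell_constants()]), `protein` (name of
#'   the induced enzyme in `constants$masses_kda`), `times_h` (default
#'   sampling grid), `n_reps`, `beta_over_alpha`, and `noise` (see
#'   [generate_dataset()]).
#' @export
rab5_scenario <- function(name = c("nf73", "bhk_gfp_rab5",
                                   "bhk_endogenous")) {
  name <- match.arg(name)
  base <- list(
    constants = cell_constants(),
    protein = "rabex5_135_480",
    times_h = c(0, 3, 6, 9, 12),
    n_reps = 3L,
    beta_over_alpha = 1e-5,
    noise = list(cv = 0.15, activity_scale = 1, activity_background = 0.05,
                 endosome_d0 = 0.5, endosome_k = 1.5,
                 endosomes_per_cell = 20L, n_cells = 30L, n_top = 90L)
  )
  kp <- function(sigma, z_tot) {
    kinetic_params(alpha = 2e4, beta = 0.2, gamma = 1e4, lam = 9.375e-2,
                   sigma = sigma, z_tot = z_tot, x_tot = 0)
  }
  sc <- switch(name,
    nf73 = c(base, list(
      name = "nf73", params = kp(0, 2.5e-5),
      profile = induction_profile(1.5, 15, 2.765, 12))),
    bhk_gfp_rab5 = c(base, list(
      name = "bhk_gfp_rab5", params = kp(0.1, 1.2e-5),
      profile = induction_profile(3.2, 32, 1.6, 7))),
    bhk_endogenous = c(base, list(
      name = "bhk_endogenous", params = kp(0, 6e-6),
      profile = induction_profile(3.2, 32, 1.6, 7)))
  )
  structure(sc, class = "rab5_scenario")
}

# lognormal factors with unit mean and coefficient of variation cv
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# quasi-steady-state Rab5-GTP along an enzyme time course (concentrations M)
qss_activity <- function(params, x_tot_M) {
  vapply(x_tot_M, function(x) steady_state_general(set_x_tot(params, x)),
         numeric(1))
}

# full-ODE Rab5-GTP with time-varying x_tot(t); times in hours. The run
# starts from the pre-induction steady state at the leaky baseline (cells
# equilibrate under Dox for many hours before induction). For a pure
# indirect system (sigma = 0) the zero state of the deterministic equations
# is invariant, so ignition of the feedback is seeded by a small basal
# exchange source beta * z_seed with z_seed = 1e-4 * z_tot, standing in for
# GEF-independent nucleotide exchange / molecular-number fluctuations; it
# keeps the sub-threshold state at ~0.01% of z_tot, negligible against the
# activated levels.
ode_activity <- function(params, profile, constants, protein, times_h) {
  mw <- constants$masses_kda[[protein]]
  z_seed <- if (params$sigma == 0) 1e-4 * params$z_tot else 0
  rhs <- function(t, y, p) {
    x_fg <- induction_timecourse(profile, t / 3600)
    p$x_tot <- fg_per_cell_to_molar(x_fg, mw, constants$volume_fl)
    d <- rab5_rhs(t, y, p)[[1L]]
    d[1L] <- d[1L] + p$beta * z_seed
    list(d)
  }
  x_base_M <- fg_per_cell_to_molar(profile$baseline, mw,
                                   constants$volume_fl)
  z0 <- max(steady_state_general(set_x_tot(params, x_base_M)), z_seed)
  x20 <- params$gamma * x_base_M * z0 /
    (params$lam * (1 + params$sigma) + params$gamma * z0)
  out <- deSolve::ode(y = c(z0, x20), times = unique(c(0, times_h * 3600)),
                      func = rhs, parms = params, method = "lsoda",
                      rtol = 1e-8, atol = 1e-14)
  z <- out[match(times_h * 3600, out[, 1L]), 2L]
  pmin(pmax(z, 0), params$z_tot)
}

#' Generate a synthetic Tet-Off induction dataset
#'
#' Emulates the induction assays: the enzyme abundance follows the scenario's
#' induction profile; the true Rab5-GTP level `z(t)` is computed from the
#' kinetic model (by default the quasi-steady state, valid because induction
#' takes hours while the activation kinetics relax in seconds); and noisy
#' observations are drawn with multiplicative lognormal noise:
#'
#' * enzyme immunoblot bands (fg/cell), `n_reps` replicate arms;
#' * a pull-down activity readout `(background + scale * z/z_tot) * noise`,
#'   proportional to GTP-bound Rab5 on top of an assay background;
#' * endosome diameters: per endosome `(d0 + k * (z/z_tot)^(1/3)) * noise`,
#'   reported as the `n_top` largest of `n_cells * endosomes_per_cell`
#'   simulated diameters (the 90-largest-in-30-cells protocol);
#' * a control arm with the enzyme held at the leaky baseline.
#'
#' Identical seeds yield identical datasets.
#'
#' @param scenario A [rab5_scenario()] (or a list with the same fields).
#' @param seed Integer seed; every random draw derives from it.
#' @param times_h Optional sampling times (h); defaults to
#'   `scenario$times_h`.
#' @param mode `"qss"` (default) or `"ode"` for full time-dependent
#'   integration of the activation kinetics under the rising enzyme level.
#' @return A `rab5_dataset` list: `times_h`, matrices `enzyme_fg` /
#'   `activity` / `control` (times x replicates), `enzyme_true_fg`,
#'   `z_true_M`, `z_control_M`, `endosomes` and `endosomes_control`
#'   (times x `n_top` matrices of diameters), `seed`, `mode`, and the
#'   generating `scenario` (true parameters included, for recovery tests).
#' @export
generate_dataset <- function(scenario, seed, times_h = NULL,
                             mode = c("qss", "ode")) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(times_h)) times_h <- scenario$times_h
  params <- as_rab5_params(scenario$params)
  constants <- scenario$constants
  mw <- constants$masses_kda[[scenario$protein]]
  nz <- scenario$noise
  n_t <- length(times_h)
  n_r <- scenario$n_reps

  x_true_fg <- induction_timecourse(scenario$profile, times_h)
  x_true_M <- fg_per_cell_to_molar(x_true_fg, mw, constants$volume_fl)
  z_true <- if (mode == "qss") {
    qss_activity(params, x_true_M)
  } else {
    ode_activity(params, scenario$profile, constants, scenario$protein,
                 times_h)
  }
  x_base_M <- fg_per_cell_to_molar(scenario$profile$baseline, mw,
                                   constants$volume_fl)
  z_ctrl <- qss_activity(params, rep(x_base_M, n_t))

  with_local_seed(seed, {
    draw_mat <- function(mean_vec) {
      matrix(rep(mean_vec, n_r) * lnoise(n_t * n_r, nz$cv), nrow = n_t)
    }
    signal <- nz$activity_background +
      nz$activity_scale * z_true / params$z_tot
    signal_ctrl <- nz$activity_background +
      nz$activity_scale * z_ctrl / params$z_tot
    enzyme <- draw_mat(x_true_fg)
    activity <- draw_mat(signal)
    control <- draw_mat(signal_ctrl)
    draw_endo <- function(zv) {
      t(vapply(zv, function(z) {
        n <- nz$n_cells * nz$endosomes_per_cell
        d <- (nz$endosome_d0 + nz$endosome_k * (z / params$z_tot)^(1 / 3)) *
          lnoise(n, nz$cv)
        sort(d, decreasing = TRUE)[seq_len(nz$n_top)]
      }, numeric(nz$n_top)))
    }
    endosomes <- draw_endo(z_true)
    endosomes_ctrl <- draw_endo(z_ctrl)
  })

  structure(list(times_h = times_h, enzyme_fg = enzyme,
                 enzyme_true_fg = x_true_fg, activity = activity,
                 control = control, z_true_M = z_true,
                 z_control_M = z_ctrl, endosomes = endosomes,
                 endosomes_control = endosomes_ctrl, seed = seed,
                 mode = mode, scenario = scenario),
            class = "rab5_dataset")
}

#' @export
print.rab5_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic induction dataset ('%s', seed %d, %s mode)\n",
    if (is.null(x$scenario$name)) "custom" else x$scenario$name,
    x$seed, x$mode))
  cat(sprintf("  %d time points (%s h), %d replicate arms\n",
              length(x$times_h), paste(x$times_h, collapse = ", "),
              ncol(x$enzyme_fg)))
  cat(sprintf("  enzyme %0.3g -> %0.3g fg/cell; peak z/z_tot = %0.3g\n",
              x$enzyme_true_fg[1L], x$enzyme_true_fg[length(x$times_h)],
              max(x$z_true_M) / x$scenario$params$z_tot))
  invisible(x)
}

#' Write / read a synthetic dataset as a CSV bundle
#'
#' Writes `timecourse.csv` (`time_h,rep,enzyme_fg_per_cell,activity_au,
#' control_au`), `endosomes.csv` (`time_h,arm,diameter_um`), and
#' `manifest.json` (seed, mode, scenario) into a directory.
#'
#' @param dataset A `rab5_dataset`.
#' @param dir Output directory (created if missing).
#' @return `read_dataset()` returns the reconstructed `rab5_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rab5_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_t <- length(dataset$times_h); n_r <- ncol(dataset$enzyme_fg)
  tc <- data.frame(
    time_h = rep(dataset$times_h, n_r),
    rep = rep(seq_len(n_r), each = n_t),
    enzyme_fg_per_cell = as.vector(dataset$enzyme_fg),
    activity_au = as.vector(dataset$activity),
    control_au = as.vector(dataset$control)
  )
  utils::write.csv(tc, file.path(dir, "timecourse.csv"), row.names = FALSE,
                   quote = FALSE)
  n_top <- ncol(dataset$endosomes)
  eo <- data.frame(
    time_h = rep(dataset$times_h, 2L * n_top),
    arm = rep(c("induced", "control"), each = n_t * n_top),
    diameter_um = c(as.vector(dataset$endosomes),
                    as.vector(dataset$endosomes_control))
  )
  utils::write.csv(eo, file.path(dir, "endosomes.csv"), row.names = FALSE,
                   quote = FALSE)
  sc <- dataset$scenario
  manifest <- list(
    seed = dataset$seed, mode = dataset$mode,
    name = if (is.null(sc$name)) "custom" else sc$name,
    params = unclass(as_rab5_params(sc$params)),
    profile = unclass(sc$profile),
    constants = list(volume_fl = sc$constants$volume_fl,
                     masses_kda = as.list(sc$constants$masses_kda)),
    protein = sc$protein, times_h = dataset$times_h, n_reps = sc$n_reps,
    beta_over_alpha = sc$beta_over_alpha, noise = sc$noise,
    enzyme_true_fg = dataset$enzyme_true_fg, z_true_M = dataset$z_true_M,
    z_control_M = dataset$z_control_M
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  tc <- utils::read.csv(file.path(dir, "timecourse.csv"))
  eo <- utils::read.csv(file.path(dir, "endosomes.csv"))
  times_h <- man$times_h
  n_t <- length(times_h)
  n_r <- man$n_reps
  as_mat <- function(v) matrix(v, nrow = n_t)
  sc <- structure(list(
    name = man$name,
    params = as_rab5_params(man$params),
    profile = structure(man$profile, class = "rab5_induction_profile"),
    constants = cell_constants(man$constants$volume_fl,
                               unlist(man$constants$masses_kda)),
    protein = man$protein, times_h = times_h, n_reps = n_r,
    beta_over_alpha = man$beta_over_alpha, noise = man$noise
  ), class = "rab5_scenario")
  ind <- eo$arm == "induced"
  structure(list(
    times_h = times_h,
    enzyme_fg = as_mat(tc$enzyme_fg_per_cell),
    enzyme_true_fg = man$enzyme_true_fg,
    activity = as_mat(tc$activity_au),
    control = as_mat(tc$control_au),
    z_true_M = man$z_true_M, z_control_M = man$z_control_M,
    endosomes = matrix(eo$diameter_um[ind], nrow = n_t),
    endosomes_control = matrix(eo$diameter_um[!ind], nrow = n_t),
    seed = man$seed, mode = man$mode, scenario = sc
  ), class = "rab5_dataset")
}
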