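#' Detect the onset of positive-feedback Rab5 activation in a time course
#'
#' Default rule: the onset is the first time point at which the per-time
#' replicate mean of the readout exceeds the control mean plus `k` control
#' standard deviations (computed over the control arm's per-time replicate
#' means) and stays above it at every later point. The reported interval is
#' `(previous time point, that time point)`, and the enzyme level at onset is
#' read conservatively at the lower edge of the interval. No onset within the
#' observation window is a valid outcome (`detected = FALSE`).
#'
#' A change-point alternative (`method = "changepoint"`) fits a one-step mean
#' shift by least squares and applies the same `k`-SD separation criterion to
#' the post-break mean.
#'
#' @param dataset A `rab5_dataset` (from [generate_dataset()] or
#'   [read_dataset()]), which carries the control arm.
#' @param k Detection stringency (number of control SDs); default 3. Larger
#'   `k` gives a later (or no) onset.
#' @param readout `"activity"` (pull-down signal, default) or `"endosomes"`
#'   (mean of the largest-diameter protocol).
#' @param method `"threshold"` (sustained exceedance, default) or
#'   `"changepoint"`.
#' @return A `rab5_onset` list: `detected`, `interval` (h; `c(NA, NA)` when
#'   not detected), `x_at_onset_fg`, `x_at_onset_M`, `plateau_fg`,
#'   `plateau_M`, and `rule` (settings echo).
#' @export
detect_onset <- function(dataset, k = 3,
                         readout = c("activity", "endosomes"),
                         method = c("threshold", "changepoint")) {
  stopifnot(inherits(dataset, "rab5_dataset"))
  readout <- match.arg(readout)
  method <- match.arg(method)
  if (length(dataset$times_h) < 2L) {
    stop("onset detection needs at least two time points", call. = FALSE)
  }
  obs <- switch(readout, activity = dataset$activity,
                endosomes = dataset$endosomes)
  ctrl <- switch(readout, activity = dataset$control,
                 endosomes = dataset$endosomes_control)
  if (is.null(ctrl)) {
    stop("dataset has no control arm for readout '", readout, "'",
         call. = FALSE)
  }
  m <- rowMeans(obs)
  cm <- rowMeans(ctrl)
  thr <- mean(cm) + k * stats::sd(cm)

  idx <- NA_integer_
  if (method == "threshold") {
    above <- m > thr
    sustained <- rev(cumprod(rev(above))) == 1
    if (any(sustained)) idx <- which(sustained)[1L]
  } else {
    n <- length(m)
    if (n >= 3L) {
      rss <- vapply(2:n, function(i) {
        sum((m[1:(i - 1)] - mean(m[1:(i - 1)]))^2) +
          sum((m[i:n] - mean(m[i:n]))^2)
      }, numeric(1))
      i <- (2:n)[which.min(rss)]
      if (mean(m[i:n]) > thr) idx <- i
    }
  }

  constants <- dataset$scenario$constants
  mw <- constants$masses_kda[[dataset$scenario$protein]]
  enzyme_mean <- rowMeans(dataset$enzyme_fg)
  plateau_fg <- max(enzyme_mean)
  out <- list(detected = !is.na(idx), rule = list(k = k, readout = readout,
                                                 method = method,
                                                 threshold = thr),
              plateau_fg = plateau_fg,
              plateau_M = fg_per_cell_to_molar(plateau_fg, mw,
                                               constants$volume_fl))
  if (is.na(idx)) {
    out$interval <- c(NA_real_, NA_real_)
    out$x_at_onset_fg <- NA_real_
    out$x_at_onset_M <- NA_real_
  } else {
    lo <- max(idx - 1L, 1L)
    out$interval <- c(dataset$times_h[lo], dataset$times_h[idx])
    out$x_at_onset_fg <- enzyme_mean[lo]
    out$x_at_onset_M <- fg_per_cell_to_molar(enzyme_mean[lo], mw,
                                             constants$volume_fl)
  }
  structure(out, class = "rab5_onset")
}

#' @export
print.rab5_onset <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "Onset detected between %g and %g h; enzyme at onset %0.3g fg/cell (%0.3g M)\n",
      x$interval[1L], x$interval[2L], x$x_at_onset_fg, x$x_at_onset_M))
  } else {
    cat(sprintf(
      "No onset detected (plateau %0.3g fg/cell = %0.3g M stayed below threshold)\n",
      x$plateau_fg, x$plateau_M))
  }
  invisible(x)
}

#' Estimate (or bound) the tripartite-complex affinity from an onset result
#'
#' When an onset was detected, inverts the delayed-onset relation at the
#' enzyme level of the interval's lower edge:
#' `lambda/gamma = x_onset * z_tot / (beta/alpha)` (type `"estimate"`). When
#' no onset was detected, the plateau enzyme level yields a lower bound on
#' the affinity instead (type `"lower_bound"`) — absence of activation at the
#' plateau implies the threshold lies above it.
#'
#' @param onset A `rab5_onset` from [detect_onset()].
#' @param z_tot Total Rab5 concentration (M).
#' @param beta_over_alpha Ratio beta/alpha (M); default 1e-5.
#' @return A `rab5_affinity` list: `type` (`"estimate"` or `"lower_bound"`),
#'   `lambda_over_gamma` (M), `value_rounded` (one significant figure, the
#'   printed precision of such estimates), and `x_used_M`.
#' @export
infer_affinity <- function(onset, z_tot, beta_over_alpha = 1e-5) {
  stopifnot(inherits(onset, "rab5_onset"))
  if (z_tot <= 0 || beta_over_alpha <= 0) {
    stop("z_tot and beta_over_alpha must be positive", call. = FALSE)
  }
  x_used <- if (onset$detected) onset$x_at_onset_M else onset$plateau_M
  if (!is.finite(x_used) || x_used <= 0) {
    stop("degenerate enzyme level at onset (", format(x_used),
         "); cannot estimate the affinity", call. = FALSE)
  }
  lg <- estimate_affinity_ratio(x_used, z_tot, beta_over_alpha)
  structure(list(
    type = if (onset$detected) "estimate" else "lower_bound",
    lambda_over_gamma = lg,
    value_rounded = round_one_sig(lg),
    order_of_magnitude = order_of_magnitude(lg),
    x_used_M = x_used, z_tot = z_tot, beta_over_alpha = beta_over_alpha
  ), class = "rab5_affinity")
}

#' @export
print.rab5_affinity <- function(x, ...) {
  lab <- if (x$type == "estimate") "lambda/gamma =" else "lambda/gamma >"
  cat(sprintf("Tripartite-complex affinity: %s %0.4g M (~%g M)\n", lab,
              x$lambda_over_gamma, x$order_of_magnitude))
  invisible(x)
}

# model prediction of the activity readout given log-parameters
activity_prediction <- function(theta, x_M, params, fit_sigma) {
  p <- params
  p$gamma <- 1
  p$lam <- exp(theta[["log_lg"]])
  p$sigma <- if (fit_sigma) exp(theta[["log_sigma"]]) else params$sigma
  z <- qss_activity(p, x_M)
  exp(theta[["log_bg"]]) + exp(theta[["log_scale"]]) * z / params$z_tot
}

#' Recover the complex affinity from a synthetic (or user) time course
#'
#' Least-squares fit of the quasi-steady-state activation model to the
#' activity readout, up to an unknown readout scale and background:
#' `activity ~ bg + scale * z(x; lambda/gamma, sigma) / z_tot`, with the
#' measured enzyme series (converted to molar) as predictor and `alpha`,
#' `beta`, `z_tot` supplied as known. Residuals are taken on the log scale
#' (the noise is multiplicative); optimization is Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) over `log(lambda/gamma)`, `log(scale)`, `log(bg)`
#' and optionally `log(sigma)`. Control-arm observations (enzyme at
#' baseline) are included, anchoring the background.
#'
#' A design in which the readout never rises above the control arm does not
#' identify the affinity; in that case an error of class
#' `"rab5_identifiability_error"` is raised carrying the lower bound from
#' [infer_affinity()].
#'
#' @param dataset A `rab5_dataset`.
#' @param known List with `alpha`, `beta`, `z_tot` (defaults: from the
#'   dataset's scenario).
#' @param fit_sigma Also fit the direct-pathway constant `sigma` (default
#'   `FALSE`: `sigma` is taken from the scenario).
#' @param n_boot Number of residual-bootstrap refits for confidence
#'   intervals (0 = none).
#' @param conf Bootstrap interval coverage (default 0.9).
#' @return A `rab5_recovery` list: `lambda_over_gamma`, `sigma`, `scale`,
#'   `background`, `ci` (when `n_boot > 0`), and the `nls.lm` fit object.
#' @export
recover_parameters <- function(dataset, known = NULL, fit_sigma = FALSE,
                               n_boot = 0L, conf = 0.9) {
  stopifnot(inherits(dataset, "rab5_dataset"))
  sc <- dataset$scenario
  params <- as_rab5_params(sc$params)
  if (!is.null(known)) {
    for (nm in intersect(names(known), c("alpha", "beta", "z_tot"))) {
      params[[nm]] <- known[[nm]]
    }
  }
  onset <- detect_onset(dataset)
  if (!onset$detected) {
    bound <- infer_affinity(onset, params$z_tot, sc$beta_over_alpha)
    cond <- structure(
      class = c("rab5_identifiability_error", "error", "condition"),
      list(message = paste0(
        "all observations lie below the activation onset; lambda/gamma is ",
        "not identifiable (lower bound ",
        format(bound$lambda_over_gamma), " M)"),
        call = sys.call(-1), bound = bound))
    stop(cond)
  }

  constants <- sc$constants
  mw <- constants$masses_kda[[sc$protein]]
  x_M <- fg_per_cell_to_molar(rowMeans(dataset$enzyme_fg), mw,
                              constants$volume_fl)
  x_base_M <- fg_per_cell_to_molar(sc$profile$baseline, mw,
                                   constants$volume_fl)
  n_r <- ncol(dataset$activity)
  y <- c(as.vector(dataset$activity), as.vector(dataset$control))
  x_pred <- c(rep(x_M, n_r), rep(x_base_M, length(dataset$times_h) * n_r))

  lg0 <- infer_affinity(onset, params$z_tot,
                        sc$beta_over_alpha)$lambda_over_gamma
  start <- c(log_lg = log(lg0),
             log_scale = log(max(max(y) - min(y), 1e-6)),
             log_bg = log(max(min(y), 1e-12)))
  if (fit_sigma) {
    start <- c(start, log_sigma = log(max(params$sigma, 1e-4)))
  }
  resid_fn <- function(theta, yy, xx) {
    pred <- activity_prediction(theta, xx, params, fit_sigma)
    log(yy) - log(pmax(pred, 1e-300))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, yy = y, xx = x_pred,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  est <- fit$par
  out <- list(
    lambda_over_gamma = exp(est[["log_lg"]]),
    sigma = if (fit_sigma) exp(est[["log_sigma"]]) else params$sigma,
    scale = exp(est[["log_scale"]]),
    background = exp(est[["log_bg"]]),
    onset = onset, fit = fit, convergence = fit$info
  )
  if (n_boot > 0L) {
    res <- stats::residuals(fit)
    log_pred <- log(y) - res
    # errors-in-variables: the enzyme predictor is itself a noisy replicate
    # mean, so each refit also perturbs it by its per-time standard error
    # (log scale, pooled over time points)
    logx <- log(pmax(dataset$enzyme_fg, 1e-300))
    se_logx <- sqrt(mean(apply(logx, 1L, stats::var))) / sqrt(ncol(logx))
    n_ctrl <- length(dataset$times_h) * n_r
    boot <- vapply(seq_len(n_boot), function(b) {
      xb <- x_M * exp(stats::rnorm(length(x_M), 0, se_logx))
      xxb <- c(rep(xb, n_r), rep(x_base_M, n_ctrl))
      yb <- exp(log_pred + sample(res, length(res), replace = TRUE))
      fb <- minpack.lm::nls.lm(par = est, fn = resid_fn, yy = yb,
                               xx = xxb,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 100))
      exp(fb$par[["log_lg"]])
    }, numeric(1))
    a <- (1 - conf) / 2
    q <- stats::quantile(boot, c(a, 1 - a), names = FALSE)
    # basic (reflected) bootstrap interval: corrects the attenuation bias
    # that the noisy predictor induces in both the estimate and its
    # bootstrap replicates
    out$ci <- pmax(c(2 * out$lambda_over_gamma - q[2L],
                     2 * out$lambda_over_gamma - q[1L]), 0)
    out$conf <- conf
    out$boot <- boot
  }
  structure(out, class = "rab5_recovery")
}

#' @export
print.rab5_recovery <- function(x, ...) {
  cat(sprintf("Recovered lambda/gamma = %0.4g M (sigma = %0.3g)\n",
              x$lambda_over_gamma, x$sigma))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CI: [%0.4g, %0.4g] M\n", 100 * x$conf,
                x$ci[1L], x$ci[2L]))
  }
  invisible(x)
}
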