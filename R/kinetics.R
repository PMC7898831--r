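# First-order hydrolysis kinetics of the sugar phosphate, inferred from
# time-resolved post-hydrolysis equilibrium conversions.

#' Convert a time series of shifted conversions into hydrolysis observations
#'
#' For each measured post-hydrolysis conversion c2, infers the cumulative
#' hydrolyzed sugar phosphate h via [hydrolyzed_amount()] and the residual
#' pool `residual_mM = c1*N0 - h`, where c1 is the pre-hydrolysis
#' equilibrium conversion of `system` (or a measured value, if supplied).
#'
#' @param time_h Incubation times (hours), non-negative.
#' @param c2 Post-hydrolysis equilibrium conversions (fractions), same
#'   length.
#' @param system A [reaction_system()].
#' @param pH Optional pH metadata (scalar or vector).
#' @param c1 Pre-hydrolysis conversion; defaults to the closed-form
#'   equilibrium of `system`.
#' @param tol,clamp Passed to [hydrolyzed_amount()]. For noisy series use
#'   `clamp = FALSE` with `tol` widened to the measurement noise mapped
#'   into h-space (see [conversion_noise_to_h()]).
#' @return A data.frame of class `hydrolysis_observations` with columns
#'   `time_h`, `pH`, `c2`, `h_mM`, `residual_mM`, and attributes `system`,
#'   `c1`, `A0` (= c1*N0, the initial sugar-phosphate pool in mM).
#' @export
quantify_hydrolysis <- function(time_h, c2, system, pH = NA_real_,
                                c1 = NULL, tol = NULL, clamp = TRUE) {
  system <- as_reaction_system(system)
  if (length(time_h) != length(c2)) {
    stop("`time_h` and `c2` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("incubation times must be finite and non-negative", call. = FALSE)
  }
  if (is.null(c1)) c1 <- solve_equilibrium_conversion(system)
  A0 <- c1 * system$N0
  h <- vapply(c2, hydrolyzed_amount, numeric(1), system = system,
              tol = tol, clamp = clamp)
  out <- data.frame(time_h = as.numeric(time_h),
                    pH = rep_len(as.numeric(pH), length(time_h)),
                    c2 = as.numeric(c2),
                    h_mM = h,
                    residual_mM = A0 - h)
  attr(out, "system") <- system
  attr(out, "c1") <- c1
  attr(out, "A0") <- A0
  class(out) <- c("hydrolysis_observations", "data.frame")
  out
}

#' Local sensitivity of the inferred hydrolyzed amount to conversion noise
#'
#' Maps a conversion-scale noise standard deviation into h-space via the
#' derivative of [hydrolyzed_amount()] at the unshifted equilibrium, where
#' the sensitivity is largest relative to h itself. Useful for choosing the
#' `tol` of [hydrolyzed_amount()] when processing noisy series.
#'
#' @param sigma_c Conversion noise standard deviation (fraction).
#' @param system A [reaction_system()].
#' @return Noise standard deviation on h (mM).
#' @export
conversion_noise_to_h <- function(sigma_c, system) {
  system <- as_reaction_system(system)
  c1 <- solve_equilibrium_conversion(system)
  eps <- 1e-6
  slope <- hydrolyzed_amount(c1 + eps, system, clamp = FALSE) / eps
  sigma_c * slope
}

#' Fit a first-order decay to the residual sugar phosphate
#'
#' Nonlinear least squares of `residual_mM(t) = A * exp(-k t)`. By default
#' the amplitude A is fixed to the known initial pool c1*N0 (attribute `A0`
#' of [quantify_hydrolysis()] output), since the first equilibrium anchors
#' the experiment; set `fix_amplitude = FALSE` to fit A as well. The fit is
#' performed on the untransformed exponential (not log-linearised) to avoid
#' bias from near-zero residuals late in the decay.
#'
#' @param obs A data.frame with columns `time_h` and `residual_mM`
#'   (typically from [quantify_hydrolysis()]).
#' @param fix_amplitude Fix A to `amplitude` (default `TRUE`).
#' @param amplitude Initial pool A (mM); defaults to the `A0` attribute of
#'   `obs`. Required when fixing the amplitude and `obs` carries no `A0`.
#' @return An object of class `decay_fit`: list with `k` (1/h), `t_half`
#'   (h, `log(2)/k`; `NA` when k <= 0), `amplitude` (mM),
#'   `amplitude_fitted`, `rms` (mM), `n`, `negative_rate` flag.
#' @examples
#' sys <- reaction_system(2, 8, 0.15)
#' sim <- simulate_experiment(sys, true_k = log(2) / 3.9,
#'                            times = c(0, 1, 2, 3, 5))
#' obs <- quantify_hydrolysis(sim$time_h, sim$c2, sys)
#' fit_first_order(obs)
#' @export
fit_first_order <- function(obs, fix_amplitude = TRUE, amplitude = NULL) {
  if (!is.data.frame(obs) ||
      !all(c("time_h", "residual_mM") %in% names(obs))) {
    stop("`obs` must be a data.frame with columns time_h and residual_mM",
         call. = FALSE)
  }
  t <- obs$time_h
  y <- obs$residual_mM
  n_t <- length(unique(t))
  if (is.null(amplitude)) amplitude <- attr(obs, "A0")
  if (fix_amplitude && is.null(amplitude)) {
    stop("`amplitude` required when fix_amplitude = TRUE and `obs` has no ",
         "A0 attribute", call. = FALSE)
  }
  need <- if (fix_amplitude) 2L else 3L
  if (n_t < need) {
    stop("need at least ", need, " distinct time points for this fit",
         call. = FALSE)
  }
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    stop("degenerate fit: residual amounts are constant over time, the ",
         "decay rate is unidentifiable", call. = FALSE)
  }
  # starting values from a log-linear regression on positive residuals
  pos <- y > 0
  k0 <- if (sum(pos) >= 2L && length(unique(t[pos])) >= 2L) {
    max(-coef(lm(log(y[pos]) ~ t[pos]))[2L], 1e-6)
  } else {
    log(2) / max(max(t), 1e-6)
  }
  A0 <- if (is.null(amplitude)) max(y) else amplitude
  df <- data.frame(t = t, y = y)
  if (fix_amplitude) {
    fit <- minpack.lm::nlsLM(y ~ amplitude * exp(-k * t), data = df,
                             start = list(k = k0),
                             control = nls.control(maxiter = 200))
    k <- coef(fit)[["k"]]
    A <- amplitude
  } else {
    fit <- minpack.lm::nlsLM(y ~ A * exp(-k * t), data = df,
                             start = list(A = A0, k = k0),
                             control = nls.control(maxiter = 200))
    k <- coef(fit)[["k"]]
    A <- coef(fit)[["A"]]
  }
  negative <- k <= 0
  if (negative) {
    warning("fitted rate constant is non-positive (k = ", format(k),
            " 1/h); half-life undefined")
  }
  structure(list(k = k,
                 t_half = if (negative) NA_real_ else log(2) / k,
                 amplitude = A,
                 amplitude_fitted = !fix_amplitude,
                 rms = sqrt(mean(residuals(fit)^2)),
                 n = length(t),
                 negative_rate = negative),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit>  k = %.4g 1/h   t_half = %.4g h   A = %.4g mM (%s)   RMS = %.2g mM   n = %d\n",
    x$k, x$t_half, x$amplitude,
    if (x$amplitude_fitted) "fitted" else "fixed", x$rms, x$n))
  if (x$negative_rate) cat("  warning: non-positive rate constant\n")
  invisible(x)
}

#' Bootstrap confidence intervals for the decay rate and half-life
#'
#' Case-resampling bootstrap over observations: rows are resampled with
#' replacement, the decay is refit, and percentile intervals are taken over
#' the successful resamples. Chosen over asymptotic covariance because
#' these experiments typically have only 4-6 time points.
#'
#' @param obs Observations as for [fit_first_order()]; at least 4 rows.
#' @param fix_amplitude,amplitude Passed to [fit_first_order()].
#' @param n_resamples Number of bootstrap resamples, >= 100.
#' @param seed Integer seed; required for reproducibility.
#' @param level Confidence level (default 0.95).
#' @return A list with `k_ci`, `t_half_ci` (length-2 vectors), the point
#'   `fit`, and `n_ok` (resamples that produced a positive rate).
#' @export
bootstrap_ci <- function(obs, fix_amplitude = TRUE, amplitude = NULL,
                         n_resamples = 1000, seed, level = 0.95) {
  if (nrow(obs) < 4L) {
    stop("refusing to bootstrap fewer than 4 observations", call. = FALSE)
  }
  if (n_resamples < 100) stop("n_resamples must be >= 100", call. = FALSE)
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer `seed` is required", call. = FALSE)
  }
  fit <- fit_first_order(obs, fix_amplitude = fix_amplitude,
                         amplitude = amplitude)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ks <- rep(NA_real_, n_resamples)
  for (i in seq_len(n_resamples)) {
    idx <- sample.int(nrow(obs), replace = TRUE)
    ks[i] <- tryCatch(
      suppressWarnings(
        fit_first_order(obs[idx, , drop = FALSE],
                        fix_amplitude = fix_amplitude,
                        amplitude = if (is.null(amplitude)) attr(obs, "A0")
                                    else amplitude)$k),
      error = function(e) NA_real_)
  }
  ok <- ks[is.finite(ks) & ks > 0]
  if (length(ok) < 0.5 * n_resamples) {
    warning("more than half of the bootstrap resamples failed or gave a ",
            "non-positive rate; intervals are unreliable")
  }
  alpha <- (1 - level) / 2
  k_ci <- unname(quantile(ok, c(alpha, 1 - alpha)))
  list(k_ci = k_ci,
       t_half_ci = sort(log(2) / rev(k_ci)),
       fit = fit,
       n_ok = length(ok))
}

#' pH-rate profile: linear trend of log10(k) against pH
#'
#' Hydrolysis of sugar phosphates is acid-catalysed, so the rate constant
#' decreases roughly exponentially with pH well into the alkaline region;
#' this fits the ordinary least-squares line of log10(k) on pH.
#'
#' @param fits Either a data.frame with columns `pH` and `k_per_h`, or a
#'   named list of [fit_first_order()] results whose names are pH values.
#' @return A list with `slope` (per pH unit; negative for acid-catalysed
#'   decay), `intercept`, `r_squared`, and the assembled `data`.
#' @export
ph_rate_profile <- function(fits) {
  if (is.data.frame(fits)) {
    if (!all(c("pH", "k_per_h") %in% names(fits))) {
      stop("data.frame input needs columns `pH` and `k_per_h`",
           call. = FALSE)
    }
    df <- data.frame(pH = fits$pH, k_per_h = fits$k_per_h)
  } else if (is.list(fits)) {
    if (is.null(names(fits)) ||
        any(is.na(suppressWarnings(as.numeric(names(fits)))))) {
      stop("list input must be named by numeric pH values", call. = FALSE)
    }
    df <- data.frame(pH = as.numeric(names(fits)),
                     k_per_h = vapply(fits, function(f) f$k, numeric(1)))
  } else {
    stop("`fits` must be a data.frame or a named list of decay fits",
         call. = FALSE)
  }
  if (nrow(df) < 2L) stop("need at least two pH points", call. = FALSE)
  if (any(!is.finite(df$k_per_h)) || any(df$k_per_h <= 0)) {
    stop("all rate constants must be positive and finite", call. = FALSE)
  }
  fit <- lm(log10(k_per_h) ~ pH, data = df)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((log10(df$k_per_h) - mean(log10(df$k_per_h)))^2)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       data = df)
}
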