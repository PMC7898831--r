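# Seeded synthetic-data generators: Gaussian-band reference spectra, noisy
# mixture spectra at known conversion, and complete simulated hydrolysis
# experiments, so every pipeline stage is testable without instrument data.

# evaluate expr with a locally seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

#' Specification for synthetic reference spectra
#'
#' Describes the two pure-component reference spectra as sums of Gaussian
#' absorption bands on a wavelength grid. Defaults emulate a pyrimidine
#' nucleoside/nucleobase pair in an alkaline quench: a nucleoside band near
#' 262 nm and a red-shifted nucleobase band near 284 nm, on the
#' 250-350 nm grid typical of plate-reader reaction monitoring.
#'
#' @param wavelengths Wavelength grid (nm), strictly ascending.
#' @param nucleoside_peaks,nucleobase_peaks data.frames with columns
#'   `center` (nm), `width` (nm, Gaussian sd) and `height` (AU at unit
#'   concentration).
#' @param noise_sd Absorbance noise standard deviation (AU), >= 0, used by
#'   [simulate_mixture()].
#' @param seed Integer seed for downstream noisy generation.
#' @param min_peak_separation Minimum distance (nm) required between the
#'   closest peak centers of the two species, default 5.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(wavelengths = seq(250, 350, by = 1),
                           nucleoside_peaks = data.frame(center = 262,
                                                         width = 10,
                                                         height = 1.0),
                           nucleobase_peaks = data.frame(center = 284,
                                                         width = 12,
                                                         height = 0.95),
                           noise_sd = 0.005,
                           seed = 1L,
                           min_peak_separation = 5) {
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly ascending", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (pk in list(nucleoside_peaks, nucleobase_peaks)) {
    if (!all(c("center", "width", "height") %in% names(pk))) {
      stop("peak tables need columns center, width, height", call. = FALSE)
    }
    if (any(pk$center < min(wavelengths)) ||
        any(pk$center > max(wavelengths))) {
      stop("peak centers must lie inside the wavelength grid", call. = FALSE)
    }
    if (any(pk$width <= 0) || any(pk$height <= 0)) {
      stop("peak widths and heights must be positive", call. = FALSE)
    }
  }
  sep <- min(abs(outer(nucleoside_peaks$center, nucleobase_peaks$center, "-")))
  if (sep < min_peak_separation) {
    stop("the two species need distinct band positions (closest centers ",
         format(sep), " nm apart, need >= ", min_peak_separation, " nm)",
         call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 nucleoside_peaks = nucleoside_peaks,
                 nucleobase_peaks = nucleobase_peaks,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

gaussian_bands <- function(wl, peaks) {
  rowSums(vapply(seq_len(nrow(peaks)), function(i) {
    peaks$height[i] * exp(-0.5 * ((wl - peaks$center[i]) / peaks$width[i])^2)
  }, numeric(length(wl))))
}

#' Generate unit-concentration reference spectra
#'
#' Builds smooth (noise-free) Gaussian-band spectra for the nucleoside and
#' the nucleobase from a [synthetic_spec()]. Deterministic.
#'
#' @param spec A [synthetic_spec()].
#' @return A [reference_set()].
#' @examples
#' refs <- make_reference_spectra(synthetic_spec())
#' @export
make_reference_spectra <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be a synthetic_spec", call. = FALSE)
  }
  wl <- spec$wavelengths
  reference_set(
    spectrum(wl, gaussian_bands(wl, spec$nucleoside_peaks), "nucleoside"),
    spectrum(wl, gaussian_bands(wl, spec$nucleobase_peaks), "nucleobase"),
    medium = "synthetic")
}

#' Simulate a mixture spectrum at known conversion
#'
#' Returns `(1 - conversion) * ref_N + conversion * ref_B` plus additive
#' Gaussian absorbance noise; reproducible per seed.
#'
#' @param conversion Fraction in \[0, 1\].
#' @param refs A [reference_set()] on a common grid.
#' @param noise_sd Absorbance noise sd (AU), >= 0.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param label Sample label.
#' @return A [spectrum()].
#' @export
simulate_mixture <- function(conversion, refs, noise_sd = 0, seed = NULL,
                             label = sprintf("c=%.3f", conversion)) {
  if (conversion < 0 || conversion > 1) {
    stop("conversion must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  wl <- refs$nucleoside_ref$wavelengths
  if (!isTRUE(all.equal(wl, refs$nucleobase_ref$wavelengths))) {
    stop("reference spectra must share one wavelength grid", call. = FALSE)
  }
  y <- (1 - conversion) * refs$nucleoside_ref$absorbances +
    conversion * refs$nucleobase_ref$absorbances
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(y), sd = noise_sd))
  }
  spectrum(wl, y, label)
}

#' Simulate a discontinuous phosphorolysis/hydrolysis experiment
#'
#' Emulates the measurement campaign: a phosphorolysis reaction is run to
#' its first equilibrium (conversion c1, sugar-phosphate pool c1*N0), the
#' pool decays first-order during incubation, and re-equilibration after
#' each incubation time yields the shifted conversion
#' `c2(t) = conversion_after_hydrolysis(c1*N0*(1 - exp(-k t)))`. Phosphate
#' liberated by hydrolysis feeds back into the substrate reservoir through
#' the mass balance `P = P0 - c2*N0 + h`. Additive Gaussian noise on the
#' measured conversions is truncated to keep them inside (0, 1).
#'
#' @param system A [reaction_system()]; default mirrors the uridine
#'   demonstration system (K = 0.15, 2 mM nucleoside, 8 mM phosphate).
#' @param true_k First-order hydrolysis rate constant (1/h), >= 0.
#' @param times Incubation times (h); including 0 is recommended.
#' @param sigma_c Conversion noise sd (fraction), >= 0.
#' @param pH pH metadata label.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A data.frame with columns `time_h`, `pH`, `c2_true`, `c2`,
#'   `h_true_mM`, plus attributes `system`, `true_k`, `c1`, `sigma_c`.
#' @examples
#' simulate_experiment(true_k = log(2) / 3.9, times = c(0, 1, 2, 3, 5))
#' @export
simulate_experiment <- function(system = reaction_system(2, 8, 0.15),
                                true_k, times, sigma_c = 0, pH = NA_real_,
                                seed = NULL) {
  system <- as_reaction_system(system)
  if (!is.numeric(true_k) || length(true_k) != 1L || true_k < 0) {
    stop("`true_k` must be a single non-negative rate (1/h)", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (sigma_c < 0) stop("sigma_c must be >= 0", call. = FALSE)
  c1 <- solve_equilibrium_conversion(system)
  A0 <- c1 * system$N0
  h <- A0 * (1 - exp(-true_k * times))
  c2_true <- vapply(h, conversion_after_hydrolysis, numeric(1),
                    system = system)
  c2 <- c2_true
  if (sigma_c > 0) {
    c2 <- c2 + with_seed(seed, rnorm(length(c2), sd = sigma_c))
    c2 <- pmin(pmax(c2, 1e-6), 1 - 1e-6)
  }
  out <- data.frame(time_h = as.numeric(times),
                    pH = rep_len(as.numeric(pH), length(times)),
                    c2_true = c2_true, c2 = c2, h_true_mM = h)
  attr(out, "system") <- system
  attr(out, "true_k") <- true_k
  attr(out, "c1") <- c1
  attr(out, "sigma_c") <- sigma_c
  out
}

#' End-to-end parameter-recovery study
#'
#' Runs the full pipeline — simulate conversions (optionally render them as
#' noisy spectra and unmix them back), infer hydrolyzed amounts, fit the
#' first-order decay — over seeded replicates, and reports recovery
#' statistics for the rate constant and half-life. Hydrolyzed amounts are
#' inferred unclamped with a noise-propagated tolerance so that symmetric
#' conversion noise stays symmetric in h-space (see
#' [conversion_noise_to_h()]).
#'
#' @param n_replicates Number of replicates, >= 1.
#' @param system A [reaction_system()].
#' @param true_k True rate constant (1/h), > 0.
#' @param times Incubation times (h).
#' @param sigma_c Conversion noise sd (fraction).
#' @param seed Integer seed; replicate i uses `seed + i`.
#' @param use_spectra If `TRUE`, route each conversion through a synthetic
#'   mixture spectrum plus unmixing instead of using it directly.
#' @param spec [synthetic_spec()] for the spectra route (controls the
#'   absorbance noise via its `noise_sd`).
#' @param fix_amplitude Passed to [fit_first_order()].
#' @return A list with `estimates` (data.frame: replicate, k_hat,
#'   t_half_hat), `true_k`, `true_t_half`, `median_k`, `median_t_half`,
#'   `bias_k`, `rmse_k`, `n_failed`.
#' @export
end_to_end_recovery <- function(n_replicates, system, true_k, times,
                                sigma_c = 0.01, seed = 1L,
                                use_spectra = FALSE,
                                spec = synthetic_spec(),
                                fix_amplitude = TRUE) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  system <- as_reaction_system(system)
  if (true_k <= 0) stop("true_k must be positive", call. = FALSE)
  refs <- if (use_spectra) make_reference_spectra(spec)
  # effective conversion noise: direct noise plus, on the spectra route,
  # absorbance noise propagated through the least-squares weights
  # (delta method on w_B/(w_N + w_B) at equal weights)
  sigma_c_eff <- sigma_c
  if (use_spectra && spec$noise_sd > 0) {
    A <- cbind(refs$nucleoside_ref$absorbances,
               refs$nucleobase_ref$absorbances)
    g <- c(-0.5, 0.5)  # gradient of w_B/(w_N+w_B) at w_N = w_B = 0.5
    var_c <- spec$noise_sd^2 * drop(t(g) %*% solve(crossprod(A)) %*% g)
    sigma_c_eff <- sqrt(sigma_c^2 + var_c)
  }
  # tolerance wide enough that ~6-sigma conversion noise never errors out
  sigma_h <- if (sigma_c_eff > 0) conversion_noise_to_h(sigma_c_eff, system)
             else 0
  tol <- max(1e-3 * system$N0, 8 * sigma_h)
  clamp <- sigma_c_eff == 0
  k_hat <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer(seed) + r
    sim <- simulate_experiment(system, true_k, times, sigma_c = sigma_c,
                               seed = rep_seed)
    c2 <- sim$c2
    if (use_spectra) {
      c2 <- with_seed(rep_seed + 10000L, vapply(c2, function(ci) {
        mix <- simulate_mixture(ci, refs, noise_sd = spec$noise_sd,
                                seed = NULL)
        unmix(mix, refs)$conversion
      }, numeric(1)))
      c2 <- pmin(pmax(c2, 1e-6), 1 - 1e-6)
    }
    obs <- quantify_hydrolysis(sim$time_h, c2, system, tol = tol,
                               clamp = clamp)
    k_hat[r] <- tryCatch(
      suppressWarnings(fit_first_order(obs, fix_amplitude = fix_amplitude)$k),
      error = function(e) NA_real_)
  }
  ok <- is.finite(k_hat) & k_hat > 0
  est <- data.frame(replicate = seq_len(n_replicates), k_hat = k_hat,
                    t_half_hat = ifelse(ok, log(2) / k_hat, NA_real_))
  list(estimates = est,
       true_k = true_k,
       true_t_half = log(2) / true_k,
       median_k = median(k_hat[ok]),
       median_t_half = median(est$t_half_hat[ok]),
       bias_k = mean(k_hat[ok]) - true_k,
       rmse_k = sqrt(mean((k_hat[ok] - true_k)^2)),
       n_failed = sum(!ok))
}
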