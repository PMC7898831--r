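# Conversion readout from UV absorption spectra (250-350 nm) by linear
# deconvolution against unit-concentration reference spectra of the
# nucleoside and the nucleobase.

#' Construct a UV absorption spectrum
#'
#' @param wavelengths Wavelength grid (nm), strictly ascending.
#' @param absorbances Absorbances (AU), same length, finite.
#' @param label Free-text sample label (id, time point, pH).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, absorbances, label = "") {
  wavelengths <- as.numeric(wavelengths)
  absorbances <- as.numeric(absorbances)
  if (length(wavelengths) != length(absorbances)) {
    stop("wavelengths and absorbances must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least two wavelengths", call. = FALSE)
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be finite and strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(absorbances))) {
    stop("absorbances must be finite (sample '", label, "')", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, absorbances = absorbances,
                 label = as.character(label)[1L]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> '%s': %d points, %g-%g nm, max A = %.3f AU\n",
              x$label, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), max(x$absorbances)))
  invisible(x)
}

#' Pair of unit-concentration reference spectra
#'
#' Reference spectra must be recorded (or normalized) at unit concentration
#' in the same medium as the samples (e.g. a 100 mM NaOH quench), so that
#' the unmixing weights are directly proportional to concentrations and the
#' weight ratio is a mole fraction.
#'
#' @param nucleoside_ref,nucleobase_ref [spectrum()] objects.
#' @param medium Free-text medium tag.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(nucleoside_ref, nucleobase_ref, medium = "") {
  if (!inherits(nucleoside_ref, "spectrum") ||
      !inherits(nucleobase_ref, "spectrum")) {
    stop("references must be spectrum objects", call. = FALSE)
  }
  r1 <- range(nucleoside_ref$wavelengths)
  r2 <- range(nucleobase_ref$wavelengths)
  if (max(r1[1], r2[1]) >= min(r1[2], r2[2])) {
    stop("reference spectra have no overlapping wavelength range",
         call. = FALSE)
  }
  structure(list(nucleoside_ref = nucleoside_ref,
                 nucleobase_ref = nucleobase_ref,
                 medium = as.character(medium)[1L]),
            class = "reference_set")
}

#' Read sample spectra from CSV
#'
#' Expects a comma-separated file with a header row, one `wavelength_nm`
#' column and one or more sample columns (one spectrum each, named by the
#' column header).
#'
#' @param path Path to the CSV file.
#' @return A named list of [spectrum()] objects, one per sample column.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty spectra file: ", path, call. = FALSE)
  wl_idx <- which(names(df) == "wavelength_nm")
  if (length(wl_idx) == 0L) {
    stop("missing `wavelength_nm` column in ", path, call. = FALSE)
  }
  if (length(wl_idx) > 1L) {
    stop("duplicated `wavelength_nm` column in ", path, call. = FALSE)
  }
  for (j in seq_along(df)) {
    bad <- which(!is.na(df[[j]]) & is.na(suppressWarnings(as.numeric(df[[j]]))))
    bad <- c(bad, which(is.na(df[[j]])))
    if (length(bad) > 0L) {
      stop("non-numeric or missing value in column `", names(df)[j],
           "`, data row ", min(bad), " of ", path, call. = FALSE)
    }
    df[[j]] <- as.numeric(df[[j]])
  }
  wl <- df[[wl_idx]]
  if (any(diff(wl) <= 0)) {
    stop("`wavelength_nm` must be strictly ascending in ", path,
         call. = FALSE)
  }
  samples <- setdiff(seq_along(df), wl_idx)
  if (length(samples) == 0L) {
    stop("no sample columns in ", path, call. = FALSE)
  }
  out <- lapply(samples, function(j) spectrum(wl, df[[j]], names(df)[j]))
  names(out) <- names(df)[samples]
  out
}

#' Read a reference set from CSV
#'
#' Expects columns `wavelength_nm,nucleoside,nucleobase`.
#'
#' @param path Path to the CSV file.
#' @param medium Medium tag stored on the resulting [reference_set()].
#' @return A [reference_set()].
#' @export
read_reference_set <- function(path, medium = "") {
  sp <- read_spectra(path)
  miss <- setdiff(c("nucleoside", "nucleobase"), names(sp))
  if (length(miss) > 0L) {
    stop("reference CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  reference_set(sp$nucleoside, sp$nucleobase, medium = medium)
}

# interpolate a reference onto the sample grid; extrapolation forbidden
interp_ref <- function(ref, wl) {
  if (min(wl) < min(ref$wavelengths) - 1e-9 ||
      max(wl) > max(ref$wavelengths) + 1e-9) {
    stop("sample grid (", min(wl), "-", max(wl), " nm) extends beyond the ",
         "reference grid (", min(ref$wavelengths), "-",
         max(ref$wavelengths), " nm); extrapolation is not allowed",
         call. = FALSE)
  }
  approx(ref$wavelengths, ref$absorbances, xout = wl, rule = 1)$y
}

#' Estimate the degree of conversion from one mixture spectrum
#'
#' Solves a least-squares decomposition of the sample spectrum into the
#' nucleoside and nucleobase reference spectra (optionally plus a constant
#' baseline), by default with non-negative component weights (physical
#' concentrations cannot be negative). Since B + N = N0 at every
#' equilibrium, the mole-fraction readout
#' `conversion = w_B / (w_N + w_B)` is the degree of conversion, provided
#' the references are unit-concentration normalized.
#'
#' With `nonneg = TRUE` the baseline is handled as the difference of two
#' non-negative columns, so it may take either sign while the component
#' weights stay constrained.
#'
#' @param x A [spectrum()] to unmix.
#' @param refs A [reference_set()].
#' @param baseline Include a constant baseline term (default `TRUE`).
#' @param nonneg Constrain component weights to be non-negative (default
#'   `TRUE`); plain least squares is available for diagnostics.
#' @param residual_threshold Residual RMS (AU) above which the quality
#'   `flag` is raised. Default 0.01 AU.
#' @param cond_cap Maximum acceptable condition number of the two-column
#'   reference design matrix. Default 1000.
#' @return An object of class `unmix_result`: list with
#'   `fraction_nucleoside`, `fraction_nucleobase` (weights, >= 0 under
#'   `nonneg`), `conversion`, `baseline`, `residual_rms` (AU), `flag`
#'   (logical) and `label`.
#' @examples
#' refs <- make_reference_spectra(synthetic_spec())
#' mix <- simulate_mixture(0.65, refs, noise_sd = 0, seed = 1)
#' unmix(mix, refs)$conversion # 0.65
#' @export
unmix <- function(x, refs, baseline = TRUE, nonneg = TRUE,
                  residual_threshold = 0.01, cond_cap = 1000) {
  if (!inherits(x, "spectrum")) stop("`x` must be a spectrum", call. = FALSE)
  if (!inherits(refs, "reference_set")) {
    stop("`refs` must be a reference_set", call. = FALSE)
  }
  wl <- x$wavelengths
  A <- cbind(N = interp_ref(refs$nucleoside_ref, wl),
             B = interp_ref(refs$nucleobase_ref, wl))
  kap <- kappa(A, exact = TRUE)
  if (!is.finite(kap) || kap > cond_cap) {
    stop(sprintf(paste0("reference spectra are ill-conditioned (condition ",
                        "number %.3g > cap %.3g); choose references with ",
                        "more distinct band shapes"), kap, cond_cap),
         call. = FALSE)
  }
  y <- x$absorbances
  if (nonneg) {
    D <- if (baseline) cbind(A, bp = 1, bm = -1) else A
    w <- pracma::lsqnonneg(D, y)$x
    wN <- w[1L]; wB <- w[2L]
    b0 <- if (baseline) w[3L] - w[4L] else 0
    resid <- y - D %*% w
  } else {
    D <- if (baseline) cbind(A, b = 1) else A
    fit <- .lm.fit(D, y)
    co <- coef(fit)
    wN <- co[1L]; wB <- co[2L]
    b0 <- if (baseline) co[3L] else 0
    resid <- fit$residuals
  }
  scale <- max(abs(y), 1e-12)
  if (wN + wB <= 1e-8 * scale) {
    stop("conversion undefined: both component weights are ~0 ",
         "(blank or baseline-only spectrum '", x$label, "')", call. = FALSE)
  }
  rms <- sqrt(mean(resid^2))
  structure(list(fraction_nucleoside = wN,
                 fraction_nucleobase = wB,
                 conversion = wB / (wN + wB),
                 baseline = b0,
                 residual_rms = rms,
                 flag = rms > residual_threshold,
                 label = x$label),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf(
    "<unmix_result> '%s': conversion = %.4f (wN = %.4g, wB = %.4g), residual RMS = %.2g AU%s\n",
    x$label, x$conversion, x$fraction_nucleoside, x$fraction_nucleobase,
    x$residual_rms, if (x$flag) "  [FLAGGED]" else ""))
  invisible(x)
}

#' Batch conversion readout from spectra files
#'
#' Reads sample spectra and references from CSV, unmixes every sample and
#' returns a tidy table.
#'
#' @param sample_path CSV of sample spectra (see [read_spectra()]).
#' @param ref_path CSV of reference spectra (see [read_reference_set()]).
#' @param config Named list of options forwarded to [unmix()]: `baseline`,
#'   `nonneg`, `residual_threshold`, `cond_cap`.
#' @return A data.frame with one row per sample: `label`, `conversion`,
#'   `fraction_nucleoside`, `fraction_nucleobase`, `residual_rms`, `flag`.
#' @export
conversions_from_files <- function(sample_path, ref_path, config = list()) {
  samples <- read_spectra(sample_path)
  refs <- read_reference_set(ref_path)
  opts <- list(baseline = TRUE, nonneg = TRUE, residual_threshold = 0.01,
               cond_cap = 1000)
  unknown <- setdiff(names(config), names(opts))
  if (length(unknown) > 0L) {
    stop("unknown unmixing option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  opts[names(config)] <- config
  rows <- lapply(samples, function(s) {
    res <- tryCatch(
      unmix(s, refs, baseline = opts$baseline, nonneg = opts$nonneg,
            residual_threshold = opts$residual_threshold,
            cond_cap = opts$cond_cap),
      error = function(e) {
        stop("sample '", s$label, "': ", conditionMessage(e), call. = FALSE)
      })
    data.frame(label = res$label, conversion = res$conversion,
               fraction_nucleoside = res$fraction_nucleoside,
               fraction_nucleobase = res$fraction_nucleobase,
               residual_rms = res$residual_rms, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
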