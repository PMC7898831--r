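# Experimental design window: the maximum attainable equilibrium shift
# delta_c_max as a function of the equilibrium constant K and the phosphate
# excess (P0/N0 equivalents). Large shifts make the hydrolysis readout
# sensitive; the extremes generate almost no sugar phosphate (tiny c1) or
# leave no room for re-equilibration (c1 near 1).

default_K_grid <- function() 10^seq(log10(0.01), log10(1), length.out = 31)
default_ratio_grid <- function() seq(0.5, 20, length.out = 100)

#' Scan the working window over K and phosphate equivalents
#'
#' For every grid cell, solves the pre-hydrolysis equilibrium conversion c1
#' and the full-hydrolysis ceiling c2max, and tabulates the maximum
#' apparent shift `delta = c2max - c1`. The map depends only on the ratio
#' P0/N0, not on the absolute concentration scale.
#'
#' @param K_grid Equilibrium constants, each in (0, 1\]. Default: 31
#'   log-spaced points in \[0.01, 1\].
#' @param ratio_grid Phosphate:nucleoside ratios (equivalents), > 0.
#'   Default: 100 points in \[0.5, 20\].
#' @param N0 Nucleoside concentration (mM) used to realise the ratios;
#'   the result is invariant to it.
#' @return An object of class `window_map`: list with `K_grid`,
#'   `ratio_grid` and matrices `c1`, `c2max`, `delta` indexed (K, ratio).
#' @examples
#' wm <- window_scan(K_grid = 0.15, ratio_grid = seq(2.5, 10, by = 0.5))
#' max(wm$delta)
#' @export
window_scan <- function(K_grid = default_K_grid(),
                        ratio_grid = default_ratio_grid(),
                        N0 = 1) {
  if (length(K_grid) == 0L || length(ratio_grid) == 0L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (any(K_grid <= 0) || any(K_grid > 1)) {
    stop("K_grid values must lie in (0, 1]", call. = FALSE)
  }
  if (any(ratio_grid <= 0)) stop("ratios must be positive", call. = FALSE)
  nk <- length(K_grid); nr <- length(ratio_grid)
  c1m <- matrix(NA_real_, nk, nr, dimnames = list(format(K_grid),
                                                  format(ratio_grid)))
  c2m <- c1m
  for (i in seq_len(nk)) {
    for (j in seq_len(nr)) {
      sys <- reaction_system(N0, ratio_grid[j] * N0, K_grid[i])
      res <- tryCatch({
        c1 <- solve_equilibrium_conversion(sys)
        c(c1, max_shift(c1, sys)$c2_max)
      }, error = function(e) {
        stop("window cell (K = ", K_grid[i], ", ratio = ", ratio_grid[j],
             "): ", conditionMessage(e), call. = FALSE)
      })
      c1m[i, j] <- res[1L]
      c2m[i, j] <- res[2L]
    }
  }
  structure(list(K_grid = K_grid, ratio_grid = ratio_grid,
                 c1 = c1m, c2max = c2m, delta = c2m - c1m),
            class = "window_map")
}

#' @export
print.window_map <- function(x, ...) {
  cat(sprintf(
    "<window_map>  %d K values x %d ratios;  delta_c_max in [%.3f, %.3f]\n",
    length(x$K_grid), length(x$ratio_grid), min(x$delta), max(x$delta)))
  invisible(x)
}

#' Long-format table of a window map
#'
#' @param x A `window_map`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with columns `K`, `ratio`, `c1`, `c2max`, `delta`.
#' @export
as.data.frame.window_map <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  grid <- expand.grid(K = x$K_grid, ratio = x$ratio_grid,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(grid,
             c1 = as.vector(x$c1),
             c2max = as.vector(x$c2max),
             delta = as.vector(x$delta))
}

# delta_c_max as a function of the phosphate excess at fixed K
delta_at_ratio <- function(K, ratio) {
  sys <- reaction_system(1, ratio, K)
  max_shift(solve_equilibrium_conversion(sys), sys)$delta_c_max
}

#' Recommend a phosphate-excess interval for a target shift
#'
#' Inverts the working-window curve: returns the contiguous interval of
#' phosphate:nucleoside ratios over which the maximum attainable shift
#' `delta_c_max(ratio)` is at least `target_delta`. The curve is unimodal
#' in the ratio; unimodality is asserted on a dense grid before the
#' crossing points are bracketed by root finding.
#'
#' @param K Equilibrium constant, in (0, 1\].
#' @param target_delta Desired minimum shift (fraction), > 0.
#' @param ratio_range Ratios considered, default \[0.5, 50\].
#' @param n_grid Dense-grid size for the unimodality check and bracketing.
#' @return A list with `interval` (length-2 ratios), `max_delta` and
#'   `argmax_ratio`.
#' @examples
#' recommend_equivalents(K = 0.15, target_delta = 0.20)
#' @export
recommend_equivalents <- function(K, target_delta,
                                  ratio_range = c(0.5, 50), n_grid = 800) {
  if (K <= 0 || K > 1) stop("K must lie in (0, 1]", call. = FALSE)
  if (target_delta <= 0 || target_delta >= 1) {
    stop("target_delta must be a fraction in (0, 1)", call. = FALSE)
  }
  ratios <- exp(seq(log(ratio_range[1L]), log(ratio_range[2L]),
                    length.out = n_grid))
  deltas <- vapply(ratios, function(r) delta_at_ratio(K, r), numeric(1))
  imax <- which.max(deltas)
  dmax <- deltas[imax]
  # assert unimodality: nondecreasing up to the argmax, nonincreasing after
  tolm <- 1e-12
  if (any(diff(deltas[seq_len(imax)]) < -tolm) ||
      any(diff(deltas[imax:length(deltas)]) > tolm)) {
    stop("delta_c_max(ratio) is not unimodal on the requested range; ",
         "cannot bracket a contiguous interval", call. = FALSE)
  }
  if (target_delta > dmax) {
    stop(sprintf(paste0("target shift %.4f is unattainable at K = %.3g: ",
                        "the maximum delta_c_max over ratios [%.3g, %.3g] ",
                        "is %.4f (at %.3g equivalents)"),
                 target_delta, K, ratio_range[1L], ratio_range[2L], dmax,
                 ratios[imax]), call. = FALSE)
  }
  f <- function(r) delta_at_ratio(K, r) - target_delta
  lo <- if (deltas[1L] >= target_delta) ratios[1L] else {
    stats::uniroot(f, c(ratios[1L], ratios[imax]), tol = 1e-10)$root
  }
  hi <- if (deltas[n_grid] >= target_delta) ratios[n_grid] else {
    stats::uniroot(f, c(ratios[imax], ratios[n_grid]), tol = 1e-10)$root
  }
  list(interval = c(lo, hi), max_delta = dmax, argmax_ratio = ratios[imax])
}
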