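# Closed-form mass-action algebra for nucleoside phosphorolysis:
#   N + P <-> B + P1P,  K = [P1P][B] / ([N][P])
# All concentrations in mM, conversions as fractions in [0,1].

#' Define a phosphorolysis reaction system
#'
#' A reaction system is fully specified by the initial nucleoside
#' concentration `N0`, the initial phosphate concentration `P0` and the
#' dimensionless equilibrium constant `K` of the phosphorolysis reaction.
#' Initial product concentrations (nucleobase, pentose-1-phosphate) are
#' zero by construction.
#'
#' @param N0 Initial nucleoside concentration (mM), > 0.
#' @param P0 Initial phosphate concentration (mM), > 0.
#' @param K Dimensionless equilibrium constant
#'   \eqn{K = [P1P][B]/([N][P])}, > 0. Natural nucleosides fall in
#'   roughly 0.01-0.8; uridine has K = 0.15 at 37 degC, pH 7.5.
#' @return An object of class `reaction_system`.
#' @examples
#' uridine <- reaction_system(N0 = 2, P0 = 8, K = 0.15)
#' solve_equilibrium_conversion(uridine)
#' @export
reaction_system <- function(N0, P0, K) {
  for (nm in c("N0", "P0", "K")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single finite positive number, got: ",
           deparse(substitute(x)), " = ", format(x), call. = FALSE)
    }
  }
  structure(list(N0 = as.numeric(N0), P0 = as.numeric(P0), K = as.numeric(K)),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system>  N0 =", format(x$N0), "mM,  P0 =", format(x$P0),
      "mM,  K =", format(x$K),
      sprintf(" (P0/N0 = %.3g equivalents)\n", x$P0 / x$N0))
  invisible(x)
}

as_reaction_system <- function(system) {
  if (!inherits(system, "reaction_system")) {
    stop("`system` must be created with reaction_system()", call. = FALSE)
  }
  system
}

# Admissible root of the post-hydrolysis mass-action quadratic
#   N0 (1-K) c^2 + [K (N0+P0) + h (K-1)] c - K (P0 + h) = 0
# (h = 0 gives the pre-hydrolysis equilibrium). The physically admissible
# conversion lies in [max(0, h/N0), min(1, (P0+h)/N0)]: B <= N0 and both
# products of the shifted state non-negative. Root picked by interval
# membership (not by discriminant branch, which breaks for K > 1);
# uniqueness asserted. K = 1 collapses to the linear case.
shift_conversion_root <- function(N0, P0, K, h) {
  a <- N0 * (1 - K)
  b <- K * (N0 + P0) + h * (K - 1)
  d <- -K * (P0 + h)
  lo <- max(0, h / N0)
  hi <- min(1, (P0 + h) / N0)
  if (abs(a) <= 1e-14 * N0 * max(1, K)) {
    roots <- -d / b
  } else {
    disc <- b^2 - 4 * a * d
    if (disc < 0) {
      stop("no real equilibrium conversion for N0=", N0, ", P0=", P0,
           ", K=", K, ", h=", h, call. = FALSE)
    }
    # numerically stable quadratic roots (avoid cancellation)
    q <- -0.5 * (b + sign(b + (b == 0)) * sqrt(disc))
    roots <- c(q / a, d / q)
  }
  tol <- 1e-12
  ok <- roots >= lo - tol & roots <= hi + tol & is.finite(roots)
  if (sum(ok) == 0L) {
    stop("no admissible equilibrium conversion in [", format(lo), ", ",
         format(hi), "] for N0=", N0, ", P0=", P0, ", K=", K, ", h=", h,
         call. = FALSE)
  }
  cands <- unique(signif(roots[ok], 15))
  if (length(cands) > 1L) {
    stop("equilibrium conversion not unique in the physical interval ",
         "(roots ", paste(format(roots[ok]), collapse = ", "), ")",
         call. = FALSE)
  }
  min(max(roots[ok][1L], lo), hi)
}

#' Equilibrium conversion of the pre-hydrolysis phosphorolysis reaction
#'
#' Solves the law of mass action under the pre-hydrolysis mass balances
#' (\eqn{B = P1P = c N0}, \eqn{N = N0 - cN0}, \eqn{P = P0 - cN0}), i.e. the
#' quadratic \eqn{N0(1-K)c^2 + K(N0+P0)c - K P0 = 0}, for the physically
#' admissible degree of conversion c1.
#'
#' @param system A [reaction_system()].
#' @return The equilibrium conversion c1, a fraction in \[0, 1).
#' @examples
#' solve_equilibrium_conversion(reaction_system(2, 8, 0.15)) # ~0.508
#' @export
solve_equilibrium_conversion <- function(system) {
  system <- as_reaction_system(system)
  shift_conversion_root(system$N0, system$P0, system$K, h = 0)
}

#' Equilibrium constant from a measured equilibrium conversion
#'
#' Exact closed-form inverse of [solve_equilibrium_conversion()]:
#' \eqn{K = c1^2 N0 / ((1 - c1)(P0 - c1 N0))}.
#'
#' @param c1 Measured pre-hydrolysis equilibrium conversion, in \[0, 1).
#' @param N0,P0 Initial nucleoside and phosphate concentrations (mM).
#' @return The dimensionless equilibrium constant K.
#' @examples
#' estimate_K_from_equilibrium(0.5, N0 = 2, P0 = 8) # 1/7
#' @export
estimate_K_from_equilibrium <- function(c1, N0, P0) {
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) || c1 < 0 || c1 >= 1) {
    stop("`c1` must be a single fraction in [0, 1)", call. = FALSE)
  }
  if (N0 <= 0 || P0 <= 0) stop("N0 and P0 must be positive", call. = FALSE)
  if (c1 == 0) {
    warning("c1 = 0 carries no information about K; returning 0")
    return(0)
  }
  if (c1 * N0 >= P0) {
    stop("infeasible conversion: c1*N0 >= P0 (phosphate overdrawn)",
         call. = FALSE)
  }
  c1^2 * N0 / ((1 - c1) * (P0 - c1 * N0))
}

#' Hydrolyzed sugar phosphate from a shifted equilibrium conversion
#'
#' When a fraction of the pentose-1-phosphate is lost to hydrolysis and the
#' phosphorolysis reaction is allowed to re-equilibrate, the new conversion
#' c2 exceeds the original c1. Inserting the shifted mass balances
#' (\eqn{P1P = c2 N0 - h}, \eqn{B = c2 N0}, \eqn{N = N0 - c2 N0},
#' \eqn{P = P0 - c2 N0 + h}) into the law of mass action and solving for the
#' hydrolyzed amount h gives the closed form
#' \deqn{h = \frac{c2^2 N0 - K (1 - c2)(P0 - c2 N0)}{K (1 - c2) + c2}.}
#'
#' Measurement noise can place c2 slightly below the unshifted equilibrium
#' c1, which maps to a slightly negative h. By default such values are
#' clamped to 0 when they exceed `-tol`, and rejected as inconsistent
#' below `-tol`. For kinetic fitting of noisy series set `clamp = FALSE`
#' (with a suitably widened `tol`) to keep the noise symmetric in h-space.
#'
#' @param c2 Post-hydrolysis equilibrium conversion, a fraction in (0, 1).
#' @param system A [reaction_system()].
#' @param tol Tolerance (mM) for negative inferred amounts; default
#'   `1e-3 * N0`.
#' @param clamp If `TRUE` (default), clamp inferred amounts in `[-tol, 0)`
#'   to 0; if `FALSE`, return the raw value (still erroring below `-tol`).
#' @return Hydrolyzed pentose-1-phosphate h (mM).
#' @examples
#' sys <- reaction_system(2, 8, 0.15)
#' hydrolyzed_amount(0.72, sys) # ~1 mM: full hydrolysis of the Rib1P pool
#' @export
hydrolyzed_amount <- function(c2, system, tol = NULL, clamp = TRUE) {
  system <- as_reaction_system(system)
  if (is.null(tol)) tol <- 1e-3 * system$N0
  if (!is.numeric(c2) || length(c2) != 1L || !is.finite(c2) ||
      c2 <= 0 || c2 >= 1) {
    stop("`c2` must be a single fraction in (0, 1)", call. = FALSE)
  }
  N0 <- system$N0; P0 <- system$P0; K <- system$K
  h <- (c2^2 * N0 - K * (1 - c2) * (P0 - c2 * N0)) / (K * (1 - c2) + c2)
  if (h < -tol) {
    stop(sprintf(paste0("inconsistent measurement: c2 = %.6g sits below the ",
                        "unshifted equilibrium (inferred h = %.4g mM < -tol ",
                        "= %.4g mM)"), c2, h, -tol), call. = FALSE)
  }
  if (clamp && h < 0) h <- 0
  if (h > c2 * N0 + tol) {
    stop(sprintf(paste0("inconsistent measurement: inferred h = %.4g mM ",
                        "exceeds the nucleobase formed (c2*N0 = %.4g mM)"),
                 h, c2 * N0), call. = FALSE)
  }
  h
}

#' Joint determination of K and the hydrolyzed amount
#'
#' When the first (pre-hydrolysis) equilibrium is monitored as well, K need
#' not be known in advance: it is estimated from c1 via
#' [estimate_K_from_equilibrium()] and the hydrolyzed amount then follows
#' from c2 via [hydrolyzed_amount()].
#'
#' @param c1 Pre-hydrolysis equilibrium conversion, in (0, 1).
#' @param c2 Post-hydrolysis equilibrium conversion, `c1 <= c2 < 1`.
#' @param N0,P0 Initial concentrations (mM).
#' @param tol Tolerance passed to [hydrolyzed_amount()] (also used to judge
#'   `c2 < c1`, on the conversion scale as `tol / N0`).
#' @return A list with elements `K` and `h` (mM).
#' @export
hydrolyzed_amount_joint <- function(c1, c2, N0, P0, tol = 1e-3 * N0) {
  if (!is.numeric(c1) || length(c1) != 1L || c1 <= 0 || c1 >= 1) {
    stop("`c1` must be a single fraction in (0, 1)", call. = FALSE)
  }
  if (c2 < c1 - tol / N0) {
    stop("inconsistent measurements: c2 < c1 (equilibrium cannot shift back)",
         call. = FALSE)
  }
  K <- estimate_K_from_equilibrium(c1, N0, P0)
  system <- reaction_system(N0, P0, K)
  h <- if (c2 <= c1) 0 else hydrolyzed_amount(c2, system, tol = tol)
  list(K = K, h = h)
}

#' Maximum attainable equilibrium shift
#'
#' Under full hydrolysis of the initially generated sugar phosphate
#' (\eqn{h = c1 N0}), the post-hydrolysis conversion reaches its ceiling
#' c2max, the admissible root of
#' \deqn{N0 (1-K) c^2 + X c - K (P0 + c1 N0) = 0, \quad
#'       X = c1 N0 K - c1 N0 + N0 K + K P0.}
#' The maximum apparent shift is `delta_c_max = c2_max - c1`. The K = 1
#' degeneracy is solved linearly as \eqn{c = K (P0 + c1 N0) / X}.
#'
#' @param c1 Pre-hydrolysis equilibrium conversion, in \[0, 1). Usually
#'   [solve_equilibrium_conversion()] of the same system, but a measured
#'   value may be supplied.
#' @param system A [reaction_system()].
#' @return An object of class `shift_window`: list with `c1`, `c2_max`,
#'   `delta_c_max`.
#' @examples
#' max_shift(0.50, reaction_system(2, 8, 0.15)) # c2_max ~ 0.72
#' @export
max_shift <- function(c1, system) {
  system <- as_reaction_system(system)
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) ||
      c1 < 0 || c1 >= 1) {
    stop("`c1` must be a single fraction in [0, 1)", call. = FALSE)
  }
  c2max <- shift_conversion_root(system$N0, system$P0, system$K,
                                 h = c1 * system$N0)
  structure(list(c1 = c1, c2_max = c2max, delta_c_max = c2max - c1),
            class = "shift_window")
}

#' @export
print.shift_window <- function(x, ...) {
  cat(sprintf(
    "<shift_window>  c1 = %.4f   c2_max = %.4f   delta_c_max = %.4f (%.1f pp)\n",
    x$c1, x$c2_max, x$delta_c_max, 100 * x$delta_c_max))
  invisible(x)
}

#' Equilibrium conversion after a given hydrolytic loss (forward model)
#'
#' Exact inverse of [hydrolyzed_amount()]: given the cumulative hydrolyzed
#' amount h, returns the conversion c2 at which the re-equilibrated system
#' settles — the admissible root of
#' \eqn{N0(1-K)c^2 + [K(N0+P0) + h(K-1)]c - K(P0+h) = 0}.
#' This is the forward model used by the simulator; `h = 0` returns the
#' unshifted equilibrium conversion.
#'
#' @param h Hydrolyzed pentose-1-phosphate (mM), in \[0, c1*N0\].
#' @param system A [reaction_system()].
#' @return The post-hydrolysis equilibrium conversion c2.
#' @examples
#' sys <- reaction_system(2, 8, 0.15)
#' conversion_after_hydrolysis(1.0, sys) # ~0.7202, the 72 % ceiling
#' @export
conversion_after_hydrolysis <- function(h, system) {
  system <- as_reaction_system(system)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0) {
    stop("`h` must be a single non-negative amount (mM)", call. = FALSE)
  }
  c1 <- solve_equilibrium_conversion(system)
  hmax <- c1 * system$N0
  if (h > hmax * (1 + 1e-9) + 1e-12) {
    stop(sprintf(paste0("h = %.6g mM exceeds the full-hydrolysis bound ",
                        "c1*N0 = %.6g mM"), h, hmax), call. = FALSE)
  }
  h <- min(h, hmax)
  c2 <- shift_conversion_root(system$N0, system$P0, system$K, h = h)
  if (c2 * system$N0 < h - 1e-9 * system$N0) {
    stop("internal inconsistency: resulting state has negative sugar phosphate",
         call. = FALSE)
  }
  c2
}

#' Full equilibrium state at a given conversion and hydrolyzed amount
#'
#' Expands a conversion (and optional cumulative hydrolyzed amount) into all
#' four reagent concentrations via the mass balances
#' \eqn{B = c N0}, \eqn{N = N0 - B}, \eqn{P1P = B - h},
#' \eqn{P = P0 - B + h}.
#'
#' @param system A [reaction_system()].
#' @param c Conversion fraction in \[0, 1\].
#' @param h Cumulative hydrolyzed pentose-1-phosphate (mM), default 0.
#' @return An object of class `equilibrium_state`: list with `c`, `N`, `B`,
#'   `P`, `P1P`, `h`.
#' @export
equilibrium_state <- function(system, c, h = 0) {
  system <- as_reaction_system(system)
  if (c < 0 || c > 1) stop("`c` must be in [0, 1]", call. = FALSE)
  if (h < 0) stop("`h` must be non-negative", call. = FALSE)
  B <- c * system$N0
  st <- list(c = c, N = system$N0 - B, B = B, P = system$P0 - B + h,
             P1P = B - h, h = h)
  if (st$P1P < -1e-9 * system$N0 || st$P < -1e-9 * system$P0) {
    stop("state violates non-negativity of concentrations", call. = FALSE)
  }
  structure(st, class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_state>  c = %.4f  N = %.4g  B = %.4g  P = %.4g  P1P = %.4g  h = %.4g (mM)\n",
    x$c, x$N, x$B, x$P, x$P1P, x$h))
  invisible(x)
}
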