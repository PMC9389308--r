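# Core LMS (Box-Cox) standardization math. All functions are pure,
# vectorized, and deterministic.

# Switch point for the L -> 0 limit of the Box-Cox transform. Well below the
# resolution of any tabulated L, well above double-precision noise.
.L_EPS <- 1e-7

#' LMS z-score (standard deviation score)
#'
#' Converts a measurement `x` to a standard deviation score under the LMS
#' model: `z = ((x/M)^L - 1) / (L * S)` for `|L| >= 1e-7`, and the Box-Cox
#' limit `z = log(x/M) / S` as `L -> 0`. `M` is the reference median in
#' measurement units, `S` the coefficient of variation, `L` the Box-Cox
#' power that removes age-specific skewness.
#'
#' @param x measurement (same units as `M`); must be positive.
#' @param L Box-Cox power (dimensionless).
#' @param M reference median; must be positive.
#' @param S coefficient of variation; must be positive.
#' @return z-score (SDS), dimensionless. Vectorized over all arguments.
#' @examples
#' lms_z(11, L = 1, M = 10, S = 0.1)  # 1
#' lms_z(10 * exp(0.2), L = 0, M = 10, S = 0.1)  # 2
#' @seealso [lms_value()] for the inverse, [z_to_centile()].
#' @export
lms_z <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(x)) || any(x <= 0)) stop("`x` must be positive and finite")
  if (any(!is.finite(M)) || any(M <= 0)) stop("`M` must be positive and finite")
  if (any(!is.finite(S)) || any(S <= 0)) stop("`S` must be positive and finite")
  z <- numeric(n)
  bc <- abs(L) >= .L_EPS
  z[bc] <- ((x[bc] / M[bc])^L[bc] - 1) / (L[bc] * S[bc])
  z[!bc] <- log(x[!bc] / M[!bc]) / S[!bc]
  z
}

#' Inverse LMS: measurement at a given z-score
#'
#' Returns the measurement value sitting at z-score `z` of the reference
#' distribution: `x = M * (1 + L*S*z)^(1/L)` (`|L| >= 1e-7`) or
#' `x = M * exp(S*z)` in the `L -> 0` limit. Used to draw centile curves
#' and to simulate measurements with known true z.
#'
#' @inheritParams lms_z
#' @param z z-score (SDS).
#' @return measurement in the units of `M`.
#' @export
lms_value <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(z))) stop("`z` must be finite")
  if (any(!is.finite(M)) || any(M <= 0)) stop("`M` must be positive and finite")
  if (any(!is.finite(S)) || any(S <= 0)) stop("`S` must be positive and finite")
  x <- numeric(n)
  bc <- abs(L) >= .L_EPS
  arg <- 1 + L[bc] * S[bc] * z[bc]
  if (any(arg <= 0)) {
    stop("domain error: 1 + L*S*z must be positive (first violation at z = ",
         format(z[bc][which(arg <= 0)[1]]), ")")
  }
  x[bc] <- M[bc] * arg^(1 / L[bc])
  x[!bc] <- M[!bc] * exp(S[!bc] * z[!bc])
  x
}

#' Convert between z-scores and centiles
#'
#' Centiles relate to z-scores through the standard normal distribution:
#' `centile = 100 * pnorm(z)`. The two functions are mutual inverses on
#' (0, 100).
#'
#' @param z z-score (SDS).
#' @return `z_to_centile()`: centile in percent, in (0, 100).
#' @export
z_to_centile <- function(z) {
  if (any(!is.finite(z))) stop("`z` must be finite")
  100 * stats::pnorm(z)
}

#' @rdname z_to_centile
#' @param p centile in percent, strictly inside (0, 100).
#' @return `centile_to_z()`: the z-score whose centile is `p`.
#' @export
centile_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100)) {
    stop("centile `p` must lie strictly inside (0, 100)")
  }
  stats::qnorm(p / 100)
}

#' Approximate SDS from two centile curves
#'
#' A fallback scorer for references published only as centile curves: the
#' distance of `x` from the median, in units of half the gap between the
#' 50th and 3rd centiles, `(x - P50) / (0.5 * (P50 - P3))`. It is exact at
#' the median (0) and pins the 3rd centile at -2; since the true z at the
#' 3rd centile is -1.8808, the approximation overstates |SDS| by a factor
#' 2/1.8808 there. The pipeline's primary scorer is the exact [lms_z()].
#'
#' @param x measurement.
#' @param p50,p3 reference values of the 50th and 3rd centile at the
#'   child's age and sex; `p3 < p50` required.
#' @return approximate SDS, linear in `x`.
#' @export
approx_sds <- function(x, p50, p3) {
  n <- max(length(x), length(p50), length(p3))
  x <- rep_len(x, n); p50 <- rep_len(p50, n); p3 <- rep_len(p3, n)
  if (any(p3 >= p50)) stop("require P3 < P50 at every evaluation point")
  (x - p50) / (0.5 * (p50 - p3))
}

#' Body mass index
#'
#' `weight / height^2` in kg/m^2. Heights are measured and stored in cm
#' throughout the package; this is the one place they are converted to
#' metres, via [cm_to_m()].
#'
#' @param weight_kg body weight in kilograms, positive.
#' @param height_m body height in metres, positive.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(20, 1.0)           # 20
#' bmi(65, cm_to_m(165))  # 23.88
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("`weight_kg` must be positive")
  }
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("`height_m` must be positive")
  }
  weight_kg / height_m^2
}

#' @rdname bmi
#' @param height_cm height in centimetres.
#' @return `cm_to_m()`: height in metres.
#' @export
cm_to_m <- function(height_cm) height_cm / 100
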