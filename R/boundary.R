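#' Intersection of the background and expressed mixture components
#'
#' Solves \eqn{\pi_2 N(x; \mu_2, \sigma_2) = \pi_3 N(x; \mu_3, \sigma_3)} for
#' the point between the two component means where the weighted densities of
#' the low-abundance background component and the expressed component are
#' equal. In log2(TPM+1) space this point is the expressed-gene decision
#' boundary used to validate the conventional TPM = 1 cutoff.
#'
#' Taking logs turns the equation into a quadratic in \eqn{x}; the root lying
#' in the open interval \eqn{(\mu_2, \mu_3)} is selected (a bisection fallback
#' guards against numerically ill-conditioned coefficients).
#'
#' @param weights Component weights. Either the last two entries of the full
#'   3-vector \eqn{(\pi_1,\pi_2,\pi_3)} or a length-2 vector
#'   \eqn{(\pi_2,\pi_3)}. Only the ratio matters.
#' @param means Component means, same convention as `weights`; must satisfy
#'   \eqn{\mu_2 < \mu_3}.
#' @param sds Component standard deviations, same convention; all positive.
#' @return The boundary location (a single numeric) in the same units as
#'   `means`.
#' @section Errors:
#' Throws a condition of class `tpmeta_degenerate` when \eqn{\mu_2 = \mu_3}
#' and `tpmeta_no_boundary` when no root lies strictly inside
#' \eqn{(\mu_2, \mu_3)}.
#' @examples
#' analytic_boundary(c(0.5, 0.5), c(1, 3), c(0.4, 0.4)) # symmetric: 2
#' @export
analytic_boundary <- function(weights, means, sds) {
  pick23 <- function(v, nm) {
    if (length(v) == 3L) v[2:3]
    else if (length(v) == 2L) v
    else tpmeta_stop("tpmeta_bad_args", sprintf("'%s' must have length 2 or 3", nm))
  }
  w <- pick23(weights, "weights")
  m <- pick23(means, "means")
  s <- pick23(sds, "sds")
  if (any(!is.finite(c(w, m, s))) || any(w <= 0) || any(s <= 0))
    tpmeta_stop("tpmeta_bad_args",
                "weights and sds must be finite and positive")
  if (m[1] == m[2])
    tpmeta_stop("tpmeta_degenerate",
                "component means are equal: no separating boundary")
  if (m[1] > m[2])
    tpmeta_stop("tpmeta_bad_args", "background mean must be below expressed mean")

  # log pi2 phi(x; m2, s2) - log pi3 phi(x; m3, s3) = 0  <=>  ax^2 + bx + c = 0
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- m[1] / s[1]^2 - m[2] / s[2]^2
  cc <- m[2]^2 / (2 * s[2]^2) - m[1]^2 / (2 * s[1]^2) +
    log(w[1] * s[2]) - log(w[2] * s[1])

  f <- function(x) {
    log(w[1]) + dnorm(x, m[1], s[1], log = TRUE) -
      log(w[2]) - dnorm(x, m[2], s[2], log = TRUE)
  }

  roots <- numeric(0)
  if (abs(a) < 1e-14) {
    if (abs(b) > 0) roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m[1] & roots < m[2]]

  if (length(inside) == 0L) {
    # closed form found nothing usable; bisect if the weighted log-density
    # difference changes sign across the interval
    eps <- (m[2] - m[1]) * 1e-9
    lo <- m[1] + eps
    hi <- m[2] - eps
    if (sign(f(lo)) * sign(f(hi)) < 0) {
      inside <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    } else {
      tpmeta_stop("tpmeta_no_boundary",
                  "no interior boundary between background and expressed components")
    }
  }
  if (length(inside) > 1L) {
    # keep the crossing where background dominance gives way to expression
    # (density difference decreasing through zero)
    slope <- vapply(inside, function(x) f(x + 1e-7) - f(x - 1e-7), numeric(1))
    inside <- if (any(slope < 0)) inside[slope < 0][1] else inside[1]
  }
  unname(inside)
}
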