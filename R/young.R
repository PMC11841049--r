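#' Bundled reference wetting measurements for the water/dodecane model
#'
#' Reference values measured for the bundled force field in long
#' (10 x 10 x 200, 10^6-step) simulations, used by the prediction
#' examples and as regression anchors for the scaled-down protocols:
#'
#' * `gamma_12`: the water/dodecane interfacial tension, 27.3 mN/m
#'   (standard error 0.4).
#' * `surface_energies`: substrate surface energies \eqn{\gamma_{s,\alpha}}
#'   in mN/m for wall amplitudes \eqn{A_s} = 0 to 50, per fluid.
#' * `contact_angles`: Young-equation and explicit-droplet contact angles
#'   (degrees) for dodecane droplets in water at selected amplitude
#'   combinations.
#' * `sam`: experimental contact angles of water droplets in dodecane on
#'   silica bearing mixed OH/CH3 monolayers, the inverted water-wall
#'   amplitudes, and the angles simulated with them.
#'
#' @return a list with elements `gamma_12`, `gamma_12_se`,
#'   `surface_energies`, `contact_angles` and `sam`
#' @export
reference_wetting_data <- function() {
  list(
    gamma_12 = 27.3,
    gamma_12_se = 0.4,
    surface_energies = data.frame(
      A_s = c(0, 10, 20, 30, 40, 50),
      dodecane = c(-77.1, 38.5, 102.8, 132.8, 147.9, 158.9),
      dodecane_err = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
      water = c(-64.7, 28.5, 89.8, 123.1, 143.3, 156.4),
      water_err = c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4)),
    contact_angles = data.frame(
      A_s_wat = c(10, 30, 30, 40, 40, 40, 50, 50),
      A_s_dod = c(10, 30, 40, 30, 40, 50, 40, 50),
      theta_young = c(111, 111, 155, 67, 100, 125, 72, 95),
      theta_droplet = c(108, 105, 141, 64, 99, 122, 72, 94)),
    sam = data.frame(
      oh_fraction = c(0.72, 0.48, 0.22),
      theta_exp = c(51, 95, 139),
      A_s_wat = c(27, 35, 48),
      theta_sim = c(56, 97, 142))
  )
}

#' Contact angle from the Young equation
#'
#' \deqn{\cos\theta = (\gamma_{s1} - \gamma_{s2}) / \gamma_{12}}
#' where phase 2 is the droplet and phase 1 the surrounding bath. The
#' angle is defined only under partial wetting,
#' \eqn{|\gamma_{s1} - \gamma_{s2}| < \gamma_{12}}; outside that window
#' the droplet spreads or detaches and this function raises an error
#' (classify with [spreading_regime()] first).
#'
#' @param gamma_12 bath/droplet interfacial tension (> 0), any tension
#'   unit as long as all three arguments share it
#' @param gamma_s1 substrate surface energy of the bath phase
#' @param gamma_s2 substrate surface energy of the droplet phase
#' @return contact angle(s) in degrees
#' @examples
#' young_angle(27.3, 28.5, 38.5)   # ~111 deg
#' @export
young_angle <- function(gamma_12, gamma_s1, gamma_s2) {
  stopifnot(all(gamma_12 > 0))
  ct <- (gamma_s1 - gamma_s2) / gamma_12
  if (any(abs(ct) > 1))
    stop("|gamma_s1 - gamma_s2| >= gamma_12: no finite contact angle; ",
         "use spreading_regime() to classify")
  acos(ct) * 180 / pi
}

#' de Gennes spreading parameter and wetting regime
#'
#' \deqn{S = \gamma_{s1} - \gamma_{s2} - \gamma_{12}.}
#' With phase 2 the droplet: `S > 0` means the droplet spreads out
#' (complete wetting), `S < -2 gamma_12` means it detaches from the
#' substrate, and in between the droplet sits with the finite angle
#' \eqn{\cos\theta = 1 + S/\gamma_{12}}. The boundaries are classified as
#' `"spread"` boundary \eqn{\theta = 0} and `"detach-threshold"`
#' \eqn{\theta = 180^\circ}.
#'
#' @inheritParams young_angle
#' @return data frame with columns `S`, `regime` (factor: spread,
#'   partial, detach-threshold, detach) and `theta_deg` (NA outside
#'   partial wetting)
#' @export
spreading_regime <- function(gamma_12, gamma_s1, gamma_s2) {
  stopifnot(all(gamma_12 > 0))
  S <- gamma_s1 - gamma_s2 - gamma_12
  regime <- ifelse(S > 0, "spread",
                   ifelse(S < -2 * gamma_12, "detach",
                          ifelse(S == -2 * gamma_12, "detach-threshold",
                                 "partial")))
  ct <- 1 + S / gamma_12
  theta <- ifelse(regime %in% c("partial", "detach-threshold"),
                  acos(pmax(-1, pmin(1, ct))) * 180 / pi, NA_real_)
  data.frame(S = S,
             regime = factor(regime, levels = c("spread", "partial",
                                                "detach-threshold",
                                                "detach")),
             theta_deg = theta)
}

#' Cubic fit of surface energy versus wall amplitude
#'
#' Ordinary least-squares third-degree polynomial
#' \eqn{\gamma_s(A_s) = c_0 + c_1 A_s + c_2 A_s^2 + c_3 A_s^3} through
#' the measured (amplitude, surface-energy) points. The dependence is
#' smooth enough that six points over 0-50 give a coefficient of
#' determination of 0.9999 for both bundled fluids.
#'
#' @param A_s wall amplitudes (strictly increasing, >= 4 points)
#' @param gamma_s surface energies (mN/m)
#' @return an object of class `gamma_fit`: `coefficients` (c0..c3),
#'   `r_squared`, the data, and `predict(fit, A)` support
#' @examples
#' se <- reference_wetting_data()$surface_energies
#' fit <- fit_gamma_cubic(se$A_s, se$water)
#' round(fit$r_squared, 4)
#' @export
fit_gamma_cubic <- function(A_s, gamma_s) {
  if (is.data.frame(A_s)) {
    gamma_s <- A_s[[2]]
    A_s <- A_s[[1]]
  }
  stopifnot(length(A_s) == length(gamma_s))
  if (length(A_s) < 4)
    stop("cubic fit requires at least 4 points")
  if (any(diff(A_s) <= 0))
    stop("amplitudes must be strictly increasing")
  fit <- lm(gamma_s ~ A_s + I(A_s^2) + I(A_s^3))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((gamma_s - mean(gamma_s))^2)
  out <- list(coefficients = unname(coef(fit)),
              r_squared = 1 - ss_res / ss_tot,
              A_s = A_s, gamma_s = gamma_s)
  class(out) <- "gamma_fit"
  out
}

#' @export
predict.gamma_fit <- function(object, A_s, ...) {
  cf <- object$coefficients
  cf[1] + cf[2] * A_s + cf[3] * A_s^2 + cf[4] * A_s^3
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "Cubic surface-energy fit over A_s in [%g, %g]: R^2 = %.6f\n",
    min(x$A_s), max(x$A_s), x$r_squared))
  cat("  coefficients (c0..c3):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Contact-angle and wetting-regime map over wall amplitudes
#'
#' Evaluates the Young equation and the spreading parameter on a grid of
#' (bath amplitude, droplet amplitude) pairs using fitted or tabulated
#' surface energies per side. The partial-wetting band is the region
#' \eqn{-2\gamma_{12} < S < 0}; its boundaries are the level sets S = 0
#' (spreading) and S = -2 gamma_12 (detachment). With two different
#' fluids the map is asymmetric about the diagonal because the two
#' \eqn{\gamma_s(A_s)} curves differ.
#'
#' @param fit_1 surface-energy model for the bath side: a `gamma_fit` or
#'   a function of the amplitude
#' @param fit_2 surface-energy model for the droplet side
#' @param gamma_12 interfacial tension (same units as the fits)
#' @param A_1,A_2 amplitude grids
#' @return an object of class `wetting_map`: matrices `theta_deg`, `S`
#'   and `regime` over the grid
#' @export
predict_angle_map <- function(fit_1, fit_2, gamma_12,
                              A_1 = seq(0, 50, by = 1),
                              A_2 = seq(0, 50, by = 1)) {
  g1 <- if (is.function(fit_1)) fit_1(A_1) else predict(fit_1, A_1)
  g2 <- if (is.function(fit_2)) fit_2(A_2) else predict(fit_2, A_2)
  S <- outer(g1, g2, function(a, b) a - b - gamma_12)
  reg <- spreading_regime(gamma_12, rep(g1, times = length(g2)),
                          rep(g2, each = length(g1)))
  theta <- matrix(reg$theta_deg, length(A_1), length(A_2))
  regime <- matrix(as.character(reg$regime), length(A_1), length(A_2))
  out <- list(A_1 = A_1, A_2 = A_2, theta_deg = theta, S = S,
              regime = regime, gamma_12 = gamma_12)
  class(out) <- "wetting_map"
  out
}

#' @export
print.wetting_map <- function(x, ...) {
  tab <- table(factor(x$regime))
  cat(sprintf("Wetting map on a %d x %d amplitude grid (gamma_12 = %g)\n",
              length(x$A_1), length(x$A_2), x$gamma_12))
  cat("  regimes:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @param x a `wetting_map`
#' @param ... passed to [graphics::image()]
#' @rdname predict_angle_map
#' @export
plot.wetting_map <- function(x, ...) {
  graphics::image(x$A_1, x$A_2, x$theta_deg,
                  xlab = "bath-side amplitude A_s,1",
                  ylab = "droplet-side amplitude A_s,2",
                  main = "Young contact angle [deg]", ...)
  graphics::contour(x$A_1, x$A_2, x$S, levels = c(-2 * x$gamma_12, 0),
                    add = TRUE, lwd = 2, labels = c("detach", "spread"))
  invisible(x)
}

#' Invert the Young equation for a wall amplitude
#'
#' Given a target contact angle, the interfacial tension and the surface
#' energy of the fixed side, the required surface energy of the free side
#' follows in closed form from the Young equation; the amplitude is then
#' the root of the fitted cubic \eqn{\gamma_s(A_s) = \gamma_{target}}
#' found by bracketed root-finding on the search interval. This is the
#' workflow used to parametrize substrate hydrophobicity from measured
#' contact angles without explicit droplet simulations.
#'
#' @param theta_target target contact angle in degrees
#' @param gamma_fixed surface energy of the fixed side (mN/m)
#' @param fit_free a [fit_gamma_cubic()] result for the free side
#' @param gamma_12 interfacial tension (mN/m)
#' @param free_side is the free (solved-for) side the `"droplet"` phase
#'   or the `"bath"` phase?
#' @param interval amplitude search interval
#' @return list with the continuous `amplitude`, the `nearest_integer`
#'   amplitude, the implied `gamma_target`, and `theta_check` (the angle
#'   recovered at the continuous root)
#' @examples
#' ref <- reference_wetting_data()
#' fit <- fit_gamma_cubic(ref$surface_energies$A_s,
#'                        ref$surface_energies$water)
#' # water droplet in dodecane, A_s,dod fixed at 30:
#' invert_for_amplitude(95, 132.8, fit, ref$gamma_12,
#'                      free_side = "droplet")
#' @export
invert_for_amplitude <- function(theta_target, gamma_fixed, fit_free,
                                 gamma_12, free_side = c("droplet", "bath"),
                                 interval = c(0, 50)) {
  free_side <- match.arg(free_side)
  stopifnot(theta_target > 0, theta_target < 180, gamma_12 > 0)
  ct <- cos(theta_target * pi / 180)
  # Young: cos(theta) = (gamma_bath - gamma_droplet)/gamma_12
  gamma_target <- if (free_side == "droplet")
    gamma_fixed - gamma_12 * ct
  else
    gamma_fixed + gamma_12 * ct
  f <- function(a) predict(fit_free, a) - gamma_target
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi))
    stop(sprintf(
      "target angle unreachable: gamma_s in [%.1f, %.1f] cannot equal %.1f",
      predict(fit_free, interval[1]), predict(fit_free, interval[2]),
      gamma_target))
  root <- uniroot(f, interval, tol = 1e-10)$root
  g_free <- predict(fit_free, root)
  theta_check <- if (free_side == "droplet")
    young_angle(gamma_12, gamma_fixed, g_free)
  else
    young_angle(gamma_12, g_free, gamma_fixed)
  list(amplitude = root, nearest_integer = round(root),
       gamma_target = gamma_target, theta_check = theta_check)
}
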