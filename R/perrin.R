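# Steady-state fluorescence polarization and the Perrin analysis.
#
# The Perrin equation relates polarization P, intrinsic polarization P0,
# excited-state lifetime tau and rotational relaxation time rho:
#   (1/P - 1/3) = (1/P0 - 1/3) (1 + 3 tau / rho),
# and rho = 3 eta V / (R T), so (1/P - 1/3) is linear in T/eta. rho is
# recovered from the slope and intercept of that line and reported at a
# reference condition (water, 20 C, by default).

#' Degree of fluorescence polarization
#'
#' \eqn{P = (I_\parallel - G I_\perp) / (I_\parallel + G I_\perp)} with
#' \eqn{G} the grating correction factor; see [gratingFactor()].
#'
#' @param I_par emission intensity with both polarizers vertical.
#' @param I_perp emission intensity with crossed polarizers.
#' @param G grating correction factor (> 0, default 1).
#' @return P. Values above 0.5 (one-photon limit) are flagged with a
#'   warning as unphysical.
#' @examples
#' polarization(3, 1)  # 0.5
#' @export
polarization <- function(I_par, I_perp, G = 1) {
  if (any(I_par < 0) || any(I_perp < 0)) stop("intensities must be >= 0")
  if (G <= 0) stop("grating factor must be > 0")
  tot <- I_par + G * I_perp
  if (any(tot == 0)) stop("polarization undefined: zero total intensity")
  P <- (I_par - G * I_perp) / tot
  if (any(P > 0.5 + 1e-12))
    warning("P > 0.5 exceeds the one-photon excitation limit")
  P
}

#' Grating correction factor
#'
#' \eqn{G = i_\perp / i_\parallel}, measured with horizontally polarized
#' excitation: \eqn{i_\perp} with the emission polarizer vertical and
#' \eqn{i_\parallel} with both polarizers horizontal.
#'
#' @param i_perp,i_par the two correction intensities (> 0).
#' @return G.
#' @export
gratingFactor <- function(i_perp, i_par) {
  if (any(i_perp <= 0) || any(i_par <= 0))
    stop("correction intensities must be > 0")
  i_perp / i_par
}

#' Construct a PolarizationSeries
#'
#' @param temp_K temperatures (K).
#' @param eta_poise solvent viscosities (poise).
#' @param P polarization values.
#' @param tau excited-state lifetime of the dye (ns).
#' @param truth optional list of ground-truth parameters (synthetic
#'   data).
#' @return a \linkS4class{PolarizationSeries}.
#' @export
polarizationSeries <- function(temp_K, eta_poise, P, tau,
                               truth = list()) {
  new("PolarizationSeries",
      data = data.frame(temp_K = temp_K, eta_poise = eta_poise, P = P),
      tau = tau, truth = truth)
}

#' Read a (temp_C or temp_K, eta, P) CSV as a PolarizationSeries
#'
#' @param file CSV with header; columns \code{temp_K} (or \code{temp_C})
#'   and \code{eta_poise}, \code{P}.
#' @param tau dye lifetime (ns).
#' @return a \linkS4class{PolarizationSeries}.
#' @export
readPolarizationSeries <- function(file, tau) {
  d <- utils::read.csv(file)
  tk <- if ("temp_K" %in% names(d)) d$temp_K else d$temp_C + 273.15
  polarizationSeries(tk, d$eta_poise, d$P, tau)
}

#' Fit a Perrin plot and extract the rotational relaxation time
#'
#' Ordinary least squares of \eqn{(1/P - 1/3)} on \eqn{T/\eta}. The
#' intrinsic polarization is \eqn{P_0 = 1/(a + 1/3)} with \eqn{a} the
#' intercept, and the rotational relaxation time at the reference
#' condition is \eqn{\rho = 3 \tau (a/b) (\eta_{ref}/T_{ref})} with
#' \eqn{b} the slope.
#'
#' @param series a \linkS4class{PolarizationSeries} with >= 3 points and
#'   a known lifetime.
#' @param eta_ref,T_ref reference condition for the reported rho
#'   (default water at 20 C: 0.01002 poise, 293.15 K).
#' @return the series with \code{fit} filled in: \code{slope},
#'   \code{intercept} (and standard errors), \code{P0}, \code{rho_ns}
#'   (Inf, with a warning, when the slope is not positive: a molecule
#'   rigid on the fluorescence timescale), and the reference condition.
#' @seealso [genPerrin()], [sucroseViscosity()]
#' @export
perrinFit <- function(series, eta_ref = .ETA_W20, T_ref = 293.15) {
  stopifnot(is(series, "PolarizationSeries"))
  d <- series@data
  if (nrow(d) < 3) stop("need at least 3 points to fit a Perrin plot")
  if (!length(series@tau)) stop("series has no lifetime tau")
  x <- d$temp_K / d$eta_poise
  if (stats::sd(x) / mean(x) < 1e-10)
    stop("degenerate Perrin abscissa: no spread in T/eta")
  y <- 1 / d$P - 1 / 3
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(suppressWarnings(summary(fit)))  # 0-residual fits are fine
  a <- cf[1, 1]
  b <- cf[2, 1]
  P0 <- 1 / (a + 1 / 3)
  if (b <= 0) {
    warning("non-positive Perrin slope: molecule effectively immobile, ",
            "rho reported as Inf")
    rho <- Inf
    rho_se <- NA_real_
  } else {
    rho <- 3 * series@tau * (a / b) * (eta_ref / T_ref)
    # first-order error propagation on a/b
    rho_se <- rho * sqrt((cf[1, 2] / a)^2 + (cf[2, 2] / b)^2)
  }
  series@fit <- list(slope = b, intercept = a,
                     slope_se = cf[2, 2], intercept_se = cf[1, 2],
                     P0 = P0, rho_ns = rho, rho_se = rho_se,
                     eta_ref = eta_ref, T_ref = T_ref)
  series
}

#' Rotational correlation time from a rotational relaxation time
#'
#' The rotational relaxation time \eqn{\rho} (rotation through 68.4
#' degrees, cos(theta) = 1/e) and the rotational correlation time
#' \eqn{\phi} (rotation through one radian) differ by a factor of 3.
#' The standard Debye relation is \eqn{\rho = 3\phi}; the inverse
#' convention (\eqn{\phi = 3\rho}) circulates in parts of the
#' polarization literature and is available behind the
#' \code{convention} flag.
#'
#' @param rho rotational relaxation time (ns, > 0).
#' @param convention \code{"debye"} (default; \eqn{\phi = \rho/3}) or
#'   \code{"inverse"} (\eqn{\phi = 3\rho}).
#' @return phi in ns.
#' @examples
#' correlationTime(30.9)  # 10.3
#' @export
correlationTime <- function(rho, convention = c("debye", "inverse")) {
  convention <- match.arg(convention)
  if (any(rho <= 0)) stop("rho must be > 0")
  if (convention == "debye") rho / 3 else 3 * rho
}
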