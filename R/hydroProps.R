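# Transport-property relations: the Svedberg equation, s20,w
# standardization, frictional ratios, equivalent-sphere rotational
# relaxation, and ensemble summaries.

.ETA_W20 <- 0.01002     # water at 20 C, poise
.RHO_W20 <- 0.99823     # water at 20 C, g/cm^3
.RGAS <- 8.31446261815324e7  # erg / (mol K)

#' Construct a HydroParams object
#'
#' Defaults describe the standard conditions used throughout: water at
#' 20 C (eta = 1.002 cP, rho = 0.99823 g/cm^3), partial specific volume
#' 0.55 cm^3/g and 0.3 g/g bound water for DNA quadruplexes, and the
#' package's quadruplex-calibrated atomic element radius.
#'
#' @param vbar partial specific volume (cm^3/g).
#' @param hydration bound water (g/g).
#' @param eta solvent viscosity (poise).
#' @param rho_solvent solvent density (g/cm^3).
#' @param temperature absolute temperature (K).
#' @param aer hydrated atomic element radius (Angstrom, in [1.5, 4.5]).
#' @return a \linkS4class{HydroParams}.
#' @export
hydroParams <- function(vbar = 0.55, hydration = 0.3, eta = .ETA_W20,
                        rho_solvent = .RHO_W20, temperature = 293.15,
                        aer = defaultAER()) {
  new("HydroParams", vbar = vbar, hydration = hydration, eta = eta,
      rho_solvent = rho_solvent, temperature = temperature, aer = aer)
}

#' Package default atomic element radius for quadruplex DNA
#'
#' The AER calibrated so that the idealized stacked three-quadruplex
#' reference model reproduces the bead-shell prediction expected for a
#' compact 9-quartet column (see the methods vignette and
#' [calibrateAER()]).
#'
#' @return AER in Angstrom.
#' @export
defaultAER <- function() 2.67

#' Sedimentation coefficient from friction and mass (Svedberg relation)
#'
#' \eqn{s = M (1 - \bar{v}\rho) / (N_A f)}, reported in Svedberg
#' (10^-13 s).
#'
#' @param f_trans translational friction coefficient (g/s, > 0).
#' @param mass molar mass (Da, > 0).
#' @param params a \linkS4class{HydroParams}.
#' @return s in Svedberg.
#' @export
sedimentationCoefficient <- function(f_trans, mass, params = hydroParams()) {
  if (f_trans <= 0) stop("friction coefficient must be > 0")
  if (mass <= 0) stop("mass must be > 0")
  buoy <- 1 - params@vbar * params@rho_solvent
  if (buoy < 0)
    stop("vbar * rho_solvent > 1: the particle floats (negative buoyancy)")
  if (buoy == 0) {
    warning("neutral buoyancy: (1 - vbar * rho) = 0, s = 0")
    return(0)
  }
  mass * buoy / (.NA_AVOG * f_trans) * 1e13
}

#' Standardize an observed sedimentation coefficient to water at 20 C
#'
#' \eqn{s_{20,w} = s_{obs} \frac{\eta_{buffer}}{\eta_{20,w}}
#' \frac{1 - \bar{v}\rho_{20,w}}{1 - \bar{v}\rho_{buffer}}}: the
#' viscosity and temperature/density correction applied to measured
#' sedimentation velocities.
#'
#' @param s_obs observed sedimentation coefficient (Svedberg).
#' @param eta_buffer buffer viscosity (poise, > 0).
#' @param rho_buffer buffer density (g/cm^3, > 0).
#' @param params a \linkS4class{HydroParams} supplying vbar.
#' @return s20,w in Svedberg.
#' @export
s20wStandardize <- function(s_obs, eta_buffer, rho_buffer,
                            params = hydroParams()) {
  if (eta_buffer <= 0 || rho_buffer <= 0)
    stop("buffer viscosity and density must be > 0")
  b_w <- 1 - params@vbar * .RHO_W20
  b_buf <- 1 - params@vbar * rho_buffer
  if (sign(b_w) != sign(b_buf) || b_buf == 0)
    stop("buoyancy term changes sign between buffer and water: ",
         "standardization undefined")
  s_obs * (eta_buffer / .ETA_W20) * (b_w / b_buf)
}

#' Inverse of the s20,w standardization
#'
#' @inheritParams s20wStandardize
#' @param s20w standardized value (Svedberg).
#' @return the value observed in the buffer.
#' @export
s20wDestandardize <- function(s20w, eta_buffer, rho_buffer,
                              params = hydroParams()) {
  b_w <- 1 - params@vbar * .RHO_W20
  b_buf <- 1 - params@vbar * rho_buffer
  s20w / ((eta_buffer / .ETA_W20) * (b_w / b_buf))
}

#' Frictional ratio f/f0 from a sedimentation coefficient
#'
#' \eqn{f = M(1-\bar{v}\rho)/(N_A s)}; \eqn{f_0 = 6\pi\eta R_0} with
#' \eqn{R_0} the radius of the reference sphere of equal mass. With the
#' \code{"anhydrous"} convention \eqn{R_0 = (3 M \bar{v}/4\pi N_A)^{1/3}}
#' (a dry sphere); with \code{"hydrated"}, the sphere volume also carries
#' the bound water \eqn{\delta} (\eqn{\bar{v} + \delta} cm^3/g).
#'
#' @param s sedimentation coefficient (Svedberg, > 0), standardized to
#'   the conditions in \code{params}.
#' @param mass molar mass (Da).
#' @param params a \linkS4class{HydroParams}.
#' @param convention reference-sphere volume convention.
#' @return f/f0 (numeric), with attributes \code{convention} and
#'   \code{R0_A} (reference radius, Angstrom).
#' @export
frictionalRatio <- function(s, mass, params = hydroParams(),
                            convention = c("anhydrous", "hydrated")) {
  convention <- match.arg(convention)
  if (s <= 0) stop("s must be > 0")
  buoy <- 1 - params@vbar * params@rho_solvent
  f <- mass * buoy / (.NA_AVOG * s * 1e-13)
  veff <- if (convention == "anhydrous") params@vbar else
    params@vbar + params@hydration
  R0 <- (3 * mass * veff / (4 * pi * .NA_AVOG))^(1 / 3)
  out <- f / (6 * pi * params@eta * R0)
  attr(out, "convention") <- convention
  attr(out, "R0_A") <- R0 * 1e8
  out
}

#' Rotational relaxation time of the equivalent anhydrous sphere
#'
#' \eqn{\rho_0 = 3 \eta M \bar{v} / (R T)}: the rotational relaxation
#' time of a rigid sphere of the same mass and partial specific volume,
#' without bound solvent.
#'
#' @param mass molar mass (Da, > 0).
#' @param params a \linkS4class{HydroParams}.
#' @return rho0 in ns.
#' @examples
#' equivalentSphereRho0(21632.8)  # ~14.6 ns
#' @export
equivalentSphereRho0 <- function(mass, params = hydroParams()) {
  if (mass < 0) stop("mass must be >= 0")
  3 * params@eta * mass * params@vbar /
    (.RGAS * params@temperature) * 1e9
}

#' Rotational relaxation time from rotational diffusion eigenvalues
#'
#' Isotropic-average convention: \eqn{\rho = 1 / (2 \bar{D}_r)} with
#' \eqn{\bar{D}_r} the mean eigenvalue of the rotational diffusion
#' tensor. For a sphere this equals the Stokes-Einstein-Debye value
#' \eqn{3 \eta V / (R T)} (time to rotate through 68.4 degrees,
#' cos(theta) = 1/e).
#'
#' @param Dr_eig three positive rotational diffusion eigenvalues (1/s).
#' @return rho in ns.
#' @export
rotationalRelaxation <- function(Dr_eig) {
  if (any(!is.finite(Dr_eig)) || any(Dr_eig <= 0))
    stop("rotational diffusion eigenvalues must be positive")
  1 / (2 * mean(Dr_eig)) * 1e9
}

#' Shape/hydration asymmetry ratio rho / rho0
#'
#' @param rho measured or predicted rotational relaxation time (ns).
#' @param rho0 equivalent-sphere value (ns).
#' @return the dimensionless ratio; 1 for an anhydrous sphere, larger
#'   for hydrated and/or asymmetric particles.
#' @export
asymmetryRatio <- function(rho, rho0) {
  if (rho <= 0 || rho0 <= 0) stop("relaxation times must be > 0")
  rho / rho0
}

#' Sedimentation coefficient of the maximally compact hydrated sphere
#'
#' The fastest sedimentation compatible with the mass: a smooth sphere
#' carrying \code{hydration} g/g of bound water.
#'
#' @inheritParams equivalentSphereRho0
#' @return s in Svedberg.
#' @export
maxSphereSedimentation <- function(mass, params = hydroParams()) {
  veff <- params@vbar + params@hydration
  Rh <- (3 * mass * veff / (4 * pi * .NA_AVOG))^(1 / 3)
  f <- 6 * pi * params@eta * Rh
  sedimentationCoefficient(f, mass, params)
}

#' Summarize transport properties over a snapshot ensemble
#'
#' @param results list of \linkS4class{HydroResult} objects (>= 1), e.g.
#'   one per snapshot of a jittered coordinate ensemble.
#' @return data.frame with one row per property (s20w, s, Dt, rho_rot,
#'   f_ratio) giving mean, min, max and range width.
#' @export
ensembleAverage <- function(results) {
  if (!length(results)) stop("empty ensemble")
  if (!all(vapply(results, is, logical(1), "HydroResult")))
    stop("results must be HydroResult objects")
  grab <- function(what) vapply(results, function(r) as.numeric(slot(r, what)[1]),
                                numeric(1))
  props <- c("s20w", "s", "Dt", "rho_rot", "f_ratio")
  out <- do.call(rbind, lapply(props, function(p) {
    v <- grab(p)
    data.frame(property = p, mean = mean(v), min = min(v), max = max(v),
               width = max(v) - min(v))
  }))
  out
}
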