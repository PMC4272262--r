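#' @import methods
NULL

#' CDSpectrum: a wavelength-indexed circular dichroism trace
#'
#' Container for a CD spectrum, either as raw ellipticity (millidegrees,
#' \code{units = "raw"}) or as molar circular dichroism
#' (\eqn{\Delta\epsilon}, L mol^-1 cm^-1, \code{units = "molar"}).
#' Normalization provenance (strand concentration and path length) is kept
#' in \code{meta} once a spectrum has been converted to the molar scale.
#'
#' @slot wavelength numeric, strictly increasing wavelength grid in nm.
#' @slot value numeric, signal at each grid point.
#' @slot units character, one of \code{"raw"} (millidegrees) or
#'   \code{"molar"} (\eqn{\Delta\epsilon}).
#' @slot meta list, free-form provenance; after normalization it records
#'   \code{conc_M} (strand concentration, mol/L) and \code{path_cm}.
#'
#' @seealso [normalizeToMolarCD()], [compositeSpectrum()],
#'   [classifyTopology()]
#' @export
setClass("CDSpectrum",
  representation(wavelength = "numeric", value = "numeric",
                 units = "character", meta = "list"),
  prototype(units = "raw", meta = list()))

setValidity("CDSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@value))
    msg <- c(msg, "wavelength and value must have equal length")
  if (length(object@wavelength) > 1 && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (any(!is.finite(object@value)))
    msg <- c(msg, "values must be finite")
  if (!object@units %in% c("raw", "molar"))
    msg <- c(msg, "units must be 'raw' or 'molar'")
  if (length(msg)) msg else TRUE
})

#' StructureModel: idealized atomic coordinates of a candidate architecture
#'
#' Holds heavy-atom coordinates of an idealized nucleic-acid assembly
#' together with per-residue topology labels (which quartet layer a guanine
#' belongs to, whether a residue is a loop, linker, duplex or flank
#' residue) and the builder parameters that produced it.
#'
#' @slot atoms data.frame with columns \code{atom} (PDB atom name),
#'   \code{element}, \code{resid} (1-based residue index), \code{resname}
#'   (DA/DC/DG/DT), \code{x}, \code{y}, \code{z} (\enc{Å}{Angstrom}).
#' @slot topology data.frame with one row per residue: \code{resid},
#'   \code{role} (\code{"quartet"}, \code{"loop"}, \code{"linker"},
#'   \code{"duplex"}, \code{"flank"}), \code{unit} (structural unit index)
#'   and \code{layer} (quartet layer index, NA otherwise).
#' @slot provenance list of builder parameters (rise, twist, gap, ...).
#'
#' @seealso [buildParallelUnit()], [stackUnits()], [buildBeadsOnString()],
#'   [buildDuplexQuadruplexHybrid()], [writeModelPDB()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", topology = "data.frame",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("StructureModel", function(object) {
  msg <- character()
  need <- c("atom", "element", "resid", "resname", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (!all(c("resid", "role", "unit", "layer") %in% names(object@topology)))
    msg <- c(msg, "topology must have columns resid, role, unit, layer")
  if (nrow(object@atoms) &&
      any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' HydroParams: solvent and particle parameters for hydrodynamic work
#'
#' @slot vbar numeric, partial specific volume (cm^3/g); 0.55 for DNA
#'   quadruplexes.
#' @slot hydration numeric, bound water (g water / g DNA); default 0.3.
#' @slot eta numeric, solvent viscosity in poise (water 20 C: 0.01002).
#' @slot rho_solvent numeric, solvent density (g/cm^3).
#' @slot temperature numeric, absolute temperature (K).
#' @slot aer numeric, hydrated atomic element radius (\enc{Å}{Angstrom})
#'   used when tiling a structure surface with mini-beads.
#'
#' @seealso [hydroParams()], [shellModel()]
#' @export
setClass("HydroParams",
  representation(vbar = "numeric", hydration = "numeric", eta = "numeric",
                 rho_solvent = "numeric", temperature = "numeric",
                 aer = "numeric"))

setValidity("HydroParams", function(object) {
  msg <- character()
  if (object@vbar <= 0) msg <- c(msg, "vbar must be > 0")
  if (object@hydration < 0) msg <- c(msg, "hydration must be >= 0")
  if (object@eta <= 0) msg <- c(msg, "eta must be > 0")
  if (object@rho_solvent <= 0) msg <- c(msg, "rho_solvent must be > 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@aer < 1.5 || object@aer > 4.5)
    msg <- c(msg, "aer must lie in [1.5, 4.5] Angstrom")
  if (length(msg)) msg else TRUE
})

#' HydroResult: rigid-body transport properties of one structure
#'
#' @slot f_trans numeric, orientationally averaged translational friction
#'   coefficient (g/s).
#' @slot Dt numeric, translational diffusion coefficient at the centre of
#'   diffusion (cm^2/s).
#' @slot Dr numeric(3), eigenvalues of the rotational diffusion tensor
#'   (s^-1), descending.
#' @slot s numeric, sedimentation coefficient in Svedberg (10^-13 s).
#' @slot s20w numeric, value standardized to water at 20 C.
#' @slot f_ratio numeric, frictional ratio f/f0 (anhydrous reference
#'   sphere convention unless noted).
#' @slot rho_rot numeric, rotational relaxation time (ns),
#'   isotropic-average convention.
#' @slot conditions list, the \linkS4class{HydroParams} values and mass
#'   used, plus diagnostic fields (bead counts, sigma ladder, anisotropic
#'   relaxation times).
#'
#' @seealso [shellModel()], [ensembleAverage()]
#' @export
setClass("HydroResult",
  representation(f_trans = "numeric", Dt = "numeric", Dr = "numeric",
                 s = "numeric", s20w = "numeric", f_ratio = "numeric",
                 rho_rot = "numeric", conditions = "list"),
  prototype(conditions = list()))

#' PolarizationSeries: a steady-state fluorescence polarization series
#'
#' Measurements of polarization P against temperature in a viscous
#' (sucrose-containing) buffer, the raw material of a Perrin plot.
#'
#' @slot data data.frame with columns \code{temp_K}, \code{eta_poise},
#'   \code{P}.
#' @slot tau numeric, excited-state lifetime of the reporter dye (ns).
#' @slot fit list, filled by [perrinFit()]: slope, intercept, their
#'   standard errors, P0 and rho at the reference condition.
#' @slot truth list, ground-truth parameters when the series is synthetic.
#'
#' @seealso [perrinFit()], [genPerrin()]
#' @export
setClass("PolarizationSeries",
  representation(data = "data.frame", tau = "numeric", fit = "list",
                 truth = "list"),
  prototype(fit = list(), truth = list()))

setValidity("PolarizationSeries", function(object) {
  msg <- character()
  if (!all(c("temp_K", "eta_poise", "P") %in% names(object@data)))
    msg <- c(msg, "data must have columns temp_K, eta_poise, P")
  if (nrow(object@data)) {
    if (any(object@data$temp_K <= 0)) msg <- c(msg, "temperatures must be > 0 K")
    if (any(object@data$eta_poise <= 0)) msg <- c(msg, "viscosities must be > 0")
    if (any(object@data$P < -1 / 3 - 1e-9 | object@data$P > 0.5 + 1e-9))
      msg <- c(msg, "P outside [-1/3, 0.5] is unphysical for one-photon excitation")
  }
  if (length(object@tau) && any(object@tau <= 0))
    msg <- c(msg, "tau must be > 0")
  if (length(msg)) msg else TRUE
})

#' LifetimeData: frequency-domain phase/modulation measurements
#'
#' @slot freq_MHz numeric, modulation frequencies in MHz.
#' @slot phase_deg numeric, phase delay in degrees, in [0, 90).
#' @slot modulation numeric, demodulation ratio in (0, 1].
#' @slot fit list, filled by [lifetimeFit()]: lifetimes \code{tau_ns},
#'   fractional intensities \code{fractions}, residual report.
#' @slot truth list, ground truth for synthetic data.
#'
#' @seealso [lifetimeFit()], [genLifetime()]
#' @export
setClass("LifetimeData",
  representation(freq_MHz = "numeric", phase_deg = "numeric",
                 modulation = "numeric", fit = "list", truth = "list"),
  prototype(fit = list(), truth = list()))

setValidity("LifetimeData", function(object) {
  msg <- character()
  n <- length(object@freq_MHz)
  if (length(object@phase_deg) != n || length(object@modulation) != n)
    msg <- c(msg, "freq_MHz, phase_deg and modulation must have equal length")
  if (n) {
    if (any(object@freq_MHz <= 0)) msg <- c(msg, "frequencies must be > 0")
    if (any(object@phase_deg < 0 | object@phase_deg >= 90))
      msg <- c(msg, "phase must lie in [0, 90) degrees")
    if (any(object@modulation <= 0 | object@modulation > 1))
      msg <- c(msg, "modulation must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
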