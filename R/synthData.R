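# Seeded synthetic-data generators. Every input the analysis stages
# consume can be produced here with known ground truth, which the
# generators echo back for recovery tests.

.residue_gaps <- function(atoms) {
  ctr <- cbind(tapply(atoms$x, atoms$resid, mean),
               tapply(atoms$y, atoms$resid, mean),
               tapply(atoms$z, atoms$resid, mean))
  ctr <- ctr[order(as.integer(rownames(ctr))), , drop = FALSE]
  sqrt(rowSums(diff(ctr)^2))
}

#' Describe a synthetic-data generation request
#'
#' @param kind one of \code{"perrin"}, \code{"lifetime"}, \code{"cd"},
#'   \code{"ensemble"}.
#' @param seed integer RNG seed; identical spec => identical output.
#' @param truth list of ground-truth parameters (kind-specific; unset
#'   entries take the package defaults).
#' @param noise list of noise parameters (kind-specific).
#' @return a list of class \code{"genSpec"}.
#' @export
genSpec <- function(kind = c("perrin", "lifetime", "cd", "ensemble"),
                    seed = 1L, truth = list(), noise = list()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), truth = truth,
                 noise = noise), class = "genSpec")
}

.with_defaults <- function(x, defaults) {
  for (nm in names(defaults))
    if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  x
}

#' Generate a synthetic Perrin polarization series
#'
#' Emulates a steady-state polarization experiment in 20 % sucrose over
#' 5-39 C at 2 C intervals: viscosities come from
#' [sucroseViscosity()], P follows the Perrin equation for the
#' ground-truth (rho at water/20 C, P0, tau), and multiplicative
#' Gaussian noise of coefficient of variation \code{cv} is applied.
#'
#' Truth defaults: \code{rho_ns = 8.8}, \code{P0 = 0.46},
#' \code{tau_ns = 4} (the short reference construct and the
#' calibration-standard lifetime); noise default \code{cv = 0.02};
#' temperature grid \code{seq(5, 39, 2)}, \code{sucrose_pct = 20}.
#'
#' @param spec a [genSpec()] of kind \code{"perrin"}.
#' @return a \linkS4class{PolarizationSeries} with \code{truth} echoed.
#' @export
genPerrin <- function(spec) {
  stopifnot(inherits(spec, "genSpec"), spec$kind == "perrin")
  tr <- .with_defaults(spec$truth,
                       list(rho_ns = 8.8, P0 = 0.46, tau_ns = 4,
                            temp_C = seq(5, 39, 2), sucrose_pct = 20))
  nz <- .with_defaults(spec$noise, list(cv = 0.02))
  if (tr$rho_ns <= 0 || tr$P0 <= 0 || tr$tau_ns <= 0)
    stop("truth parameters rho_ns, P0, tau_ns must be > 0")
  TK <- tr$temp_C + 273.15
  eta <- sucroseViscosity(tr$temp_C, tr$sucrose_pct)
  # rho at each condition from its water/20 C reference value
  rho_T <- tr$rho_ns * (eta / .ETA_W20) * (293.15 / TK)
  a <- 1 / tr$P0 - 1 / 3
  y <- a * (1 + 3 * tr$tau_ns / rho_T)
  P <- 1 / (y + 1 / 3)
  if (any(P <= 0 | P > 0.5))
    stop("truth parameters imply P outside (0, 0.5]")
  set.seed(spec$seed)
  if (nz$cv > 0) P <- P * (1 + stats::rnorm(length(P), 0, nz$cv))
  polarizationSeries(TK, eta, P, tau = tr$tau_ns, truth = tr)
}

#' Generate synthetic frequency-domain lifetime data
#'
#' Phase and modulation on a log-spaced MHz grid from the closed-form
#' multi-exponential model, plus Gaussian noise (defaults 0.2 degrees
#' phase, 0.004 modulation). Truth defaults to a two-lifetime decay
#' with \code{tau_ns = c(1.5, 4.5)} and \code{fractions = c(0.4, 0.6)}.
#'
#' @param spec a [genSpec()] of kind \code{"lifetime"}.
#' @return a \linkS4class{LifetimeData} with \code{truth} echoed.
#' @export
genLifetime <- function(spec) {
  stopifnot(inherits(spec, "genSpec"), spec$kind == "lifetime")
  tr <- .with_defaults(spec$truth,
                       list(tau_ns = c(1.5, 4.5), fractions = NULL,
                            freq_MHz = exp(seq(log(10), log(200),
                                               length.out = 12))))
  if (is.null(tr$fractions))
    tr$fractions <- if (length(tr$tau_ns) == 2) c(0.4, 0.6) else
      rep(1 / length(tr$tau_ns), length(tr$tau_ns))
  nz <- .with_defaults(spec$noise,
                       list(sigma_phase = 0.2, sigma_mod = 0.004))
  pm <- phaseModulation(tr$freq_MHz, tr$tau_ns, tr$fractions)
  set.seed(spec$seed)
  ph <- pm$phase_deg
  mo <- pm$modulation
  if (nz$sigma_phase > 0)
    ph <- ph + stats::rnorm(length(ph), 0, nz$sigma_phase)
  if (nz$sigma_mod > 0)
    mo <- mo + stats::rnorm(length(mo), 0, nz$sigma_mod)
  ph <- pmin(pmax(ph, 0), 90 - 1e-6)
  mo <- pmin(pmax(mo, 1e-6), 1)
  lifetimeData(tr$freq_MHz, ph, mo, truth = tr)
}

#' Parameterized component spectra for composite-CD experiments
#'
#' Gaussian-band stand-ins for the molar CD spectra of the three
#' structural classes entering composite predictions: a parallel
#' quadruplex (positive band at 260 nm, negative at 240 nm), a hybrid
#' quadruplex (positive band at 290 nm) and a B-form hairpin duplex
#' (weak positive 275 nm / negative 245 nm couple).
#'
#' @param grid wavelength grid (nm).
#' @param parallel_amp amplitude of the parallel 260-nm band (molar CD
#'   units).
#' @return named list of three molar \linkS4class{CDSpectrum} objects:
#'   \code{parallel}, \code{hybrid}, \code{duplex}.
#' @export
cdComponentSpectra <- function(grid = 220:340, parallel_amp = 100) {
  g <- function(mu, sd, amp) amp * exp(-(grid - mu)^2 / (2 * sd^2))
  mk <- function(v) cdSpectrum(grid, v, units = "molar",
                               meta = list(synthetic = TRUE))
  list(parallel = mk(g(260, 8, parallel_amp) + g(240, 6, -0.45 * parallel_amp)),
       hybrid = mk(g(290, 9, 0.55 * parallel_amp) +
                     g(237, 7, -0.15 * parallel_amp)),
       duplex = mk(g(275, 10, 0.12 * parallel_amp) +
                     g(245, 8, -0.10 * parallel_amp)))
}

#' Generate a synthetic composite CD spectrum
#'
#' Weighted sum of component spectra plus wavelength-independent
#' Gaussian noise. Truth defaults: component weights
#' \code{c(parallel = 1, hybrid = 1, duplex = 1)} (one structural unit
#' each) on the bundled Gaussian components; noise default
#' \code{sd = 0}.
#'
#' @param spec a [genSpec()] of kind \code{"cd"}.
#' @param components list of molar \linkS4class{CDSpectrum}s (default
#'   [cdComponentSpectra()]).
#' @return a molar \linkS4class{CDSpectrum} with truth in \code{meta}.
#' @export
genCDMixture <- function(spec, components = cdComponentSpectra()) {
  stopifnot(inherits(spec, "genSpec"), spec$kind == "cd")
  tr <- .with_defaults(spec$truth,
                       list(weights = rep(1, length(components))))
  nz <- .with_defaults(spec$noise, list(sd = 0))
  out <- compositeSpectrum(components, tr$weights)
  set.seed(spec$seed)
  if (nz$sd > 0)
    out@value <- out@value + stats::rnorm(length(out@value), 0, nz$sd)
  out@meta$truth <- tr
  out
}

#' Generate a rigid-jitter coordinate ensemble
#'
#' Stands in for snapshots of a molecular-dynamics trajectory: \code{n}
#' copies of the structure with zero-mean Gaussian displacements of
#' scale \code{sigma} applied to loop, linker and flank atoms only
#' (quartet cores and duplex stems stay rigid), clash-filtered against
#' the structure's own validity rules.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param n number of snapshots (>= 1).
#' @param sigma displacement scale (Angstrom, >= 0).
#' @param seed RNG seed.
#' @return list of \code{n} \linkS4class{StructureModel}s.
#' @export
genJitterEnsemble <- function(structure, n, sigma = 1.0, seed = 1L) {
  stopifnot(is(structure, "StructureModel"))
  if (n < 1) stop("n must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  flex_res <- structure@topology$resid[
    structure@topology$role %in% c("loop", "linker", "flank")]
  flex <- structure@atoms$resid %in% flex_res
  # reference consecutive-residue centroid spacing, for the scatter check
  base_gap <- .residue_gaps(structure@atoms)
  set.seed(seed)
  out <- vector("list", n)
  attempts <- 0L
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max(2L * n, 10L))
        stop("jitter sigma = ", sigma, " A rejects more than half of the ",
             "snapshots via the clash filter; reduce sigma")
      m <- structure
      if (sigma > 0 && any(flex)) {
        nf <- sum(flex)
        m@atoms$x[flex] <- m@atoms$x[flex] + stats::rnorm(nf, 0, sigma)
        m@atoms$y[flex] <- m@atoms$y[flex] + stats::rnorm(nf, 0, sigma)
        m@atoms$z[flex] <- m@atoms$z[flex] + stats::rnorm(nf, 0, sigma)
        # restore excluded volume the way the builders do, then check
        m@atoms <- .resolve_clashes(m@atoms, m@topology,
                                    movable = c("loop", "linker", "flank"))
      }
      # a usable snapshot keeps the chain recognisable (no consecutive
      # residues scattered far beyond their reference spacing) and
      # satisfies the structural invariants
      ok <- all(.residue_gaps(m@atoms) - base_gap < 8) &&
        isTRUE(tryCatch(validateStructure(m), error = function(e) FALSE))
      if (ok) break
    }
    out[[i]] <- m
  }
  out
}
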