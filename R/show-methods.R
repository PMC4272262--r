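# Compact show() methods for the S4 containers.

#' @export
setMethod("show", "CDSpectrum", function(object) {
  cat(sprintf("CDSpectrum: %d points, %.0f-%.0f nm, units = %s\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength), object@units))
  if (length(object@value)) {
    i <- which.max(abs(object@value))
    cat(sprintf("  extreme value %.3g at %.0f nm\n",
                object@value[i], object@wavelength[i]))
  }
})

#' @export
setMethod("show", "StructureModel", function(object) {
  tp <- table(object@topology$role)
  cat(sprintf("StructureModel (%s): %d residues, %d atoms\n",
              if (is.null(object@provenance$builder)) "?" else
                object@provenance$builder,
              nrow(object@topology), nrow(object@atoms)))
  cat("  roles:", paste(sprintf("%s=%d", names(tp), tp), collapse = ", "),
      "\n")
  nq <- sum(object@topology$role == "quartet") / 4
  if (nq >= 1)
    cat(sprintf("  %d quartet layers, axial extent %.1f A, Rg %.1f A\n",
                as.integer(nq), axialExtent(object),
                radiusOfGyration(object)))
})

#' @export
setMethod("show", "HydroResult", function(object) {
  cat("HydroResult:\n")
  cat(sprintf("  s20,w    = %.3f S\n", object@s20w))
  cat(sprintf("  Dt       = %.3e cm^2/s  (f = %.3e g/s)\n",
              object@Dt, object@f_trans))
  cat(sprintf("  f/f0     = %.3f (%s)\n", as.numeric(object@f_ratio),
              attr(object@f_ratio, "convention")))
  cat(sprintf("  rho      = %.1f ns (isotropic average)\n", object@rho_rot))
})

#' @export
setMethod("show", "PolarizationSeries", function(object) {
  cat(sprintf("PolarizationSeries: %d points, T %.1f-%.1f K, tau = %s ns\n",
              nrow(object@data), min(object@data$temp_K),
              max(object@data$temp_K),
              if (length(object@tau)) format(object@tau) else "?"))
  if (length(object@fit))
    cat(sprintf("  Perrin fit: P0 = %.3f, rho = %.1f ns (ref %g poise, %g K)\n",
                object@fit$P0, object@fit$rho_ns, object@fit$eta_ref,
                object@fit$T_ref))
})

#' @export
setMethod("show", "LifetimeData", function(object) {
  cat(sprintf("LifetimeData: %d frequencies (%.0f-%.0f MHz)\n",
              length(object@freq_MHz), min(object@freq_MHz),
              max(object@freq_MHz)))
  if (length(object@fit))
    cat(sprintf("  fit: tau = %s ns, fractions = %s, red. chisq = %.2f\n",
                paste(round(object@fit$tau_ns, 2), collapse = "/"),
                paste(round(object@fit$fractions, 2), collapse = "/"),
                object@fit$chisq))
})
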