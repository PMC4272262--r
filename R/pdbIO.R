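# PDB input/output for structure models (via bio3d), with an optional
# plain-text topology sidecar carrying the per-residue role labels that
# the PDB format cannot hold.

#' Write a StructureModel to a PDB file
#'
#' Standard ATOM records (residue names DA/DC/DG/DT, chain A); the
#' per-residue topology can be written alongside as a CSV sidecar.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param file output PDB path.
#' @param topology_file optional path for the topology sidecar CSV
#'   (columns resid, role, unit, layer).
#' @return invisibly, \code{file}.
#' @export
writeModelPDB <- function(model, file, topology_file = NULL) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = a$resid, resid = a$resname,
                   elety = a$atom, chain = rep("A", nrow(a)),
                   eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  if (!is.null(topology_file))
    utils::write.csv(model@topology, topology_file, row.names = FALSE)
  invisible(file)
}

#' Read a PDB file as a StructureModel
#'
#' @param file PDB path.
#' @param topology_file optional sidecar CSV written by
#'   [writeModelPDB()]; without it every residue's role is
#'   \code{"unknown"}.
#' @return a \linkS4class{StructureModel}.
#' @export
readModelPDB <- function(file, topology_file = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  atoms <- data.frame(atom = at$elety, element = .elem_of(at$elety),
                      resid = at$resno, resname = at$resid,
                      x = at$x, y = at$y, z = at$z)
  topo <- if (!is.null(topology_file)) {
    t <- utils::read.csv(topology_file)
    t$role <- as.character(t$role)
    t
  } else {
    data.frame(resid = sort(unique(atoms$resid)), role = "unknown",
               unit = NA_integer_, layer = NA_integer_)
  }
  m <- new("StructureModel", atoms = atoms, topology = topo,
           provenance = list(source = file))
  validateStructure(m)
  m
}
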