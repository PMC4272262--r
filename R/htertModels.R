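# Sequence-specific convenience builders for the hTERT core promoter:
# the stacked three-quadruplex column, the unstacked beads-on-a-string
# variant, and the duplex-quadruplex hybrid, plus the single-unit
# reference quadruplex (the 1XAV c-myc variant).

# partition of the 68-nt hTERT promoter sequence into three all-parallel
# quadruplex units (G-tracts contribute three quartet guanines each;
# surplus guanines of longer tracts fall into the adjacent loops),
# two inter-unit linkers, and a single 3' flanking guanine
.HTERT_PARTITION <- list(
  unit1 = list(loops = list(c("G", "A"), c("G", "C", "T"), "A")),
  linker1 = c("C", "C", "C", "G", "G", "A"),
  unit2 = list(loops = list(c("G", "G", "C", "T"), c("C", "C"),
                            c("G", "A", "C", "C", "C"))),
  linker2 = "A",
  unit3 = list(loops = list(c("G", "T", "C"), c("A", "C"), c("G", "C"))),
  flank3 = "G")

#' Reassemble the hTERT sequence from the structural partition
#'
#' The partition used by the model builders (three 4-tract parallel
#' units, two linkers, one 3' flank) concatenates back to the full
#' 68-mer; used to verify the bookkeeping.
#'
#' @return the reassembled sequence string.
#' @export
htertPartitionSequence <- function() {
  p <- .HTERT_PARTITION
  unit_seq <- function(u) {
    lp <- u$loops
    paste0("GGG", paste0(lp[[1]], collapse = ""),
           "GGG", paste0(lp[[2]], collapse = ""),
           "GGG", paste0(lp[[3]], collapse = ""), "GGG")
  }
  paste0(unit_seq(p$unit1), paste0(p$linker1, collapse = ""),
         unit_seq(p$unit2), paste0(p$linker2, collapse = ""),
         unit_seq(p$unit3), paste0(p$flank3, collapse = ""))
}

.htert_units <- function(loop_radius = 15) {
  p <- .HTERT_PARTITION
  mk <- function(u, idx) buildParallelUnit(
    3, vapply(u$loops, length, integer(1)),
    loop_bases = unlist(u$loops), loop_radius = loop_radius,
    unit = idx)
  list(mk(p$unit1, 1L), mk(p$unit2, 2L), mk(p$unit3, 3L))
}

#' Idealized stacked three-quadruplex model of the hTERT promoter
#'
#' Three contiguous all-parallel 3-quartet units stacked coaxially
#' (9 quartet layers on one axis, 3.4 A interface gaps), with the
#' inter-unit linker nucleotides on the outside of the junctions and
#' the terminal guanine stacked on the 3' end.
#'
#' @param loop_radius radial anchor of the propeller-loop residues (A).
#' @param interface_gap stacking gap between units (A).
#' @return a \linkS4class{StructureModel} (68 residues).
#' @export
htertStackedModel <- function(loop_radius = 15,
                              interface_gap = .DEFAULT_GAP) {
  p <- .HTERT_PARTITION
  units <- .htert_units(loop_radius)
  # stack the 3' flank onto the last unit
  units[[3]] <- buildParallelUnit(
    3, vapply(p$unit3$loops, length, integer(1)),
    loop_bases = unlist(p$unit3$loops), loop_radius = loop_radius,
    flank3 = p$flank3, unit = 3L)
  stackUnits(units, interface_gap = interface_gap,
             linker_bases = list(p$linker1, p$linker2))
}

#' Unstacked beads-on-a-string model of the hTERT promoter
#'
#' The same three parallel quadruplex units as
#' [htertStackedModel()], but connected by extended single-strand
#' linkers with no inter-quadruplex stacking.
#'
#' @inheritParams htertStackedModel
#' @return a \linkS4class{StructureModel}.
#' @export
htertBeadsModel <- function(loop_radius = 15) {
  p <- .HTERT_PARTITION
  units <- .htert_units(loop_radius)
  units[[3]] <- buildParallelUnit(
    3, vapply(p$unit3$loops, length, integer(1)),
    loop_bases = unlist(p$unit3$loops), loop_radius = loop_radius,
    flank3 = p$flank3, unit = 3L)
  buildBeadsOnString(units, list(p$linker1, p$linker2))
}

#' Duplex-quadruplex hybrid model of the hTERT promoter
#'
#' The previously proposed architecture: a parallel quadruplex, an 8-bp
#' B-form hairpin and an antiparallel-like quadruplex tethered in
#' series.
#'
#' @return a \linkS4class{StructureModel}.
#' @export
htertHybridModel <- function() {
  buildDuplexQuadruplexHybrid()
}

#' Idealized single parallel quadruplex (1XAV-like reference unit)
#'
#' A 3-quartet all-parallel unit with the 1XAV loop architecture
#' (propeller loops of 1, 2 and 1 nt) and the TGA / TAA flanking
#' residues of the 22-mer c-myc promoter variant.
#'
#' @inheritParams htertStackedModel
#' @return a \linkS4class{StructureModel} (22 residues).
#' @export
xavModel <- function(loop_radius = 15) {
  buildParallelUnit(3, c(1, 2, 1),
                    loop_bases = c("T", "T", "A", "T"),
                    flank5 = c("T", "G", "A"), flank3 = c("T", "A", "A"),
                    loop_radius = loop_radius)
}
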