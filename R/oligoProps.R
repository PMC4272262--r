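# Sequence-derived physical properties of oligodeoxynucleotides.
#
# Molecular weights use the free-acid monomer convention; extinction
# coefficients use the nearest-neighbour method with the
# Cantor-Warshaw-Tinoco parameter set (the set used by the major
# oligonucleotide vendors), swappable via the `params` argument.

# average monomer masses (Da), free acid; terminal correction removes one
# condensation-water-equivalent plus terminal phosphate/hydroxyl difference
.MONOMER_MW <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.2)
.TERMINAL_MW <- -61.96

# nearest-neighbour epsilon(260 nm), mM^-1 cm^-1 (Cantor, Warshaw & Tinoco)
.NN_EPS260 <- list(
  pair = c(AA = 27.4, AC = 21.2, AG = 25.0, AT = 22.8,
           CA = 21.2, CC = 14.6, CG = 18.0, CT = 15.2,
           GA = 25.2, GC = 17.6, GG = 21.6, GT = 20.0,
           TA = 23.4, TC = 16.2, TG = 19.0, TT = 16.8),
  mono = c(A = 15.4, C = 7.4, G = 11.5, T = 8.7))

.as_bases <- function(seq) {
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet"))
    seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop("sequence must be a single character string (or a DNAString)")
  s <- toupper(gsub("[ 0-9'′-]", "", seq))
  if (nchar(s) == 0L) stop("empty sequence")
  b <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(b), c("A", "C", "G", "T"))
  if (length(bad))
    stop("invalid sequence: non-ACGT character(s) ", paste(bad, collapse = ", "))
  b
}

#' Base composition of a DNA sequence
#'
#' @param seq character string (whitespace tolerated) or
#'   \code{Biostrings::DNAString} over the alphabet ACGT.
#' @return named integer vector with counts of A, C, G and T.
#' @examples
#' baseComposition("TGAGGGTGGGTAGGGTGGGTAA")
#' @export
baseComposition <- function(seq) {
  b <- .as_bases(seq)
  vapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(x) sum(b == x), integer(1))
}

#' Molecular weight of a DNA oligonucleotide (free acid)
#'
#' Average molecular weight from base composition,
#' \eqn{M = n_A 313.21 + n_C 289.18 + n_G 329.21 + n_T 304.2 - 61.96} Da.
#'
#' @inheritParams baseComposition
#' @return molecular weight in Da.
#' @examples
#' molecularWeight("TGAGGGTGGGTAGGGTGGGTAA")  # 6991.6
#' @export
molecularWeight <- function(seq) {
  n <- baseComposition(seq)
  unname(sum(.MONOMER_MW[names(n)] * n) + .TERMINAL_MW)
}

#' Nearest-neighbour extinction coefficient at 260 nm
#'
#' \eqn{\epsilon_{260} = \sum_{pairs} \epsilon_{NN} - \sum_{internal}
#' \epsilon_{mono}}, in mM^-1 cm^-1. Requires at least one dinucleotide.
#'
#' @inheritParams baseComposition
#' @param params list with elements \code{pair} (16 named dinucleotide
#'   values) and \code{mono} (4 named monomer values); defaults to the
#'   Cantor-Warshaw-Tinoco table.
#' @return extinction coefficient in mM^-1 cm^-1.
#' @examples
#' extinction260("TGAGGGTGGGTAGGGTGGGTAA")  # 228.7
#' @export
extinction260 <- function(seq, params = .NN_EPS260) {
  b <- .as_bases(seq)
  if (length(b) < 2L)
    stop("nearest-neighbour method needs a sequence of length >= 2")
  pairs <- paste0(b[-length(b)], b[-1])
  unname(sum(params$pair[pairs]) -
         sum(params$mono[b[-c(1L, length(b))]]))
}

#' Strand concentration from absorbance (Beer-Lambert)
#'
#' @param A absorbance at 260 nm (dimensionless, >= 0).
#' @param eps extinction coefficient in mM^-1 cm^-1.
#' @param path path length in cm (default 1).
#' @return strand concentration in micromolar.
#' @examples
#' concentrationFromAbsorbance(0.5, 659.3)  # ~0.758 uM
#' @export
concentrationFromAbsorbance <- function(A, eps, path = 1) {
  if (!is.numeric(A) || any(A < 0)) stop("absorbance must be >= 0")
  if (eps <= 0) stop("extinction coefficient must be > 0")
  if (path <= 0) stop("path length must be > 0")
  1000 * A / (eps * path)
}

#' Tabulate sequence properties for a set of oligonucleotides
#'
#' @param seqs named character vector (or \code{DNAStringSet}) of
#'   sequences.
#' @return data.frame with name, length, base counts, molecular weight
#'   (1 decimal) and epsilon260 (1 decimal).
#' @examples
#' oligoPropertyTable(c(x = "ACGT", y = "GGGTTAGGG"))
#' @export
oligoPropertyTable <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    n <- baseComposition(seqs[[i]])
    data.frame(name = nm[i], length = sum(n),
               A = n[["A"]], C = n[["C"]], G = n[["G"]], T = n[["T"]],
               mw = round(molecularWeight(seqs[[i]]), 1),
               eps260 = round(extinction260(seqs[[i]]), 1))
  })
  do.call(rbind, rows)
}

#' Reference promoter and quadruplex sequences
#'
#' The 68-nt G-rich human telomerase reverse transcriptase (hTERT) core
#' promoter sequence and the 22-nt c-myc promoter sequence variant whose
#' parallel quadruplex structure (PDB 1XAV) serves as the single-unit
#' reference throughout the package.
#'
#' @return named character vector with elements \code{hTERT} and
#'   \code{oneXAV}.
#' @examples
#' nchar(referenceSequences()["hTERT"])  # 68
#' @export
referenceSequences <- function() {
  c(hTERT = paste0("GGGGAGGGGCTGGGAGGGCCCGGAGGGGGCTGGGCC",
                   "GGGGACCCGGGAGGGGTCGGGACGGGGCGGGG"),
    oneXAV = "TGAGGGTGGGTAGGGTGGGTAA")
}

#' Read sequences from FASTA or plain text
#'
#' Reads a FASTA file via Biostrings when installed, otherwise with a
#' minimal parser; a file with no header lines is treated as one sequence
#' per line.
#'
#' @param file path to a FASTA or plain-text sequence file.
#' @return named character vector of sequences.
#' @export
readSequences <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no sequences in ", file)
  if (any(startsWith(lines, ">"))) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      x <- Biostrings::readDNAStringSet(file)
      out <- as.character(x)
      names(out) <- names(x)
      return(out)
    }
    hdr <- which(startsWith(lines, ">"))
    ends <- c(hdr[-1] - 1L, length(lines))
    out <- vapply(seq_along(hdr), function(i)
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
    names(out) <- sub("^>\\s*", "", lines[hdr])
    out
  } else {
    out <- gsub("\\s", "", lines)
    names(out) <- paste0("seq", seq_along(out))
    out
  }
}
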