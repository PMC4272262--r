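# Builders for idealized candidate architectures: a single parallel
# G-quadruplex unit, coaxially stacked multi-quadruplex columns,
# unstacked beads-on-a-string arrangements, and the duplex-quadruplex
# hybrid. All builders are deterministic given their parameters.

.DEFAULT_RISE <- 3.3      # intra-unit quartet rise, A
.DEFAULT_TWIST <- 30      # helical twist per quartet step, degrees
.DEFAULT_GAP <- 3.4       # stacking gap between units, A
.EXTENDED_RISE <- 5.9     # extended single-strand rise, A per nt

.structure_model <- function(atoms, topology, provenance) {
  atoms <- .resolve_clashes(atoms, topology,
                            movable = c("loop", "flank", "linker"))
  m <- new("StructureModel", atoms = atoms, topology = topology,
           provenance = provenance)
  validateStructure(m)
  m
}

#' Build one idealized all-parallel G-quadruplex unit
#'
#' Constructs a parallel-stranded quadruplex with \code{n_quartets}
#' stacked G-quartet layers (rise 3.3 A, twist 30 deg per step) and three
#' propeller (double-chain-reversal) loops running down the outside of
#' the core. Flanking residues may be stacked on either end.
#'
#' @param n_quartets number of stacked quartet layers (>= 2).
#' @param loop_lengths integer length-3, nucleotides per propeller loop
#'   (each >= 1).
#' @param loop_bases optional character vector of loop bases, in strand
#'   order (defaults to all "A").
#' @param flank5,flank3 character vectors of flanking bases stacked below
#'   the first and above the last quartet (default none).
#' @param rise,twist_deg quartet stacking rise (A) and twist (degrees).
#' @param loop_radius radial anchor of propeller-loop residues (A).
#' @param loop_style \code{"propeller"} (lateral loops, parallel
#'   topology) or \code{"edgewise"} (loops across the terminal faces, an
#'   antiparallel-like variant used by the hybrid model).
#' @param phase_deg rotation of the whole unit about the helix axis.
#' @param unit integer label recorded in the topology.
#' @return a \linkS4class{StructureModel}; the helix axis is z, the first
#'   quartet plane is at z = 0.
#' @examples
#' u <- buildParallelUnit(3, c(1, 2, 1))
#' nrow(topology(u))
#' @export
buildParallelUnit <- function(n_quartets, loop_lengths,
                              loop_bases = NULL,
                              flank5 = character(), flank3 = character(),
                              rise = .DEFAULT_RISE,
                              twist_deg = .DEFAULT_TWIST,
                              loop_radius = 15,
                              loop_style = c("propeller", "edgewise"),
                              phase_deg = 0, unit = 1L) {
  loop_style <- match.arg(loop_style)
  if (n_quartets < 2)
    stop("n_quartets must be >= 2: a single quartet has no stack")
  if (length(loop_lengths) != 3 || any(loop_lengths < 1))
    stop("need three loop lengths >= 1: a propeller loop requires at least one nucleotide")
  if (is.null(loop_bases)) loop_bases <- rep("A", sum(loop_lengths))
  if (length(loop_bases) != sum(loop_lengths))
    stop("loop_bases must supply ", sum(loop_lengths), " bases")
  twist <- twist_deg * pi / 180
  phase <- phase_deg * pi / 180
  z_top <- (n_quartets - 1) * rise

  res <- list()   # list of list(coords, base, role, layer)
  add <- function(coords, base, role, layer = NA_integer_)
    res[[length(res) + 1L]] <<- list(coords = coords, base = base,
                                     role = role, layer = layer)
  for (m in seq_along(flank5))
    add(.axial_residue(.base_template(flank5[m]),
                       phase - 0.5, -rise * (length(flank5) - m + 1)),
        flank5[m], "flank")
  li <- 0L
  for (k in 0:3) {
    for (q in seq_len(n_quartets))
      add(.quartet_residue(k, phase + (q - 1) * twist, (q - 1) * rise),
          "G", "quartet", q)
    if (k < 3) {
      L <- loop_lengths[k + 1]
      r_loop <- loop_radius + 0.6 * min(L - 1, 4)
      for (m in seq_len(L)) {
        li <- li + 1L
        b <- loop_bases[li]
        frac <- m / (L + 1)
        if (loop_style == "propeller") {
          # loops descend the groove on a helical arc; alternating
          # radial/tilt stagger keeps consecutive bases clear
          th <- phase + k * pi / 2 + (20 + 55 * frac) * pi / 180
          zz <- (z_top + 2) - (z_top + 4) * frac
          r_m <- r_loop + 1.4 * ((m - 1) %% 2)
          add(.side_residue(.base_template(b), r_m, th, zz,
                            tilt = 0.5 + 1.1 * ((m - 1) %% 2)), b, "loop")
        } else {
          # edgewise loops cross the terminal faces on the outer rim,
          # climbing away from the face residue by residue
          on_top <- (k %% 2L == 0L)
          th <- phase + k * pi / 2 + (20 + 60 * frac) * pi / 180
          dzm <- 3.6 + 1.8 * (m - 1)
          zz <- if (on_top) z_top + dzm else -dzm
          add(.side_residue(.base_template(b),
                            8.5 + 1.5 * ((m - 1) %% 2), th, zz,
                            tilt = 0.45 + 1.0 * ((m - 1) %% 2)),
              b, "loop")
        }
      }
    }
  }
  for (m in seq_along(flank3))
    add(.axial_residue(.base_template(flank3[m]),
                       phase + 1.0 + 0.4 * m, z_top + rise * m),
        flank3[m], "flank")

  atoms <- do.call(rbind, lapply(seq_along(res), function(i)
    .atoms_df(res[[i]]$coords, i, .resname_of(res[[i]]$base))))
  topo <- data.frame(resid = seq_along(res),
                     role = vapply(res, `[[`, character(1), "role"),
                     unit = as.integer(unit),
                     layer = vapply(res, `[[`, integer(1), "layer"))
  .structure_model(atoms, topo,
    list(builder = "parallel_unit", n_quartets = n_quartets,
         loop_lengths = loop_lengths, rise = rise, twist_deg = twist_deg,
         loop_radius = loop_radius, loop_style = loop_style,
         phase_deg = phase_deg))
}

.translate_model <- function(m, dz, dx = 0, dy = 0) {
  m@atoms$x <- m@atoms$x + dx
  m@atoms$y <- m@atoms$y + dy
  m@atoms$z <- m@atoms$z + dz
  m
}

.rotate_model_z <- function(m, ang) {
  xy <- as.matrix(m@atoms[, c("x", "y")]) %*% .rot2(ang)
  m@atoms$x <- xy[, 1]
  m@atoms$y <- xy[, 2]
  m
}

.quartet_z_range <- function(m) {
  # range of quartet base *planes* (guanine ring atoms, not backbone)
  lp <- quartetLayerPositions(m)
  range(lp$z)
}

.combine_models <- function(parts, units, provenance) {
  atoms <- NULL
  topo <- NULL
  off <- 0L
  for (i in seq_along(parts)) {
    a <- parts[[i]]@atoms
    t <- parts[[i]]@topology
    a$resid <- a$resid + off
    t$resid <- t$resid + off
    t$unit <- units[[i]]
    off <- off + nrow(t)
    atoms <- rbind(atoms, a)
    topo <- rbind(topo, t)
  }
  .structure_model(atoms, topo, provenance)
}

# deterministic clash relaxation between parts of an assembly: residues
# with movable roles that contact previously accepted atoms are pushed
# radially outward (whole-residue rigid moves) until they clear
.resolve_clashes <- function(atoms, topo, movable = c("loop", "flank"),
                             margin = 1.6, max_push = 12) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  mov_res <- topo$resid[topo$role %in% movable]
  accepted <- !(atoms$resid %in% mov_res)   # rigid parts anchor the search
  for (ri in mov_res) {
    sel <- atoms$resid == ri
    ok_against <- accepted & abs(atoms$resid - ri) >= 2
    if (any(ok_against)) {
      P <- xyz[ok_against, , drop = FALSE]
      mind <- function(cand)
        sqrt(max(0, min(outer(rowSums(cand^2), rowSums(P^2), `+`) -
                          2 * cand %*% t(P))))
      cand <- xyz[sel, , drop = FALSE]
      if (mind(cand) < margin) {
        ctr <- colMeans(cand)
        rr <- sqrt(sum(ctr[1:2]^2))
        dirv <- if (rr > 1e-6) c(ctr[1:2] / rr, 0) else c(1, 0, 0)
        for (push in seq(0.8, max_push, by = 0.8)) {
          cand2 <- sweep(cand, 2, push * dirv, `+`)
          if (mind(cand2) >= margin) break
        }
        xyz[sel, ] <- cand2
      }
    }
    accepted[sel] <- TRUE
  }
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

# deterministic greedy placement of linker residues around an interface:
# candidate cylindrical positions are scanned outward until the residue
# clears all previously placed atoms by `margin`
.place_free_linkers <- function(existing_xyz, bases, z_center,
                                r_start = 15, margin = 1.8) {
  placed <- existing_xyz
  res <- vector("list", length(bases))
  for (m in seq_along(bases)) {
    tmpl <- .base_template(bases[m])
    found <- FALSE
    for (r in seq(r_start, r_start + 9, by = 1.5)) {
      for (dz in c(0, 1.5, -1.5, 3, -3, 4.5, -4.5)) {
        for (th in seq(0, 2 * pi - 1e-6, by = pi / 9) + 0.15 * m) {
          cand <- .side_residue(tmpl, r, th, z_center + dz, tilt = pi / 4)
          d2min <- min(outer(rowSums(cand^2), rowSums(placed^2), `+`) -
                         2 * cand %*% t(placed))
          if (d2min > margin^2) {
            res[[m]] <- cand
            placed <- rbind(placed, cand)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (!found)
      stop("could not place linker residue ", m, " without a clash")
  }
  atoms <- do.call(rbind, lapply(seq_along(res), function(i)
    .atoms_df(res[[i]], i, .resname_of(bases[i]))))
  topo <- data.frame(resid = seq_along(res), role = "linker",
                     unit = NA_integer_, layer = NA_integer_)
  new("StructureModel", atoms = atoms, topology = topo, provenance = list())
}

# bare StructureModel for a run of linker residues (no validity yet)
.linker_part <- function(bases, positions, style = c("side", "axial"),
                         role = "linker") {
  style <- match.arg(style)
  res <- lapply(seq_along(bases), function(m) {
    p <- positions[[m]]
    if (style == "side")
      .side_residue(.base_template(bases[m]), p[1], p[2], p[3],
                    tilt = pi / 4)
    else
      .axial_residue(.base_template(bases[m]), p[2], p[3])
  })
  atoms <- do.call(rbind, lapply(seq_along(res), function(i)
    .atoms_df(res[[i]], i, .resname_of(bases[i]))))
  topo <- data.frame(resid = seq_along(res), role = role, unit = NA_integer_,
                     layer = NA_integer_)
  new("StructureModel", atoms = atoms, topology = topo, provenance = list())
}

#' Stack parallel quadruplex units coaxially
#'
#' Places the units on a common helix axis, 5' to 3', with the terminal
#' quartet planes of adjacent units separated by \code{interface_gap}
#' and the helical twist continued across the interface. Linker residues
#' (if any) are inserted on the outside of each junction.
#'
#' @param units list of parallel-unit \linkS4class{StructureModel}s.
#' @param interface_gap axial gap between facing terminal quartets (A,
#'   > 0; default 3.4, a stacking contact).
#' @param linker_bases list (length \code{length(units) - 1}) of
#'   character vectors of linker bases per junction; empty vectors give
#'   direct stacking.
#' @param linker_radius radial position of linker residues (A).
#' @return a single \linkS4class{StructureModel}, quartet layers coaxial.
#' @examples
#' u <- buildParallelUnit(3, c(1, 2, 1))
#' st <- stackUnits(list(u, u, u))
#' @export
stackUnits <- function(units, interface_gap = .DEFAULT_GAP,
                       linker_bases = NULL, linker_radius = 15) {
  if (!length(units)) stop("no units supplied")
  if (length(units) == 1L) return(units[[1]])
  if (interface_gap <= 0) stop("interface_gap must be > 0")
  if (is.null(linker_bases))
    linker_bases <- rep(list(character()), length(units) - 1)
  # position all units first
  placed <- list(units[[1]])
  iface_z <- numeric(0)
  ztop <- .quartet_z_range(units[[1]])[2]
  twist_cont <- .DEFAULT_TWIST * pi / 180
  for (i in seq_along(units)[-1]) {
    zr <- .quartet_z_range(units[[i]])
    u2 <- .rotate_model_z(units[[i]], twist_cont)
    dz <- ztop + interface_gap - zr[1]
    u2 <- .translate_model(u2, dz)
    iface_z <- c(iface_z, ztop + interface_gap / 2)
    ztop <- zr[2] + dz
    twist_cont <- twist_cont + .DEFAULT_TWIST * pi / 180
    placed[[i]] <- u2
  }
  # relax residual loop/flank contacts between neighbouring units
  tmp_atoms <- NULL
  tmp_topo <- NULL
  off <- 0L
  for (u in placed) {
    a <- u@atoms
    t <- u@topology
    a$resid <- a$resid + off
    t$resid <- t$resid + off
    off <- off + nrow(t)
    tmp_atoms <- rbind(tmp_atoms, a)
    tmp_topo <- rbind(tmp_topo, t)
  }
  tmp_atoms <- .resolve_clashes(tmp_atoms, tmp_topo)
  off <- 0L
  for (i in seq_along(placed)) {
    n <- nrow(placed[[i]]@atoms)
    seg <- tmp_atoms[(off + 1):(off + n), ]
    placed[[i]]@atoms$x <- seg$x
    placed[[i]]@atoms$y <- seg$y
    placed[[i]]@atoms$z <- seg$z
    off <- off + n
  }
  all_xyz <- do.call(rbind, lapply(placed, function(u)
    as.matrix(u@atoms[, c("x", "y", "z")])))
  # then thread the linkers through whatever space is left
  parts <- list(placed[[1]])
  unit_ids <- list(1L)
  for (i in seq_along(units)[-1]) {
    lb <- linker_bases[[i - 1]]
    if (length(lb)) {
      lp <- .place_free_linkers(all_xyz, lb, iface_z[i - 1],
                                r_start = linker_radius)
      all_xyz <- rbind(all_xyz,
                       as.matrix(lp@atoms[, c("x", "y", "z")]))
      parts[[length(parts) + 1L]] <- lp
      unit_ids[[length(unit_ids) + 1L]] <- NA_integer_
    }
    parts[[length(parts) + 1L]] <- placed[[i]]
    unit_ids[[length(unit_ids) + 1L]] <- i
  }
  .combine_models(parts, unit_ids,
    list(builder = "stacked", n_units = length(units),
         interface_gap = interface_gap))
}

#' Arrange quadruplex units as beads on a string
#'
#' Places the units collinearly with extended single-strand linkers
#' (5.9 A per nucleotide) and no inter-quadruplex stacking: facing
#' terminal quartets of adjacent units are kept more than 10 A apart
#' regardless of linker length.
#'
#' @param units list of quadruplex-unit \linkS4class{StructureModel}s.
#' @param linker_bases list (length \code{length(units) - 1}) of
#'   character vectors of linker bases per junction (each >= 1 base).
#' @return a \linkS4class{StructureModel}.
#' @examples
#' u <- buildParallelUnit(3, c(1, 2, 1))
#' b <- buildBeadsOnString(list(u, u, u),
#'                         list(c("A", "A"), c("A", "A")))
#' @export
buildBeadsOnString <- function(units, linker_bases) {
  if (!length(units)) stop("no units supplied")
  if (length(units) == 1L) return(units[[1]])
  if (length(linker_bases) != length(units) - 1 ||
      any(!vapply(linker_bases, length, integer(1))))
    stop("need >= 1 linker nucleotide per junction")
  parts <- list()
  unit_ids <- list()
  ztop <- NA_real_
  for (i in seq_along(units)) {
    u <- units[[i]]
    zr <- .quartet_z_range(u)
    if (i == 1L) {
      u2 <- u
      ztop <- zr[2]
    } else {
      lb <- linker_bases[[i - 1]]
      gap <- max(10.5, .EXTENDED_RISE * length(lb))
      u2 <- .rotate_model_z(u, 0.7 * i)
      dz <- ztop + gap - zr[1]
      u2 <- .translate_model(u2, dz)
      z0 <- ztop
      pos <- lapply(seq_along(lb), function(m)
        c(3.0, 2.2 * m + 0.5 * i, z0 + gap * m / (length(lb) + 1)))
      parts[[length(parts) + 1L]] <- .linker_part(lb, pos, "axial")
      unit_ids[[length(unit_ids) + 1L]] <- NA_integer_
      ztop <- zr[2] + dz
    }
    parts[[length(parts) + 1L]] <- u2
    unit_ids[[length(unit_ids) + 1L]] <- i
  }
  .combine_models(parts, unit_ids,
    list(builder = "beads_on_string", n_units = length(units)))
}

# an idealized B-form hairpin: n_bp base-pair pseudo-planes (rise 3.4 A,
# twist 36 deg), two backbone clusters per pair at radius `backbone_r`,
# capped by `loop_bases` residues
.build_hairpin <- function(n_bp, stem_bases5 = rep("G", n_bp),
                           stem_bases3 = rep("C", n_bp),
                           loop_bases = c("T", "T", "T"),
                           rise = 3.4, twist_deg = 36, backbone_r = 9.9) {
  if (n_bp < 1) stop("a hairpin needs at least one base pair")
  twist <- twist_deg * pi / 180
  res <- list()
  add <- function(coords, base, role)
    res[[length(res) + 1L]] <<- list(coords = coords, base = base,
                                     role = role)
  bp_res <- function(base, phi, z, strand) {
    b <- .base_template(base)
    er <- c(cos(phi), sin(phi), 0)
    et <- c(-sin(phi), cos(phi), 0)
    # base reaches from the backbone toward the helix axis
    anchor <- (backbone_r - 2.2) * er + c(0, 0, z)
    b3 <- t(anchor + t(-b[, 1] %o% er + b[, 2] %o% et * strand))
    rownames(b3) <- rownames(b)
    c1 <- anchor + 1.0 * er
    bb <- t(c1 + t(.BACKBONE[, 1] %o% er + .BACKBONE[, 2] %o% (et * strand) +
                     .BACKBONE[, 3] %o% c(0, 0, strand * 0.3)))
    bb <- sweep(bb, 1, c(rep(0, nrow(bb))), `+`)
    rownames(bb) <- rownames(.BACKBONE)
    # keep backbone phosphates at backbone_r: rescale radial positions
    rr <- sqrt(bb[, 1]^2 + bb[, 2]^2)
    scl <- pmin(1, backbone_r / pmax(rr, 1e-6))
    bb[, 1] <- bb[, 1] * scl
    bb[, 2] <- bb[, 2] * scl
    rbind(b3, matrix(c1, 1, dimnames = list("C1'", NULL)), bb)
  }
  # 5' strand up
  for (i in seq_len(n_bp))
    add(bp_res(stem_bases5[i], (i - 1) * twist, (i - 1) * rise, +1),
        stem_bases5[i], "duplex")
  # loop over the top
  ztop <- (n_bp - 1) * rise
  for (m in seq_along(loop_bases))
    add(.side_residue(.base_template(loop_bases[m]), 5.5,
                      (n_bp - 1) * twist + m * 1.4, ztop + 3.6 + 1.1 * (m %% 2),
                      tilt = pi / 2.5),
        loop_bases[m], "loop")
  # 3' strand down (opposite side: minor-groove offset 154 deg)
  for (i in rev(seq_len(n_bp)))
    add(bp_res(stem_bases3[i], (i - 1) * twist + 154 * pi / 180,
               (i - 1) * rise, -1),
        stem_bases3[i], "duplex")
  atoms <- do.call(rbind, lapply(seq_along(res), function(i)
    .atoms_df(res[[i]]$coords, i, .resname_of(res[[i]]$base))))
  topo <- data.frame(resid = seq_along(res),
                     role = vapply(res, `[[`, character(1), "role"),
                     unit = NA_integer_, layer = NA_integer_)
  .structure_model(atoms, topo,
    list(builder = "hairpin", n_bp = n_bp, rise = rise,
         twist_deg = twist_deg, backbone_r = backbone_r))
}

#' Build the duplex-quadruplex hybrid architecture
#'
#' The previously proposed alternative architecture for long G-rich
#' promoter sequences: one parallel quadruplex unit and one
#' antiparallel-like quadruplex unit tethered in series (no coaxial
#' quartet stacking), with an 8-bp B-form hairpin stem (rise 3.4 A/bp,
#' twist 36 deg) folded back alongside the quadruplex pair.
#'
#' @param parallel_unit,antiparallel_unit optional pre-built units; by
#'   default a 3-quartet parallel unit with loops (2, 3, 1) and a
#'   3-quartet edgewise-loop unit with loops (3, 2, 2) are used.
#' @param hairpin_bp number of base pairs in the hairpin stem (>= 1;
#'   default 8).
#' @param hairpin_loop character vector of hairpin-loop bases.
#' @param linker_bases list of two character vectors: bases tethering
#'   quadruplex 1 to quadruplex 2 and the assembly to the hairpin.
#' @param tether_gap axial clearance between the facing terminal
#'   quartet planes of the two quadruplex units (A; large enough to
#'   exclude stacking).
#' @param hairpin_offset lateral offset of the hairpin axis from the
#'   quadruplex axis (A).
#' @return a \linkS4class{StructureModel}.
#' @examples
#' h <- buildDuplexQuadruplexHybrid()
#' table(topology(h)$role)
#' @export
buildDuplexQuadruplexHybrid <- function(parallel_unit = NULL,
                                        antiparallel_unit = NULL,
                                        hairpin_bp = 8,
                                        hairpin_loop = c("T", "T", "T"),
                                        linker_bases = list(
                                          c("A", "C", "A", "C", "A", "C"),
                                          c("A", "C", "A", "C", "A", "C")),
                                        tether_gap = 24,
                                        hairpin_offset = 30) {
  if (hairpin_bp < 1) stop("a hairpin needs at least one base pair")
  if (is.null(parallel_unit))
    parallel_unit <- buildParallelUnit(3, c(2, 3, 1), unit = 1L)
  if (is.null(antiparallel_unit))
    antiparallel_unit <- buildParallelUnit(3, c(3, 2, 2),
                                           loop_style = "edgewise",
                                           unit = 2L)
  hp <- .build_hairpin(hairpin_bp, loop_bases = hairpin_loop)
  # quadruplex 1 on the z axis; quadruplex 2 above it, unstacked;
  # hairpin folded back alongside
  z1_top <- .quartet_z_range(parallel_unit)[2]
  ap <- .translate_model(antiparallel_unit,
                         z1_top + tether_gap -
                           .quartet_z_range(antiparallel_unit)[1])
  zmid <- z1_top + tether_gap / 2
  hp2 <- .translate_model(hp, zmid - mean(range(hp@atoms$z)),
                          dx = hairpin_offset)
  fixed <- rbind(as.matrix(parallel_unit@atoms[, c("x", "y", "z")]),
                 as.matrix(ap@atoms[, c("x", "y", "z")]),
                 as.matrix(hp2@atoms[, c("x", "y", "z")]))
  lk1 <- .place_free_linkers(fixed, linker_bases[[1]], zmid, r_start = 8)
  fixed <- rbind(fixed, as.matrix(lk1@atoms[, c("x", "y", "z")]))
  lk2 <- .place_free_linkers(fixed, linker_bases[[2]], zmid, r_start = 11)
  parts <- list(parallel_unit, lk1, hp2, lk2, ap)
  unit_ids <- list(1L, NA_integer_, NA_integer_, NA_integer_, 2L)
  .combine_models(parts, unit_ids,
    list(builder = "duplex_quadruplex_hybrid", hairpin_bp = hairpin_bp,
         tether_gap = tether_gap, hairpin_offset = hairpin_offset))
}

#' Validate the geometric invariants of a structure model
#'
#' Checks that (i) every quartet layer holds exactly four guanines whose
#' base atoms are coplanar to better than 0.5 A RMS, (ii) consecutive
#' quartet layers within a unit are spaced by the builder rise within
#' 0.1 A, and (iii) no two non-bonded atoms (atoms of non-adjacent
#' residues) approach closer than \code{clash_cutoff}.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param clash_cutoff minimum allowed non-bonded contact distance (A).
#' @return invisibly \code{TRUE}; errors describe the first violation.
#' @export
validateStructure <- function(model, clash_cutoff = 1.5) {
  atoms <- model@atoms
  topo <- model@topology
  base_names <- unique(c(rownames(.BASE_PURINE), rownames(.BASE_PYRIMIDINE),
                         "O6", "N6", "O4", "N4"))
  q <- topo[topo$role == "quartet", ]
  if (nrow(q)) {
    key <- interaction(q$unit, q$layer, drop = TRUE)
    for (lv in levels(key)) {
      rs <- q$resid[key == lv]
      if (length(rs) != 4)
        stop("quartet layer ", lv, " has ", length(rs),
             " guanines (expected 4)")
      ba <- atoms[atoms$resid %in% rs & atoms$atom %in% base_names &
                    atoms$resname == "DG", c("x", "y", "z")]
      xyz <- scale(as.matrix(ba), scale = FALSE)
      rms <- sqrt(min(svd(xyz)$d^2) / nrow(xyz))
      if (rms > 0.5)
        stop("quartet layer ", lv, " out-of-plane RMS ", round(rms, 2),
             " A exceeds 0.5 A")
    }
    rise <- model@provenance$rise
    if (is.null(rise)) rise <- .DEFAULT_RISE
    for (u in unique(q$unit)) {
      zl <- vapply(sort(unique(q$layer[q$unit == u])), function(l)
        mean(atoms$z[atoms$resid %in% q$resid[q$unit == u & q$layer == l]]),
        numeric(1))
      if (length(zl) > 1 && any(abs(diff(zl) - rise) > 0.1))
        stop("quartet rise in unit ", u, " deviates from ", rise,
             " A by more than 0.1 A")
    }
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1) {
    d <- as.matrix(stats::dist(xyz))
    dr <- abs(outer(atoms$resid, atoms$resid, `-`))
    bad <- which(d < clash_cutoff & dr >= 2, arr.ind = TRUE)
    if (nrow(bad)) {
      i <- bad[1, 1]; j <- bad[1, 2]
      stop(sprintf("steric clash: %s/res%d and %s/res%d at %.2f A",
                   atoms$atom[i], atoms$resid[i], atoms$atom[j],
                   atoms$resid[j], d[i, j]))
    }
  }
  invisible(TRUE)
}

#' Quartet layer positions of a model
#'
#' @param model a \linkS4class{StructureModel}.
#' @return data.frame with unit, layer and the mean z of the layer's
#'   guanine base atoms.
#' @export
quartetLayerPositions <- function(model) {
  q <- model@topology[model@topology$role == "quartet", ]
  if (!nrow(q)) return(data.frame(unit = integer(), layer = integer(),
                                  z = numeric()))
  key <- unique(q[, c("unit", "layer")])
  key$z <- vapply(seq_len(nrow(key)), function(i) {
    rs <- q$resid[q$unit == key$unit[i] & q$layer == key$layer[i]]
    mean(model@atoms$z[model@atoms$resid %in% rs])
  }, numeric(1))
  key[order(key$z), ]
}

#' Axial extent of the stacked quartet layers
#'
#' @param model a \linkS4class{StructureModel}.
#' @return difference between the highest and lowest quartet-layer z (A).
#' @export
axialExtent <- function(model) {
  lp <- quartetLayerPositions(model)
  if (!nrow(lp)) return(NA_real_)
  diff(range(lp$z))
}

#' Radius of gyration of the atom coordinates
#'
#' @param model a \linkS4class{StructureModel}.
#' @return unweighted radius of gyration (A).
#' @export
radiusOfGyration <- function(model) {
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Minimum separation between quartet cores of different units
#'
#' Used to distinguish stacked (contact at the interface gap) from
#' unstacked beads-on-a-string arrangements (> 10 A).
#'
#' @param model a \linkS4class{StructureModel} with >= 2 units.
#' @return minimum atom-atom distance between quartet-core atoms of
#'   different units (A).
#' @export
minInterUnitSeparation <- function(model) {
  q <- model@topology[model@topology$role == "quartet", ]
  un <- unique(q$unit)
  if (length(un) < 2) stop("model has fewer than two quartet units")
  ring <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N2", "N1", "C6",
            "O6")
  core <- model@atoms[model@atoms$atom %in% ring, ]
  best <- Inf
  for (i in seq_along(un)) for (j in seq_along(un)) if (i < j) {
    a <- as.matrix(core[core$resid %in% q$resid[q$unit == un[i]],
                        c("x", "y", "z")])
    b <- as.matrix(core[core$resid %in% q$resid[q$unit == un[j]],
                        c("x", "y", "z")])
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    best <- min(best, sqrt(max(min(d2), 0)))
  }
  best
}

#' Diameter of the duplex region of a hybrid model
#'
#' @param model a \linkS4class{StructureModel} containing duplex residues.
#' @return twice the maximum radial distance of duplex-backbone
#'   phosphorus atoms from the duplex axis (A).
#' @export
duplexDiameter <- function(model) {
  dres <- model@topology$resid[model@topology$role == "duplex"]
  if (!length(dres)) stop("model contains no duplex residues")
  p <- model@atoms[model@atoms$resid %in% dres & model@atoms$atom == "P", ]
  ctr <- c(mean(p$x), mean(p$y))
  2 * max(sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2))
}
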