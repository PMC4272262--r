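# Idealized nucleotide geometry templates.
#
# All coordinates in Angstrom. The quartet template places a planar
# guanine so that four copies related by 90-degree rotations about the
# helix axis form a G-quartet with Hoogsteen contacts
# N1(i)...O6(i+1) = N2(i)...N7(i+1) = 2.9 A. Backbone atoms are attached
# at fixed offsets in a local (radial, tangential, axial) frame; the
# result is an idealized volume-faithful model, not a stereochemically
# refined one.

# guanine heavy atoms in the quartet position (base plane = z, helix
# axis through the origin); C1p is the glycosidic attachment point
.QUARTET_G <- rbind(
  N9 = c(4.0565, 5.3936),
  C8 = c(4.8972, 4.2980),
  N7 = c(4.2305, 3.1329),
  C5 = c(2.9054, 3.4546),
  C4 = c(2.8069, 4.8388),
  N3 = c(1.7148, 5.6409),
  C2 = c(0.5843, 4.9496),
  N2 = c(-0.5883, 5.6215),
  N1 = c(0.5216, 3.5862),
  C6 = c(1.6253, 2.7544),
  O6 = c(1.5253, 1.5187),
  C1p = c(4.4190, 6.8182))

# free-standing base templates (local plane coordinates, origin at the
# glycosidic nitrogen, C1' attachment along -x roughly)
.BASE_PURINE <- rbind(
  N9 = c(0, 0), C8 = c(0.694, 1.194), N7 = c(2.025, 1.020),
  C5 = c(2.231, -0.328), C4 = c(0.988, -0.945), N3 = c(0.661, -2.260),
  C2 = c(1.730, -3.043), N1 = c(3.015, -2.583), C6 = c(3.365, -1.246),
  X6 = c(4.546, -0.869))  # O6 (G) or N6 (A)

.BASE_PYRIMIDINE <- rbind(
  N1 = c(0, 0), C2 = c(0.703, 1.177), O2 = c(0.120, 2.280),
  N3 = c(2.093, 1.224), C4 = c(2.871, 0.094), X4 = c(4.100, 0.150),
  C5 = c(2.167, -1.148), C6 = c(0.784, -1.160))  # X4: O4 (T) / N4 (C)

# backbone offsets from C1' in the local (u = radial out, v = tangential,
# w = axial) frame
.BACKBONE <- rbind(
  `O4'` = c(0.7, 0.7, 0.6),
  `C2'` = c(0.9, -1.0, -0.5),
  `C3'` = c(2.0, -0.8, 0.2),
  `C4'` = c(1.9, 0.7, 0.5),
  `C5'` = c(2.9, 1.2, 1.1),
  `O3'` = c(3.1, -1.6, 0.6),
  `O5'` = c(3.6, 0.9, 2.2),
  P     = c(4.3, -0.3, 2.8),
  OP1   = c(5.3, -1.3, 3.3),
  OP2   = c(5.1, 0.8, 2.2))

.elem_of <- function(atom) substr(gsub("[^A-Za-z].*$", "", atom), 1, 1)

.rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# one guanine of a quartet layer: position k (0..3), layer angle `phase`,
# plane at height z. Returns matrix of atom coordinates with rownames.
.quartet_residue <- function(k, phase, z) {
  ang <- phase + k * pi / 2
  xy <- .QUARTET_G %*% .rot2(ang)
  c1 <- xy["C1p", ]
  u <- c1 / sqrt(sum(c1^2))        # radial out at C1'
  v <- c(-u[2], u[1])              # tangential
  bb <- cbind(outer(.BACKBONE[, 1], u[1]) + outer(.BACKBONE[, 2], v[1]),
              outer(.BACKBONE[, 1], u[2]) + outer(.BACKBONE[, 2], v[2]))
  bb <- sweep(bb, 2, c1, `+`)
  base3 <- cbind(xy[rownames(xy) != "C1p", , drop = FALSE], z)
  c13 <- matrix(c(c1, z), 1, dimnames = list("C1'", NULL))
  bb3 <- cbind(bb, z + .BACKBONE[, 3])
  out <- rbind(base3, c13, bb3)
  rownames(out)[rownames(out) == "O6"] <- "O6"
  out
}

# a free nucleotide placed with its base in the (tangential, axial) plane
# at cylindrical position (r, theta, z); used for loop/linker residues.
# `tilt` rotates the base within that plane.
.side_residue <- function(base, r, theta, z, tilt = 0) {
  er <- c(cos(theta), sin(theta), 0)
  et <- c(-sin(theta), cos(theta), 0)
  ez <- c(0, 0, 1)
  bt <- base %*% .rot2(tilt)
  anchor <- r * er + z * ez
  b3 <- t(anchor + t(bt[, 1] %o% et + bt[, 2] %o% ez))
  rownames(b3) <- rownames(base)
  c1 <- anchor + 1.5 * er
  # backbone runs along the loop path (tangentially), phosphates outward
  bb <- t(c1 + t(.BACKBONE[, 1] %o% et + .BACKBONE[, 2] %o% er +
                   .BACKBONE[, 3] %o% ez))
  rownames(bb) <- rownames(.BACKBONE)
  out <- rbind(b3, matrix(c1, 1, dimnames = list("C1'", NULL)), bb)
  out
}

# a nucleotide stacked on the helix axis (flanking residues, extended
# single-strand linkers): base roughly horizontal at modest radius
.axial_residue <- function(base, theta, z, r_scale = 1) {
  xy <- base %*% .rot2(theta)
  xy <- sweep(xy * r_scale, 2, c(2.0 * cos(theta), 2.0 * sin(theta)), `+`)
  b3 <- cbind(xy, z)
  n0 <- b3[1, 1:2]
  rr <- sqrt(sum(n0^2))
  u <- if (rr > 1e-6) c(n0 / rr, 0) else c(1, 0, 0)
  v <- c(-u[2], u[1], 0)
  c1 <- c(b3[1, 1:2], z) + 1.5 * u
  bb <- t(c1 + t(.BACKBONE[, 1] %o% u + .BACKBONE[, 2] %o% v +
                   .BACKBONE[, 3] %o% c(0, 0, 1)))
  rownames(bb) <- rownames(.BACKBONE)
  out <- rbind(b3, matrix(c1, 1, dimnames = list("C1'", NULL)), bb)
  out
}

.base_template <- function(base) {
  switch(base,
    G = , A = {
      b <- .BASE_PURINE
      rownames(b)[rownames(b) == "X6"] <- if (base == "G") "O6" else "N6"
      b
    },
    C = , T = {
      b <- .BASE_PYRIMIDINE
      rownames(b)[rownames(b) == "X4"] <- if (base == "T") "O4" else "N4"
      b
    },
    stop("unknown base: ", base))
}

.resname_of <- function(base) paste0("D", base)

# assemble an atoms data.frame from a named coordinate matrix
.atoms_df <- function(coords, resid, resname) {
  data.frame(atom = rownames(coords), element = .elem_of(rownames(coords)),
             resid = resid, resname = resname,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             row.names = NULL)
}
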