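# Rigid-body bead-shell hydrodynamics.
#
# The surface of the AER-inflated atomic model is tiled with mini-beads
# of radius sigma; the 3N x 3N pairwise mobility supermatrix
# (Rotne-Prager-Yamakawa tensor, regularized for overlap) is solved for
# the forces sustaining each rigid-body motion; the resulting 6 x 6
# resistance matrix gives the diffusion tensors, and properties are
# extrapolated linearly in sigma to the sigma -> 0 limit.

.KB <- 1.380649e-16   # Boltzmann constant, erg/K
.NA_AVOG <- 6.02214076e23

# near-uniform points on the unit sphere (Fibonacci lattice)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# tile the exposed surface of a union of spheres (centers cm, radii cm)
# with mini-bead centres at spacing ~2*sigma
.shell_beads <- function(centers, radii, sigma, max_beads = 2500) {
  N <- nrow(centers)
  if (N == 1L) {
    n <- max(12L, ceiling(4 * pi * radii[1]^2 / (3.46 * sigma^2)))
    return(sweep(.fib_sphere(n) * radii[1], 2, centers[1, ], `+`))
  }
  D <- as.matrix(stats::dist(centers))
  out <- vector("list", N)
  for (i in seq_len(N)) {
    n <- max(6L, ceiling(4 * pi * radii[i]^2 / (3.46 * sigma^2)))
    p <- sweep(.fib_sphere(n) * radii[i], 2, centers[i, ], `+`)
    nb <- which(D[i, ] < radii[i] + radii & seq_len(N) != i)
    keep <- rep(TRUE, nrow(p))
    for (j in nb) {
      d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      keep <- keep & (d2 > (radii[j] - 1e-12)^2)
    }
    out[[i]] <- p[keep, , drop = FALSE]
  }
  beads <- do.call(rbind, out)
  if (nrow(beads) > max_beads)
    stop("shell resolution produced ", nrow(beads), " beads (cap ",
         max_beads, "); use a larger sigma or raise max_beads")
  beads
}

# 3N x 3N Rotne-Prager-Yamakawa mobility supermatrix for equal bead
# radii sigma, with the overlap-regularized form for r < 2*sigma
.rpy_mobility <- function(P, sigma, eta) {
  N <- nrow(P)
  dx <- outer(P[, 1], P[, 1], `-`)
  dy <- outer(P[, 2], P[, 2], `-`)
  dz <- outer(P[, 3], P[, 3], `-`)
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  diag(r) <- 1
  ex <- dx / r; ey <- dy / r; ez <- dz / r
  near <- which(r < 2 * sigma)
  rn <- r[near]
  inv6 <- 1 / (6 * pi * eta * sigma)
  c1 <- 1 / (8 * pi * eta * r)
  c2 <- 2 * sigma^2 / (r * r)
  B <- matrix(0, 3 * N, 3 * N)
  ix <- seq(1L, 3L * N, 3L)
  I <- list(ix, ix + 1L, ix + 2L)
  comps <- list(list(1L, 1L, ex, ex), list(1L, 2L, ex, ey),
                list(1L, 3L, ex, ez), list(2L, 2L, ey, ey),
                list(2L, 3L, ey, ez), list(3L, 3L, ez, ez))
  for (cc in comps) {
    a <- cc[[1]]; b <- cc[[2]]
    del <- as.numeric(a == b)
    ee <- cc[[3]] * cc[[4]]
    M <- c1 * ((del + ee) + c2 * (del / 3 - ee))
    M[near] <- inv6 * ((1 - 9 * rn / (32 * sigma)) * del +
                         (3 * rn / (32 * sigma)) * ee[near])
    diag(M) <- del * inv6
    B[I[[a]], I[[b]]] <- M
    if (a != b) B[I[[b]], I[[a]]] <- M
  }
  B
}

.cross_rows <- function(R, f)
  cbind(R[, 2] * f[, 3] - R[, 3] * f[, 2],
        R[, 3] * f[, 1] - R[, 1] * f[, 3],
        R[, 1] * f[, 2] - R[, 2] * f[, 1])

#' Shell-bead tiling of a union of atom spheres
#'
#' Exposes the mini-bead shell used internally by [shellModel()]:
#' every atom is inflated to its radius and the exposed surface of the
#' union is tiled with bead centres at spacing ~2 sigma.
#'
#' @param centers n x 3 matrix of atom centres (Angstrom).
#' @param radii atom radii (Angstrom), recycled to n.
#' @param sigma mini-bead radius (Angstrom).
#' @param max_beads cap on the bead count.
#' @return m x 3 matrix of bead centres (Angstrom).
#' @export
shellBeads <- function(centers, radii, sigma, max_beads = 10000) {
  centers <- as.matrix(centers)
  radii <- rep_len(radii, nrow(centers))
  .shell_beads(centers * 1e-8, radii * 1e-8, sigma * 1e-8,
               max_beads = max_beads) * 1e8
}

#' Rigid-body diffusion tensors of a bead array
#'
#' Solves the Rotne-Prager-Yamakawa mobility supermatrix for the rigid
#' translations and rotations of a bead array, assembles the 6 x 6
#' resistance matrix, and returns the diffusion tensors with the
#' translational block referred to the centre of diffusion.
#'
#' @param beads n x 3 matrix of bead centres (cm).
#' @param sigma common bead radius (cm).
#' @param eta solvent viscosity (poise).
#' @param temperature absolute temperature (K).
#' @return list with \code{Dt} (trace/3 of the translational tensor at
#'   the centre of diffusion, cm^2/s), \code{Dr_eig} (rotational
#'   eigenvalues, 1/s, descending; NA for a single bead), \code{f_trans}
#'   (kT/Dt, g/s), and \code{n_beads}.
#' @examples
#' b <- rigidBodyTensors(matrix(0, 1, 3), 1e-7, 0.01002, 293.15)
#' b$f_trans / (6 * pi * 0.01002 * 1e-7)  # exactly 1
#' @export
rigidBodyTensors <- function(beads, sigma, eta, temperature) {
  N <- nrow(beads)
  kT <- .KB * temperature
  if (N == 1L) {
    f <- 6 * pi * eta * sigma
    return(list(Dt = kT / f, Dr_eig = rep(NA_real_, 3), f_trans = f,
                n_beads = 1L))
  }
  O <- colMeans(beads)
  Pc <- sweep(beads, 2, O)
  B <- .rpy_mobility(beads, sigma, eta)
  U <- matrix(0, 3 * N, 6)
  for (k in 1:3) {
    u <- matrix(0, N, 3)
    u[, k] <- 1
    U[, k] <- as.numeric(t(u))
  }
  E <- diag(3)
  for (k in 1:3)   # velocity field of unit rotation: u_i = e_k x r_i
    U[, 3 + k] <- as.numeric(t(.cross_rows(matrix(E[k, ], N, 3, byrow = TRUE),
                                           Pc)))
  Fm <- tryCatch({
    R <- chol(B)
    backsolve(R, forwardsolve(t(R), U))
  }, error = function(e)
    tryCatch(solve(B, U), error = function(e2)
      stop("mobility supermatrix is singular or ill-conditioned: ",
           conditionMessage(e2))))
  Xi <- matrix(0, 6, 6)
  for (k in 1:6) {
    f <- matrix(Fm[, k], N, 3, byrow = TRUE)
    Xi[1:3, k] <- colSums(f)
    Xi[4:6, k] <- colSums(.cross_rows(Pc, f))
  }
  Xi <- (Xi + t(Xi)) / 2
  D <- kT * solve(Xi)
  Dtt <- D[1:3, 1:3]
  Dtr <- D[4:6, 1:3]   # coupling block (rotation rows, translation cols)
  Drr <- D[4:6, 4:6]
  # centre of diffusion (makes Dtt stationary)
  A <- matrix(c(Drr[2, 2] + Drr[3, 3], -Drr[1, 2], -Drr[1, 3],
                -Drr[1, 2], Drr[1, 1] + Drr[3, 3], -Drr[2, 3],
                -Drr[1, 3], -Drr[2, 3], Drr[1, 1] + Drr[2, 2]), 3, 3)
  rhs <- c(Dtr[2, 3] - Dtr[3, 2], Dtr[3, 1] - Dtr[1, 3],
           Dtr[1, 2] - Dtr[2, 1])
  rD <- tryCatch(solve(A, rhs), error = function(e) c(0, 0, 0))
  Ur <- matrix(c(0, -rD[3], rD[2],
                 rD[3], 0, -rD[1],
                 -rD[2], rD[1], 0), 3, 3, byrow = TRUE)
  DttD <- Dtt - Ur %*% Drr %*% Ur + Dtr %*% Ur - t(Dtr %*% Ur)
  Dt <- mean(diag(DttD))
  list(Dt = Dt,
       Dr_eig = sort(eigen(Drr, symmetric = TRUE)$values, decreasing = TRUE),
       f_trans = kT / Dt, n_beads = N)
}

#' Kirkwood double-sum estimate of translational diffusion
#'
#' The classical Kirkwood approximation for a rigid array of equal
#' beads, \eqn{D_t = \frac{k T}{N^2}\left[\frac{N}{6\pi\eta\sigma} +
#' \sum_{i \ne j}\frac{1}{6\pi\eta r_{ij}}\right]}; used as an
#' independent cross-check of the supermatrix solution on small
#' clusters.
#'
#' @inheritParams rigidBodyTensors
#' @return Dt in cm^2/s.
#' @export
kirkwoodDt <- function(beads, sigma, eta, temperature) {
  N <- nrow(beads)
  kT <- .KB * temperature
  if (N == 1L) return(kT / (6 * pi * eta * sigma))
  r <- as.matrix(stats::dist(beads))
  s <- sum(1 / r[upper.tri(r)]) * 2
  (kT / N^2) * (N / (6 * pi * eta * sigma) + s / (6 * pi * eta))
}

#' Bead-shell hydrodynamic calculation for a structure model
#'
#' Converts a \linkS4class{StructureModel} to a shell of mini-beads at
#' each radius in \code{sigma_ladder} (every heavy atom inflated to the
#' hydrated atomic element radius \code{aer(params)}), solves the
#' rigid-body mobility problem at each resolution, extrapolates
#' linearly in sigma to the zero-size limit, and derives sedimentation
#' and rotational quantities.
#'
#' @param structure a \linkS4class{StructureModel}, or an n x 3 matrix of
#'   atom coordinates in Angstrom.
#' @param mass molar mass of the molecule (Da), used for the Svedberg
#'   relation and frictional ratio.
#' @param params a \linkS4class{HydroParams} (default: water at 20 C,
#'   quadruplex conventions).
#' @param sigma_ladder >= 3 decreasing mini-bead radii (Angstrom) for the
#'   sigma -> 0 extrapolation.
#' @param max_beads cap on the number of shell beads per resolution.
#' @return a \linkS4class{HydroResult}.
#' @seealso [rigidBodyTensors()], [sedimentationCoefficient()],
#'   [rotationalRelaxation()]
#' @export
shellModel <- function(structure, mass, params = hydroParams(),
                       sigma_ladder = c(2.5, 2.1, 1.8),
                       max_beads = 2500) {
  xyz <- if (is(structure, "StructureModel"))
    as.matrix(structure@atoms[, c("x", "y", "z")]) else as.matrix(structure)
  if (ncol(xyz) != 3) stop("coordinates must be n x 3")
  if (length(sigma_ladder) < 3 || any(diff(sigma_ladder) >= 0))
    stop("sigma_ladder must give >= 3 strictly decreasing radii")
  aer_cm <- params@aer * 1e-8
  centers <- xyz * 1e-8
  res <- lapply(sigma_ladder, function(sA) {
    beads <- .shell_beads(centers, rep(aer_cm, nrow(centers)), sA * 1e-8,
                          max_beads = max_beads)
    rigidBodyTensors(beads, sA * 1e-8, params@eta, params@temperature)
  })
  n_beads <- vapply(res, `[[`, numeric(1), "n_beads")
  Dt_l <- vapply(res, `[[`, numeric(1), "Dt")
  Dr_l <- t(vapply(res, `[[`, numeric(3), "Dr_eig"))
  Dt <- unname(stats::coef(stats::lm(Dt_l ~ sigma_ladder))[1])
  Dr <- vapply(1:3, function(k)
    unname(stats::coef(stats::lm(Dr_l[, k] ~ sigma_ladder))[1]), numeric(1))
  f <- .KB * params@temperature / Dt
  s <- sedimentationCoefficient(f, mass, params)
  s20w <- s20wStandardize(s, params@eta, params@rho_solvent, params)
  new("HydroResult",
      f_trans = f, Dt = Dt, Dr = sort(Dr, decreasing = TRUE),
      s = s, s20w = s20w,
      f_ratio = frictionalRatio(s20w, mass, params),
      rho_rot = rotationalRelaxation(Dr),
      conditions = list(mass = mass, vbar = params@vbar,
                        hydration = params@hydration, eta = params@eta,
                        rho_solvent = params@rho_solvent,
                        temperature = params@temperature, aer = params@aer,
                        sigma_ladder = sigma_ladder, n_beads = n_beads,
                        relax_ns = 1e9 / (2 * sort(Dr, decreasing = TRUE))))
}

#' Calibrate the atomic element radius against a target sedimentation
#' coefficient
#'
#' Hydrodynamic bead-shell calculations for nucleic acids require a
#' hydrated atomic element radius (AER); published recommendations are
#' calibrated against structures of known sedimentation coefficient.
#' This helper tunes the AER (within the physically sensible range
#' 1.5-4.5 Angstrom) so that a reference structure reproduces a target
#' s value under the given conditions.
#'
#' @inheritParams shellModel
#' @param target_s target sedimentation coefficient (Svedberg).
#' @param interval AER search interval (Angstrom).
#' @param tol convergence tolerance on s (Svedberg).
#' @return the calibrated AER (Angstrom).
#' @export
calibrateAER <- function(structure, mass, target_s,
                         params = hydroParams(),
                         sigma_ladder = c(2.5, 2.1, 1.8),
                         interval = c(1.5, 4.5), tol = 0.005,
                         max_beads = 2500) {
  fs <- function(a) {
    p <- params
    p@aer <- a
    shellModel(structure, mass, p, sigma_ladder, max_beads)@s20w - target_s
  }
  lo <- fs(interval[1])
  hi <- fs(interval[2])
  if (sign(lo) == sign(hi))
    stop("target s = ", target_s,
         " S is not bracketed by AER in [", interval[1], ", ", interval[2],
         "] (s range ", round(hi + target_s, 2), " - ",
         round(lo + target_s, 2), " S)")
  stats::uniroot(fs, interval, f.lower = lo, f.upper = hi,
                 tol = tol)$root
}
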