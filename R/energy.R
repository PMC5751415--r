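# Force-field energy terms: bonded (harmonic bond/angle, cosine
# torsion), nonbonded (Lennard-Jones + Coulomb with 1-4 scaling),
# Generalized Born solvation with OBC-rescaled pairwise descreening,
# and LCPO solvent-accessible surface area. Amber conventions
# throughout: k(r - r0)^2 without the 1/2, Rmin/2 + well-depth LJ,
# (V_n/2)(1 + cos(n phi - gamma)) torsions, 1-4 scalings 1.2 (elec)
# and 2.0 (vdW). All pairs are summed; no cutoff.

vec_norm <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

clamp_cos <- function(x, what) {
  out <- x
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("degenerate ", what, " geometry; cosine clamped", call. = FALSE)
    out[bad] <- 1
  }
  if (any(out > 1 | out < -1)) out <- pmin(1, pmax(-1, out))
  out
}

#' Bonded molecular-mechanics energy
#'
#' Harmonic bonds `sum k_b (r - r0)^2`, harmonic angles
#' `sum k_theta (theta - theta0)^2` and periodic torsions
#' `sum (V_n/2)(1 + cos(n phi - gamma))`. Colinear angle or torsion
#' geometry is resolved by clamping the cosine with a warning.
#'
#' @param top A [topology()].
#' @param snap A [snapshot()] (or bare N x 3 matrix).
#' @return Named numeric `c(e_bond, e_angle, e_torsion)` in kcal/mol.
#' @export
bonded_energy <- function(top, snap) {
  snap <- check_snapshot(top, snap)
  xyz <- snap$coordinates
  e_bond <- 0
  if (nrow(top$bonds) > 0) {
    d <- vec_norm(xyz[top$bonds$i, , drop = FALSE] -
                    xyz[top$bonds$j, , drop = FALSE])
    e_bond <- sum(top$bonds$k_b * (d - top$bonds$r0)^2)
  }
  e_angle <- 0
  if (nrow(top$angles) > 0) {
    u <- xyz[top$angles$i, , drop = FALSE] - xyz[top$angles$j, , drop = FALSE]
    v <- xyz[top$angles$k, , drop = FALSE] - xyz[top$angles$j, , drop = FALSE]
    ct <- clamp_cos(rowSums(u * v) / (vec_norm(u) * vec_norm(v)), "angle")
    theta <- acos(ct)
    e_angle <- sum(top$angles$k_theta * (theta - top$angles$theta0)^2)
  }
  e_torsion <- 0
  if (nrow(top$torsions) > 0) {
    tt <- top$torsions
    b1 <- xyz[tt$j, , drop = FALSE] - xyz[tt$i, , drop = FALSE]
    b2 <- xyz[tt$k, , drop = FALSE] - xyz[tt$j, , drop = FALSE]
    b3 <- xyz[tt$l, , drop = FALSE] - xyz[tt$k, , drop = FALSE]
    n1 <- cross3(b1, b2)
    n2 <- cross3(b2, b3)
    m1 <- cross3(n1, b2 / pmax(vec_norm(b2), 1e-12))
    x <- rowSums(n1 * n2)
    y <- rowSums(m1 * n2)
    denom <- vec_norm(n1) * vec_norm(n2)
    phi <- atan2(y, x)
    if (any(denom < 1e-12)) {
      warning("degenerate torsion geometry; dihedral set to 0", call. = FALSE)
      phi[denom < 1e-12] <- 0
    }
    e_torsion <- sum(tt$v_n / 2 * (1 + cos(tt$periodicity * phi - tt$phase)))
  }
  c(e_bond = e_bond, e_angle = e_angle, e_torsion = e_torsion)
}

pair_dist <- function(xyz, pairs) {
  vec_norm(xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE])
}

#' Nonbonded energy (Lennard-Jones + Coulomb)
#'
#' Sums over every atom pair not excluded as 1-2 or 1-3; 1-4 pairs
#' (three bonds apart) are divided by 1.2 (electrostatic) and 2.0
#' (van der Waals). Lorentz-Berthelot combination:
#' `Rmin_ij = rmin_half_i + rmin_half_j`, `eps_ij = sqrt(eps_i eps_j)`.
#' The Coulomb constant is 332.0636 kcal A mol^-1 e^-2. No cutoff is
#' applied.
#'
#' @inheritParams bonded_energy
#' @param eps_in Interior dielectric dividing the Coulomb term.
#' @return Named numeric `c(e_vdw, e_elec)` in kcal/mol.
#' @export
nonbonded_energy <- function(top, snap, eps_in = 1) {
  snap <- check_snapshot(top, snap)
  xyz <- snap$coordinates
  at <- top$atoms
  one_set <- function(pairs, elec_scale, vdw_scale) {
    if (nrow(pairs) == 0) return(c(0, 0))
    r <- pair_dist(xyz, pairs)
    if (any(r < 1e-6)) {
      b <- which(r < 1e-6)[1]
      stop(sprintf("atoms %d and %d are coincident (r = %g A)",
                   pairs[b, 1], pairs[b, 2], r[b]), call. = FALSE)
    }
    i <- pairs[, 1]; j <- pairs[, 2]
    rmin <- at$rmin_half[i] + at$rmin_half[j]
    eps <- sqrt(at$epsilon[i] * at$epsilon[j])
    sr6 <- (rmin / r)^6
    e_vdw <- sum(eps * (sr6^2 - 2 * sr6)) * vdw_scale
    e_elec <- sum(cgbsa_constants$k_coulomb * at$charge[i] * at$charge[j] /
                    (eps_in * r)) * elec_scale
    c(e_vdw, e_elec)
  }
  full <- one_set(top$pairs$full, 1, 1)
  s14 <- one_set(top$pairs$scaled14, 1 / 1.2, 1 / 2.0)
  c(e_vdw = full[1] + s14[1], e_elec = full[2] + s14[2])
}

#' Effective Born radii (OBC rescaling)
#'
#' Pairwise-descreening integrals over neighbour spheres (scaled by
#' each atom's `gb_screen` factor) with the tanh rescaling
#' `1/R_i = 1/rho_i' - tanh(alpha psi - beta psi^2 + gamma psi^3) / rho_i`
#' where `rho_i' = gb_radius - gb_offset`.
#'
#' @inheritParams bonded_energy
#' @param cfg A [solvent_config()].
#' @return Numeric vector of effective Born radii in A.
#' @export
effective_born_radii <- function(top, snap, cfg = solvent_config()) {
  snap <- check_snapshot(top, snap)
  xyz <- snap$coordinates
  at <- top$atoms
  n <- nrow(at)
  rho <- at$gb_radius - cfg$gb_offset
  if (any(rho <= 0)) {
    stop("atom ", which(rho <= 0)[1],
         " has gb_radius <= gb_offset; offset radius non-positive",
         call. = FALSE)
  }
  sj <- at$gb_screen * rho
  dmat <- as.matrix(stats::dist(xyz))
  a <- cfg$gb_scaling[1]; b <- cfg$gb_scaling[2]; g <- cfg$gb_scaling[3]
  # descreening of atom i (rows) by atom j (columns), vectorised
  rmat <- dmat
  smat <- matrix(sj, n, n, byrow = TRUE)
  rhom <- matrix(rho, n, n)
  active <- rhom < rmat + smat
  diag(active) <- FALSE
  l_ij <- 1 / pmax(rhom, abs(rmat - smat))
  u_ij <- 1 / (rmat + smat)
  term <- l_ij - u_ij + 0.25 * rmat * (u_ij^2 - l_ij^2) +
    0.5 * log(u_ij / l_ij) / rmat + 0.25 * smat^2 * (l_ij^2 - u_ij^2) / rmat
  inside <- rhom < smat - rmat
  term[inside] <- term[inside] + 2 * (1 / rhom[inside] - l_ij[inside])
  term[!active] <- 0
  psi <- 0.5 * rowSums(term) * rho
  inv <- 1 / rho - tanh(a * psi - b * psi^2 + g * psi^3) / at$gb_radius
  if (any(inv <= 0)) {
    i <- which(inv <= 0)[1]
    stop("effective Born radius non-positive for atom ", i,
         " (", at$name[i], ")", call. = FALSE)
  }
  1 / inv
}

#' Generalized Born solvation energy
#'
#' `dG_GB = -(k_e/2) sum_ij (1/eps_in - exp(-kappa f_ij)/eps_out)
#' q_i q_j / f_ij` with
#' `f_ij = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`, summed over
#' all ordered pairs including self terms (`f_ii = R_i`). The Debye
#' screening constant `kappa` follows from `salt_conc`; it is zero in
#' pure water.
#'
#' @inheritParams effective_born_radii
#' @param born_radii Optional precomputed effective radii; computed
#'   via [effective_born_radii()] when `NULL`.
#' @return Scalar `g_gb` in kcal/mol.
#' @export
gb_energy <- function(top, snap, cfg = solvent_config(), born_radii = NULL) {
  snap <- check_snapshot(top, snap)
  q <- top$atoms$charge
  if (all(q == 0)) return(0)
  if (is.null(born_radii)) born_radii <- effective_born_radii(top, snap, cfg)
  xyz <- snap$coordinates
  d2 <- as.matrix(stats::dist(xyz))^2
  rr <- outer(born_radii, born_radii)
  f <- sqrt(d2 + rr * exp(-d2 / (4 * rr)))
  kappa <- debye_kappa(cfg$salt_conc)
  pref <- 1 / cfg$eps_in - exp(-kappa * f) / cfg$eps_out
  qq <- outer(q, q)
  -(cgbsa_constants$k_coulomb / 2) * sum(pref * qq / f)
}

#' LCPO solvent-accessible surface area
#'
#' Linear Combination of Pairwise Overlaps. For atom i with solvated
#' radius `r_i = vdw_radius + probe` and neighbour set N(i) (atoms
#' within `r_i + r_j` of i, radii solvated):
#' `A_i = P1 S1 + P2 sum_j A_ij + P3 sum_{j,k} A_jk + P4 sum_j A_ij
#' sum_k A_jk`, with `S1 = 4 pi r_i^2`, `A_ij` the pairwise overlap
#' of j on i, and the j,k sums running over neighbour pairs of i that
#' are themselves neighbours. Per-atom areas are clamped to
#' `[0, S1]`.
#'
#' @inheritParams bonded_energy
#' @param probe Solvent probe radius in A (default 1.4).
#' @return List with `per_atom` (numeric, A^2) and `total` (A^2).
#' @export
lcpo_sasa <- function(top, snap, probe = 1.4) {
  snap <- check_snapshot(top, snap)
  xyz <- snap$coordinates
  at <- top$atoms
  n <- nrow(at)
  rad <- at$vdw_radius + probe
  s1 <- 4 * pi * rad^2
  dmat <- as.matrix(stats::dist(xyz))
  ri <- matrix(rad, n, n)
  rj <- t(ri)
  nbm <- dmat < ri + rj
  diag(nbm) <- FALSE
  # overlap of sphere j's cap on sphere i, zero for non-neighbours
  aij <- 2 * pi * ri * (ri - dmat / 2 - (ri^2 - rj^2) / (2 * dmat))
  aij[!nbm] <- 0
  diag(aij) <- 0
  # inner(i, j) = sum_{k in N(i) inter N(j)} A_jk; matrix product over
  # the shared-neighbour mask
  w <- aij * nbm
  inner <- nbm %*% t(w)
  t2 <- rowSums(aij)
  t3 <- rowSums(nbm * inner)
  t4 <- rowSums(aij * inner)
  area <- at$p1 * s1 + at$p2 * t2 + at$p3 * t3 + at$p4 * t4
  per_atom <- pmin(pmax(area, 0), s1)
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Total single-configuration free energy (MM + GB + SA)
#'
#' `G = E_MM + G_GB + G_SA` with `G_SA = surface_tension * SASA +
#' surface_offset`. Bonded terms can be excluded (they cancel exactly
#' in single-trajectory binding energies).
#'
#' @inheritParams effective_born_radii
#' @param include_bonded Include bond/angle/torsion terms
#'   (default `TRUE`).
#' @return An `energy_breakdown`: list with `e_bond`, `e_angle`,
#'   `e_torsion`, `e_vdw`, `e_elec`, `g_gb`, `g_sa` and `total`
#'   (kcal/mol); `total` is the exact sum of the seven components.
#' @export
total_free_energy <- function(top, snap, cfg = solvent_config(),
                              include_bonded = TRUE) {
  snap <- check_snapshot(top, snap)
  bonded <- if (include_bonded) bonded_energy(top, snap) else {
    c(e_bond = 0, e_angle = 0, e_torsion = 0)
  }
  nb <- nonbonded_energy(top, snap, cfg$eps_in)
  g_gb <- gb_energy(top, snap, cfg)
  sasa <- lcpo_sasa(top, snap, cfg$probe_radius)
  g_sa <- cfg$surface_tension * sasa$total + cfg$surface_offset
  parts <- c(bonded, nb, g_gb = g_gb, g_sa = g_sa)
  structure(as.list(c(parts, total = sum(parts))), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kcal/mol):\n")
  for (k in c("e_bond", "e_angle", "e_torsion", "e_vdw", "e_elec",
              "g_gb", "g_sa", "total")) {
    cat(sprintf("  %-10s %12.4f\n", k, x[[k]]))
  }
  invisible(x)
}
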