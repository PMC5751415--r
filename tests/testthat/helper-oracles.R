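# Independent oracles, written against the definitions rather than
# the package internals: numerical Shrake-Rupley surface area,
# brute-force nonbonded double loop with its own bond-graph
# classification, and a textbook Pearson correlation.

golden_spiral_points <- function(m) {
  k <- seq_len(m)
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * k - 1) / m
  theta <- 2 * pi * k / golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

# Numerical SASA: fraction of surface points on each solvated sphere
# outside every other solvated sphere.
shrake_rupley_sasa <- function(xyz, radii, probe, n_points = 960) {
  rs <- radii + probe
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  per <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rs[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums((p - matrix(xyz[j, ], n_points, 3, byrow = TRUE))^2)
      free <- free & d2 > rs[j]^2
    }
    per[i] <- 4 * pi * rs[i]^2 * mean(free)
  }
  list(per_atom = per, total = sum(per))
}

# All-pairs LJ + Coulomb with an independent Floyd-Warshall bond-graph
# classification (1-2/1-3 excluded, 1-4 scaled by 1/1.2 and 1/2).
brute_nonbonded <- function(top, xyz, eps_in = 1) {
  n <- nrow(top$atoms)
  g <- matrix(Inf, n, n)
  diag(g) <- 0
  if (nrow(top$bonds) > 0) {
    for (r in seq_len(nrow(top$bonds))) {
      g[top$bonds$i[r], top$bonds$j[r]] <- 1
      g[top$bonds$j[r], top$bonds$i[r]] <- 1
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (g[i, k] + g[k, j] < g[i, j]) g[i, j] <- g[i, k] + g[k, j]
  }
  e_vdw <- 0
  e_elec <- 0
  at <- top$atoms
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (g[i, j] <= 2) next
    sc_e <- if (g[i, j] == 3) 1 / 1.2 else 1
    sc_v <- if (g[i, j] == 3) 1 / 2.0 else 1
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rmin <- at$rmin_half[i] + at$rmin_half[j]
    eps <- sqrt(at$epsilon[i] * at$epsilon[j])
    e_vdw <- e_vdw + sc_v * eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    e_elec <- e_elec + sc_e * 332.0636 * at$charge[i] * at$charge[j] / (eps_in * r)
  }
  c(e_vdw = e_vdw, e_elec = e_elec)
}

# Textbook Pearson r^2 from raw sums, independent of stats::cor.
pearson_r2_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# Uniform-parameter test topology over given coordinates.
plain_cluster_topology <- function(n, p = c(1, -1, 0, 0), charge = 0,
                                   radius = 1.7, epsilon = 0) {
  topology(
    data.frame(name = sprintf("A%d", seq_len(n)), charge = charge,
               rmin_half = radius, epsilon = epsilon, gb_radius = radius,
               vdw_radius = radius, p1 = p[1], p2 = p[2], p3 = p[3],
               p4 = p[4], stringsAsFactors = FALSE),
    receptor = seq_len(n), ligand = integer(0)
  )
}

# Chain-grown random cluster with pairwise spacing in [dmin, dmax]:
# neighbours overlap at solvated radii without deep multi-sphere
# burial, the regime the pairwise-overlap expansion is valid in.
chain_cluster <- function(n, seed, dmin = 4.2, dmax = 5.5) {
  set.seed(seed)
  xyz <- matrix(0, 1, 3)
  while (nrow(xyz) < n) {
    base <- xyz[sample(nrow(xyz), 1), ]
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    cand <- base + dir * stats::runif(1, dmin, dmax)
    d <- sqrt(rowSums((xyz - matrix(cand, nrow(xyz), 3, byrow = TRUE))^2))
    if (min(d) >= dmin) xyz <- rbind(xyz, cand)
  }
  unname(xyz)
}

rigid_transform <- function(xyz, angle = 0.7, axis = c(1, 2, 2),
                            shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s1 * K + (1 - c1) * (K %*% K)
  sweep(xyz %*% t(R), 2, -shift)
}
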