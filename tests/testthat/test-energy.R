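test_that("bonded terms match hand values on single-term systems", {
  at4 <- plain_cluster_topology(4)$atoms
  top <- topology(at4, bonds = data.frame(i = 1, j = 2, k_b = 100, r0 = 1.5),
                  receptor = 1:4, ligand = integer(0))
  xyz <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(8, 8, 8), c(16, 16, 16))
  expect_equal(unname(bonded_energy(top, snapshot(xyz))["e_bond"]), 1.00,
               tolerance = 1e-10)
  top_a <- topology(at4, angles = data.frame(i = 1, j = 2, k = 3, k_theta = 50,
                                             theta0 = pi / 2 - 0.1),
                    receptor = 1:4, ligand = integer(0))
  xyz_a <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(9, 9, 9))
  expect_equal(unname(bonded_energy(top_a, snapshot(xyz_a))["e_angle"]), 0.50,
               tolerance = 1e-10)
  # planar cis dihedral: phi = 0, V2 with phase pi vanishes
  top_t <- topology(at4, torsions = data.frame(i = 1, j = 2, k = 3, l = 4,
                                               v_n = 2.0, periodicity = 2,
                                               phase = pi),
                    receptor = 1:4, ligand = integer(0))
  xyz_t <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(unname(bonded_energy(top_t, snapshot(xyz_t))["e_torsion"]), 0,
               tolerance = 1e-10)
})

test_that("nonbonded closed forms: Coulomb pair and LJ minimum", {
  top <- plain_cluster_topology(2, charge = 0)
  top$atoms$charge <- c(1, -1)
  top <- topology(top$atoms, receptor = 1, ligand = 2)
  sn <- snapshot(rbind(c(0, 0, 0), c(3.320636, 0, 0)))
  e <- nonbonded_energy(top, sn, eps_in = 1)
  expect_equal(unname(e["e_elec"]), -100.00, tolerance = 1e-6)
  # LJ pair at its minimum: rmin_half 1.7 each, eps 0.1
  top2 <- plain_cluster_topology(2, epsilon = 0.1)
  top2 <- topology(top2$atoms, receptor = 1, ligand = 2)
  sn2 <- snapshot(rbind(c(0, 0, 0), c(3.4, 0, 0)))
  expect_equal(unname(nonbonded_energy(top2, sn2)["e_vdw"]), -0.1,
               tolerance = 1e-10)
  # all charges and well depths zero
  expect_equal(unname(nonbonded_energy(plain_cluster_topology(3),
                                       snapshot(chain_cluster(3, 1)))),
               c(0, 0))
  # coincident atoms are a hard error naming the pair
  expect_error(nonbonded_energy(top, snapshot(matrix(0, 2, 3))), "coincident")
})

test_that("nonbonded energies match the brute-force oracle with exclusions", {
  for (seed in c(11, 23)) {
    set.seed(seed)
    n <- 40
    xyz <- chain_cluster(n, seed, dmin = 3.0, dmax = 4.0)
    atoms <- data.frame(
      name = sprintf("A%d", 1:n), charge = stats::rnorm(n, 0, 0.3),
      rmin_half = stats::runif(n, 1.6, 1.9),
      epsilon = stats::runif(n, 0.05, 0.2),
      gb_radius = 1.7, vdw_radius = 1.7, p1 = 0, p2 = 0, p3 = 0, p4 = 0)
    # bonded chain so 1-2/1-3 exclusions and 1-4 scaling are exercised
    bonds <- data.frame(i = 1:(n - 1), j = 2:n, k_b = 300, r0 = 3.5)
    top <- topology(atoms, bonds = bonds, receptor = 1:(n - 5),
                    ligand = (n - 4):n)
    got <- nonbonded_energy(top, snapshot(xyz))
    want <- brute_nonbonded(top, xyz)
    expect_equal(unname(got["e_vdw"]), unname(want["e_vdw"]), tolerance = 1e-8)
    expect_equal(unname(got["e_elec"]), unname(want["e_elec"]), tolerance = 1e-8)
  }
})

test_that("GB single sphere reproduces the analytic Born energy", {
  born <- function(q, R, eps_out) {
    -(332.0636 / 2) * (1 - 1 / eps_out) * q^2 / R
  }
  for (case in list(c(1, 2.0, 78.5), c(-0.5, 1.4, 78.5), c(2, 3.0, 40))) {
    q <- case[1]; R <- case[2]; eo <- case[3]
    top <- plain_cluster_topology(1, charge = q, radius = R + 0.09)
    top$atoms$gb_radius <- R + 0.09  # offset radius becomes exactly R
    sn <- snapshot(matrix(0, 1, 3))
    cfg <- solvent_config(eps_out = eo)
    expect_equal(gb_energy(top, sn, cfg), born(q, R, eo), tolerance = 1e-8)
  }
  # the measured reference point: q = 1 e, R = 2 A, eps 78.5
  top <- plain_cluster_topology(1, charge = 1, radius = 2.09)
  expect_equal(round(gb_energy(top, snapshot(matrix(0, 1, 3))), 2), -81.96)
  # zero charge: no electrostatic solvation
  top0 <- plain_cluster_topology(1, charge = 0, radius = 2.09)
  expect_equal(gb_energy(top0, snapshot(matrix(0, 1, 3))), 0)
})

test_that("GB two-sphere energy approaches Born + screened Coulomb at range", {
  top <- plain_cluster_topology(2, radius = 2.09)
  top$atoms$charge <- c(1, -1)
  top <- topology(top$atoms, receptor = 1, ligand = 2)
  sn <- snapshot(rbind(c(0, 0, 0), c(100, 0, 0)))
  # two self terms of -81.9584 plus +332.0636 * (1 - 1/78.5) / 100
  expect_equal(round(gb_energy(top, sn), 2), -160.64)
})

test_that("salt screening weakens the GB energy monotonically", {
  tc <- make_toy_complex(8, 3, seed = 5)
  g <- vapply(c(0, 0.15, 1), function(salt) {
    gb_energy(tc$top, tc$ref, solvent_config(salt_conc = salt))
  }, numeric(1))
  # ionic screening adds to the dielectric response: the solvation
  # energy grows in magnitude with salt, approaching the conductor
  # limit
  expect_true(all(diff(abs(g)) > 0))
})

test_that("GB vanishes as the solvent dielectric approaches the interior", {
  tc <- make_toy_complex(8, 3, seed = 5)
  g <- vapply(c(78.5, 10, 2, 1.001), function(eo) {
    abs(gb_energy(tc$top, tc$ref, solvent_config(eps_out = eo)))
  }, numeric(1))
  expect_true(all(diff(g) < 0))
  expect_lt(g[4], 1e-2 * g[1])
})

test_that("LCPO with P = (1,0,0,0) gives isolated-sphere areas exactly", {
  top <- plain_cluster_topology(1, p = c(1, 0, 0, 0))
  sn <- snapshot(matrix(0, 1, 3))
  expect_equal(lcpo_sasa(top, sn, probe = 1.4)$total, 4 * pi * 3.1^2,
               tolerance = 1e-12)
  # beyond the neighbour cutoff areas are additive
  top2 <- plain_cluster_topology(2, p = c(1, 0, 0, 0))
  sn2 <- snapshot(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(lcpo_sasa(top2, sn2, 1.4)$total, 2 * 4 * pi * 3.1^2,
               tolerance = 1e-12)
})

test_that("LCPO tracks the numerical Shrake-Rupley oracle", {
  # overlapping two-sphere system: the pairwise cap formula is exact,
  # so agreement is limited only by the oracle's 960-point resolution
  top <- plain_cluster_topology(2)
  sn <- snapshot(rbind(c(0, 0, 0), c(4.0, 0, 0)))
  lc <- lcpo_sasa(top, sn, 1.4)$total
  or <- shrake_rupley_sasa(sn$coordinates, rep(1.7, 2), 1.4)$total
  expect_lt(abs(lc - or) / or, 0.05)
  # random 3-15 atom clusters: pairwise-overlap expansion within 10%
  for (seed in 1:8) {
    n <- 3 + (seed * 5) %% 13
    xyz <- chain_cluster(n, seed * 7)
    top_n <- plain_cluster_topology(n)
    lc_n <- lcpo_sasa(top_n, snapshot(xyz), 1.4)$total
    or_n <- shrake_rupley_sasa(xyz, rep(1.7, n), 1.4)$total
    expect_lt(abs(lc_n - or_n) / or_n, 0.10)
  }
})

test_that("total free energy is the exact sum of its components", {
  tc <- make_toy_complex(10, 4, seed = 9)
  br <- total_free_energy(tc$top, tc$ref)
  expect_equal(br$total,
               br$e_bond + br$e_angle + br$e_torsion + br$e_vdw + br$e_elec +
                 br$g_gb + br$g_sa,
               tolerance = 1e-10)
  # uncharged isolated atom: only the nonpolar term survives
  top1 <- plain_cluster_topology(1, p = c(1, 0, 0, 0))
  cfg <- solvent_config(surface_tension = 0.0072, surface_offset = 0.92)
  br1 <- total_free_energy(top1, snapshot(matrix(0, 1, 3)), cfg)
  expect_equal(br1$total, 0.0072 * 4 * pi * 3.1^2 + 0.92, tolerance = 1e-10)
})

test_that("all energy terms are invariant under rigid-body motion", {
  tc <- make_toy_complex(12, 4, seed = 21)
  moved <- snapshot(rigid_transform(tc$ref$coordinates), tc$ref$time)
  e0 <- total_free_energy(tc$top, tc$ref)
  e1 <- total_free_energy(tc$top, moved)
  for (k in c("e_bond", "e_angle", "e_torsion", "e_vdw", "e_elec",
              "g_gb", "g_sa", "total")) {
    expect_equal(e1[[k]], e0[[k]], tolerance = 1e-6)
  }
})
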