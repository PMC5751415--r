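test_that("bonded terms cancel exactly in single-trajectory dG", {
  tc <- make_toy_complex(15, 5, seed = 3)
  frames <- make_trajectory(tc$top, tc$ref, 4, noise_sigma = 0.3, seed = 3)
  for (f in frames) {
    with_b <- snapshot_delta_g(tc$top, f, include_bonded = TRUE)
    without <- snapshot_delta_g(tc$top, f, include_bonded = FALSE)
    expect_equal(with_b$dg, without$dg, tolerance = 1e-8)
    # the bonded components themselves are far from zero
    expect_gt(abs(with_b$complex$e_bond) + abs(with_b$complex$e_angle), 1e-3)
  }
})

test_that("dG reduces to the cross Coulomb term for a bare charge pair", {
  atoms <- data.frame(name = c("R", "L"), charge = c(1, -1), rmin_half = 1.7,
                      epsilon = 0, gb_radius = 1.7, vdw_radius = 1.7,
                      p1 = 0, p2 = 0, p3 = 0, p4 = 0)
  top <- topology(atoms, receptor = 1, ligand = 2)
  sn <- snapshot(rbind(c(0, 0, 0), c(3.320636, 0, 0)))
  # GB and SA disabled: zero surface coefficients, eps_out ~ eps_in
  cfg <- solvent_config(eps_in = 1, eps_out = 1 + 1e-12,
                        surface_tension = 0, surface_offset = 0)
  res <- snapshot_delta_g(top, sn, cfg)
  expect_equal(res$dg, -100.00, tolerance = 1e-4)
})

test_that("dG vanishes in the separation limit", {
  tc <- make_toy_complex(10, 4, seed = 8, ligand_net_charge = 0,
                         pocket_charge = 0)
  far <- tc$ref$coordinates
  far[tc$top$ligand, 1] <- far[tc$top$ligand, 1] + 300
  res <- snapshot_delta_g(tc$top, snapshot(far))
  expect_lt(abs(res$dg), 0.05)
})

test_that("empty partitions are rejected", {
  top1 <- plain_cluster_topology(3)
  expect_error(snapshot_delta_g(top1, snapshot(chain_cluster(3, 2))),
               "partition")
})

test_that("window_series tiles the trajectory per the 10/10 protocol", {
  # 100 snapshots covering 100 ns, left-edge stamps 0..99
  s <- data.frame(time_ns = 0:99, dg = rep(-50, 100))
  w <- window_series(s, window_len = 10, stride = 10)
  expect_equal(nrow(w), 10)
  expect_equal(w$t_start_ns, seq(0, 90, 10))
  expect_equal(w$mean_dg, rep(-50, 10))
  expect_equal(w$sd_dg, rep(0, 10))
  expect_equal(w$n_snapshots, rep(10L, 10))
  # a step function recovers the step values exactly
  s2 <- data.frame(time_ns = 0:99, dg = rep(1:10, each = 10))
  w2 <- window_series(s2, 10, 10)
  expect_equal(w2$mean_dg, as.numeric(1:10))
  expect_equal(w2$sd_dg, rep(0, 10))
})

test_that("window means are permutation-invariant and subsampling works", {
  set.seed(4)
  s <- data.frame(time_ns = 0:99, dg = rnorm(100, -60, 3))
  w <- window_series(s, 10, 10)
  perm <- s[sample(nrow(s)), ]
  w_perm <- window_series(perm, 10, 10)
  expect_equal(w_perm$mean_dg, w$mean_dg)
  w_sub <- window_series(s, 10, 10, snaps_per_window = 5)
  expect_equal(w_sub$n_snapshots, rep(5L, 10))
  expect_warning(window_series(s[1:3, ], 10, 10), "shorter")
})

test_that("per-window r^2 matches a textbook Pearson computation", {
  means <- c(-75, -55, -78, -40, -50)
  expd <- c(-12.54, -10.60, -12.90, -9.55, -10.19)
  # one-window series per ligand carrying the given means
  ws <- lapply(means, function(m) {
    data.frame(window_index = 1L, t_start_ns = 0, t_end_ns = 10,
               mean_dg = m, sd_dg = 0, n_snapshots = 10L)
  })
  names(ws) <- sprintf("L%d", seq_along(means))
  ex <- as.list(expd)
  names(ex) <- names(ws)
  corr <- correlate_windows(ws, ex, range = c(0, 10), n_resample = 10, seed = 1)
  expect_equal(corr$per_window$r2, pearson_r2_oracle(means, expd),
               tolerance = 1e-10)
})

test_that("r^2 is invariant under affine rescaling and exact for affine data", {
  set.seed(7)
  grid <- data.frame(window_index = 1:5, t_start_ns = seq(0, 40, 10),
                     t_end_ns = seq(10, 50, 10))
  expd <- c(-12, -11, -10.5, -9.8, -9.1)
  mk_ws <- function(vals_by_window) {
    lapply(seq_along(expd), function(k) {
      cbind(grid, mean_dg = vals_by_window[, k], sd_dg = 0, n_snapshots = 10L)
    })
  }
  # computed means exactly affine in the experimental values
  vals <- t(sapply(1:5, function(w) 3 - 5 * expd))
  vals <- vals + rnorm(5, 0, 0)  # no noise
  ws <- mk_ws(vals)
  names(ws) <- sprintf("L%d", 1:5)
  ex <- stats::setNames(as.list(expd), names(ws))
  corr <- correlate_windows(ws, ex, range = c(0, 50), n_resample = 10, seed = 2)
  expect_equal(corr$per_window$r2, rep(1, 5), tolerance = 1e-10)
  expect_equal(corr$range_average, 1, tolerance = 1e-10)
  # negative slope gives the same r^2 = 1
  ws_neg <- mk_ws(t(sapply(1:5, function(w) 3 + 5 * expd)))
  names(ws_neg) <- names(ws)
  corr_neg <- correlate_windows(ws_neg, ex, range = c(0, 50),
                                n_resample = 10, seed = 2)
  expect_equal(corr_neg$per_window$r2, rep(1, 5), tolerance = 1e-10)
  # affine rescaling of the computed vector leaves r^2 unchanged
  ws_scaled <- mk_ws(0.25 * t(sapply(1:5, function(w) 3 - 5 * expd)) - 40)
  names(ws_scaled) <- names(ws)
  corr_s <- correlate_windows(ws_scaled, ex, range = c(0, 50),
                              n_resample = 10, seed = 2)
  expect_equal(corr_s$per_window$r2, corr$per_window$r2, tolerance = 1e-10)
})

test_that("degenerate correlation inputs are rejected", {
  grid <- data.frame(window_index = 1L, t_start_ns = 0, t_end_ns = 10)
  ws2 <- list(L1 = cbind(grid, mean_dg = -50, sd_dg = 0, n_snapshots = 10L),
              L2 = cbind(grid, mean_dg = -60, sd_dg = 0, n_snapshots = 10L))
  expect_error(correlate_windows(ws2, list(L1 = -10, L2 = -11)), "3 ligands")
  ws3 <- c(ws2, list(L3 = cbind(grid, mean_dg = -70, sd_dg = 0,
                                n_snapshots = 10L)))
  expect_error(
    correlate_windows(ws3, list(L1 = -10, L2 = -10, L3 = -10)),
    "zero variance")
})

test_that("correlation is deterministic under a fixed seed", {
  spec <- panel_spec(snapshots_per_window = 4, n_windows = 5, n_receptors = 1,
                     seed = 11)
  panel <- make_ligand_panel(spec, n_receptor_atoms = 12, n_ligand_atoms = 4)
  a <- score_panel(panel, 1, range = c(0, 50), n_resample = 50, seed = 11)
  b <- score_panel(panel, 1, range = c(0, 50), n_resample = 50, seed = 11)
  expect_identical(a$correlation$per_window, b$correlation$per_window)
  expect_identical(a$correlation$range_average, b$correlation$range_average)
})
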