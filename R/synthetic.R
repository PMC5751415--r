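# Deterministic toy receptor-ligand systems: a jittered-lattice
# receptor with a positively charged pocket face, an anionic ligand
# chain docked against it, Gaussian coordinate noise, and optional
# per-window rigid ligand displacement to induce window-scale drift
# in the binding-energy profile.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy receptor-ligand complex
#'
#' Receptor atoms sit on a jittered cubic lattice (3 A spacing,
#' +/-0.3 A jitter); ligand atoms form a chain docked 3.5 A off the
#' receptor's +x face, so the minimum interatomic distance is at
#' least 2.2 A by construction. The receptor face nearest the ligand
#' carries positive partial charge and the ligand is net anionic, so
#' the electrostatic cross term is attractive and scales linearly
#' with any uniform scaling of the ligand charges. Each molecule is a
#' bonded chain (consecutive bonds, angles, torsions at their
#' reference geometry), exercising bonded-term cancellation in
#' single-trajectory binding energies.
#'
#' @param n_receptor_atoms,n_ligand_atoms Atom counts (>= 1).
#' @param seed Integer seed; identical seeds give identical systems.
#' @param ligand_net_charge Net ligand charge in e (default -2).
#' @param pocket_charge Total positive charge on the receptor pocket
#'   face (default +2 e, spread over the atoms nearest the ligand).
#' @return List with `top` (a [topology()]) and `ref` (a
#'   [snapshot()] of the reference pose).
#' @export
make_toy_complex <- function(n_receptor_atoms, n_ligand_atoms, seed = 1,
                             ligand_net_charge = -2, pocket_charge = 2) {
  stopifnot(n_receptor_atoms >= 1, n_ligand_atoms >= 1)
  with_seed(seed, {
    spacing <- 3.0
    side <- ceiling(n_receptor_atoms^(1 / 3))
    grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    grid <- grid[order(grid$z, grid$y, grid$x), ][seq_len(n_receptor_atoms), ]
    rec_xyz <- as.matrix(grid) * spacing +
      matrix(stats::runif(3 * n_receptor_atoms, -0.3, 0.3),
             ncol = 3)
    x_face <- max(rec_xyz[, 1])
    # ligand chain along y, docked off the +x face
    lig_x <- x_face + 3.5
    lig_y0 <- mean(rec_xyz[, 2])
    lig_z0 <- mean(rec_xyz[, 3])
    lig_xyz <- cbind(
      lig_x + stats::runif(n_ligand_atoms, -0.2, 0.2),
      lig_y0 + (seq_len(n_ligand_atoms) - (n_ligand_atoms + 1) / 2) * spacing +
        stats::runif(n_ligand_atoms, -0.2, 0.2),
      lig_z0 + stats::runif(n_ligand_atoms, -0.2, 0.2)
    )
    xyz <- rbind(rec_xyz, lig_xyz)
    n <- n_receptor_atoms + n_ligand_atoms
    # receptor charges: small zero-sum background plus a positive
    # pocket face (atoms nearest the ligand)
    q_rec <- stats::rnorm(n_receptor_atoms, 0, 0.05)
    q_rec <- q_rec - mean(q_rec)
    d_to_lig <- apply(rec_xyz, 1, function(p) {
      min(sqrt(colSums((t(lig_xyz) - p)^2)))
    })
    n_pocket <- min(3, n_receptor_atoms)
    pocket <- order(d_to_lig)[seq_len(n_pocket)]
    q_rec[pocket] <- q_rec[pocket] + pocket_charge / n_pocket
    q_lig <- stats::rnorm(n_ligand_atoms, 0, 0.05)
    q_lig <- q_lig - mean(q_lig) + ligand_net_charge / n_ligand_atoms
    atoms <- data.frame(
      name = c(sprintf("R%d", seq_len(n_receptor_atoms)),
               sprintf("L%d", seq_len(n_ligand_atoms))),
      charge = c(q_rec, q_lig),
      rmin_half = stats::runif(n, 1.6, 1.9),
      epsilon = stats::runif(n, 0.05, 0.2),
      gb_radius = stats::runif(n, 1.5, 2.0),
      vdw_radius = stats::runif(n, 1.5, 1.9),
      p1 = stats::runif(n, 0.4, 0.8),
      p2 = stats::runif(n, -0.2, -0.1),
      p3 = stats::runif(n, -0.01, 0),
      p4 = stats::runif(n, 0, 0.001),
      stringsAsFactors = FALSE
    )
    chain_terms <- function(first, count, xyz) {
      idx <- first + seq_len(count) - 1
      bonds <- angles <- torsions <- NULL
      if (count >= 2) {
        i <- idx[-count]; j <- idx[-1]
        bonds <- data.frame(i = i, j = j, k_b = 300,
                            r0 = vec_norm(xyz[i, , drop = FALSE] -
                                            xyz[j, , drop = FALSE]))
      }
      if (count >= 3) {
        i <- idx[seq_len(count - 2)]
        j <- idx[seq_len(count - 2) + 1]
        k <- idx[seq_len(count - 2) + 2]
        u <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
        v <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
        th <- acos(pmin(1, pmax(-1, rowSums(u * v) /
                                  (vec_norm(u) * vec_norm(v)))))
        angles <- data.frame(i = i, j = j, k = k, k_theta = 50, theta0 = th)
      }
      if (count >= 4) {
        i <- idx[seq_len(count - 3)]
        torsions <- data.frame(i = i, j = i + 1, k = i + 2, l = i + 3,
                               v_n = 1.0, periodicity = 3, phase = 0)
      }
      list(bonds = bonds, angles = angles, torsions = torsions)
    }
    rec_terms <- chain_terms(1, n_receptor_atoms, xyz)
    lig_terms <- chain_terms(n_receptor_atoms + 1, n_ligand_atoms, xyz)
    cat_df <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else rbind(a, b)
    top <- topology(
      atoms = atoms,
      bonds = cat_df(rec_terms$bonds, lig_terms$bonds),
      angles = cat_df(rec_terms$angles, lig_terms$angles),
      torsions = cat_df(rec_terms$torsions, lig_terms$torsions),
      receptor = seq_len(n_receptor_atoms),
      ligand = n_receptor_atoms + seq_len(n_ligand_atoms)
    )
    list(top = top, ref = snapshot(xyz, time = 0))
  })
}

#' Generate a synthetic trajectory around a reference pose
#'
#' Frames are the reference coordinates plus i.i.d. Gaussian noise;
#' optionally the ligand is rigidly displaced along +x (away from the
#' receptor) by a per-window amount, inducing window-scale drift in
#' the binding energy. Time stamps are evenly spaced over
#' `duration_ns`, frame k at `(k-1) * duration_ns / n_frames`.
#'
#' @param top A [topology()] (supplies the ligand atom set).
#' @param ref Reference [snapshot()].
#' @param n_frames Number of frames (>= 1).
#' @param noise_sigma Gaussian coordinate noise SD in A (>= 0).
#' @param drift Numeric vector of per-window ligand displacements in
#'   A (length = number of windows; frames are split into that many
#'   equal blocks), or `NULL` for none.
#' @param seed Integer seed.
#' @param duration_ns Nominal trajectory length in ns (default 100).
#' @return List of [snapshot()]s.
#' @export
make_trajectory <- function(top, ref, n_frames, noise_sigma = 0,
                            drift = NULL, seed = 1, duration_ns = 100) {
  stopifnot(n_frames >= 1, noise_sigma >= 0)
  lig <- top$ligand
  with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      xyz <- ref$coordinates
      if (noise_sigma > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                            ncol = 3)
      }
      if (!is.null(drift) && length(drift) > 0) {
        w <- min(length(drift), 1 + (k - 1) %/% ceiling(n_frames / length(drift)))
        xyz[lig, 1] <- xyz[lig, 1] + drift[w]
      }
      snapshot(xyz, time = (k - 1) * duration_ns / n_frames)
    })
  })
}

#' Panel specification for the synthetic study design
#'
#' Defaults mirror the study shape: five ligands against a shared
#' receptor, ligand charge scalings lambda = 0.2 ... 1.0, prescribed
#' experimental binding energies affine in lambda spanning about
#' 3 kcal/mol (-9.5 to -12.5), ten 10-ns windows, and mild coordinate
#' noise.
#'
#' @param n_ligands Number of ligands.
#' @param interaction_scale Per-ligand charge scaling lambda.
#' @param experimental_dg Prescribed experimental dG per ligand,
#'   kcal/mol.
#' @param n_receptors Number of independently generated receptors.
#' @param snapshots_per_window Snapshots per 10-ns window.
#' @param n_windows Number of windows.
#' @param noise_sigma Coordinate noise SD in A.
#' @param drift_profile Optional n_ligands x n_windows matrix of
#'   per-window ligand displacements (A).
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_ligands = 5,
                       interaction_scale = seq(0.2, 1.0, length.out = n_ligands),
                       experimental_dg = -8.75 - 3.75 * interaction_scale,
                       n_receptors = 2,
                       snapshots_per_window = 100,
                       n_windows = 10,
                       noise_sigma = 0.03,
                       drift_profile = NULL,
                       seed = 1) {
  stopifnot(length(interaction_scale) == n_ligands,
            length(experimental_dg) == n_ligands,
            noise_sigma >= 0, n_windows >= 1, snapshots_per_window >= 1)
  if (!is.null(drift_profile)) {
    drift_profile <- as.matrix(drift_profile)
    stopifnot(nrow(drift_profile) == n_ligands,
              ncol(drift_profile) == n_windows)
  }
  structure(list(n_ligands = n_ligands, interaction_scale = interaction_scale,
                 experimental_dg = experimental_dg, n_receptors = n_receptors,
                 snapshots_per_window = snapshots_per_window,
                 n_windows = n_windows, noise_sigma = noise_sigma,
                 drift_profile = drift_profile, seed = seed),
            class = "panel_spec")
}

#' Uniformly scale a topology's ligand partial charges
#'
#' At fixed geometry the receptor-ligand electrostatic cross term is
#' exactly linear in this scaling, which is how the synthetic panel
#' controls binding strength with a known ground truth.
#'
#' @param top A [topology()].
#' @param lambda Dimensionless scaling factor.
#' @return The topology with ligand charges multiplied by `lambda`.
#' @export
scale_ligand_charges <- function(top, lambda) {
  top$atoms$charge[top$ligand] <- top$atoms$charge[top$ligand] * lambda
  top
}

#' Generate a full synthetic ligand panel
#'
#' For each receptor, builds a shared toy complex, scales the ligand
#' charges by each ligand's lambda, and simulates a noisy trajectory
#' per ligand. Prescribed experimental dG values are converted to Kd
#' fixtures (5% relative Kd error) via [dg_to_kd()].
#'
#' @param spec A [panel_spec()].
#' @param n_receptor_atoms,n_ligand_atoms Toy system size (defaults
#'   30 and 6).
#' @param temperature Temperature for the dG -> Kd conversion (K).
#' @return List of class `synthetic_panel`: one entry per receptor,
#'   each a list of per-ligand entries `top`, `frames`, `affinity`
#'   (an [affinity_measurement()]), `lambda`, `experimental_dg`.
#' @export
make_ligand_panel <- function(spec = panel_spec(), n_receptor_atoms = 30,
                              n_ligand_atoms = 6, temperature = 300) {
  stopifnot(inherits(spec, "panel_spec"))
  receptors <- lapply(seq_len(spec$n_receptors), function(r) {
    base <- make_toy_complex(n_receptor_atoms, n_ligand_atoms,
                             seed = spec$seed + 1000 * r)
    ligands <- lapply(seq_len(spec$n_ligands), function(k) {
      lam <- spec$interaction_scale[k]
      top_k <- scale_ligand_charges(base$top, lam)
      drift <- if (is.null(spec$drift_profile)) NULL else spec$drift_profile[k, ]
      frames <- make_trajectory(
        top_k, base$ref,
        n_frames = spec$snapshots_per_window * spec$n_windows,
        noise_sigma = spec$noise_sigma, drift = drift,
        seed = spec$seed + 1000 * r + k,
        duration_ns = 10 * spec$n_windows
      )
      kd <- dg_to_kd(spec$experimental_dg[k], temperature)
      aff <- affinity_measurement(sprintf("L%d", k), sprintf("R%d", r),
                                  kd, 0.05 * kd)
      list(top = top_k, frames = frames, affinity = aff,
           lambda = lam, experimental_dg = spec$experimental_dg[k])
    })
    names(ligands) <- sprintf("L%d", seq_len(spec$n_ligands))
    ligands
  })
  names(receptors) <- sprintf("R%d", seq_len(spec$n_receptors))
  structure(receptors, class = "synthetic_panel")
}

#' Score a synthetic panel end to end
#'
#' Runs the full pipeline on one receptor of a generated panel:
#' per-snapshot binding energies, sliding windows, and the
#' correlation of window means with the prescribed experimental dG.
#'
#' @param panel A `synthetic_panel` from [make_ligand_panel()].
#' @param receptor Receptor name or index (default 1).
#' @param cfg A [solvent_config()].
#' @param window_len,stride Window geometry in ns.
#' @param range Range for the average r^2, ns.
#' @param n_resample,seed Monte-Carlo settings for the r^2 error.
#' @param temperature Temperature (K) for experimental conversion.
#' @return List with `windows` (named list of [window_series()]
#'   frames), `correlation` (a `correlation_series`) and `dg_series`.
#' @export
score_panel <- function(panel, receptor = 1, cfg = solvent_config(),
                        window_len = 10, stride = 10, range = c(40, 100),
                        n_resample = 1000, seed = 1, temperature = 300) {
  ligs <- panel[[receptor]]
  dg_series <- lapply(ligs, function(l) trajectory_delta_g(l$top, l$frames, cfg))
  windows <- lapply(dg_series, window_series, window_len = window_len,
                    stride = stride)
  experiment <- lapply(ligs, function(l) {
    kd_to_dg(l$affinity$kd, temperature, err = l$affinity$kd_err)
  })
  corr <- correlate_windows(windows, experiment, range = range,
                            n_resample = n_resample, seed = seed)
  list(windows = windows, correlation = corr, dg_series = dg_series)
}
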