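# Single-trajectory MM/GBSA: per-snapshot binding energies, sliding
# window profiles, and correlation with experimental affinities.

#' Per-snapshot single-trajectory binding energy
#'
#' Evaluates the complex, receptor-only and ligand-only free energies
#' on coordinates extracted from the SAME complex snapshot and returns
#' `dG = G_complex - G_receptor - G_ligand`. Bonded terms are excluded
#' by default: under single-trajectory extraction each molecule's
#' internal bonded energy appears identically in the complex and in
#' its isolated evaluation, so they cancel exactly.
#'
#' @param top A [topology()] whose partition defines receptor and
#'   ligand atom sets (both non-empty).
#' @param snap A [snapshot()] of the complex.
#' @param cfg A [solvent_config()].
#' @param include_bonded Evaluate bonded terms anyway (the difference
#'   is zero to numerical identity; mainly for verification).
#' @param parts Optional precomputed receptor/ligand sub-topologies
#'   from [binding_parts()]; avoids rebuilding exclusion lists on
#'   every frame of a trajectory.
#' @return List with `dg` (kcal/mol) and the three
#'   `energy_breakdown`s: `complex`, `receptor`, `ligand`.
#' @export
snapshot_delta_g <- function(top, snap, cfg = solvent_config(),
                             include_bonded = FALSE, parts = NULL) {
  snap <- check_snapshot(top, snap)
  if (is.null(parts)) parts <- binding_parts(top)
  rec_top <- parts$receptor
  lig_top <- parts$ligand
  rec_snap <- snapshot(snap$coordinates[top$receptor, , drop = FALSE], snap$time)
  lig_snap <- snapshot(snap$coordinates[top$ligand, , drop = FALSE], snap$time)
  g_c <- total_free_energy(top, snap, cfg, include_bonded)
  g_r <- total_free_energy(rec_top, rec_snap, cfg, include_bonded)
  g_l <- total_free_energy(lig_top, lig_snap, cfg, include_bonded)
  list(dg = g_c$total - g_r$total - g_l$total,
       complex = g_c, receptor = g_r, ligand = g_l)
}

#' Binding-energy series over a trajectory
#'
#' Applies [snapshot_delta_g()] to each frame.
#'
#' @inheritParams snapshot_delta_g
#' @param frames List of [snapshot()]s.
#' @return Data frame with columns `time_ns` and `dg`.
#' @export
trajectory_delta_g <- function(top, frames, cfg = solvent_config()) {
  parts <- binding_parts(top)
  dg <- vapply(frames, function(f) {
    snapshot_delta_g(top, f, cfg, parts = parts)$dg
  }, numeric(1))
  t_ns <- vapply(frames, function(f) f$time, numeric(1))
  data.frame(time_ns = t_ns, dg = dg)
}

#' Receptor and ligand sub-topologies of a complex
#'
#' @param top A [topology()] with non-empty receptor and ligand sets.
#' @return List with `receptor` and `ligand` sub-topologies.
#' @export
binding_parts <- function(top) {
  if (length(top$receptor) == 0 || length(top$ligand) == 0) {
    stop("topology partition must define non-empty receptor and ligand sets",
         call. = FALSE)
  }
  list(receptor = subset_topology(top, top$receptor, "receptor"),
       ligand = subset_topology(top, top$ligand, "ligand"))
}

#' Sliding-window statistics of a binding-energy series
#'
#' Partitions a per-snapshot dG series into windows
#' `[k stride, k stride + window_len)` and reports per-window mean and
#' sample standard deviation over `snaps_per_window` evenly spaced
#' snapshots. With `stride == window_len` (the default protocol) the
#' windows tile the trajectory: a 100 ns series at 10/10 yields 10
#' windows starting at 0, 10, ..., 90 ns.
#'
#' @param dg_series Data frame with columns `time_ns`, `dg` (as from
#'   [trajectory_delta_g()]), snapshots evenly spaced in time.
#' @param window_len Window length in ns (default 10).
#' @param stride Window start spacing in ns (default `window_len`).
#' @param snaps_per_window Snapshots used per window; `NULL` (default)
#'   uses every snapshot falling in the window, an integer subsamples
#'   evenly.
#' @return Data frame of class `window_series` with columns
#'   `window_index`, `t_start_ns`, `t_end_ns`, `mean_dg`, `sd_dg`,
#'   `n_snapshots`. Empty (with a warning) when the series is shorter
#'   than one window.
#' @export
window_series <- function(dg_series, window_len = 10, stride = window_len,
                          snaps_per_window = NULL) {
  stopifnot(all(c("time_ns", "dg") %in% names(dg_series)))
  n_snap <- nrow(dg_series)
  t0 <- min(dg_series$time_ns)
  span <- max(dg_series$time_ns) - t0
  # evenly spaced snapshots at the left edge of their sampling
  # interval: the series covers span * n/(n-1) ns of trajectory
  duration <- if (n_snap > 1) span * n_snap / (n_snap - 1) else window_len
  starts <- numeric(0)
  k <- 0
  repeat {
    s <- t0 + k * stride
    if (s + window_len > t0 + duration + 1e-9) break
    starts <- c(starts, s)
    k <- k + 1
  }
  if (length(starts) == 0) {
    warning("series span shorter than one window; empty result", call. = FALSE)
    out <- data.frame(window_index = integer(0), t_start_ns = numeric(0),
                      t_end_ns = numeric(0), mean_dg = numeric(0),
                      sd_dg = numeric(0), n_snapshots = integer(0))
    class(out) <- c("window_series", class(out))
    return(out)
  }
  rows <- lapply(seq_along(starts), function(w) {
    s <- starts[w]; e <- s + window_len
    in_w <- dg_series$time_ns >= s - 1e-9 & dg_series$time_ns < e - 1e-9
    vals <- dg_series$dg[in_w]
    if (!is.null(snaps_per_window) && length(vals) > snaps_per_window) {
      sel <- round(seq(1, length(vals), length.out = snaps_per_window))
      vals <- vals[sel]
    }
    data.frame(window_index = w, t_start_ns = s, t_end_ns = e,
               mean_dg = mean(vals),
               sd_dg = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
               n_snapshots = length(vals))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_series", class(out))
  out
}

#' Per-window correlation with experimental binding energies
#'
#' For each window, computes the squared Pearson correlation between
#' the per-ligand window-mean dG and the experimental dG across the
#' panel. The range average is the mean r^2 over windows fully
#' contained in `range` (default 40-100 ns). Error bars on r^2 come
#' from Monte-Carlo resampling: each draw perturbs every experimental
#' dG by a zero-mean normal with its propagated error and the sample
#' SD of the resampled r^2 values is reported.
#'
#' @param window_sets Named list, ligand id -> [window_series()]
#'   data frame; all ligands must share the window grid.
#' @param experiment Named list or vector, ligand id ->
#'   `binding_free_energy` (or numeric dG with, optionally, an
#'   `err` attribute-free list). Errors default to 0 for numerics.
#' @param range Numeric `(t_lo, t_hi)` in ns for the range average.
#' @param n_resample Monte-Carlo draws for the r^2 error (default
#'   1000).
#' @param seed Integer seed for the resampling.
#' @return List of class `correlation_series` with `per_window` (data
#'   frame `window_index, t_start_ns, t_end_ns, r2, r2_err`) and
#'   `range_average`.
#' @export
correlate_windows <- function(window_sets, experiment, range = c(40, 100),
                              n_resample = 1000, seed = 1) {
  ligs <- names(window_sets)
  if (length(ligs) < 3) {
    stop("need at least 3 ligands for a meaningful r^2", call. = FALSE)
  }
  if (!all(ligs %in% names(experiment))) {
    stop("experimental dG missing for some ligands", call. = FALSE)
  }
  grid <- window_sets[[1]][, c("window_index", "t_start_ns", "t_end_ns")]
  for (lg in ligs[-1]) {
    g <- window_sets[[lg]][, c("window_index", "t_start_ns", "t_end_ns")]
    if (!isTRUE(all.equal(grid, g, check.attributes = FALSE))) {
      stop("ligands do not share a common window grid", call. = FALSE)
    }
  }
  exp_val <- vapply(ligs, function(lg) {
    e <- experiment[[lg]]
    if (inherits(e, "binding_free_energy")) e$value else as.numeric(e)
  }, numeric(1))
  exp_err <- vapply(ligs, function(lg) {
    e <- experiment[[lg]]
    if (inherits(e, "binding_free_energy")) e$err else 0
  }, numeric(1))
  if (stats::sd(exp_val) == 0) {
    stop("experimental dG vector has zero variance; r^2 undefined",
         call. = FALSE)
  }
  means <- sapply(ligs, function(lg) window_sets[[lg]]$mean_dg)
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  r2 <- apply(means, 1, function(m) {
    if (stats::sd(m) == 0) {
      stop("computed window means have zero variance; r^2 undefined",
           call. = FALSE)
    }
    stats::cor(m, exp_val)^2
  })
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  draws <- matrix(NA_real_, n_resample, nrow(grid))
  for (b in seq_len(n_resample)) {
    pert <- exp_val + stats::rnorm(length(exp_val), 0, exp_err)
    if (stats::sd(pert) == 0) pert <- pert + 1e-12 * seq_along(pert)
    draws[b, ] <- apply(means, 1, function(m) stats::cor(m, pert)^2)
  }
  r2_err <- apply(draws, 2, stats::sd)
  per_window <- data.frame(grid, r2 = r2, r2_err = r2_err)
  inside <- per_window$t_start_ns >= range[1] - 1e-9 &
    per_window$t_end_ns <= range[2] + 1e-9
  range_average <- if (any(inside)) mean(per_window$r2[inside]) else NA_real_
  structure(list(per_window = per_window, range_average = range_average,
                 range = range),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("correlation series: %d windows, range-average r^2 = %.3f over [%g, %g] ns\n",
              nrow(x$per_window), x$range_average, x$range[1], x$range[2]))
  invisible(x)
}
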