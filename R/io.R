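# File formats owned by the package: topology JSON (schema
# "cgbsa-top-1"), multi-frame XYZ and multi-model PDB coordinates,
# and the YAML run configuration. All round trips are lossless to
# double precision.

TOPOLOGY_FORMAT <- "cgbsa-top-1"

#' Write a topology to JSON
#'
#' Serialises a [topology()] to the versioned `cgbsa-top-1` JSON
#' schema: an `atoms` array (name, charge, rmin_half, epsilon,
#' gb_radius, vdw_radius, p1-p4, gb_screen), `bonds`/`angles`/
#' `torsions` arrays, and a `partition` object with `receptor` and
#' `ligand` index arrays.
#'
#' @param top A [topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  obj <- list(
    format = TOPOLOGY_FORMAT,
    atoms = top$atoms,
    bonds = top$bonds,
    angles = top$angles,
    torsions = top$torsions,
    partition = list(receptor = top$receptor, ligand = top$ligand)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a topology from JSON
#'
#' Parses and validates a `cgbsa-top-1` file; every schema violation
#' is reported with the offending field (missing per-atom parameters
#' name the atom).
#'
#' @param path Path to a topology JSON file.
#' @return A validated [topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !identical(obj$format, TOPOLOGY_FORMAT)) {
    stop("topology format version mismatch: expected '", TOPOLOGY_FORMAT,
         "', found '", obj$format %||% "<missing>", "'", call. = FALSE)
  }
  atoms <- as.data.frame(obj$atoms)
  need <- c("name", "charge", "rmin_half", "epsilon", "gb_radius",
            "vdw_radius", "p1", "p2", "p3", "p4")
  for (col in need) {
    if (is.null(atoms[[col]])) {
      stop("topology parse error at atoms[*].", col, ": field missing",
           call. = FALSE)
    }
    bad <- which(is.na(atoms[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("topology parse error at atoms[%d].%s (atom '%s'): value missing",
                   bad[1], col,
                   if (is.na(atoms$name[bad[1]])) "?" else atoms$name[bad[1]]),
           call. = FALSE)
    }
  }
  as_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0) return(NULL)
    d <- as.data.frame(x)
    missing <- setdiff(cols, names(d))
    if (length(missing) > 0) {
      stop("topology parse error: missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    d[cols]
  }
  if (is.null(obj$partition$receptor) && is.null(obj$partition$ligand)) {
    stop("topology parse error at partition: field missing", call. = FALSE)
  }
  topology(
    atoms = atoms,
    bonds = as_df(obj$bonds, c("i", "j", "k_b", "r0")),
    angles = as_df(obj$angles, c("i", "j", "k", "k_theta", "theta0")),
    torsions = as_df(obj$torsions,
                     c("i", "j", "k", "l", "v_n", "periodicity", "phase")),
    receptor = unlist(obj$partition$receptor) %||% integer(0),
    ligand = unlist(obj$partition$ligand) %||% integer(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks: atom count, a comment line carrying the time
#' stamp (`t= <ns> ns`), then `name x y z` records in Angstrom.
#'
#' @param frames List of [snapshot()]s.
#' @param path Output path.
#' @param names Atom names (recycled from `"X"` when missing).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, names = NULL) {
  if (inherits(frames, "cgbsa_snapshot")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$coordinates)
    nm <- names %||% rep("X", n)
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.9g ns", f$time), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", nm,
                       f$coordinates[, 1], f$coordinates[, 2],
                       f$coordinates[, 3]), con)
  }
  invisible(path)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1
  fi <- 0
  while (pos <= length(lines)) {
    if (grepl("^\\s*$", lines[pos])) { pos <- pos + 1; next }
    fi <- fi + 1
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) {
      stop("XYZ parse error at frame ", fi, ": bad atom count line",
           call. = FALSE)
    }
    if (pos + 1 + n > length(lines)) {
      stop("XYZ parse error: frame ", fi, " truncated", call. = FALSE)
    }
    comment <- lines[pos + 1]
    t_ns <- NA_real_
    m <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) t_ns <- as.numeric(m[2])
    block <- lines[pos + 1 + seq_len(n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0) {
      stop("XYZ parse error: frame ", fi, ", atom ", bad[1],
           ": malformed record", call. = FALSE)
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("XYZ parse error: frame ", fi, ": non-numeric coordinates",
           call. = FALSE)
    }
    frames[[fi]] <- list(xyz = xyz, time = t_ns)
    pos <- pos + 2 + n
  }
  frames
}

read_pdb_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB trajectories requires the bio3d package",
         call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(r) {
    list(xyz = matrix(xyz[r, ], ncol = 3, byrow = TRUE), time = NA_real_)
  })
}

#' Read a trajectory (multi-frame XYZ or multi-model PDB)
#'
#' @param path Path to the file.
#' @param format `"xyz"` or `"pdb"` (default from the file
#'   extension).
#' @param n_expected Optional atom count to enforce per frame; a
#'   mismatch names the frame.
#' @param dt_ns Uniform frame spacing in ns, used when the file
#'   carries no time stamps (frame k at `(k-1) dt_ns`).
#' @return List of [snapshot()]s, time-stamped.
#' @export
read_trajectory <- function(path, format = NULL, n_expected = NULL,
                            dt_ns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  format <- match.arg(format, c("xyz", "pdb"))
  raw <- if (format == "xyz") read_xyz_frames(path) else read_pdb_frames(path)
  if (length(raw) == 0) stop("no frames in ", path, call. = FALSE)
  lapply(seq_along(raw), function(k) {
    f <- raw[[k]]
    if (!is.null(n_expected) && nrow(f$xyz) != n_expected) {
      stop(sprintf("frame %d has %d atoms, expected %d", k, nrow(f$xyz),
                   n_expected), call. = FALSE)
    }
    t_ns <- f$time
    if (is.na(t_ns)) t_ns <- if (!is.null(dt_ns)) (k - 1) * dt_ns else k - 1
    snapshot(f$xyz, time = t_ns)
  })
}

#' Write a window series table
#' @param windows Named list of [window_series()] data frames (names
#'   are ligand ids) or a single data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_window_csv <- function(windows, path) {
  if (is.data.frame(windows)) windows <- list(ligand = windows)
  df <- do.call(rbind, lapply(names(windows), function(lg) {
    w <- windows[[lg]]
    data.frame(ligand = lg, window = w$window_index,
               t_start_ns = w$t_start_ns, t_end_ns = w$t_end_ns,
               mean_dg = w$mean_dg, sd_dg = w$sd_dg,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a correlation series table
#' @param corr A `correlation_series` from [correlate_windows()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(corr, path) {
  df <- data.frame(window = corr$per_window$window_index,
                   r2 = corr$per_window$r2,
                   r2_err = corr$per_window$r2_err)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration with strict key validation
#'
#' Collects the workflow's tunable parameters with the package-wide
#' defaults. Unknown keys are rejected.
#'
#' @param ... Overrides for any of: `temperature`, `ph`, `theta`,
#'   `margin`, `window_len`, `stride`, `snaps_per_window`,
#'   `r2_range`, `n_resample`, `seed`, plus any [solvent_config()]
#'   field under `solvent`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(temperature = 300, ph = 7.40, theta = 0.75, margin = 1.0,
                   solvent = unclass(solvent_config()), window_len = 10,
                   stride = 10, snaps_per_window = NULL, r2_range = c(40, 100),
                   n_resample = 1000, seed = 1)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(over$solvent)) {
    bad <- setdiff(names(over$solvent), names(defaults$solvent))
    if (length(bad) > 0) {
      stop("unknown solvent key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    defaults$solvent[names(over$solvent)] <- over$solvent
    over$solvent <- NULL
  }
  defaults[names(over)] <- over
  defaults$solvent <- do.call(solvent_config, defaults$solvent)
  structure(defaults, class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file whose keys are [run_config()]
#'   fields; unknown keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  run_config(yaml::read_yaml(path))
}
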