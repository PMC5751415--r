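# Parametrised molecular system: atoms with nonbonded, GB and LCPO
# parameters, bonded terms, and a receptor/ligand partition. Plain
# data frames inside a validated list; indices are 1-based.

#' Construct a molecular topology
#'
#' @param atoms Data frame, one row per atom, with columns `name`,
#'   `charge` (e), `rmin_half` (A, Lennard-Jones Rmin/2), `epsilon`
#'   (kcal/mol well depth), `gb_radius` (A, intrinsic Born radius),
#'   `vdw_radius` (A, for surface area), `p1`..`p4` (LCPO
#'   coefficients) and optionally `gb_screen` (pairwise-descreening
#'   scale factor, default 0.8).
#' @param bonds Data frame `i, j, k_b, r0` (kcal mol^-1 A^-2, A); may
#'   have zero rows.
#' @param angles Data frame `i, j, k, k_theta, theta0` (kcal mol^-1
#'   rad^-2, rad).
#' @param torsions Data frame `i, j, k, l, v_n, periodicity, phase`
#'   (kcal/mol, integer, rad).
#' @param receptor Integer indices of receptor atoms.
#' @param ligand Integer indices of ligand atoms; together with
#'   `receptor` must partition `1:nrow(atoms)`.
#' @return An object of class `cgbsa_topology` with derived exclusion
#'   (1-2/1-3) and scaled 1-4 pair lists.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, torsions = NULL,
                     receptor, ligand) {
  empty <- function(cols) {
    stats::setNames(as.data.frame(rep(list(numeric(0)), length(cols))), cols)
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "k_b", "r0"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "k_theta", "theta0"))
  if (is.null(torsions)) {
    torsions <- empty(c("i", "j", "k", "l", "v_n", "periodicity", "phase"))
  }
  need <- c("name", "charge", "rmin_half", "epsilon", "gb_radius",
            "vdw_radius", "p1", "p2", "p3", "p4")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    stop("atoms table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(atoms$gb_screen)) atoms$gb_screen <- 0.8
  n <- nrow(atoms)
  if (n < 1) stop("topology needs at least one atom", call. = FALSE)
  num_ok <- function(x) all(is.finite(x))
  if (!num_ok(atoms$charge)) stop("non-finite charge", call. = FALSE)
  if (any(atoms$epsilon < 0)) stop("negative LJ well depth", call. = FALSE)
  for (col in c("rmin_half", "gb_radius", "vdw_radius")) {
    if (any(!is.finite(atoms[[col]]) | atoms[[col]] <= 0)) {
      bad <- which(!is.finite(atoms[[col]]) | atoms[[col]] <= 0)[1]
      stop(sprintf("atom %d has non-positive %s", bad, col), call. = FALSE)
    }
  }
  receptor <- as.integer(receptor)
  ligand <- as.integer(ligand)
  if (length(intersect(receptor, ligand)) > 0) {
    stop("receptor and ligand atom sets overlap", call. = FALSE)
  }
  if (!setequal(c(receptor, ligand), seq_len(n))) {
    stop("receptor + ligand must partition all atoms", call. = FALSE)
  }
  idx_cols <- list(bonds = c("i", "j"), angles = c("i", "j", "k"),
                   torsions = c("i", "j", "k", "l"))
  for (tbl in names(idx_cols)) {
    d <- get(tbl)
    for (cc in idx_cols[[tbl]]) {
      v <- d[[cc]]
      if (length(v) > 0 && (any(v < 1) || any(v > n))) {
        stop(tbl, " index out of range", call. = FALSE)
      }
    }
  }
  top <- structure(
    list(atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
         receptor = sort(receptor), ligand = sort(ligand)),
    class = "cgbsa_topology"
  )
  top$pairs <- nonbonded_pairs(top)
  top
}

#' @export
print.cgbsa_topology <- function(x, ...) {
  cat(sprintf("cgbsa topology: %d atoms (%d receptor, %d ligand), %d bonds, %d angles, %d torsions\n",
              nrow(x$atoms), length(x$receptor), length(x$ligand),
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top A `cgbsa_topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

# Bond-graph distances classify atom pairs: 1-2 and 1-3 are excluded
# from nonbonded sums, 1-4 pairs are scaled. A pair reachable by both
# a 3-bond and a shorter path counts as excluded.
nonbonded_pairs <- function(top) {
  n <- nrow(top$atoms)
  if (n < 2) {
    return(list(full = cbind(i = integer(0), j = integer(0)),
                scaled14 = cbind(i = integer(0), j = integer(0))))
  }
  adj <- vector("list", n)
  if (nrow(top$bonds) > 0) {
    for (r in seq_len(nrow(top$bonds))) {
      i <- top$bonds$i[r]; j <- top$bonds$j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  dist_class <- matrix(Inf, n, n)  # graph distance, capped at 4
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    for (depth in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(d[nxt])]
      if (length(nxt) == 0) break
      d[nxt] <- depth
      frontier <- nxt
    }
    dist_class[s, ] <- d
  }
  ut <- which(upper.tri(dist_class), arr.ind = TRUE)
  gd <- dist_class[ut]
  full <- ut[gd > 3, , drop = FALSE]
  scaled14 <- ut[gd == 3, , drop = FALSE]
  colnames(full) <- colnames(scaled14) <- c("i", "j")
  list(full = full, scaled14 = scaled14)
}

#' Extract the sub-topology of an atom subset
#'
#' Keeps the selected atoms (reindexed consecutively) and every
#' bonded term fully contained in the subset; exclusion lists are
#' rebuilt. Used to evaluate receptor-only and ligand-only energies
#' on coordinates taken from a complex snapshot.
#'
#' @param top A `cgbsa_topology`.
#' @param keep Integer atom indices to keep.
#' @param role `"receptor"` or `"ligand"`: all kept atoms are assigned
#'   this role in the sub-topology's partition.
#' @return A `cgbsa_topology` over the kept atoms.
#' @export
subset_topology <- function(top, keep, role = c("receptor", "ligand")) {
  role <- match.arg(role)
  keep <- sort(as.integer(keep))
  if (length(keep) == 0) stop("empty atom subset", call. = FALSE)
  map <- rep(NA_integer_, nrow(top$atoms))
  map[keep] <- seq_along(keep)
  pick <- function(d, cols) {
    if (nrow(d) == 0) return(d)
    inside <- rep(TRUE, nrow(d))
    for (cc in cols) inside <- inside & d[[cc]] %in% keep
    d <- d[inside, , drop = FALSE]
    for (cc in cols) d[[cc]] <- map[d[[cc]]]
    rownames(d) <- NULL
    d
  }
  m <- length(keep)
  topology(
    atoms = top$atoms[keep, , drop = FALSE],
    bonds = pick(top$bonds, c("i", "j")),
    angles = pick(top$angles, c("i", "j", "k")),
    torsions = pick(top$torsions, c("i", "j", "k", "l")),
    receptor = if (role == "receptor") seq_len(m) else integer(0),
    ligand = if (role == "ligand") seq_len(m) else integer(0)
  )
}

#' Construct a coordinate snapshot
#'
#' @param coordinates Numeric N x 3 matrix of positions in Angstrom.
#' @param time Time stamp in ns (default 0).
#' @return An object of class `cgbsa_snapshot`.
#' @export
snapshot <- function(coordinates, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3 || !all(is.finite(coordinates))) {
    stop("coordinates must be a finite N x 3 matrix (A)", call. = FALSE)
  }
  structure(list(coordinates = coordinates, time = time),
            class = "cgbsa_snapshot")
}

check_snapshot <- function(top, snap) {
  if (!inherits(snap, "cgbsa_snapshot")) snap <- snapshot(snap)
  if (nrow(snap$coordinates) != nrow(top$atoms)) {
    stop("snapshot has ", nrow(snap$coordinates),
         " atoms but topology has ", nrow(top$atoms), call. = FALSE)
  }
  snap
}

#' Implicit-solvent configuration
#'
#' Parameters of the Generalized Born (OBC-style) and LCPO
#' surface-area terms. Defaults are the common MM/GBSA scoring
#' choices: interior dielectric 1, water dielectric 78.5, no salt,
#' Born-radius offset 0.09 A with tanh rescaling coefficients
#' (1.0, 0.8, 4.85), surface tension 0.0072 kcal mol^-1 A^-2 with
#' zero offset, and a 1.4 A solvent probe.
#'
#' @param eps_in Solute interior dielectric (>= 1).
#' @param eps_out Solvent dielectric (> `eps_in`).
#' @param salt_conc Monovalent salt concentration in M (>= 0).
#' @param gb_offset Born-radius offset in A.
#' @param gb_scaling Numeric length-3 `(alpha, beta, gamma)` of the
#'   tanh rescaling.
#' @param surface_tension kcal mol^-1 A^-2 multiplying the SASA.
#' @param surface_offset Constant added to the nonpolar term, kcal/mol.
#' @param probe_radius Solvent probe radius in A.
#' @return An object of class `solvent_config`.
#' @export
solvent_config <- function(eps_in = 1, eps_out = 78.5, salt_conc = 0,
                           gb_offset = 0.09, gb_scaling = c(1.0, 0.8, 4.85),
                           surface_tension = 0.0072, surface_offset = 0,
                           probe_radius = 1.4) {
  if (!(eps_out > eps_in && eps_in >= 1)) {
    stop("need eps_out > eps_in >= 1", call. = FALSE)
  }
  if (salt_conc < 0) stop("salt_conc must be >= 0", call. = FALSE)
  if (probe_radius < 0) stop("probe_radius must be >= 0", call. = FALSE)
  stopifnot(length(gb_scaling) == 3)
  structure(
    list(eps_in = eps_in, eps_out = eps_out, salt_conc = salt_conc,
         gb_offset = gb_offset, gb_scaling = as.numeric(gb_scaling),
         surface_tension = surface_tension, surface_offset = surface_offset,
         probe_radius = probe_radius),
    class = "solvent_config"
  )
}
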