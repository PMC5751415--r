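# Henderson-Hasselbalch charge-state assignment and microstate
# enumeration for ligands with several independent ionisable sites.

#' Construct an ionisable site
#'
#' One acidic or basic functional group with a pKa. Acids carry -1 e
#' when ionised (deprotonated); bases carry +1 e when ionised
#' (protonated).
#'
#' @param label Site name, e.g. `"N1"` or `"C6''OH"`.
#' @param kind `"acid"` or `"base"`.
#' @param pka Site pKa; must lie in [-5, 20].
#' @return An object of class `ionisable_site`.
#' @export
ionisable_site <- function(label, kind = c("acid", "base"), pka) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1)
  if (!is.finite(pka) || pka < -5 || pka > 20) {
    stop("pka must be finite and within [-5, 20]", call. = FALSE)
  }
  structure(
    list(label = label, kind = kind, pka = pka,
         ionised_charge = if (kind == "acid") -1L else 1L),
    class = "ionisable_site"
  )
}

#' Construct a ligand specification
#'
#' A ligand as an ordered list of ionisable sites with unique labels.
#'
#' @param ligand_id Ligand label.
#' @param sites List of [ionisable_site()] objects.
#' @return An object of class `ligand_spec`.
#' @export
ligand_spec <- function(ligand_id, sites) {
  stopifnot(is.character(ligand_id), is.list(sites))
  ok <- vapply(sites, inherits, logical(1), "ionisable_site")
  if (!all(ok)) stop("all sites must be ionisable_site objects", call. = FALSE)
  labels <- vapply(sites, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("site labels must be unique within a ligand", call. = FALSE)
  }
  structure(list(ligand_id = ligand_id, sites = sites), class = "ligand_spec")
}

#' Fraction of a site in its ionised form
#'
#' Henderson-Hasselbalch for an independent site: an acid is ionised
#' (deprotonated) with fraction `1 / (1 + 10^(pKa - pH))`, a base
#' (protonated) with fraction `1 / (1 + 10^(pH - pKa))`. Equals 0.5
#' exactly at `pH == pKa`.
#'
#' @param site An [ionisable_site()].
#' @param ph Solution pH (default 7.40, the biological assay pH).
#' @return Ionised fraction in [0, 1].
#' @export
ionised_fraction <- function(site, ph = 7.40) {
  stopifnot(inherits(site, "ionisable_site"))
  if (site$kind == "acid") {
    1 / (1 + 10^(site$pka - ph))
  } else {
    1 / (1 + 10^(ph - site$pka))
  }
}

new_charge_state <- function(ligand_id, labels, forms, charges, state_label = NA_character_) {
  assignment <- stats::setNames(forms, labels)
  net <- sum(ifelse(forms == "ionised", charges, 0L))
  structure(
    list(ligand_id = ligand_id, assignment = assignment,
         state_label = state_label, net_charge = as.integer(net)),
    class = "charge_state"
  )
}

#' Net formal charge of a charge state
#'
#' @param state A `charge_state`.
#' @return Integer net charge in e.
#' @export
net_charge <- function(state) {
  stopifnot(inherits(state, "charge_state"))
  state$net_charge
}

#' Default (dominant) charge state at a given pH
#'
#' A site is marked ionised when its ionised fraction is at least
#' `theta`. The default `theta = 0.75` is stricter than majority rule:
#' a site just past its pKa (fraction barely above one half) stays in
#' its neutral form, which matches how dominant-microspecies pKa
#' predictors assign charge near the pH.
#'
#' @param ligand A [ligand_spec()].
#' @param ph Solution pH (default 7.40).
#' @param theta Ionisation threshold in (0.5, 1] (default 0.75).
#' @return A `charge_state` with the derived net charge and, when the
#'   pattern matches the catalogued benzophenone/azepane states, a
#'   state label (see [charge_state_catalogue()]).
#' @export
default_state <- function(ligand, ph = 7.40, theta = 0.75) {
  stopifnot(inherits(ligand, "ligand_spec"))
  if (!(theta > 0.5 && theta <= 1)) {
    stop("theta must lie in (0.5, 1]", call. = FALSE)
  }
  fr <- vapply(ligand$sites, ionised_fraction, numeric(1), ph = ph)
  labels <- vapply(ligand$sites, `[[`, character(1), "label")
  charges <- vapply(ligand$sites, `[[`, integer(1), "ionised_charge")
  forms <- ifelse(fr >= theta, "ionised", "neutral")
  st <- new_charge_state(ligand$ligand_id, labels, forms, charges)
  st$state_label <- match_state_label(st)
  st
}

#' Enumerate plausible charge states around a pH
#'
#' Sites whose pKa lies within `margin` of the pH are treated as
#' ambiguous (the uncertainty band of empirical pKa predictors, about
#' 1 pKa unit RMS) and enumerated in both forms; the remaining sites
#' are fixed at their majority form. The default state under `theta`
#' is returned first.
#'
#' @inheritParams default_state
#' @param margin Ambiguity half-width in pKa units (default 1.0).
#' @param theta Threshold used to order the default state first.
#' @return List of `charge_state` objects, `2^n_ambiguous` of them.
#' @export
enumerate_states <- function(ligand, ph = 7.40, margin = 1.0, theta = 0.75) {
  stopifnot(inherits(ligand, "ligand_spec"))
  if (!is.finite(margin) || margin < 0) stop("margin must be >= 0", call. = FALSE)
  fr <- vapply(ligand$sites, ionised_fraction, numeric(1), ph = ph)
  labels <- vapply(ligand$sites, `[[`, character(1), "label")
  charges <- vapply(ligand$sites, `[[`, integer(1), "ionised_charge")
  pkas <- vapply(ligand$sites, `[[`, numeric(1), "pka")
  ambiguous <- abs(pkas - ph) < margin
  n_amb <- sum(ambiguous)
  if (n_amb > 20) {
    stop("more than 20 ambiguous sites; refusing the 2^n enumeration",
         call. = FALSE)
  }
  majority <- ifelse(fr >= 0.5, "ionised", "neutral")
  grid <- if (n_amb == 0) {
    data.frame(row.names = 1)  # single state: every site at majority form
  } else {
    expand.grid(rep(list(c("neutral", "ionised")), n_amb),
                stringsAsFactors = FALSE)
  }
  states <- lapply(seq_len(nrow(grid)), function(r) {
    forms <- majority
    forms[ambiguous] <- unlist(grid[r, ], use.names = FALSE)
    st <- new_charge_state(ligand$ligand_id, labels, forms, charges)
    st$state_label <- match_state_label(st)
    st
  })
  def <- default_state(ligand, ph, theta)
  key <- function(s) paste(s$assignment, collapse = "|")
  keys <- vapply(states, key, character(1))
  idx <- match(key(def), keys)
  if (!is.na(idx)) states <- c(states[idx], states[-idx])
  states
}

#' Catalogue of the four benzophenone/azepane charge states
#'
#' The labelled states A-D are defined by the forms of the carboxyl
#' (C15''O2H), the azepane amine (N1) and the C6'' phenol; other
#' phenols are neutral within labelled states. The carboxylate is
#' ionised in all four.
#'
#' @return A data.frame with columns `state_label`, `carboxyl`,
#'   `amine`, `phenol6` giving each group's form.
#' @export
charge_state_catalogue <- function() {
  data.frame(
    state_label = c("A", "B", "C", "D"),
    carboxyl = "ionised",
    amine = c("neutral", "ionised", "ionised", "neutral"),
    phenol6 = c("neutral", "neutral", "ionised", "ionised"),
    stringsAsFactors = FALSE
  )
}

# Label a state A-D when its (carboxyl, amine, C6'' phenol) triple
# matches the catalogue and every other phenol is neutral.
match_state_label <- function(state) {
  a <- state$assignment
  key_sites <- c("C15''O2H", "N1", "C6''OH")
  if (!all(key_sites %in% names(a))) return(NA_character_)
  other <- setdiff(names(a), key_sites)
  if (length(other) > 0 && any(a[other] == "ionised")) return(NA_character_)
  cat <- charge_state_catalogue()
  hit <- cat$carboxyl == a[["C15''O2H"]] &
    cat$amine == a[["N1"]] &
    cat$phenol6 == a[["C6''OH"]]
  if (any(hit)) cat$state_label[which(hit)[1]] else NA_character_
}

#' Build the charge state a catalogue label denotes for one ligand
#'
#' @param ligand A [ligand_spec()] containing at least the sites
#'   `C15''O2H`, `N1` and `C6''OH`.
#' @param state_label One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A `charge_state`; all sites outside the defining triple are
#'   neutral.
#' @export
state_from_label <- function(ligand, state_label) {
  stopifnot(inherits(ligand, "ligand_spec"))
  cat <- charge_state_catalogue()
  row <- cat[cat$state_label == state_label, ]
  if (nrow(row) != 1) {
    stop("unknown state label: ", state_label, call. = FALSE)
  }
  labels <- vapply(ligand$sites, `[[`, character(1), "label")
  charges <- vapply(ligand$sites, `[[`, integer(1), "ionised_charge")
  key_sites <- c("C15''O2H", "N1", "C6''OH")
  if (!all(key_sites %in% labels)) {
    stop("ligand ", ligand$ligand_id,
         " lacks the carboxyl/amine/phenol sites the catalogue labels require",
         call. = FALSE)
  }
  forms <- rep("neutral", length(labels))
  names(forms) <- labels
  forms[["C15''O2H"]] <- row$carboxyl
  forms[["N1"]] <- row$amine
  forms[["C6''OH"]] <- row$phenol6
  st <- new_charge_state(ligand$ligand_id, labels, unname(forms), charges,
                         state_label = state_label)
  st
}

#' Construct a combination of charge states over a ligand panel
#'
#' @param combination_id Combination label, e.g. `"I"`.
#' @param mapping Named character vector, ligand id -> state label.
#' @return An object of class `state_combination`.
#' @export
state_combination <- function(combination_id, mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  valid <- charge_state_catalogue()$state_label
  bad <- setdiff(unname(mapping), valid)
  if (length(bad) > 0) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(combination_id = combination_id, mapping = mapping),
            class = "state_combination")
}

#' Resolve a state combination over a ligand panel
#'
#' Expands a combination's per-ligand state labels into fully resolved
#' per-site assignments.
#'
#' @param panel List of [ligand_spec()] objects covering every ligand
#'   the combination names.
#' @param combo A [state_combination()].
#' @return Named list, ligand id -> `charge_state`.
#' @export
resolve_combination <- function(panel, combo) {
  stopifnot(inherits(combo, "state_combination"))
  ids <- vapply(panel, `[[`, character(1), "ligand_id")
  out <- lapply(names(combo$mapping), function(lig) {
    i <- match(lig, ids)
    if (is.na(i)) stop("combination names unknown ligand: ", lig, call. = FALSE)
    state_from_label(panel[[i]], combo$mapping[[lig]])
  })
  names(out) <- names(combo$mapping)
  out
}

#' Read a per-site pKa table
#'
#' Reads a CSV with header `ligand,site,kind,pka` into a list of
#' [ligand_spec()] objects (one per distinct ligand, sites in file
#' order).
#'
#' @param path Path to the CSV file.
#' @return Named list of `ligand_spec` objects.
#' @export
read_pka_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ligand", "site", "kind", "pka")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("pKa table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(as.character(df$ligand))
  out <- lapply(ids, function(lig) {
    rows <- df[df$ligand == lig, ]
    sites <- lapply(seq_len(nrow(rows)), function(i) {
      ionisable_site(rows$site[i], rows$kind[i], rows$pka[i])
    })
    ligand_spec(lig, sites)
  })
  stats::setNames(out, ids)
}

#' Emit charge states as a flat table
#'
#' @param states List of `charge_state` objects.
#' @return A data.frame with columns `ligand`, `state_label`, `site`,
#'   `form`, `net_charge`.
#' @export
charge_states_to_table <- function(states) {
  if (inherits(states, "charge_state")) states <- list(states)
  do.call(rbind, lapply(states, function(st) {
    data.frame(ligand = st$ligand_id,
               state_label = ifelse(is.na(st$state_label), "", st$state_label),
               site = names(st$assignment),
               form = unname(st$assignment),
               net_charge = st$net_charge,
               stringsAsFactors = FALSE)
  }))
}
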