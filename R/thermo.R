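# Kd <-> standard binding free energy conversions and error propagation.
#
# Under standard conditions the binding free energy relates to the
# dissociation constant as dG0 = R T ln(Kd / c0), with c0 the 1 M
# standard concentration. Experimental Kd errors are propagated to
# first order: d(dG0) = R T dKd / Kd.

#' Construct an experimental affinity measurement
#'
#' One experimental dissociation constant, with its error, for a
#' (ligand, kinase) pair. Kd values are in nM. A measurement with
#' `kd_err >= kd` is accepted with a warning (the relative error is
#' then too large for first-order propagation to be meaningful).
#'
#' @param ligand_id Ligand label (e.g. `"1"`, `"1a"`).
#' @param kinase_id Receptor label (e.g. `"PKA"`, `"PKCe"`).
#' @param kd Dissociation constant in nM; must be positive.
#' @param kd_err Error on `kd` in nM; non-negative.
#' @return An object of class `affinity_measurement`.
#' @export
affinity_measurement <- function(ligand_id, kinase_id, kd, kd_err = 0) {
  stopifnot(is.character(ligand_id), is.character(kinase_id))
  if (!is.finite(kd) || kd <= 0) {
    stop("kd must be a positive, finite concentration in nM", call. = FALSE)
  }
  if (!is.finite(kd_err) || kd_err < 0) {
    stop("kd_err must be a non-negative, finite concentration in nM", call. = FALSE)
  }
  if (kd_err >= kd) {
    warning(sprintf("kd_err (%g nM) >= kd (%g nM) for %s/%s", kd_err, kd,
                    ligand_id, kinase_id), call. = FALSE)
  }
  structure(
    list(ligand_id = ligand_id, kinase_id = kinase_id, kd = kd, kd_err = kd_err),
    class = "affinity_measurement"
  )
}

#' Convert a dissociation constant to a standard binding free energy
#'
#' Computes `dG0 = R T ln(Kd / c0)` with Kd given in nM and the
#' standard concentration `standard_conc` in M (default 1 M). The gas
#' constant is 1.9872e-3 kcal mol^-1 K^-1. No rounding is applied; the
#' returned value carries full double precision.
#'
#' @param kd Dissociation constant in nM, positive.
#' @param temperature Absolute temperature in K (default 300).
#' @param standard_conc Standard-state concentration in M (default 1).
#' @param err Optional Kd error in nM; when supplied the result's
#'   `err` field carries the first-order propagated energy error.
#' @return An object of class `binding_free_energy` with fields
#'   `value` (kcal/mol), `err` (kcal/mol) and `temperature` (K).
#' @examples
#' kd_to_dg(5.9, temperature = 300)$value   # about -11.30 kcal/mol
#' kd_to_dg(1e9)$value                      # 1 M reference: exactly 0
#' @export
kd_to_dg <- function(kd, temperature = 300, standard_conc = 1, err = 0) {
  if (!is.finite(kd) || kd <= 0) {
    stop("kd must be positive (nM)", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  if (!is.finite(standard_conc) || standard_conc <= 0) {
    stop("standard_conc must be positive (M)", call. = FALSE)
  }
  rt <- cgbsa_constants$R_gas * temperature
  kd_molar <- kd * 1e-9
  value <- rt * log(kd_molar / standard_conc)
  structure(
    list(value = value,
         err = propagate_kd_uncertainty(kd, err, temperature),
         temperature = temperature),
    class = "binding_free_energy"
  )
}

#' Convert a standard binding free energy back to a dissociation constant
#'
#' Inverse of [kd_to_dg()]: `Kd = c0 exp(dG0 / (R T))`, returned in nM.
#' Round-trips with [kd_to_dg()] to better than one part in 1e6.
#'
#' @param dg Binding free energy in kcal/mol (scalar or a
#'   `binding_free_energy` object).
#' @param temperature Absolute temperature in K (default 300; ignored
#'   when `dg` carries its own temperature).
#' @param standard_conc Standard-state concentration in M (default 1).
#' @return Dissociation constant in nM.
#' @export
dg_to_kd <- function(dg, temperature = 300, standard_conc = 1) {
  if (inherits(dg, "binding_free_energy")) {
    temperature <- dg$temperature
    dg <- dg$value
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  if (abs(dg) > 100) {
    stop("|dg| > 100 kcal/mol would overflow the concentration scale",
         call. = FALSE)
  }
  rt <- cgbsa_constants$R_gas * temperature
  standard_conc * exp(dg / rt) * 1e9
}

#' First-order propagation of a Kd error to the free-energy scale
#'
#' `d(dG0) = R T kd_err / kd`, in kcal/mol. Exact for small relative
#' errors; for large ones `R T log(1 + kd_err/kd)` would differ, and
#' the first-order form is used throughout for consistency.
#'
#' @inheritParams kd_to_dg
#' @param kd_err Error on `kd` in nM, non-negative.
#' @return Propagated error in kcal/mol.
#' @export
propagate_kd_uncertainty <- function(kd, kd_err, temperature = 300) {
  if (!is.finite(kd) || kd <= 0) stop("kd must be positive (nM)", call. = FALSE)
  if (!is.finite(kd_err) || kd_err < 0) {
    stop("kd_err must be non-negative (nM)", call. = FALSE)
  }
  cgbsa_constants$R_gas * temperature * (kd_err / kd)
}

#' Read an affinity table
#'
#' Reads a CSV with header `ligand,kinase,kd_nM,kd_err_nM` into a
#' data frame of validated measurements.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `ligand`, `kinase`, `kd_nM`,
#'   `kd_err_nM`.
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ligand", "kinase", "kd_nM", "kd_err_nM")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("affinity table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    affinity_measurement(as.character(df$ligand[i]), as.character(df$kinase[i]),
                         df$kd_nM[i], df$kd_err_nM[i])
  }
  df[required]
}

#' Convert an affinity table to binding free energies
#'
#' Applies [kd_to_dg()] and [propagate_kd_uncertainty()] row-wise.
#'
#' @param affinities Data frame as returned by [read_affinity_table()].
#' @param temperature Absolute temperature in K (default 300).
#' @return A data.frame with columns `ligand`, `kinase`,
#'   `dg_kcal_mol`, `dg_err_kcal_mol`, `temperature_K`.
#' @export
affinity_to_dg_table <- function(affinities, temperature = 300) {
  dg <- vapply(affinities$kd_nM, function(k) kd_to_dg(k, temperature)$value,
               numeric(1))
  dg_err <- mapply(propagate_kd_uncertainty, affinities$kd_nM,
                   affinities$kd_err_nM, MoreArgs = list(temperature = temperature))
  data.frame(ligand = affinities$ligand, kinase = affinities$kinase,
             dg_kcal_mol = dg, dg_err_kcal_mol = as.numeric(dg_err),
             temperature_K = temperature, stringsAsFactors = FALSE)
}

#' Write a binding-free-energy table
#'
#' @param dg_table Data frame from [affinity_to_dg_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dg_table <- function(dg_table, path) {
  utils::write.csv(dg_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
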