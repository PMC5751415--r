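# Reference panel: (-)-balanol and its fluorinated azepane analogues
# (1a, 1c, 1d, 1e) measured against PKA and PKC-epsilon, with
# Marvin-predicted per-site pKa values. These published experimental
# numbers are inputs to the workflow, shipped both as accessors here
# and as CSV fixtures under inst/extdata/.

#' Experimental affinities of the balanol analogue panel
#'
#' Dissociation constants (nM, with errors) of (-)-balanol (`1`) and
#' its fluorinated analogues `1a`, `1c`, `1d`, `1e` against PKA and
#' PKC-epsilon.
#'
#' @return Data frame with columns `ligand`, `kinase`, `kd_nM`,
#'   `kd_err_nM`.
#' @export
balanol_affinities <- function() {
  data.frame(
    ligand = rep(c("1", "1a", "1c", "1d", "1e"), times = 2),
    kinase = rep(c("PKA", "PKCe"), each = 5),
    kd_nM = c(5.9, 7.9, 6.4, 9.2, 43,
              0.73, 19, 0.4, 110, 38),
    kd_err_nM = c(0.5, 0.5, 0.1, 0.8, 4,
                  0.06, 8, 0.02, 19, 9.5),
    stringsAsFactors = FALSE
  )
}

#' Predicted pKa values of the balanol analogue panel
#'
#' Per-site pKa values of the six ionisable groups on each analogue:
#' the azepane amine N1 (base) and five acidic groups (the benzamide
#' phenol C5'OH, the benzophenone phenols C4''OH, C6''OH, C10''OH and
#' the carboxyl C15''O2H).
#'
#' @return Data frame with columns `ligand`, `site`, `kind`, `pka`.
#' @export
balanol_pka_table <- function() {
  sites <- c("N1", "C5'OH", "C4''OH", "C6''OH", "C10''OH", "C15''O2H")
  kinds <- c("base", "acid", "acid", "acid", "acid", "acid")
  pka <- rbind(
    `1`  = c(9.65, 8.58, 7.94, 6.52, 7.22, 2.98),
    `1a` = c(8.22, 8.74, 7.77, 6.51, 7.18, 2.98),
    `1c` = c(9.37, 8.55, 7.93, 6.52, 7.22, 2.98),
    `1d` = c(6.20, 8.62, 7.96, 6.73, 7.28, 2.98),
    `1e` = c(6.20, 8.62, 7.96, 6.73, 7.28, 2.98)
  )
  data.frame(
    ligand = rep(rownames(pka), each = length(sites)),
    site = rep(sites, times = nrow(pka)),
    kind = rep(kinds, times = nrow(pka)),
    pka = as.vector(t(pka)),
    stringsAsFactors = FALSE
  )
}

#' Ligand specifications for the balanol analogue panel
#'
#' @return Named list of [ligand_spec()] objects built from
#'   [balanol_pka_table()].
#' @export
balanol_panel <- function() {
  df <- balanol_pka_table()
  ids <- unique(df$ligand)
  out <- lapply(ids, function(lig) {
    rows <- df[df$ligand == lig, ]
    ligand_spec(lig, lapply(seq_len(nrow(rows)), function(i) {
      ionisable_site(rows$site[i], rows$kind[i], rows$pka[i])
    }))
  })
  stats::setNames(out, ids)
}

#' The three explored charge-state combinations
#'
#' Combination I keeps all phenols neutral (states B for `1`, `1a`,
#' `1c`; A for `1d`, `1e`); combination II ionises the C6'' phenolate
#' throughout (C/C/C/D/D); combination III differs from II only in
#' `1a`, whose amine and phenol are both neutral (state A).
#'
#' @return Named list of [state_combination()] objects `I`, `II`,
#'   `III`.
#' @export
balanol_combinations <- function() {
  list(
    I = state_combination("I", c(`1` = "B", `1a` = "B", `1c` = "B",
                                 `1d` = "A", `1e` = "A")),
    II = state_combination("II", c(`1` = "C", `1a` = "C", `1c` = "C",
                                   `1d` = "D", `1e` = "D")),
    III = state_combination("III", c(`1` = "C", `1a` = "A", `1c` = "C",
                                     `1d` = "D", `1e` = "D"))
  )
}
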