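test_that("ionised_fraction follows Henderson-Hasselbalch", {
  acid <- ionisable_site("C6''OH", "acid", 6.52)
  base <- ionisable_site("N1", "base", 9.65)
  # half-ionised exactly at the pKa
  expect_equal(ionised_fraction(ionisable_site("s", "acid", 7.4), 7.4), 0.5)
  expect_equal(ionised_fraction(ionisable_site("s", "base", 7.4), 7.4), 0.5)
  # direct formula at assay pH
  expect_equal(ionised_fraction(acid, 7.40), 1 / (1 + 10^(6.52 - 7.40)),
               tolerance = 1e-12)
  expect_equal(round(ionised_fraction(acid, 7.40), 3), 0.884)
  expect_equal(ionised_fraction(base, 7.40), 1 / (1 + 10^(7.40 - 9.65)),
               tolerance = 1e-12)
  expect_equal(round(ionised_fraction(base, 7.40), 4), 0.9944)
})

test_that("ionised_fraction is monotone in pH, opposite for acids and bases", {
  ph <- seq(2, 12, by = 0.5)
  fa <- vapply(ph, function(p) {
    ionised_fraction(ionisable_site("a", "acid", 7), p)
  }, numeric(1))
  fb <- vapply(ph, function(p) {
    ionised_fraction(ionisable_site("b", "base", 7), p)
  }, numeric(1))
  expect_true(all(diff(fa) > 0))
  expect_true(all(diff(fb) < 0))
})

test_that("default_state reproduces the panel's assay-pH assignments", {
  panel <- balanol_panel()
  ionised_sites <- function(st) names(st$assignment[st$assignment == "ionised"])
  # amine charged for 1, 1a, 1c; neutral for 1d, 1e; phenolate C6'' and
  # carboxylate always charged; the other phenols neutral
  for (lig in c("1", "1a", "1c")) {
    st <- default_state(panel[[lig]], ph = 7.40, theta = 0.75)
    expect_setequal(ionised_sites(st), c("N1", "C6''OH", "C15''O2H"))
    expect_equal(net_charge(st), -1L)
    expect_equal(st$state_label, "C")
  }
  for (lig in c("1d", "1e")) {
    st <- default_state(panel[[lig]], ph = 7.40, theta = 0.75)
    expect_setequal(ionised_sites(st), c("C6''OH", "C15''O2H"))
    expect_equal(net_charge(st), -2L)
    expect_equal(st$state_label, "D")
  }
})

test_that("theta = 1 leaves partially ionised sites neutral", {
  lig <- balanol_panel()[["1"]]
  st <- default_state(lig, ph = 7.40, theta = 1.0)
  expect_true(all(st$assignment == "neutral"))
  expect_equal(net_charge(st), 0L)
})

test_that("enumerate_states expands exactly the ambiguous sites", {
  panel <- balanol_panel()
  # balanol: |pKa - 7.40| < 1 for C4''OH (0.54), C6''OH (0.88),
  # C10''OH (0.18) only -> 2^3 states
  states1 <- enumerate_states(panel[["1"]], ph = 7.40, margin = 1.0)
  expect_length(states1, 8)
  labels1 <- vapply(states1, `[[`, character(1), "state_label")
  expect_true(all(c("B", "C") %in% labels1))
  # 1a adds the amine (|8.22 - 7.40| = 0.82) -> 2^4 states incl. A, B, C
  states1a <- enumerate_states(panel[["1a"]], ph = 7.40, margin = 1.0)
  expect_length(states1a, 16)
  labels1a <- vapply(states1a, `[[`, character(1), "state_label")
  expect_true(all(c("A", "B", "C") %in% labels1a))
  # margin 0: the single majority-form state
  expect_length(enumerate_states(panel[["1"]], margin = 0), 1)
})

test_that("the default state leads the enumeration and net charge recounts", {
  panel <- balanol_panel()
  for (lig in names(panel)) {
    states <- enumerate_states(panel[[lig]], ph = 7.40, margin = 1.0)
    def <- default_state(panel[[lig]], ph = 7.40)
    expect_equal(states[[1]]$assignment, def$assignment)
    for (st in states) {
      # independent recount of the net charge from the assignment
      chg <- vapply(panel[[lig]]$sites, function(s) {
        if (st$assignment[[s$label]] == "ionised") s$ionised_charge else 0L
      }, integer(1))
      expect_equal(net_charge(st), sum(chg))
    }
  }
})

test_that("combinations resolve to the catalogued assignments", {
  panel <- balanol_panel()
  combos <- balanol_combinations()
  # combination III leaves the fluorinated amine and its phenol neutral
  st <- resolve_combination(panel, combos$III)[["1a"]]
  expect_equal(st$state_label, "A")
  expect_equal(unname(st$assignment[c("C15''O2H", "N1", "C6''OH")]),
               c("ionised", "neutral", "neutral"))
  # combination II, weakest multi-fluorinated ligand: state D, net -2
  st_e <- resolve_combination(panel, combos$II)[["1e"]]
  expect_equal(st_e$state_label, "D")
  expect_equal(net_charge(st_e), -2L)
  # combination I, parent ligand: ammonium + carboxylate, net 0
  st_1 <- resolve_combination(panel, combos$I)[["1"]]
  expect_equal(st_1$state_label, "B")
  expect_equal(net_charge(st_1), 0L)
  expect_error(state_combination("X", c(`1` = "E")), "unknown state")
  expect_error(resolve_combination(panel[c("1", "1c")],
                                   state_combination("X", c(`9` = "A"))),
               "unknown ligand")
})

test_that("pKa tables round trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(balanol_pka_table(), path, row.names = FALSE, quote = FALSE)
  specs <- read_pka_table(path)
  expect_named(specs, c("1", "1a", "1c", "1d", "1e"))
  expect_equal(vapply(specs[["1d"]]$sites, `[[`, numeric(1), "pka")[1], 6.20)
  tbl <- charge_states_to_table(default_state(specs[["1"]]))
  expect_named(tbl, c("ligand", "state_label", "site", "form", "net_charge"))
  expect_equal(nrow(tbl), 6)
})
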