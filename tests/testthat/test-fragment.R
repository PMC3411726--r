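# Placements and theoretical b/y/precursor ion generation.

test_that("placement validates sites and multiplicity", {
  expect_s3_class(placement("GRGDSPC", "NO", 7), "nap_placement")
  expect_error(placement("GRGDSPC", "NO", 3), "not an allowed")
  expect_error(placement("GRGDSPC", "NO", c(7, 7)), "only modeled for naphthoquinones")
  expect_silent(placement("GRGDSPC", "NQ12", c(7, 7)))
  expect_error(placement("DYKDDDDK", "NQ12", c(3, 3)), "cysteine")
  expect_error(placement("GRGDSPC", "NQ12", c(0, 0)), "cysteine")
  expect_error(placement("GRGDSPC", "NQ12", c(0, 7, 7, 7)), "at most")
})

test_that("fragment m/z values reproduce printed reference ions", {
  # unmodified GRGDSPC b4 and y6 (printed 386.18 / 634.26)
  bare <- placement("GRGDSPC", "NO", integer(0))
  expect_equal(b_ion_mz(bare, 4), 386.178, tolerance = 0.01)
  expect_equal(y_ion_mz(bare, 6), 634.261, tolerance = 0.01)
  # adducted fragments: His-adducted b5 of the amidated peptide, Cys y3
  expect_equal(b_ion_mz(placement("DASFHSWG-NH2", "NO", 5), 5), 702.29,
               tolerance = 0.01)
  expect_equal(y_ion_mz(placement("GRGDSPC", "NO", 7), 3), 450.17,
               tolerance = 0.01)
  # trivial: b1 = first residue + proton
  expect_equal(b_ion_mz(bare, 1), residue_mass("G") + proton_mass)
  # y ions never carry the N-terminal adduct
  nterm <- placement("GRGDSPC", "NO", 0)
  expect_equal(y_ion_mz(nterm, 6), y_ion_mz(bare, 6))
  expect_error(b_ion_mz(bare, 7), "index")
  expect_error(y_ion_mz(bare, 0), "index")
})

test_that("precursor m/z handles adduct deltas and losses", {
  pl <- placement("DYKDDDDK", "NDO", 3)
  expect_equal(precursor_mz(pl), 1191.4688, tolerance = 3e-3)
  pl_no <- placement("DYKDDDDK", "NO", 0)
  expect_equal(precursor_mz(pl_no, loss = "H2O"), 1139.4527, tolerance = 3e-3)
  # zero-adduct identity
  bare <- placement("DYKDDDDK", "NO", integer(0))
  expect_equal(precursor_mz(bare), peptide_mass("DYKDDDDK") + proton_mass)
  # losses remove exactly the adduct delta
  expect_equal(precursor_mz(pl, loss = "X"), precursor_mz(bare))
  expect_error(precursor_mz(bare, loss = "X"), "cannot lose")
  expect_error(precursor_mz(pl, loss = c("H2O", "H2O")), "at most one")
})

test_that("ion sets are complete, duplicate-free and complementary", {
  cases <- list(
    placement("GRGDSPC", "NO", integer(0)),
    placement("GRGDSPC", "NO", 7),
    placement("DASFHSWG-NH2", "NDO", c(5)),
    placement("DYKDDDDK", "NQ12", c(0, 3)),
    placement("GRGDSPC", "NQ12", c(0, 7, 7))
  )
  for (pl in cases) {
    ions <- theoretical_ions(pl)
    L <- pl$peptide$length
    expect_equal(nrow(ions), 2 * (L - 1) + 2 * (pl$n + 1))
    expect_false(any(duplicated(ions[c("series", "index", "loss")])))
    expect_false(is.unsorted(ions$mz))
    # complementarity: b_i + y_(L-i) = precursor + proton
    prec <- ions$mz[ions$series == "precursor" & ions$loss == ""]
    for (i in seq_len(L - 1)) {
      expect_equal(b_ion_mz(pl, i) + y_ion_mz(pl, L - i),
                   prec + proton_mass, tolerance = 1e-6)
    }
    # total delta on the precursor is exactly n * adduct delta
    bare <- placement(pl$peptide, pl$adduct, integer(0), pl$variant)
    expect_equal(prec - precursor_mz(bare), pl$n * pl$delta)
  }
})

test_that("dipeptide ion set reduces to b1, y1 and precursor species", {
  ions <- theoretical_ions(placement("GG", "NO", integer(0)))
  expect_identical(sort(unique(ions$series)), c("b", "precursor", "y"))
  expect_equal(sum(ions$series != "precursor"), 2L)
})

test_that("water satellites are off by default and labeled when on", {
  pl <- placement("YGGFLRKR", "NDO", 0)
  base <- theoretical_ions(pl)
  expect_false(any(base$loss %in% c("H2O", "+H2O") & base$series != "precursor"))
  sat <- theoretical_ions(pl, water_satellites = TRUE)
  b6w <- sat[sat$series == "b" & sat$index == 6 & sat$loss == "+H2O", ]
  # the water-gain b6 satellite printed at 712.38 for the unmodified peptide
  bare_sat <- theoretical_ions(placement("YGGFLRKR", "NDO", integer(0)),
                               water_satellites = TRUE)
  b6w0 <- bare_sat[bare_sat$series == "b" & bare_sat$index == 6 &
                     bare_sat$loss == "+H2O", ]
  expect_equal(b6w0$mz, 712.38, tolerance = 0.01)
  expect_match(b6w$label, "\\+ H2O")
})

test_that("placement enumeration covers allowed multisets in order", {
  expect_identical(enumerate_placements("GRGDSPC", "NO", 1)$label,
                   c("Nterm", "C7"))
  expect_identical(enumerate_placements("DYKDDDDK", "NDO", 1)$label,
                   c("Nterm", "K3", "K8"))
  expect_identical(enumerate_placements("YGGFLRKR", "NO", 1)$label,
                   c("Nterm", "K7"))
  # n = 0: the single empty placement
  e0 <- enumerate_placements("GRGDSPC", "NO", 0)
  expect_equal(nrow(e0), 1L)
  expect_identical(e0$sites[[1]], integer(0))
  # quinone Cys doubling allowed, amine doubling not
  e2 <- enumerate_placements("GRGDSPC", "NQ12", 2)
  expect_identical(e2$label, c("Nterm+C7", "C7+C7"))
  e2ep <- enumerate_placements("GRGDSPC", "NO", 2)
  expect_identical(e2ep$label, "Nterm+C7")
  # a peptide without nucleophilic side chains still offers its N-terminus
  expect_identical(enumerate_placements("GAGA", "NO", 1)$label, "Nterm")
})
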