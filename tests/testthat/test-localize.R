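# Site localization from fragment evidence.

test_that("strict counting reproduces the canonical single-site arguments", {
  # Cys call: unmodified b4/b5 exclude the N-terminus, adducted y3/y4 pin
  # the C-terminal region; Cys7 is the only allowed site there
  ev <- evidence_ions("GRGDSPC", "NO", series = c("b", "b", "y", "y"),
                      index = c(4, 5, 3, 4), adducts_carried = c(0, 0, 1, 1))
  loc <- localize("GRGDSPC", "NO", 1, ev)
  expect_identical(loc$assigned, "C7")
  expect_identical(loc$confidence, "unambiguous")

  # His call: adducted b5 bounds the site from above, adducted y4 from below
  ev <- evidence_ions("DASFHSWG-NH2", "NO", series = rep(c("b", "y"), c(3, 4)),
                      index = c(5:7, 4:7), adducts_carried = 1)
  loc <- localize("DASFHSWG-NH2", "NO", 1, ev)
  expect_identical(loc$assigned, "H5")
  expect_identical(loc$confidence, "unambiguous")

  # Lys3 call: adducted y6 requires a site at position >= 3, unmodified y5
  # frees the C-terminal lysine
  ev <- evidence_ions("DYKDDDDK", "NDO", series = c("b", "y", "y", "y", "y"),
                      index = c(7, 6, 7, 4, 5),
                      adducts_carried = c(1, 1, 1, 0, 0))
  loc <- localize("DYKDDDDK", "NDO", 1, ev)
  expect_identical(loc$assigned, "K3")
  expect_identical(loc$confidence, "unambiguous")

  # N-terminus call: unmodified y7 excludes every side chain, adducted b ions
  # confirm the N-terminal amine
  ev <- evidence_ions("EIVRDIKE", "NQ12", series = c("b", "b", "b", "y", "y"),
                      index = c(4, 5, 7, 4, 7),
                      adducts_carried = c(1, 1, 1, 0, 0))
  loc <- localize("EIVRDIKE", "NQ12", 1, ev)
  expect_identical(loc$assigned, "Nterm")
  expect_identical(loc$confidence, "unambiguous")
})

test_that("contradictory strict evidence yields undetermined with a lenient interval", {
  # unmodified b6 contradicts adducted b7 for any allowed site; the
  # adducted ions alone bound the site to the N-terminal region {0..3}
  ev <- evidence_ions("DYKDDDDK", "NO", series = c("b", "b", "y", "y", "y"),
                      index = c(6, 7, 3, 4, 5),
                      adducts_carried = c(0, 1, 0, 0, 0))
  loc <- localize("DYKDDDDK", "NO", 1, ev)
  expect_identical(loc$assigned, "undetermined")
  expect_identical(loc$confidence, "undetermined")
  expect_equal(nrow(loc$feasible), 0L)
  expect_identical(loc$interval, c(0L, 3L))
})

test_that("no adducted fragment evidence never yields a site call", {
  ev <- evidence_ions("EFYAPWCG", "NO", series = "b", index = 5,
                      adducts_carried = 0)
  loc <- localize("EFYAPWCG", "NO", 1, ev)
  expect_identical(loc$assigned, "undetermined")
  loc0 <- localize("GRGDSPC", "NO", 0, ev[0, ])
  expect_identical(loc0$assigned, "undetermined")
})

test_that("reactivity ranking resolves ambiguous intervals when one class wins", {
  # adducted b7 on DYKDDDDK leaves {Nterm, K3}; quinones favor the amine
  # over lysine, epoxides the reverse
  ev <- evidence_ions("DYKDDDDK", "NQ12", series = "b", index = 7,
                      adducts_carried = 1)
  loc <- localize("DYKDDDDK", "NQ12", 1, ev)
  expect_identical(sort(loc$feasible$label), c("K3", "Nterm"))
  expect_identical(loc$assigned, "Nterm")
  expect_identical(loc$confidence, "interval_resolved_by_reactivity")
  expect_identical(loc$interval, c(0L, 3L))
  ev_ep <- evidence_ions("DYKDDDDK", "NO", series = "b", index = 7,
                         adducts_carried = 1)
  loc_ep <- localize("DYKDDDDK", "NO", 1, ev_ep)
  expect_identical(loc_ep$assigned, "K3")
  expect_identical(loc_ep$confidence, "interval_resolved_by_reactivity")
  # rank-tied candidates (two lysines) stay undetermined
  ev2 <- evidence_ions("DYKDDDDK", "NQ12", series = "y", index = 7,
                       adducts_carried = 1)
  loc2 <- localize("DYKDDDDK", "NQ12", 1, ev2)
  expect_identical(sort(loc2$feasible$label), c("K3", "K8"))
  expect_identical(loc2$confidence, "undetermined")
})

test_that("adding evidence never enlarges the feasible set; lenient contains strict", {
  withr::local_seed(11)
  for (pep in model_peptide_seqs) {
    for (add in c("NO", "NQ12")) {
      for (rep in 1:10) {
        ev <- random_evidence(pep, add, 1, n_rows = 4)
        f_all <- feasible_sites(pep, add, 1, ev)
        f_sub <- feasible_sites(pep, add, 1, ev[1:2, ])
        expect_true(all(f_all$label %in% f_sub$label))
        f_len <- feasible_sites(pep, add, 1, ev, mode = "lenient")
        expect_true(all(f_all$label %in% f_len$label))
      }
    }
  }
})

test_that("feasible_sites agrees with the brute-force oracle", {
  withr::local_seed(23)
  for (pep in model_peptide_seqs) {
    for (add in c("NO", "NDO", "NQ12", "NQ14")) {
      for (n in 1:2) {
        for (rep in 1:25) {
          ev <- random_evidence(pep, add, n, n_rows = sample(0:4, 1))
          for (mode in c("strict", "lenient")) {
            expect_same_placements(
              feasible_sites(pep, add, n, ev, mode = mode),
              oracle_feasible_sites(pep, add, n, ev, mode = mode))
          }
        }
      }
    }
  }
  # n = 0: the empty placement is always feasible
  ev0 <- random_evidence("GRGDSPC", "NO", 0, 2)
  expect_same_placements(feasible_sites("GRGDSPC", "NO", 0, ev0),
                         oracle_feasible_sites("GRGDSPC", "NO", 0, ev0))
})

test_that("vacuous evidence leaves every placement feasible", {
  ev <- evidence_ions("GRGDSPC", "NO", series = character(0),
                      index = integer(0), adducts_carried = integer(0))
  f <- feasible_sites("DYKDDDDK", "NDO", 1, ev)
  expect_identical(f$label, c("Nterm", "K3", "K8"))
})

test_that("noise-free spectra localize every single-adduct placement unambiguously", {
  for (pep in model_peptide_seqs) {
    for (add in c("NO", "NQ14")) {
      for (site in allowed_sites(pep, add)) {
        pl <- placement(pep, add, site)
        sim <- simulate_spectrum(pl, ppm_sigma = 0, dropout_prob = 0,
                                 n_noise = 0, seed = 1)
        rep <- run_pipeline(sim$peaks, pep, add, 1, tol_ppm = 5)
        expect_identical(rep$localization$assigned, site_label(pep, site))
        expect_identical(rep$localization$confidence, "unambiguous")
      }
    }
  }
})
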