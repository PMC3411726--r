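# Shared fixtures and generators for the test suite.

# Reference ion annotations for the six model peptides (curated from the
# characterization experiments; `exclude` marks printed values that
# deviate from theory beyond 2-dp rounding plus 5 ppm, with notes).
printed_ions <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- readr::read_tsv(
        system.file("extdata", "printed_ions.tsv", package = "napadduct"),
        col_types = readr::cols(
          peptide = "c", adduct = "c", spectrum_n = "i", sites = "c",
          series = "c", index = "i", n_mod = "i", loss = "c",
          printed_mz = "d", exclude = "i", note = "c"
        ))
      tab$sites[is.na(tab$sites)] <<- ""
      tab$loss[is.na(tab$loss)] <<- ""
    }
    tab
  }
})

parse_sites <- function(s) {
  if (is.na(s) || s == "") integer(0) else as.integer(strsplit(s, ";")[[1]])
}

# Peak list built from the printed m/z values of one spectrum
printed_peaks <- function(pep, add, n) {
  rows <- dplyr::filter(printed_ions(), .data$peptide == pep,
                        .data$adduct == add, .data$spectrum_n == n)
  tibble::tibble(mz = rows$printed_mz, intensity = 1)
}

# Random fragment-evidence table (series, index, carried count + implied
# theoretical m/z) for the oracle-equivalence property
random_evidence <- function(peptide, adduct, n_adducts, n_rows) {
  p <- as_peptide(peptide)
  series <- sample(c("b", "y"), n_rows, replace = TRUE)
  index <- sample(seq_len(p$length - 1), n_rows, replace = TRUE)
  carried <- sample(0:n_adducts, n_rows, replace = TRUE)
  evidence_ions(p, adduct, series = series, index = index,
                adducts_carried = carried)
}

model_peptide_seqs <- c("GRGDSPC", "YGGFLRKR", "DYKDDDDK", "DASFHSWG-NH2",
                       "EFYAPWCG", "EIVRDIKE")

expect_same_placements <- function(a, b) {
  expect_identical(sort(a$label), sort(b$label))
}
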