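# Monoisotopic mass arithmetic, residue and terminus chemistry, and the
# naphthalene-metabolite adduct definitions.

# IUPAC monoisotopic masses of the light isotopes (Da).
.element_masses <- c(
  H = 1.0078250319,
  C = 12,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass of a proton in Da
#'
#' Added to a neutral monoisotopic mass to obtain a singly-protonated
#' \eqn{[M+H]^+} m/z.
#' @export
proton_mass <- 1.007276

.water_mass <- 2 * .element_masses[["H"]] + .element_masses[["O"]]
.ammonia_mass <- 3 * .element_masses[["H"]] + .element_masses[["N"]]
.h_mass <- .element_masses[["H"]]

# Residue (amino acid minus water) elemental compositions, standard 20.
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Parse a molecular formula into element counts
#'
#' @param formula Character scalar such as `"C10H8O"` (element symbols from
#'   C, H, N, O, S, each optionally followed by a count).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H8O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || formula == "") {
    return(setNames(integer(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    abort(sprintf("cannot parse formula '%s'", formula))
  }
  elems <- sub("[0-9]*$", "", parts)
  counts_chr <- sub("^[A-Za-z]+", "", parts)
  counts <- ifelse(counts_chr == "", 1L, suppressWarnings(as.integer(counts_chr)))
  if (anyNA(counts)) abort(sprintf("cannot parse formula '%s'", formula))
  unknown <- setdiff(elems, names(.element_masses))
  if (length(unknown) > 0) {
    abort(sprintf("unknown element symbol: %s", paste(unknown, collapse = ", ")))
  }
  tapply(counts, factor(elems, levels = unique(elems)), sum)[unique(elems)]
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums IUPAC monoisotopic element masses over the composition. Compositions
#' may be given as formula strings (vectorized) or as a named count vector.
#'
#' @param composition Character vector of formulas, or a named numeric vector
#'   of element counts.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass("C10H8O")   # naphthalene epoxide adduct delta, 144.0575
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(composition) {
  if (is.numeric(composition)) {
    if (length(composition) == 0) return(0)
    unknown <- setdiff(names(composition), names(.element_masses))
    if (length(unknown) > 0 || is.null(names(composition))) {
      abort(sprintf(
        "unknown element symbol: %s",
        paste(if (is.null(names(composition))) "<unnamed>" else unknown,
              collapse = ", ")
      ))
    }
    if (any(composition < 0)) abort("element counts must be non-negative")
    return(sum(composition * .element_masses[names(composition)]))
  }
  vapply(composition, function(f) {
    cnt <- parse_formula(f)
    if (length(cnt) == 0) 0 else sum(cnt * .element_masses[names(cnt)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Monoisotopic residue masses
#'
#' Residue masses are amino acid masses minus water, i.e. the mass each
#' residue contributes inside a peptide chain.
#'
#' @param code Character vector of one-letter residue codes.
#' @return Numeric vector of residue masses (Da).
#' @examples
#' residue_mass(c("G", "C", "W"))
#' @export
residue_mass <- function(code) {
  bad <- setdiff(unique(code), names(.residue_formulas))
  if (length(bad) > 0) {
    abort(sprintf("invalid residue code: %s", paste(bad, collapse = ", ")))
  }
  unname(.residue_mass_table[code])
}

.residue_mass_table <- vapply(.residue_formulas, monoisotopic_mass, numeric(1))

#' Table of the standard residues
#'
#' @return A tibble with columns `code`, `formula`, `mass`.
#' @export
residue_masses <- function() {
  tibble::tibble(
    code = names(.residue_formulas),
    formula = unname(.residue_formulas),
    mass = unname(.residue_mass_table)
  )
}

#' Construct a peptide
#'
#' Peptides are strings of one-letter residue codes with an optional
#' C-terminal amide; `"DASFHSWG-NH2"` denotes the amidated form. The
#' N-terminus is always a free amine.
#'
#' @param x A sequence string (optionally suffixed `-NH2`), or a peptide.
#' @param c_terminus `"free_acid"` or `"amide"`; overrides any suffix.
#' @return An object of class `"nap_peptide"`.
#' @examples
#' as_peptide("GRGDSPC")
#' as_peptide("DASFHSWG-NH2")
#' @export
as_peptide <- function(x, c_terminus = NULL) {
  if (inherits(x, "nap_peptide")) {
    if (!is.null(c_terminus)) x$c_terminus <- match.arg(c_terminus, c("free_acid", "amide"))
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  seq <- x
  cterm <- c_terminus
  if (grepl("-NH2$", seq, ignore.case = TRUE)) {
    seq <- sub("-NH2$", "", seq, ignore.case = TRUE)
    if (is.null(cterm)) cterm <- "amide"
  }
  cterm <- match.arg(cterm %||% "free_acid", c("free_acid", "amide"))
  residues <- strsplit(seq, "")[[1]]
  if (length(residues) < 1) abort("peptide must contain at least one residue")
  bad <- setdiff(unique(residues), names(.residue_formulas))
  if (length(bad) > 0) {
    abort(sprintf("invalid residue code: %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(sequence = seq, residues = residues, c_terminus = cterm,
         length = length(residues)),
    class = "nap_peptide"
  )
}

#' @export
print.nap_peptide <- function(x, ...) {
  suffix <- if (x$c_terminus == "amide") "-NH2" else ""
  cat(sprintf("<peptide> %s%s (L = %d, [M+H]+ = %.4f)\n",
              x$sequence, suffix, x$length, peptide_mass(x) + proton_mass))
  invisible(x)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue masses plus water for a free-acid C-terminus, or plus
#' ammonia for a C-terminal amide.
#'
#' @param peptide A peptide (or sequence string, see [as_peptide()]).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("GRGDSPC")        # 690.2755
#' peptide_mass("DASFHSWG-NH2")   # 904.3827
#' @export
peptide_mass <- function(peptide) {
  p <- as_peptide(peptide)
  terminus <- if (p$c_terminus == "amide") .ammonia_mass else .water_mass
  sum(.residue_mass_table[p$residues]) + terminus
}

.nap_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "napadduct", mustWork = FALSE)
  if (!nzchar(path)) {
    # during in-source development (pkgload), fall back to inst/
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Adduct species definitions
#'
#' The four reactive naphthalene metabolites modeled as covalent adduct
#' species: the 1,2-epoxide (`NO`), the diol epoxide (`NDO`), and the 1,2-
#' and 1,4-naphthoquinones (`NQ12`, `NQ14`; isomers with identical delta
#' mass, stored in the reduced hydroquinone form). `delta` is the
#' monoisotopic mass each adduct adds to the peptide; `targets` lists the
#' nucleophilic site classes it may modify.
#'
#' @return A tibble with columns `name`, `formula`, `class`, `symbol`,
#'   `delta`, `nominal_delta`, `targets` (list of character), `note`.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  if (is.null(.nap_cache$adducts)) {
    tab <- readr::read_tsv(.extdata("adducts.tsv"), show_col_types = FALSE,
                           progress = FALSE)
    tab$delta <- monoisotopic_mass(tab$formula)
    tab$nominal_delta <- round(tab$delta, 2)
    tab$targets <- strsplit(tab$targets, ",", fixed = TRUE)
    .nap_cache$adducts <- tab[, c("name", "formula", "class", "symbol",
                                  "delta", "nominal_delta", "targets", "note")]
  }
  .nap_cache$adducts
}

.adduct_row <- function(name) {
  tab <- adduct_table()
  i <- match(name, tab$name)
  if (is.na(i)) {
    abort(sprintf("unknown adduct '%s' (expected one of %s)",
                  name, paste(tab$name, collapse = ", ")))
  }
  tab[i, ]
}

# plain-vector adduct lookups for hot paths
.adduct_info <- function() {
  if (is.null(.nap_cache$adduct_info)) {
    tab <- adduct_table()
    .nap_cache$adduct_info <- list(
      delta = setNames(tab$delta, tab$name),
      class = setNames(tab$class, tab$name),
      symbol = setNames(tab$symbol, tab$name)
    )
  }
  .nap_cache$adduct_info
}

#' Mass delta added by an adduct species
#'
#' The default (hydroquinone, for the quinones) deltas reproduce the
#' nominal shifts +144.06 (NO), +178.06 (NDO) and +158.04 Da (both NQs).
#' The oxidized `"quinone"` redox variant, two hydrogens lighter, is only
#' defined for the naphthoquinones.
#'
#' @param name Adduct name: `"NO"`, `"NDO"`, `"NQ12"`, or `"NQ14"`.
#' @param variant `"hydroquinone"` (default) or `"quinone"`.
#' @return Monoisotopic mass delta in Da.
#' @examples
#' adduct_delta("NO")
#' adduct_delta("NQ12", variant = "quinone")
#' @export
adduct_delta <- function(name, variant = c("hydroquinone", "quinone")) {
  variant <- match.arg(variant)
  info <- .adduct_info()
  if (!name %in% names(info$delta)) .adduct_row(name)  # error with choices
  if (variant == "quinone") {
    if (info$class[[name]] != "quinone") {
      abort(sprintf("quinone redox variant is not defined for the epoxide '%s'", name))
    }
    return(info$delta[[name]] - 2 * .h_mass)
  }
  info$delta[[name]]
}

#' The six bundled model peptides
#'
#' @return A tibble with columns `peptide` (sequence, `-NH2` marking the
#'   amide), `c_terminus`, `nucleophile`, `note`.
#' @export
model_peptides <- function() {
  if (is.null(.nap_cache$peptides)) {
    .nap_cache$peptides <- readr::read_tsv(
      .extdata("model_peptides.tsv"), show_col_types = FALSE, progress = FALSE)
  }
  .nap_cache$peptides
}

# Site classes ----------------------------------------------------------------

# Map a site index (0 = N-terminus, i = residue i) to its nucleophile class.
.site_class <- function(peptide, site) {
  p <- as_peptide(peptide)
  vapply(site, function(s) {
    if (s == 0) return("N_terminus")
    switch(p$residues[s],
           C = "Cys_sidechain", K = "Lys_sidechain", H = "His_sidechain",
           "other")
  }, character(1))
}

#' Candidate adduction sites of a peptide
#'
#' Sites are numbered 0 for the N-terminal amine and 1..L for residue side
#' chains; only Cys, Lys and His side chains (and the N-terminus) are
#' nucleophilic targets of the bundled metabolites.
#'
#' @inheritParams peptide_mass
#' @param adduct Adduct name (see [adduct_table()]).
#' @return Integer vector of allowed site indices, ascending.
#' @examples
#' allowed_sites("GRGDSPC", "NO")    # N-terminus and Cys7
#' @export
allowed_sites <- function(peptide, adduct) {
  p <- as_peptide(peptide)
  targets <- .adduct_row(adduct)$targets[[1]]
  sites <- 0:p$length
  cls <- .site_class(p, sites)
  sites[cls %in% targets]
}

#' Format a site index as a residue label
#'
#' @inheritParams allowed_sites
#' @param site Integer site indices (0 = N-terminus).
#' @return Character labels such as `"Nterm"` or `"C7"`.
#' @export
site_label <- function(peptide, site) {
  p <- as_peptide(peptide)
  vapply(site, function(s) {
    if (s == 0) "Nterm" else paste0(p$residues[s], s)
  }, character(1))
}
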