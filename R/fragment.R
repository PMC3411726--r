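# Adduct placements and theoretical singly-protonated precursor and b/y
# fragment ions, including the neutral-loss species seen for these adducts.

#' Place adducts on a peptide
#'
#' A placement assigns `n` copies of one adduct species to nucleophilic
#' sites of a peptide. Sites are 0 (N-terminal amine) or 1..L (residue side
#' chains). A site may carry at most two adducts, and more than one only
#' for a naphthoquinone on cysteine (the only diadducted single residue
#' observed for these metabolites).
#'
#' @inheritParams allowed_sites
#' @param sites Integer vector of site indices (may repeat); empty for the
#'   unmodified peptide.
#' @param variant Redox variant passed to [adduct_delta()].
#' @return An object of class `"nap_placement"`.
#' @examples
#' placement("GRGDSPC", "NO", sites = 7)
#' placement("GRGDSPC", "NQ12", sites = c(7, 7))
#' @export
placement <- function(peptide, adduct, sites = integer(0),
                      variant = c("hydroquinone", "quinone")) {
  p <- as_peptide(peptide)
  variant <- match.arg(variant)
  row <- .adduct_row(adduct)
  sites <- sort(as.integer(sites))
  if (length(sites) > 3) abort("at most three adducts per peptide are modeled")
  if (length(sites) > 0) {
    ok <- allowed_sites(p, adduct)
    bad <- setdiff(sites, ok)
    if (length(bad) > 0) {
      abort(sprintf("site %s is not an allowed %s target on %s",
                    paste(bad, collapse = ", "), adduct, p$sequence))
    }
    mult <- table(sites)
    if (any(mult > 2)) abort("at most two adducts per site")
    multi <- as.integer(names(mult)[mult > 1])
    if (length(multi) > 0) {
      cls <- .site_class(p, multi)
      if (row$class != "quinone" || any(cls != "Cys_sidechain")) {
        abort("double adduction of one site is only modeled for naphthoquinones on cysteine")
      }
    }
  }
  structure(
    list(peptide = p, adduct = row$name, sites = sites, n = length(sites),
         variant = variant, delta = adduct_delta(row$name, variant),
         symbol = row$symbol),
    class = "nap_placement"
  )
}

#' @export
print.nap_placement <- function(x, ...) {
  where <- if (x$n == 0) "unmodified" else
    paste(site_label(x$peptide, x$sites), collapse = ", ")
  cat(sprintf("<placement> %s + %d x %s (%s)\n",
              x$peptide$sequence, x$n, x$adduct, where))
  invisible(x)
}

# number of placement adducts carried by b_i (sites 0..i) and y_j
# (sites L-j+1..L; the N-terminal site never travels with y ions)
.b_carried <- function(sites, i) sum(sites <= i)
.y_carried <- function(sites, j, L) sum(sites >= L - j + 1 & sites > 0)

# Fast ion-set core shared by the public API, the localizer and the
# simulator; returns plain vectors to keep tight loops cheap.
# `loss` tokens: "" (none), "H2O" (water loss), "+H2O" (water gain,
# satellites only), "X"/"2X"/"3X" (adduct-moiety losses), "H2O+X", ...
.ion_core <- function(pl, water_satellites = FALSE) {
  p <- pl$peptide
  L <- p$length
  rm <- unname(.residue_mass_table[p$residues])
  terminus <- if (p$c_terminus == "amide") .ammonia_mass else .water_mass
  delta <- pl$delta
  sites <- pl$sites
  n <- pl$n

  idx <- seq_len(L - 1)
  bcar <- vapply(idx, function(i) .b_carried(sites, i), numeric(1))
  ycar <- vapply(idx, function(j) .y_carried(sites, j, L), numeric(1))
  b_mz <- cumsum(rm)[idx] + bcar * delta + proton_mass
  y_mz <- cumsum(rev(rm))[idx] + terminus + ycar * delta + proton_mass

  series <- c(rep("b", L - 1), rep("y", L - 1))
  index <- c(idx, idx)
  carried <- c(bcar, ycar)
  loss <- rep("", 2 * (L - 1))
  mz <- c(b_mz, y_mz)

  if (isTRUE(water_satellites)) {
    series <- rep(series, 3)
    index <- rep(index, 3)
    carried <- rep(carried, 3)
    loss <- c(loss, rep("H2O", 2 * (L - 1)), rep("+H2O", 2 * (L - 1)))
    mz <- c(mz, mz - .water_mass, mz + .water_mass)
  }

  M <- sum(rm) + terminus + n * delta
  for (x in 0:n) {
    for (w in 0:1) {
      series <- c(series, "precursor")
      index <- c(index, NA_integer_)
      carried <- c(carried, n - x)
      parts <- c(if (w == 1) "H2O", if (x > 0) paste0(if (x > 1) x, "X"))
      loss <- c(loss, paste(parts, collapse = "+"))
      mz <- c(mz, M - x * delta - w * .water_mass + proton_mass)
    }
  }

  frag <- series != "precursor"
  label <- character(length(series))
  suffix <- ifelse(loss[frag] == "H2O", " - H2O",
                   ifelse(loss[frag] == "+H2O", " + H2O", ""))
  label[frag] <- paste0(series[frag], index[frag],
                        strrep(pl$symbol, carried[frag]), suffix)
  ploss <- loss[!frag]
  psuffix <- ifelse(ploss == "", "",
                    paste0(" - ", gsub("+", " - ", ploss, fixed = TRUE)))
  label[!frag] <- paste0("[M+H]+", psuffix)

  ord <- order(mz, series, index)
  list(label = label[ord], series = series[ord], index = index[ord],
       adducts_carried = carried[ord], loss = loss[ord], mz = mz[ord])
}

#' Theoretical ion set of a placement
#'
#' Generates all singly-protonated b and y fragments (indices 1..L-1), the
#' precursor, the dehydrated precursor, and precursor species having lost
#' one or more adduct moieties (`X`). With `water_satellites = TRUE`,
#' water-gain/-loss satellites of every fragment are added; these
#' non-canonical species are occasionally observed (e.g. dehydrated
#' adducted b ions) but are off by default.
#'
#' @param pl A placement from [placement()].
#' @param water_satellites Add `+/- H2O` fragment satellites?
#' @return A tibble sorted by `mz` with columns `label`, `series`, `index`,
#'   `adducts_carried`, `loss`, `mz`.
#' @examples
#' theoretical_ions(placement("GRGDSPC", "NO", sites = 7))
#' @export
theoretical_ions <- function(pl, water_satellites = FALSE) {
  stopifnot(inherits(pl, "nap_placement"))
  tibble::as_tibble(.ion_core(pl, water_satellites))
}

#' Single fragment and precursor m/z values
#'
#' `b_ion_mz()` and `y_ion_mz()` return the singly-protonated fragment m/z
#' for one index, carrying whatever placement adducts fall in the fragment
#' span (the N-terminal site never appears on y ions). `precursor_mz()`
#' accepts neutral losses: at most one `"H2O"` and at most `n` `"X"`
#' (adduct moiety) tokens.
#'
#' @param pl A placement.
#' @param i,j Fragment index, 1..L-1.
#' @param loss Character vector of loss tokens, e.g. `c("H2O", "X")`.
#' @return m/z in Da.
#' @examples
#' b_ion_mz(placement("DASFHSWG-NH2", "NO", sites = 5), 5)
#' precursor_mz(placement("DYKDDDDK", "NO", sites = 0), loss = "H2O")
#' @export
b_ion_mz <- function(pl, i) {
  stopifnot(inherits(pl, "nap_placement"))
  L <- pl$peptide$length
  if (any(i < 1 | i > L - 1)) abort(sprintf("b-ion index must be in 1..%d", L - 1))
  rm <- unname(.residue_mass_table[pl$peptide$residues])
  vapply(i, function(ii) {
    sum(rm[seq_len(ii)]) + .b_carried(pl$sites, ii) * pl$delta + proton_mass
  }, numeric(1))
}

#' @rdname b_ion_mz
#' @export
y_ion_mz <- function(pl, j) {
  stopifnot(inherits(pl, "nap_placement"))
  L <- pl$peptide$length
  if (any(j < 1 | j > L - 1)) abort(sprintf("y-ion index must be in 1..%d", L - 1))
  rm <- unname(.residue_mass_table[pl$peptide$residues])
  terminus <- if (pl$peptide$c_terminus == "amide") .ammonia_mass else .water_mass
  vapply(j, function(jj) {
    sum(rm[(L - jj + 1):L]) + terminus +
      .y_carried(pl$sites, jj, L) * pl$delta + proton_mass
  }, numeric(1))
}

#' @rdname b_ion_mz
#' @export
precursor_mz <- function(pl, loss = character()) {
  stopifnot(inherits(pl, "nap_placement"))
  n_h2o <- sum(loss == "H2O")
  n_x <- sum(loss == "X")
  if (length(loss) != n_h2o + n_x) abort("losses must be 'H2O' or 'X' tokens")
  if (n_h2o > 1) abort("at most one water loss is modeled on the precursor")
  if (n_x > pl$n) {
    abort(sprintf("cannot lose %d adduct moieties from a %d-adduct placement",
                  n_x, pl$n))
  }
  peptide_mass(pl$peptide) + pl$n * pl$delta - n_x * pl$delta -
    n_h2o * .water_mass + proton_mass
}

# All multisets of n sites over `sites` (ascending), honoring the
# multiplicity rule; deterministic lexicographic order.
.enumerate_sites <- function(sites, n, cys_ok) {
  if (n == 0) return(list(integer(0)))
  if (length(sites) == 0) return(list())
  recurse <- function(prefix, pool_start) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (k in seq(pool_start, length(sites))) {
      cand <- c(prefix, sites[k])
      mult <- sum(cand == sites[k])
      if (mult > 2) next
      if (mult > 1 && !(sites[k] %in% cys_ok)) next
      out <- c(out, recurse(cand, k))
    }
    out
  }
  recurse(integer(0), 1)
}

#' Enumerate all adduct placements
#'
#' All distinct assignments of `n` copies of one adduct over the allowed
#' sites of a peptide, in lexicographic site order. `n = 0` yields the
#' single unmodified placement; a peptide without allowed sites yields an
#' empty result for `n >= 1`.
#'
#' @inheritParams allowed_sites
#' @param n Number of adducts, 0..3.
#' @param variant Redox variant passed to [placement()].
#' @return A tibble with columns `sites` (list of integer vectors), `label`
#'   and `placement` (list of placements).
#' @examples
#' enumerate_placements("DYKDDDDK", "NDO", 1)
#' @export
enumerate_placements <- function(peptide, adduct, n,
                                 variant = c("hydroquinone", "quinone")) {
  p <- as_peptide(peptide)
  variant <- match.arg(variant)
  stopifnot(n %in% 0:3)
  key <- paste("enum", p$sequence, p$c_terminus, adduct, n, variant, sep = "|")
  if (!is.null(.nap_cache[[key]])) return(.nap_cache[[key]])
  ok <- allowed_sites(p, adduct)
  cys_ok <- if (.adduct_row(adduct)$class == "quinone") {
    ok[.site_class(p, ok) == "Cys_sidechain"]
  } else integer(0)
  site_sets <- .enumerate_sites(ok, n, cys_ok)
  pls <- lapply(site_sets, function(s) placement(p, adduct, s, variant))
  out <- tibble::tibble(
    sites = site_sets,
    label = vapply(site_sets, function(s) {
      if (length(s) == 0) "unmodified" else
        paste(site_label(p, s), collapse = "+")
    }, character(1)),
    placement = pls
  )
  .nap_cache[[key]] <- out
  out
}
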