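# Residue-level adduct site localization from annotated fragment evidence.
#
# The inference is combinatorial: a candidate placement is consistent with
# an annotated b_i ion iff the number of placement adducts on sites {0..i}
# equals the adduct count the annotation carries, and with a y_j ion iff
# the adducts on sites {L-j+1..L} match (the N-terminal site never travels
# with y ions). Unmodified fragments are constraints too ("strict" mode);
# "lenient" mode ignores them, since unmodified fragments can also arise
# from a co-eluting unadducted or positional-isomer species.

#' Site-class reactivity ranking
#'
#' Orders the four nucleophilic site classes by expected reactivity for
#' each metabolite class, used to break ties when fragment evidence leaves
#' several candidate sites. Quinones are soft electrophiles that favor the
#' cysteine thiolate, then amines; the harder epoxides favor Cys, then His.
#' The ranking is data, not code: supply your own table to override.
#'
#' @return A tibble with columns `adduct_class`, `rank`, `site_class`.
#' @export
reactivity_ranking <- function() {
  if (is.null(.nap_cache$ranking)) {
    .nap_cache$ranking <- readr::read_tsv(
      .extdata("reactivity_ranking.tsv"), show_col_types = FALSE,
      progress = FALSE)
  }
  .nap_cache$ranking
}

# b/y fragment rows of an evidence/annotation table
.fragment_evidence <- function(evidence) {
  stopifnot(is.data.frame(evidence))
  need <- c("series", "index", "adducts_carried")
  missing <- setdiff(need, names(evidence))
  if (length(missing) > 0) {
    abort(sprintf("evidence lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  evidence[evidence$series %in% c("b", "y"), need, drop = FALSE]
}

#' Placements consistent with fragment evidence
#'
#' Filters the full placement enumeration to those whose per-fragment
#' adduct counts agree with every annotated b/y ion (strict mode) or with
#' the adduct-carrying ions only (lenient mode). Contradictory evidence
#' yields an empty result, never an error.
#'
#' @inheritParams enumerate_placements
#' @param evidence A data frame of fragment annotations with columns
#'   `series` ("b"/"y"; other series are ignored), `index` and
#'   `adducts_carried` — e.g. the output of [annotate_peaks()].
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return The [enumerate_placements()] tibble restricted to consistent
#'   placements.
#' @export
feasible_sites <- function(peptide, adduct, n, evidence,
                           mode = c("strict", "lenient"),
                           variant = c("hydroquinone", "quinone")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  p <- as_peptide(peptide)
  ev <- .fragment_evidence(evidence)
  if (mode == "lenient") ev <- ev[ev$adducts_carried > 0, , drop = FALSE]
  all_pl <- enumerate_placements(p, adduct, n, variant)
  if (nrow(ev) == 0 || nrow(all_pl) == 0) return(all_pl)
  L <- p$length
  ok <- vapply(all_pl$sites, function(sites) {
    carried <- ifelse(
      ev$series == "b",
      vapply(ev$index, function(i) .b_carried(sites, i), numeric(1)),
      vapply(ev$index, function(j) .y_carried(sites, j, L), numeric(1))
    )
    all(carried == ev$adducts_carried)
  }, logical(1))
  all_pl[ok, , drop = FALSE]
}

#' Localize the adduction site(s)
#'
#' Runs [feasible_sites()] and summarizes the outcome. A single surviving
#' placement is `unambiguous`. Several candidate sites are resolved by the
#' reactivity ranking when one site class clearly outranks the rest
#' (`interval_resolved_by_reactivity`); rank ties stay `undetermined`.
#' Contradictory (empty) evidence is `undetermined`, with the reported
#' interval taken from the lenient feasible set. A site is never assigned
#' without at least one adduct-carrying b/y annotation: precursor-level
#' adduct evidence proves adduction but not its position.
#'
#' @inheritParams feasible_sites
#' @param ranking A reactivity ranking table ([reactivity_ranking()]).
#' @return An object of class `"nap_localization"`: a list with elements
#'   `peptide`, `adduct`, `n`, `mode`, `feasible` (tibble), `assigned`
#'   (site label or `"undetermined"`), `assigned_site` (integer or `NA`),
#'   `interval` (`c(lo, hi)` site range or `NULL`), `confidence`, `note`
#'   and `evidence`.
#' @examples
#' ev <- evidence_ions("GRGDSPC", "NO",
#'                     series = c("b", "b", "y", "y"),
#'                     index = c(4, 5, 3, 4),
#'                     adducts_carried = c(0, 0, 1, 1))
#' localize("GRGDSPC", "NO", n = 1, evidence = ev)
#' @export
localize <- function(peptide, adduct, n, evidence,
                     mode = c("strict", "lenient"),
                     ranking = reactivity_ranking(),
                     variant = c("hydroquinone", "quinone")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  p <- as_peptide(peptide)
  feas <- feasible_sites(p, adduct, n, evidence, mode, variant)
  ev_frag <- .fragment_evidence(evidence)
  has_adducted <- nrow(ev_frag[ev_frag$adducts_carried > 0, ]) > 0

  res <- list(peptide = p, adduct = adduct, n = n, mode = mode,
              feasible = feas, evidence = tibble::as_tibble(evidence),
              assigned = "undetermined", assigned_site = NA_integer_,
              interval = NULL, confidence = "undetermined", note = "")
  class(res) <- "nap_localization"

  interval_of <- function(pl_tbl) {
    if (n != 1 || nrow(pl_tbl) == 0) return(NULL)
    s <- sort(unique(unlist(pl_tbl$sites)))
    c(min(s), max(s))
  }

  if (n == 0) {
    res$note <- "no adducts to localize (n = 0)"
    return(res)
  }
  if (!has_adducted) {
    res$interval <- interval_of(feas)
    res$note <- "no adduct-carrying fragment evidence; site cannot be called"
    return(res)
  }
  if (nrow(feas) == 0) {
    lenient <- feasible_sites(p, adduct, n, evidence, "lenient", variant)
    res$interval <- interval_of(lenient)
    res$note <- "evidence is self-contradictory under strict counting; interval from adducted ions only"
    return(res)
  }
  res$interval <- interval_of(feas)
  if (nrow(feas) == 1) {
    res$confidence <- "unambiguous"
    if (n == 1) {
      res$assigned_site <- feas$sites[[1]][1]
      res$assigned <- site_label(p, res$assigned_site)
    } else {
      res$assigned <- feas$label[1]
    }
    return(res)
  }
  if (n > 1) {
    res$note <- "several multi-adduct placements remain feasible"
    return(res)
  }
  # several single-adduct candidates: try the reactivity ranking
  sites <- vapply(feas$sites, `[`, numeric(1), 1)
  cls <- .site_class(p, sites)
  acl <- .adduct_row(adduct)$class
  rk <- ranking[ranking$adduct_class == acl, ]
  ranks <- rk$rank[match(cls, rk$site_class)]
  if (anyNA(ranks)) {
    res$note <- "candidate site class missing from the reactivity ranking"
    return(res)
  }
  top <- which(ranks == min(ranks))
  if (length(top) == 1) {
    res$confidence <- "interval_resolved_by_reactivity"
    res$assigned_site <- sites[top]
    res$assigned <- site_label(p, res$assigned_site)
  } else {
    res$note <- "top-ranked site class is not unique among candidates"
  }
  res
}

#' @export
print.nap_localization <- function(x, ...) {
  cat(sprintf("<localization> %s + %d x %s (%s mode)\n",
              x$peptide$sequence, x$n, x$adduct, x$mode))
  cat(sprintf("  assigned:   %s (%s)\n", x$assigned, x$confidence))
  if (!is.null(x$interval)) {
    cat(sprintf("  interval:   sites %d..%d\n", x$interval[1], x$interval[2]))
  }
  cat(sprintf("  feasible:   %s\n",
              if (nrow(x$feasible) == 0) "(none)" else
                paste(x$feasible$label, collapse = ", ")))
  if (nzchar(x$note)) cat(sprintf("  note:       %s\n", x$note))
  invisible(x)
}

#' @rdname localize
#' @param x A `"nap_localization"` object.
#' @param ... Unused.
#' @method tidy nap_localization
#' @export
tidy.nap_localization <- function(x, ...) {
  tibble::tibble(
    peptide = x$peptide$sequence,
    c_terminus = x$peptide$c_terminus,
    adduct = x$adduct,
    n_adducts = x$n,
    mode = x$mode,
    n_feasible = nrow(x$feasible),
    assigned = x$assigned,
    assigned_site = x$assigned_site,
    interval_lo = if (is.null(x$interval)) NA_integer_ else x$interval[1],
    interval_hi = if (is.null(x$interval)) NA_integer_ else x$interval[2],
    confidence = x$confidence,
    note = x$note
  )
}

#' Build an evidence table of theoretical fragment annotations
#'
#' Convenience constructor for localization evidence: computes the
#' theoretical m/z implied by each (series, index, adduct count) claim,
#' mirroring the columns [annotate_peaks()] produces.
#'
#' @inheritParams allowed_sites
#' @param series,index,adducts_carried Parallel vectors describing the ions.
#' @param loss Loss token per ion (`""`, `"H2O"`, or `"+H2O"`).
#' @param variant Redox variant for the adduct delta.
#' @return A tibble with columns `series`, `index`, `adducts_carried`,
#'   `loss`, `mz`.
#' @export
evidence_ions <- function(peptide, adduct, series, index, adducts_carried,
                          loss = "", variant = c("hydroquinone", "quinone")) {
  variant <- match.arg(variant)
  p <- as_peptide(peptide)
  k <- length(series)
  index <- rep_len(index, k)
  adducts_carried <- rep_len(adducts_carried, k)
  loss <- rep_len(loss, k)
  if (any(index < 1 | index > p$length - 1)) {
    abort(sprintf("fragment index must be in 1..%d", p$length - 1))
  }
  delta <- adduct_delta(adduct, variant)
  rm <- unname(.residue_mass_table[p$residues])
  terminus <- if (p$c_terminus == "amide") .ammonia_mass else .water_mass
  base <- ifelse(series == "b",
                 cumsum(rm)[index] + proton_mass,
                 cumsum(rev(rm))[index] + terminus + proton_mass)
  loss_mass <- ifelse(loss == "H2O", .water_mass,
                      ifelse(loss == "+H2O", -.water_mass, 0))
  tibble::new_tibble(list(
    series = as.character(series), index = as.integer(index),
    adducts_carried = as.integer(adducts_carried), loss = as.character(loss),
    mz = as.numeric(base + adducts_carried * delta - loss_mass)
  ), nrow = k)
}

#' Brute-force localization oracle
#'
#' An independent check of [feasible_sites()]: placements are enumerated
#' from scratch, each placement's full ion set is regenerated, and an
#' evidence row is deemed consistent when the placement's ion of the same
#' series and index has the same m/z as the evidence claims (to 1e-6 Da).
#' In lenient mode only evidence rows whose m/z differs from the
#' unmodified fragment (i.e. adduct-shifted claims) constrain. Intended
#' for short peptides (L <= 12).
#'
#' @inheritParams feasible_sites
#' @param evidence Must additionally carry the claimed `mz` per row (as
#'   [evidence_ions()] and [annotate_peaks()] provide; for annotations the
#'   theoretical `mz` column is used).
#' @return A tibble like [enumerate_placements()], restricted to
#'   consistent placements.
#' @export
oracle_feasible_sites <- function(peptide, adduct, n, evidence,
                                  mode = c("strict", "lenient"),
                                  variant = c("hydroquinone", "quinone")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  p <- as_peptide(peptide)
  if (p$length > 12) abort("oracle is restricted to peptides of length <= 12")
  stopifnot(is.data.frame(evidence))
  ev <- evidence[evidence$series %in% c("b", "y"), , drop = FALSE]
  if (!"mz" %in% names(ev)) abort("oracle evidence requires an mz column")

  pre <- .oracle_precompute(p, adduct, n, variant)
  L <- p$length
  ev_key <- ifelse(ev$series == "b", ev$index, L + ev$index)

  # rows matching the unmodified fragment are not adduct-shifted claims and
  # do not constrain in lenient mode
  unshifted <- abs(pre$bare_mz[ev_key] - ev$mz) < 1e-6
  consistent <- vapply(pre$ion_mz, function(mz_by_key) {
    hit <- abs(mz_by_key[ev_key] - ev$mz) < 1e-6
    if (mode == "lenient") hit <- hit | unshifted
    all(hit)
  }, logical(1))

  pre$tbl[consistent, , drop = FALSE]
}

# Independent enumeration and per-placement plain-fragment m/z tables for
# the oracle, computed once per (peptide, adduct, n, variant). Fragment
# m/z values are indexed by key b_i -> i, y_j -> L + j.
.oracle_precompute <- function(p, adduct, n, variant) {
  key <- paste("oracle", p$sequence, p$c_terminus, adduct, n, variant, sep = "|")
  if (!is.null(.nap_cache[[key]])) return(.nap_cache[[key]])
  ok <- allowed_sites(p, adduct)
  quin <- .adduct_row(adduct)$class == "quinone"
  if (n == 0) {
    site_sets <- list(integer(0))
  } else if (length(ok) == 0) {
    site_sets <- list()
  } else {
    grids <- expand.grid(rep(list(ok), n))
    sets <- unique(lapply(seq_len(nrow(grids)),
                          function(r) sort(as.integer(grids[r, ]))))
    keep <- vapply(sets, function(s) {
      tab <- table(s)
      if (any(tab > 2)) return(FALSE)
      doubled <- as.integer(names(tab)[tab > 1])
      length(doubled) == 0 ||
        (quin && all(.site_class(p, doubled) == "Cys_sidechain"))
    }, logical(1))
    site_sets <- sets[keep]
    ord <- order(vapply(site_sets, function(s) {
      paste(sprintf("%03d", s), collapse = "")
    }, character(1)))
    site_sets <- site_sets[ord]
  }
  frag_mz <- function(sites) {
    ions <- theoretical_ions(placement(p, adduct, sites, variant))
    ions <- ions[ions$series %in% c("b", "y") & ions$loss == "", ]
    k <- ifelse(ions$series == "b", ions$index, p$length + ions$index)
    out <- rep(NA_real_, 2 * p$length)
    out[k] <- ions$mz
    out
  }
  pre <- list(
    site_sets = site_sets,
    ion_mz = lapply(site_sets, frag_mz),
    bare_mz = frag_mz(integer(0)),
    tbl = tibble::tibble(
      sites = site_sets,
      label = vapply(site_sets, function(s) {
        if (length(s) == 0) "unmodified" else
          paste(site_label(p, s), collapse = "+")
      }, character(1)),
      placement = lapply(site_sets, function(s) placement(p, adduct, s, variant))
    )
  )
  .nap_cache[[key]] <- pre
  pre
}
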