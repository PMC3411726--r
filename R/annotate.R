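# Matching observed peak lists to theoretical ions within a mass tolerance.

#' Signed parts-per-million mass error
#'
#' @param observed,theoretical Observed and theoretical m/z (Da); vectorized.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(1000.0010, 1000)
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    abort("theoretical m/z must be positive")
  }
  (observed - theoretical) / theoretical * 1e6
}

#' Annotate observed peaks with theoretical ions
#'
#' Greedy one-to-one assignment: candidate (peak, ion) pairs within the
#' tolerance are ranked by ascending absolute ppm error (ties broken by
#' lower theoretical, then observed, m/z) and accepted while both partners
#' are unassigned. Each ion matches at most one peak and vice versa;
#' unmatched peaks and ions are omitted. The result does not depend on the
#' input peak order, and intensity is carried through but never used.
#'
#' @param peaks A data frame with columns `mz` and (optionally) `intensity`.
#' @param ions A data frame of theoretical ions with at least `mz`
#'   (typically from [theoretical_ions()]); all its columns are carried
#'   through.
#' @param tol_ppm Matching tolerance in ppm (default 10, comfortably above
#'   the few-ppm accuracy of a 30,000-resolving-power Orbitrap).
#' @param tol_da Optional absolute tolerance in Da; overrides `tol_ppm`
#'   when given (useful when matching values printed at two decimals).
#' @return A tibble with the ion columns plus `observed_mz`, `intensity`,
#'   `ppm` and `adducted` (`adducts_carried > 0`), sorted by ion `mz`.
#' @export
annotate_peaks <- function(peaks, ions, tol_ppm = 10, tol_da = NULL) {
  stopifnot(is.data.frame(peaks), is.data.frame(ions))
  if (is.null(tol_da)) {
    if (!is.numeric(tol_ppm) || tol_ppm <= 0) abort("tol_ppm must be positive")
  } else if (!is.numeric(tol_da) || tol_da <= 0) {
    abort("tol_da must be positive")
  }
  empty <- dplyr::mutate(ions[0, , drop = FALSE],
                         observed_mz = numeric(0), intensity = numeric(0),
                         ppm = numeric(0), adducted = logical(0))
  if (nrow(peaks) == 0 || nrow(ions) == 0) return(tibble::as_tibble(empty))

  obs <- peaks$mz
  inten <- if ("intensity" %in% names(peaks)) peaks$intensity else
    rep(NA_real_, length(obs))
  # canonical sort so the greedy pass is order-invariant
  o <- order(obs, inten)
  obs <- obs[o]
  inten <- inten[o]
  theo <- ions$mz

  pair_obs <- rep(seq_along(obs), times = length(theo))
  pair_ion <- rep(seq_along(theo), each = length(obs))
  diff <- obs[pair_obs] - theo[pair_ion]
  keep <- if (is.null(tol_da)) {
    abs(diff) / theo[pair_ion] * 1e6 <= tol_ppm
  } else {
    abs(diff) <= tol_da
  }
  pair_obs <- pair_obs[keep]
  pair_ion <- pair_ion[keep]
  if (length(pair_obs) == 0) return(tibble::as_tibble(empty))

  ppm <- (obs[pair_obs] - theo[pair_ion]) / theo[pair_ion] * 1e6
  ord <- order(abs(ppm), theo[pair_ion], obs[pair_obs])
  used_obs <- logical(length(obs))
  used_ion <- logical(length(theo))
  take <- logical(length(ord))
  for (k in ord) {
    if (!used_obs[pair_obs[k]] && !used_ion[pair_ion[k]]) {
      used_obs[pair_obs[k]] <- TRUE
      used_ion[pair_ion[k]] <- TRUE
      take[k] <- TRUE
    }
  }
  sel_ion <- pair_ion[take]
  sel_obs <- pair_obs[take]
  out <- ions[sel_ion, , drop = FALSE]
  out$observed_mz <- obs[sel_obs]
  out$intensity <- inten[sel_obs]
  out$ppm <- ppm[take]
  out$adducted <- if ("adducts_carried" %in% names(out)) {
    out$adducts_carried > 0
  } else NA
  tibble::as_tibble(out[order(out$mz), , drop = FALSE])
}
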