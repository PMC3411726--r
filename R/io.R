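# Peak-list readers/writers (MGF and TSV), time-course reader, and the
# predict -> annotate -> localize pipeline.

#' Read a peak list
#'
#' Reads a centroided peak list from a Mascot generic format (MGF) file
#' (first `BEGIN IONS` block; `PEPMASS` and `TITLE` are attached as
#' attributes) or from a tab-separated file with a header row and columns
#' `mz` and `intensity`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mgf"`, or `"tsv"`.
#' @return A tibble with columns `mz`, `intensity`, sorted by m/z, with
#'   attributes `pepmass` and `title` for MGF input.
#' @export
read_peaklist <- function(path, format = c("auto", "mgf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "tsv"
  }
  if (format == "mgf") {
    spectra <- read_mgf(path)
    if (length(spectra) == 0) abort(sprintf("no spectrum block in %s", path))
    if (length(spectra) > 1) {
      warn(sprintf("%s holds %d spectra; returning the first", path,
                   length(spectra)))
    }
    return(spectra[[1]])
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("mz", "intensity"), names(tab))
  if (length(missing) > 0) {
    abort(sprintf("TSV peak list lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tab <- tab[order(tab$mz), c("mz", "intensity")]
  tibble::as_tibble(tab)
}

#' Read all spectra from an MGF file
#'
#' @inheritParams read_peaklist
#' @return A list of peak-list tibbles, each with `pepmass` and `title`
#'   attributes.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  mz <- intensity <- numeric(0)
  pepmass <- NA_real_
  title <- NA_character_
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) abort(sprintf("line %d: nested BEGIN IONS", ln))
      in_block <- TRUE
      mz <- intensity <- numeric(0)
      pepmass <- NA_real_
      title <- NA_character_
    } else if (line == "END IONS") {
      if (!in_block) abort(sprintf("line %d: END IONS without BEGIN IONS", ln))
      in_block <- FALSE
      ord <- order(mz)
      pk <- tibble::tibble(mz = mz[ord], intensity = intensity[ord])
      attr(pk, "pepmass") <- pepmass
      attr(pk, "title") <- title
      spectra[[length(spectra) + 1]] <- pk
    } else if (!in_block) {
      next  # header junk outside blocks is tolerated
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "PEPMASS") {
        pepmass <- suppressWarnings(as.numeric(strsplit(val, "[ \t]+")[[1]][1]))
        if (is.na(pepmass)) abort(sprintf("line %d: unparseable PEPMASS", ln))
      } else if (key == "TITLE") {
        title <- val
      }
    } else {
      fields <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
      if (length(fields) < 1 || anyNA(fields[1:min(2, length(fields))])) {
        abort(sprintf("line %d: malformed peak line '%s'", ln, line))
      }
      mz <- c(mz, fields[1])
      intensity <- c(intensity, if (length(fields) >= 2) fields[2] else NA_real_)
    }
  }
  if (in_block) abort("unterminated BEGIN IONS block")
  spectra
}

#' Write a peak list as MGF
#'
#' @param peaks A data frame with columns `mz` and `intensity`.
#' @param path Output path.
#' @param pepmass Optional precursor m/z for the PEPMASS header.
#' @param title Optional TITLE header.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(peaks, path, pepmass = NULL, title = NULL) {
  stopifnot(is.data.frame(peaks))
  pepmass <- pepmass %||% attr(peaks, "pepmass")
  title <- title %||% attr(peaks, "title")
  lines <- c(
    "BEGIN IONS",
    if (!is.null(title) && !is.na(title)) paste0("TITLE=", title),
    if (!is.null(pepmass) && !is.na(pepmass)) sprintf("PEPMASS=%.6f", pepmass),
    "CHARGE=1+",
    sprintf("%.6f %.6g", peaks$mz, peaks$intensity),
    "END IONS"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIM time course from TSV
#'
#' @param path Tab-separated file with header columns `time_min`, `area`
#'   and optionally `label`.
#' @return A tibble.
#' @export
read_timecourse <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("time_min", "area"), names(tab))
  if (length(missing) > 0) {
    abort(sprintf("time-course TSV lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(tab)
}

#' Candidate ion table for an n-adduct spectrum
#'
#' The union of the theoretical ion sets over every enumerated placement
#' of `n` adducts — the hypothesis set an observed spectrum attributed to
#' an n-adduct precursor is matched against (fragment adduct counts range
#' over every count achievable in the fragment's span).
#'
#' @inheritParams enumerate_placements
#' @param water_satellites Passed to [theoretical_ions()].
#' @return A tibble like [theoretical_ions()], distinct on (series, index,
#'   adducts_carried, loss), sorted by m/z.
#' @export
candidate_ions <- function(peptide, adduct, n,
                           variant = c("hydroquinone", "quinone"),
                           water_satellites = FALSE) {
  variant <- match.arg(variant)
  p <- as_peptide(peptide)
  key <- paste("cand", p$sequence, p$c_terminus, adduct, n, variant,
               water_satellites, sep = "|")
  if (!is.null(.nap_cache[[key]])) return(.nap_cache[[key]])
  pls <- enumerate_placements(p, adduct, n, variant)$placement
  if (length(pls) == 0) {
    pls <- list(placement(peptide, adduct, integer(0), variant))
  }
  ions <- dplyr::bind_rows(lapply(pls, theoretical_ions,
                                  water_satellites = water_satellites))
  ions <- dplyr::distinct(ions, .data$series, .data$index,
                          .data$adducts_carried, .data$loss,
                          .keep_all = TRUE)
  out <- ions[order(ions$mz), , drop = FALSE]
  .nap_cache[[key]] <- out
  out
}

#' Run the predict -> annotate -> localize pipeline
#'
#' Matches an observed peak list against the candidate ions of an n-adduct
#' precursor and localizes the adduction site(s) from the annotated
#' fragments.
#'
#' @param peaks A peak list (tibble with `mz`, `intensity`), e.g. from
#'   [read_peaklist()] or [simulate_spectrum()].
#' @inheritParams candidate_ions
#' @inheritParams annotate_peaks
#' @inheritParams localize
#' @return An object of class `"nap_report"`: a list with `peptide`,
#'   `adduct`, `n`, `params`, `ions` (candidate table), `annotations`,
#'   `localization`, and `flags` (character; e.g. `"no adduct evidence"`).
#' @examples
#' sim <- simulate_spectrum(placement("GRGDSPC", "NDO", 7),
#'                          ppm_sigma = 0, dropout_prob = 0, n_noise = 0)
#' run_pipeline(sim$peaks, "GRGDSPC", "NDO", n = 1)
#' @export
run_pipeline <- function(peaks, peptide, adduct, n, tol_ppm = 10,
                         tol_da = NULL, mode = c("strict", "lenient"),
                         ranking = reactivity_ranking(),
                         variant = c("hydroquinone", "quinone"),
                         water_satellites = FALSE) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  p <- as_peptide(peptide)
  ions <- candidate_ions(p, adduct, n, variant, water_satellites)
  ann <- annotate_peaks(peaks, ions, tol_ppm = tol_ppm, tol_da = tol_da)
  loc <- localize(p, adduct, n, ann, mode = mode, ranking = ranking,
                  variant = variant)
  flags <- character(0)
  if (!any(ann$adducted)) flags <- c(flags, "no adduct evidence")
  structure(
    list(peptide = p, adduct = adduct, n = n,
         params = list(tol_ppm = tol_ppm, tol_da = tol_da, mode = mode,
                       variant = variant, water_satellites = water_satellites),
         ions = ions, annotations = ann, localization = loc, flags = flags),
    class = "nap_report"
  )
}

#' @export
print.nap_report <- function(x, ...) {
  cat(sprintf("<adduct report> %s + %d x %s\n",
              x$peptide$sequence, x$n, x$adduct))
  cat(sprintf("  annotated peaks: %d / %d candidate ions\n",
              nrow(x$annotations), nrow(x$ions)))
  if (length(x$flags) > 0) {
    cat(sprintf("  flags: %s\n", paste(x$flags, collapse = "; ")))
  }
  print(x$localization)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `"nap_report"` object.
#' @param ... Unused.
#' @method tidy nap_report
#' @export
tidy.nap_report <- function(x, ...) {
  out <- tidy(x$localization)
  out$n_annotated <- nrow(x$annotations)
  out$flags <- paste(x$flags, collapse = "; ")
  out
}

#' Write a pipeline report as JSON
#'
#' @param report A `"nap_report"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "nap_report"))
  loc <- report$localization
  payload <- list(
    peptide = report$peptide$sequence,
    c_terminus = report$peptide$c_terminus,
    adduct = report$adduct,
    n_adducts = report$n,
    params = report$params,
    flags = report$flags,
    annotations = report$annotations[, setdiff(names(report$annotations),
                                               "placement")],
    localization = list(
      assigned = loc$assigned,
      assigned_site = loc$assigned_site,
      confidence = loc$confidence,
      interval = loc$interval,
      feasible = loc$feasible$label,
      note = loc$note
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Plot an annotated spectrum
#'
#' Stick plot of the observed peaks with annotated peaks highlighted and
#' labeled; adduct-carrying ions are colored separately.
#'
#' @param peaks A peak list tibble (`mz`, `intensity`).
#' @param annotations Output of [annotate_peaks()] for those peaks.
#' @return A ggplot object.
#' @export
plot_annotated_spectrum <- function(peaks, annotations) {
  stopifnot(is.data.frame(peaks), is.data.frame(annotations))
  ann <- annotations
  ann$kind <- ifelse(ann$adducted, "adducted ion", "unmodified ion")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = peaks,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity),
      colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = ann,
      ggplot2::aes(x = .data$observed_mz, xend = .data$observed_mz,
                   y = 0, yend = .data$intensity, colour = .data$kind),
      linewidth = 0.6) +
    ggplot2::geom_text(
      data = ann,
      ggplot2::aes(x = .data$observed_mz, y = .data$intensity,
                   label = .data$label, colour = .data$kind),
      angle = 90, hjust = -0.1, size = 2.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = c("adducted ion" = "#c0392b", "unmodified ion" = "#2c3e50")) +
    ggplot2::labs(x = "m/z", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
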