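# The central fitting function: runs the whole quantification pipeline and
# returns a classed object, in the classic R modelling idiom.

#' Quantify H3 tail proteoforms from annotated MS2 spectra
#'
#' Runs the full middle-down quantification pipeline: score-filter the PSMs,
#' annotate every PSM-bearing scan with its theoretical EThcD fragment
#' ladders, confirm matches by heavy-isotope companion peaks, attribute
#' (shared) confirmed fragment intensity to PSMs, compute proteoform relative
#' abundance, and extract, impurity-correct and channel-normalize TMT
#' reporter intensities for scans passing the per-condition reporter filter.
#'
#' @param spectra List of \code{ms2_spectrum} (see \code{\link{read_spectra}}).
#' @param psms PSM data frame (see \code{\link{read_psm_table}}).
#' @param design A \code{\link{run_design}}.
#' @param tol_ppm Fragment and reporter match tolerance in ppm (default 15).
#' @param pep_max,deltamod_min PSM confidence filters (defaults 0.05 and 10).
#' @param min_reporters Minimum non-missing reporters per treatment condition
#'   for a scan to enter reporter quantification (default 2).
#' @param norm Channel normalization statistic, \code{"mean"} or
#'   \code{"median"}.
#' @param share Shared-ion intensity division rule (see
#'   \code{\link{attribute_intensity}}).
#' @param max_charge,losses,min_fragment_mz Annotation settings (see
#'   \code{\link{annotate_spectrum}}).
#' @param registry Modification registry.
#' @param keep_annotations Keep the per-scan \code{annotated_spectrum}
#'   objects in the fit (default FALSE; they can be large).
#' @param verbose Log filter-stage counts to stderr.
#' @return Object of class \code{"proteoform_quant"}: a list with components
#'   \code{abundance} (per-proteoform attributed intensity, abundance
#'   fraction, scans used), \code{channel_log2} (long data frame of
#'   normalized log2 reporter signals per proteoform/scan/channel, restricted
#'   to eligible scans whose accepted PSMs all share one proteoform),
#'   \code{attributions}, \code{reporters} (raw/corrected/normalized matrices,
#'   factors, eligibility), \code{proteoforms} (named list of
#'   \code{proteoform} objects), \code{counts}, \code{design}, \code{params}
#'   and \code{call}.
#' @seealso \code{\link{diff_proteoforms}}, \code{\link{simulate_dataset}}
#' @export
quantify_proteoforms <- function(spectra, psms, design = run_design(),
                                 tol_ppm = 15, pep_max = 0.05,
                                 deltamod_min = 10, min_reporters = 2L,
                                 norm = c("mean", "median"),
                                 share = c("equal", "proportional"),
                                 max_charge = 4L, losses = c("NH3", "H2O"),
                                 min_fragment_mz = 133,
                                 registry = default_modifications(),
                                 keep_annotations = FALSE, verbose = FALSE) {
  norm <- match.arg(norm)
  share <- match.arg(share)
  cl <- match.call()
  say <- function(...) if (verbose) message(...)

  spec_ids <- vapply(spectra, `[[`, character(1), "scan_id")
  if (anyDuplicated(spec_ids)) stop("duplicate scan ids in spectra", call. = FALSE)
  names(spectra) <- spec_ids

  n_in <- nrow(psms)
  unresolved <- !psms$scan_id %in% spec_ids
  if (any(unresolved)) {
    say(sum(unresolved), " PSM(s) reference missing scans; dropped")
    psms <- psms[!unresolved, , drop = FALSE]
  }
  acc <- filter_psms(psms, pep_max = pep_max, deltamod_min = deltamod_min)
  say("PSMs: ", n_in, " in, ", nrow(acc), " passing score filters")

  scan_ids <- unique(acc$scan_id)
  annotated <- lapply(scan_ids, function(sid) {
    annotate_spectrum(spectra[[sid]], acc[acc$scan_id == sid, , drop = FALSE],
                      tol_ppm = tol_ppm, max_charge = max_charge,
                      losses = losses, min_fragment_mz = min_fragment_mz,
                      registry = registry)
  })
  names(annotated) <- scan_ids

  attributions <- attribute_intensity(annotated, share = share)
  abundance <- proteoform_abundance(attributions)
  say("scans annotated: ", length(scan_ids), "; proteoforms with confirmed intensity: ",
      nrow(abundance))

  # reporter extraction on all PSM-bearing scans
  if (length(scan_ids)) {
    raw <- t(vapply(scan_ids, function(sid) {
      extract_reporters(spectra[[sid]], design, tol_ppm = tol_ppm)
    }, stats::setNames(numeric(length(design$channels)), design$channels)))
    corrected <- t(apply(raw, 1, correct_impurities,
                         impurity_matrix = design$impurity_matrix))
    colnames(corrected) <- design$channels
    nn <- normalize_channels(corrected, method = norm)
    eligible <- reporter_quant_filter(corrected, design,
                                      min_per_condition = min_reporters)
  } else {
    raw <- corrected <- matrix(numeric(0), 0, length(design$channels),
                               dimnames = list(NULL, design$channels))
    nn <- list(normalized = raw, factors = NULL, stats = NULL)
    eligible <- logical(0)
  }
  say("scans with >=", min_reporters, " reporters per condition: ", sum(eligible))

  # scans attributable to a single proteoform feed the reporter grouping
  scan_pf <- tapply(acc$proteoform_id, acc$scan_id, function(x)
    if (length(unique(x)) == 1L) x[1] else NA_character_)
  cl2 <- NULL
  for (i in seq_along(scan_ids)) {
    sid <- scan_ids[i]
    if (!eligible[i] || is.na(scan_pf[[sid]])) next
    v <- nn$normalized[i, ]
    keep <- !is.na(v) & v > 0
    if (!any(keep)) next
    cl2 <- rbind(cl2, data.frame(
      proteoform_id = scan_pf[[sid]], scan_id = sid,
      channel = design$channels[keep],
      condition = unname(design$conditions[keep]),
      log2_signal = log2(v[keep]), stringsAsFactors = FALSE))
  }
  if (is.null(cl2)) {
    cl2 <- data.frame(proteoform_id = character(0), scan_id = character(0),
                      channel = character(0), condition = character(0),
                      log2_signal = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(cl2) <- NULL

  pf <- acc$proteoform[!duplicated(acc$proteoform_id)]
  names(pf) <- acc$proteoform_id[!duplicated(acc$proteoform_id)]

  counts <- c(psms_in = n_in, psms_unresolved_scan = sum(unresolved),
              psms_accepted = nrow(acc),
              psms_score_dropped = attr(acc, "n_dropped"),
              scans_annotated = length(scan_ids),
              scans_reporter_eligible = sum(eligible),
              proteoforms = nrow(abundance),
              proteoforms_quantifiable = length(unique(cl2$proteoform_id)))

  structure(list(
    abundance = abundance, attributions = attributions, channel_log2 = cl2,
    reporters = list(raw = raw, corrected = corrected,
                     normalized = nn$normalized, factors = nn$factors,
                     stats = nn$stats, eligible = eligible),
    proteoforms = pf, counts = counts, design = design,
    params = list(tol_ppm = tol_ppm, pep_max = pep_max,
                  deltamod_min = deltamod_min, min_reporters = min_reporters,
                  norm = norm, share = share, max_charge = max_charge,
                  losses = losses, min_fragment_mz = min_fragment_mz),
    annotated = if (keep_annotations) annotated else NULL,
    call = cl), class = "proteoform_quant")
}

#' @export
print.proteoform_quant <- function(x, ...) {
  cat("Middle-down proteoform quantification\n")
  cat(sprintf(" %d PSMs in, %d accepted; %d scans annotated\n",
              x$counts[["psms_in"]], x$counts[["psms_accepted"]],
              x$counts[["scans_annotated"]]))
  cat(sprintf(" %d proteoforms with confirmed intensity, %d quantifiable by reporters\n",
              x$counts[["proteoforms"]], x$counts[["proteoforms_quantifiable"]]))
  if (nrow(x$abundance)) {
    top <- utils::head(x$abundance, 5)
    cat(" top proteoforms by abundance:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("   %-40s %.3f\n", top$proteoform_id[i], top$abundance[i]))
    }
  }
  invisible(x)
}

#' @export
summary.proteoform_quant <- function(object, ...) {
  structure(list(counts = object$counts, abundance = object$abundance,
                 factors = object$reporters$factors,
                 params = object$params), class = "summary.proteoform_quant")
}

#' @export
print.summary.proteoform_quant <- function(x, ...) {
  cat("Pipeline stage counts:\n")
  print(x$counts)
  cat(sprintf("\nSettings: %g ppm tolerance, PEP <= %g, delta-mod >= %g, %s normalization\n",
              x$params$tol_ppm, x$params$pep_max, x$params$deltamod_min,
              x$params$norm))
  if (!is.null(x$factors)) {
    cat("\nChannel normalization factors:\n")
    print(round(x$factors, 4))
  }
  cat("\nProteoform abundances:\n")
  print(x$abundance, digits = 4)
  invisible(x)
}

#' Extract proteoform abundance estimates
#'
#' @param object A \code{proteoform_quant} fit.
#' @param ... Unused.
#' @return Named numeric vector of abundance fractions (summing to 1).
#' @export
coef.proteoform_quant <- function(object, ...) {
  stats::setNames(object$abundance$abundance, object$abundance$proteoform_id)
}

#' Plot proteoform abundances
#'
#' Horizontal bar chart of the estimated abundance fractions.
#'
#' @param x A \code{proteoform_quant} fit.
#' @param n Number of top proteoforms to show.
#' @param ... Passed to \code{barplot}.
#' @export
plot.proteoform_quant <- function(x, n = 20, ...) {
  ab <- utils::head(x$abundance, n)
  if (!nrow(ab)) {
    warning("nothing to plot")
    return(invisible(NULL))
  }
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(ab$abundance), names.arg = rev(ab$proteoform_id),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "abundance fraction",
                    main = "Proteoform relative abundance", ...)
  invisible(x)
}
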