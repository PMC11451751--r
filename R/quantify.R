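# Core computation: PSM filtering, fragment annotation with heavy-isotope
# confirmation, shared-ion intensity attribution, proteoform abundance,
# TMT reporter extraction / impurity correction / channel normalization.

#' Filter PSMs on confidence scores
#'
#' Keeps records with posterior error probability <= \code{pep_max} AND
#' delta-mod score >= \code{deltamod_min}; boundary values pass.
#'
#' @param psms PSM data frame (see \code{\link{read_psm_table}}).
#' @param pep_max Maximum posterior error probability (default 0.05).
#' @param deltamod_min Minimum delta-mod localization score (default 10).
#' @return The accepted rows, with \code{n_psms_on_scan} recomputed.
#' @export
filter_psms <- function(psms, pep_max = 0.05, deltamod_min = 10) {
  keep <- psms$pep <= pep_max & psms$delta_mod >= deltamod_min
  out <- psms[keep, , drop = FALSE]
  if (nrow(out)) {
    out$n_psms_on_scan <- as.integer(ave(seq_len(nrow(out)), out$scan_id,
                                         FUN = length))
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# indices of sorted vector `sorted` within tol_ppm of value m
.window_idx <- function(sorted, m, tol_ppm) {
  lo <- m / (1 + tol_ppm * 1e-6)
  hi <- m / (1 - tol_ppm * 1e-6)
  i1 <- findInterval(lo, sorted) + 1L
  i2 <- findInterval(hi, sorted)
  if (i2 < i1) integer(0) else i1:i2
}

#' Check for a heavy-isotope companion peak
#'
#' TRUE iff the spectrum contains a peak of positive intensity at
#' \code{mz + 1.003355/charge} within \code{tol_ppm}.
#'
#' @param spectrum An \code{ms2_spectrum}.
#' @param mz Matched (observed) peak m/z.
#' @param charge Fragment charge.
#' @param tol_ppm Tolerance in ppm.
#' @return Logical.
#' @export
confirm_isotope <- function(spectrum, mz, charge, tol_ppm = 15) {
  target <- mz + .c13_spacing / charge
  idx <- .window_idx(spectrum$mz, target, tol_ppm)
  idx <- idx[abs(ppm_error(target, spectrum$mz[idx])) <= tol_ppm &
               spectrum$intensity[idx] > 0]
  length(idx) > 0L
}

#' Annotate a spectrum with theoretical fragments of its PSMs
#'
#' Each peak is matched, per PSM, to the theoretical fragment minimizing the
#' absolute ppm error within tolerance. Exact ties are broken by charge-state
#' disambiguation (candidates whose +1 isotope companion is present at the
#' candidate's charge win), then lowest index, series order a<b<c<y<z,
#' lowest charge, and no-loss before NH3 before H2O. A peak may
#' carry at most one match per PSM, and a peak explained by several PSMs'
#' ladders lists all of them. Each match is flagged by
#' \code{\link{confirm_isotope}}. Peaks below \code{min_fragment_mz}
#' (the TMT reporter region by default) are not considered fragment
#' candidates.
#'
#' @param spectrum An \code{ms2_spectrum}.
#' @param psms PSM data frame rows referencing this scan.
#' @param tol_ppm Fragment match tolerance in ppm (default 15).
#' @param max_charge Fragment charge cap; the effective cap is
#'   \code{min(max_charge, precursor_charge - 1)}.
#' @param losses Neutral losses to consider.
#' @param min_fragment_mz Peaks below this m/z are excluded from fragment
#'   matching (default 133, above the TMT 6-plex reporters).
#' @param registry Modification registry.
#' @return Object of class \code{"annotated_spectrum"}: list with
#'   \code{scan_id}, \code{spectrum}, \code{psm_ids} (proteoform id per PSM)
#'   and \code{matches} (data frame: peak index, peak_mz, intensity, psm,
#'   proteoform_id, series, index, charge, loss, theoretical_mz, ppm,
#'   isotope_confirmed).
#' @export
annotate_spectrum <- function(spectrum, psms, tol_ppm = 15, max_charge = 4L,
                              losses = c("NH3", "H2O"), min_fragment_mz = 133,
                              registry = default_modifications()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  if (nrow(psms) && !all(psms$scan_id == spectrum$scan_id)) {
    stop("PSMs do not all reference scan ", spectrum$scan_id, call. = FALSE)
  }
  eff_charge <- max(1L, min(as.integer(max_charge),
                            spectrum$precursor_charge - 1L))
  peak_ok <- which(spectrum$mz >= min_fragment_mz)
  out <- vector("list", nrow(psms))
  for (j in seq_len(nrow(psms))) {
    lad <- fragment_ladder(psms$proteoform[[j]], max_charge = eff_charge,
                           losses = losses, registry = registry)
    o <- order(lad$mz)
    lad <- lad[o, , drop = FALSE]
    srs <- match(lad$series, .series_levels)
    lss <- match(lad$loss, .loss_levels)
    rows <- lapply(peak_ok, function(i) {
      m <- spectrum$mz[i]
      cand <- .window_idx(lad$mz, m, tol_ppm)
      if (!length(cand)) return(NULL)
      ppm <- ppm_error(lad$mz[cand], m)
      cand <- cand[abs(ppm) <= tol_ppm]
      if (!length(cand)) return(NULL)
      ppm <- ppm_error(lad$mz[cand], m)
      # charge-state disambiguation: among (near-)tied candidates prefer one
      # whose +1 isotope companion is present at the candidate's charge
      conf <- vapply(lad$charge[cand], function(ch)
        confirm_isotope(spectrum, m, ch, tol_ppm), logical(1))
      best <- cand[order(abs(ppm), !conf, lad$index[cand], srs[cand],
                         lad$charge[cand], lss[cand])][1]
      data.frame(peak = i, peak_mz = m, intensity = spectrum$intensity[i],
                 psm = j, proteoform_id = psms$proteoform_id[j],
                 series = lad$series[best], index = lad$index[best],
                 charge = lad$charge[best], loss = lad$loss[best],
                 theoretical_mz = lad$mz[best],
                 ppm = ppm_error(lad$mz[best], m),
                 stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, rows)
  }
  matches <- do.call(rbind, out)
  if (is.null(matches)) {
    matches <- data.frame(peak = integer(0), peak_mz = numeric(0),
                          intensity = numeric(0), psm = integer(0),
                          proteoform_id = character(0), series = character(0),
                          index = integer(0), charge = integer(0),
                          loss = character(0), theoretical_mz = numeric(0),
                          ppm = numeric(0), stringsAsFactors = FALSE)
  }
  matches$isotope_confirmed <- if (nrow(matches)) {
    vapply(seq_len(nrow(matches)), function(k) {
      confirm_isotope(spectrum, matches$peak_mz[k], matches$charge[k], tol_ppm)
    }, logical(1))
  } else logical(0)
  rownames(matches) <- NULL
  structure(list(scan_id = spectrum$scan_id, spectrum = spectrum,
                 psm_ids = psms$proteoform_id, matches = matches),
            class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat(sprintf("Annotated scan %s: %d PSM(s), %d fragment match(es), %d confirmed\n",
              x$scan_id, length(x$psm_ids), nrow(x$matches),
              sum(x$matches$isotope_confirmed)))
  invisible(x)
}

#' Attribute confirmed fragment intensity to PSMs
#'
#' For each isotope-confirmed match the peak's intensity is credited to its
#' PSM; a peak carrying confirmed matches from k PSMs credits intensity/k to
#' each (\code{share = "equal"}, the default) or splits proportionally to
#' each PSM's uniquely-confirmed intensity on the scan
#' (\code{share = "proportional"}). Unconfirmed matches contribute zero.
#'
#' @param annotated An \code{annotated_spectrum} or a list of them.
#' @param share Shared-ion division rule.
#' @return Data frame with one row per (scan, PSM): \code{scan_id},
#'   \code{psm}, \code{proteoform_id}, \code{intensity}.
#' @export
attribute_intensity <- function(annotated, share = c("equal", "proportional")) {
  share <- match.arg(share)
  if (inherits(annotated, "annotated_spectrum")) annotated <- list(annotated)
  rows <- lapply(annotated, function(a) {
    if (!length(a$psm_ids)) return(NULL)
    base <- data.frame(scan_id = a$scan_id, psm = seq_along(a$psm_ids),
                       proteoform_id = a$psm_ids, intensity = 0,
                       stringsAsFactors = FALSE)
    m <- a$matches[a$matches$isotope_confirmed, , drop = FALSE]
    if (nrow(m)) {
      k_per_peak <- table(m$peak)
      m$k <- as.integer(k_per_peak[as.character(m$peak)])
      if (share == "equal") {
        cred <- tapply(m$intensity / m$k, m$psm, sum)
        base$intensity[as.integer(names(cred))] <- as.numeric(cred)
      } else {
        # weight shared peaks by each PSM's uniquely-confirmed intensity
        w <- rep(0, length(a$psm_ids))
        uq <- m[m$k == 1L, , drop = FALSE]
        if (nrow(uq)) {
          uw <- tapply(uq$intensity, uq$psm, sum)
          w[as.integer(names(uw))] <- as.numeric(uw)
        }
        cred <- w
        sh <- m[m$k > 1L, , drop = FALSE]
        for (pk in unique(sh$peak)) {
          sel <- sh$psm[sh$peak == pk]
          ww <- w[sel]
          ww <- if (sum(ww) > 0) ww / sum(ww) else rep(1 / length(sel), length(sel))
          cred[sel] <- cred[sel] + sh$intensity[sh$peak == pk][1] * ww
        }
        base$intensity <- cred
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(scan_id = character(0), psm = integer(0),
                      proteoform_id = character(0), intensity = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Proteoform relative abundance
#'
#' The fraction of confirmed annotated fragment-ion intensity attributable to
#' each proteoform relative to the total over all proteoforms; attributions of
#' the same proteoform on different scans pool.
#'
#' @param attributions Output of \code{\link{attribute_intensity}}.
#' @return Data frame: \code{proteoform_id}, \code{attributed_intensity},
#'   \code{abundance}, \code{n_scans}; empty (with a warning) when no
#'   confirmed intensity exists.
#' @export
proteoform_abundance <- function(attributions) {
  tot <- sum(attributions$intensity)
  if (!nrow(attributions) || tot <= 0) {
    warning("no confirmed fragment intensity; abundance undefined")
    return(data.frame(proteoform_id = character(0),
                      attributed_intensity = numeric(0),
                      abundance = numeric(0), n_scans = integer(0)))
  }
  ai <- tapply(attributions$intensity, attributions$proteoform_id, sum)
  ns <- tapply(attributions$scan_id[attributions$intensity > 0],
               attributions$proteoform_id[attributions$intensity > 0],
               function(x) length(unique(x)))
  out <- data.frame(proteoform_id = names(ai),
                    attributed_intensity = as.numeric(ai),
                    abundance = as.numeric(ai) / tot,
                    n_scans = as.integer(ifelse(is.na(ns[names(ai)]), 0L,
                                                ns[names(ai)])),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$proteoform_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract raw TMT reporter intensities from a scan
#'
#' Nearest peak within \code{tol_ppm} of each channel's reporter m/z; a
#' missing channel (no peak in tolerance, or zero intensity) is NA.
#'
#' @param spectrum An \code{ms2_spectrum}.
#' @param design A \code{run_design}.
#' @param tol_ppm Tolerance in ppm.
#' @return Named numeric vector (one element per channel, NA = missing).
#' @export
extract_reporters <- function(spectrum, design, tol_ppm = 15) {
  out <- vapply(design$reporter_mz, function(rm) {
    idx <- .window_idx(spectrum$mz, rm, tol_ppm)
    idx <- idx[abs(ppm_error(rm, spectrum$mz[idx])) <= tol_ppm]
    if (!length(idx)) return(NA_real_)
    best <- idx[which.min(abs(ppm_error(rm, spectrum$mz[idx])))]
    v <- spectrum$intensity[best]
    if (v <= 0) NA_real_ else v
  }, numeric(1))
  stats::setNames(out, design$channels)
}

#' Correct reporter intensities for label isotopic impurities
#'
#' Solves \code{impurity_matrix \%*\% x = raw} for the true per-channel
#' signals x; negative components are clipped at zero with a warning. The
#' identity matrix (the default design) leaves the input unchanged. Missing
#' (NA) channels are treated as zero observed signal and stay NA on output.
#'
#' @param raw Named numeric vector of observed intensities (NA = missing).
#' @param impurity_matrix Square matrix, column j = isotopic distribution of
#'   label j across observed channels.
#' @return Corrected intensities, same names as \code{raw}.
#' @export
correct_impurities <- function(raw, impurity_matrix) {
  m <- as.matrix(impurity_matrix)
  if (nrow(m) != length(raw)) stop("impurity matrix does not match channels", call. = FALSE)
  obs <- ifelse(is.na(raw), 0, raw)
  x <- tryCatch(solve(m, obs),
                error = function(e) stop("singular impurity matrix in run design: ",
                                         conditionMessage(e), call. = FALSE))
  if (any(x < 0)) {
    warning("negative impurity-corrected intensities clipped at 0")
    x[x < 0] <- 0
  }
  x[is.na(raw)] <- NA_real_
  stats::setNames(as.numeric(x), names(raw))
}

#' Channel-normalize reporter intensities
#'
#' Per channel c, the statistic S_c (mean by default, median optionally) is
#' computed over all PSM-bearing scans; every intensity in channel c is then
#' multiplied by \code{max(S)/S_c}, so that after normalization all channel
#' statistics equal the largest channel's. Channels with no positive signal
#' are excluded from the maximum (warning) and left unscaled.
#'
#' @param mat Numeric matrix, scans x channels (NA = missing).
#' @param method \code{"mean"} or \code{"median"}.
#' @return List with \code{normalized} (matrix), \code{factors} and
#'   \code{stats} (named per-channel vectors).
#' @export
normalize_channels <- function(mat, method = c("mean", "median")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (!nrow(mat)) stop("no scans to normalize", call. = FALSE)
  fun <- if (method == "mean") function(x) mean(x, na.rm = TRUE) else function(x) stats::median(x, na.rm = TRUE)
  s <- apply(mat, 2, fun)
  s[is.nan(s)] <- 0
  ok <- is.finite(s) & s > 0
  if (!any(ok)) stop("all channels have zero signal", call. = FALSE)
  if (!all(ok)) warning("channel(s) with no signal excluded from normalization: ",
                        paste(colnames(mat)[!ok], collapse = ", "))
  f <- rep(1, ncol(mat))
  f[ok] <- max(s[ok]) / s[ok]
  names(f) <- colnames(mat)
  list(normalized = sweep(mat, 2, f, "*"), factors = f, stats = s)
}

#' Select scans eligible for reporter quantification
#'
#' A scan is kept iff every treatment condition has at least
#' \code{min_per_condition} non-missing reporter intensities.
#'
#' @param mat Numeric matrix, scans x channels (NA = missing); column names
#'   must be the design's channels.
#' @param design A \code{run_design}.
#' @param min_per_condition Minimum reporters per condition (default 2).
#' @return Logical vector, one element per scan (row).
#' @export
reporter_quant_filter <- function(mat, design, min_per_condition = 2L) {
  mat <- as.matrix(mat)
  conds <- unique(design$conditions)
  ok <- rep(TRUE, nrow(mat))
  for (cd in conds) {
    ch <- design$channels[design$conditions == cd]
    cnt <- rowSums(!is.na(mat[, ch, drop = FALSE]) &
                     mat[, ch, drop = FALSE] > 0)
    ok <- ok & cnt >= min_per_condition
  }
  ok
}
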