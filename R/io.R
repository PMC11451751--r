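# Readers/writers: spectra (mzML via mzR, or the package's plain TSV
# peak-list dialect), PSM tables, run-design configs, result tables.

#' Construct an MS2 spectrum
#'
#' @param scan_id Scan identifier (character).
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (>= 1).
#' @param mz,intensity Centroided peak list; peaks are sorted by m/z.
#' @return Object of class \code{"ms2_spectrum"}.
#' @export
ms2_spectrum <- function(scan_id, precursor_mz, precursor_charge, mz, intensity) {
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch", call. = FALSE)
  if (any(intensity < 0)) stop("negative peak intensity", call. = FALSE)
  if (precursor_charge < 1) stop("precursor_charge must be >= 1", call. = FALSE)
  o <- order(mz)
  structure(list(scan_id = as.character(scan_id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 scan %s: precursor %.4f m/z (%d+), %d peaks\n",
              x$scan_id, x$precursor_mz, x$precursor_charge, length(x$mz)))
  invisible(x)
}

#' Read centroided MS2 spectra
#'
#' Supports mzML (through the \pkg{mzR} Bioconductor parser; MS2 scans only)
#' and the package's TSV peak-list dialect: a tab-separated file with header
#' columns \code{scan_id}, \code{precursor_mz}, \code{precursor_charge},
#' \code{mz}, \code{intensity}, one row per peak (scans with zero peaks are
#' represented by a single row with empty \code{mz}/\code{intensity}).
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"mzML"} or \code{"tsv"}.
#' @return List of \code{ms2_spectrum} objects.
#' @export
read_spectra <- function(path, format = c("auto", "mzML", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "mzML") .read_spectra_mzml(path) else .read_spectra_tsv(path)
}

.read_spectra_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "precursor_mz", "precursor_charge", "mz", "intensity")
  if (!all(need %in% names(d))) {
    stop("peak-list TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d$scan_id <- as.character(d$scan_id)
  out <- lapply(split(d, factor(d$scan_id, levels = unique(d$scan_id))), function(g) {
    keep <- !is.na(g$mz)
    ms2_spectrum(g$scan_id[1], g$precursor_mz[1], g$precursor_charge[1],
                 g$mz[keep], g$intensity[keep])
  })
  names(out) <- NULL
  n_empty <- sum(vapply(out, function(s) length(s$mz) == 0L, logical(1)))
  if (n_empty) message(n_empty, " scan(s) with empty peak list retained")
  out
}

.read_spectra_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms2 <- which(hd$msLevel == 2L)
  if (!is.null(hd$centroided) && any(!is.na(hd$centroided[ms2]) & !hd$centroided[ms2])) {
    stop("profile-mode scans found in ", path, "; centroid the data first",
         call. = FALSE)
  }
  out <- lapply(ms2, function(i) {
    pk <- mzR::peaks(fh, i)
    sid <- if (!is.null(hd$spectrumId)) sub("^.*scan=", "", hd$spectrumId[i]) else hd$acquisitionNum[i]
    ms2_spectrum(sid, hd$precursorMZ[i], max(1L, hd$precursorCharge[i]),
                 pk[, 1], pk[, 2])
  })
  n_empty <- sum(vapply(out, function(s) length(s$mz) == 0L, logical(1)))
  if (n_empty) message(n_empty, " scan(s) with empty peak list retained")
  out
}

#' Write spectra
#'
#' @param spectra List of \code{ms2_spectrum}.
#' @param path Output file.
#' @param format \code{"auto"}, \code{"mzML"} (requires \pkg{mzR}) or
#'   \code{"tsv"}. mzML native scan ids are numeric: the trailing digits of
#'   each scan id are used when unique, sequence numbers otherwise.
#' @return \code{path}, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "mzML", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "tsv"
  }
  if (format == "tsv") {
    rows <- lapply(spectra, function(s) {
      if (!length(s$mz)) {
        data.frame(scan_id = s$scan_id, precursor_mz = s$precursor_mz,
                   precursor_charge = s$precursor_charge,
                   mz = NA_real_, intensity = NA_real_)
      } else {
        data.frame(scan_id = s$scan_id, precursor_mz = s$precursor_mz,
                   precursor_charge = s$precursor_charge,
                   mz = s$mz, intensity = s$intensity)
      }
    })
    d <- do.call(rbind, rows)
    for (col in c("precursor_mz", "mz", "intensity")) d[[col]] <- sprintf("%.10g", d[[col]])
    d$mz[d$mz == "NA"] <- ""
    d$intensity[d$intensity == "NA"] <- ""
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("writing mzML requires the mzR package", call. = FALSE)
    }
    n <- length(spectra)
    # mzML native scan ids must be integers: reuse trailing digits of the
    # scan ids when unique, else fall back to sequence numbers
    ids <- vapply(spectra, `[[`, character(1), "scan_id")
    num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", ids)))
    if (anyNA(num) || anyDuplicated(num)) num <- seq_len(n)
    hdr <- data.frame(
      seqNum = seq_len(n), acquisitionNum = num, msLevel = 2L,
      polarity = 1L,
      peaksCount = vapply(spectra, function(s) length(s$mz), integer(1)),
      totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
      retentionTime = seq_len(n), basePeakMZ = 0, basePeakIntensity = 0,
      collisionEnergy = 15, ionisationEnergy = 0,
      lowMZ = vapply(spectra, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1)),
      highMZ = vapply(spectra, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1)),
      precursorScanNum = 0L,
      precursorMZ = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
      precursorCharge = vapply(spectra, `[[`, integer(1), "precursor_charge"),
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = paste0("scan=", num),
      centroided = TRUE, ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
      isolationWindowLowerOffset = 0.8, isolationWindowUpperOffset = 0.8,
      scanWindowLowerLimit = 100, scanWindowUpperLimit = 2000,
      stringsAsFactors = FALSE
    )
    pks <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
    mzR::writeMSData(pks, file = path, header = hdr)
  }
  invisible(path)
}

#' Read a PSM table
#'
#' Tab-separated search-engine export emulation with header columns
#' \code{scan_id}, \code{base_id}, \code{mods} (positioned-modification
#' string, see \code{\link{parse_mod_string}}), \code{pep} (posterior error
#' probability) and \code{delta_mod} (mod-localization confidence score).
#' A column-mapping can adapt other layouts. Rows whose modification string
#' does not parse or violates the proteoform invariants are rejected with a
#' reason (kept in \code{attr(,"rejected")}); the run continues.
#'
#' @param path File path.
#' @param registry Modification registry.
#' @param column_map Named character vector mapping the required names to the
#'   file's column names, e.g. \code{c(scan_id = "Scan..")}.
#' @return Data frame with columns \code{scan_id}, \code{base_id},
#'   \code{mods}, \code{pep}, \code{delta_mod}, \code{proteoform_id},
#'   \code{n_psms_on_scan}, plus a list column \code{proteoform} of
#'   \code{proteoform} objects. Attribute \code{"rejected"} holds the
#'   rejected rows and reasons.
#' @export
read_psm_table <- function(path, registry = default_modifications(),
                           column_map = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "base_id", "mods", "pep", "delta_mod")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(d)) {
        stop("mapped column '", column_map[[nm]], "' not in file", call. = FALSE)
      }
      names(d)[names(d) == column_map[[nm]]] <- nm
    }
  }
  if (!all(need %in% names(d))) {
    stop("PSM table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  psms_from_table(d[, need], registry)
}

#' Build validated PSM records from a data frame
#'
#' Workhorse behind \code{\link{read_psm_table}}; useful when PSMs are
#' already in memory (e.g. from the simulator).
#'
#' @param d Data frame with columns \code{scan_id}, \code{base_id},
#'   \code{mods}, \code{pep}, \code{delta_mod}.
#' @param registry Modification registry.
#' @return See \code{\link{read_psm_table}}.
#' @export
psms_from_table <- function(d, registry = default_modifications()) {
  d$scan_id <- as.character(d$scan_id)
  d$pep <- as.numeric(d$pep)
  d$delta_mod <- as.numeric(d$delta_mod)
  n_in <- nrow(d)
  pf <- vector("list", n_in)
  reason <- character(n_in)
  for (i in seq_len(n_in)) {
    pf[i] <- list(tryCatch(
      proteoform(d$base_id[i], d$mods[i], registry = registry),
      error = function(e) {
        reason[i] <<- conditionMessage(e)
        NULL
      }))
    if (!is.null(pf[[i]]) && (is.na(d$pep[i]) || d$pep[i] < 0 || d$pep[i] > 1)) {
      reason[i] <- "pep outside [0,1]"
      pf[i] <- list(NULL)
    }
  }
  bad <- vapply(pf, is.null, logical(1))
  rejected <- cbind(d[bad, , drop = FALSE],
                    data.frame(reason = reason[bad], stringsAsFactors = FALSE))
  out <- d[!bad, , drop = FALSE]
  out$proteoform_id <- vapply(pf[!bad], proteoform_id, character(1))
  out$n_psms_on_scan <- as.integer(ave(seq_len(nrow(out)), out$scan_id,
                                       FUN = length))
  out$proteoform <- pf[!bad]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  if (nrow(rejected)) {
    message(nrow(rejected), " of ", n_in, " PSM row(s) rejected")
  }
  out
}

#' Construct a TMT run design
#'
#' Maps TMT 6-plex channels to treatment conditions and reporter m/z values,
#' with an optional isotopic impurity matrix (column j = distribution of
#' label j's signal across observed channels; identity means no impurity).
#'
#' @param channels Channel labels, default \code{"126".."131"}.
#' @param conditions Named character vector channel -> condition label;
#'   default vehicle (126-128) vs treated (129-131).
#' @param reporter_mz Named numeric channel -> reporter m/z; defaults to the
#'   standard TMT 6-plex reporter monoisotopic m/z values.
#' @param impurity_matrix Square matrix (channels x channels), columns
#'   non-negative with sums <= 1; default identity.
#' @return Object of class \code{"run_design"}.
#' @export
run_design <- function(channels = as.character(126:131),
                       conditions = NULL, reporter_mz = NULL,
                       impurity_matrix = NULL) {
  channels <- as.character(channels)
  if (is.null(conditions)) {
    if (length(channels) != 6L) stop("default conditions need 6 channels", call. = FALSE)
    conditions <- stats::setNames(rep(c("vehicle", "treated"), each = 3), channels)
  }
  conditions <- conditions[channels]
  if (any(is.na(conditions))) stop("every channel needs a condition", call. = FALSE)
  if (is.null(reporter_mz)) {
    std <- c(`126` = 126.127726, `127` = 127.131081, `128` = 128.134436,
             `129` = 129.137790, `130` = 130.141145, `131` = 131.144500)
    reporter_mz <- std[channels]
  }
  reporter_mz <- reporter_mz[channels]
  if (any(is.na(reporter_mz))) stop("every channel needs a reporter m/z", call. = FALSE)
  k <- length(channels)
  if (is.null(impurity_matrix)) impurity_matrix <- diag(k)
  impurity_matrix <- as.matrix(impurity_matrix)
  if (!all(dim(impurity_matrix) == k)) stop("impurity matrix must be ",
                                            k, "x", k, call. = FALSE)
  if (any(impurity_matrix < 0)) stop("impurity matrix must be non-negative", call. = FALSE)
  if (any(colSums(impurity_matrix) > 1 + 1e-8)) {
    stop("impurity matrix columns must sum to <= 1", call. = FALSE)
  }
  dimnames(impurity_matrix) <- list(channels, channels)
  structure(list(channels = channels,
                 conditions = stats::setNames(as.character(conditions), channels),
                 reporter_mz = stats::setNames(as.numeric(reporter_mz), channels),
                 impurity_matrix = impurity_matrix),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("TMT run design:", length(x$channels), "channels\n")
  print(data.frame(channel = x$channels, condition = x$conditions,
                   reporter_mz = x$reporter_mz, row.names = NULL))
  if (all(x$impurity_matrix == diag(length(x$channels)))) {
    cat("impurity matrix: identity\n")
  } else cat("impurity matrix: non-identity\n")
  invisible(x)
}

#' Read a run design from YAML
#'
#' Expected fields: \code{channels} (list), \code{conditions} (map channel ->
#' condition), optional \code{reporter_mz} (map) and \code{impurity_matrix}
#' (list of rows).
#'
#' @param path YAML file.
#' @return A \code{run_design}.
#' @export
read_run_design <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$channels)) stop("run design needs 'channels': ", path, call. = FALSE)
  ch <- as.character(unlist(y$channels))
  conditions <- if (!is.null(y$conditions)) unlist(y$conditions)[ch] else NULL
  reporter_mz <- if (!is.null(y$reporter_mz)) {
    v <- unlist(y$reporter_mz)
    stats::setNames(as.numeric(v), names(v))[ch]
  } else NULL
  im <- if (!is.null(y$impurity_matrix)) {
    m <- do.call(rbind, lapply(y$impurity_matrix, as.numeric))
    if (any(!is.finite(m))) stop("non-numeric impurity matrix in ", path, call. = FALSE)
    m
  } else NULL
  tryCatch(run_design(ch, conditions, reporter_mz, im),
           error = function(e) stop("invalid run design '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a run design to YAML
#' @param design A \code{run_design}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_run_design <- function(design, path) {
  y <- list(channels = as.list(design$channels),
            conditions = as.list(design$conditions),
            reporter_mz = as.list(design$reporter_mz),
            impurity_matrix = lapply(seq_len(nrow(design$impurity_matrix)),
                                     function(i) as.numeric(design$impurity_matrix[i, ])))
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))

#' Write result tables
#'
#' Writes \code{proteoforms.tsv} (per-proteoform abundance and per-channel
#' mean normalized log2 reporter signal) and \code{differential.tsv}
#' (log2 fold change, p, BH q, significance flag). Rows are sorted by
#' abundance descending, ties broken lexicographically by id; output is
#' deterministic (re-running on the same inputs is byte-identical).
#'
#' @param quant A \code{proteoform_quant} fit (or NULL for an empty table).
#' @param diff A \code{proteoform_diff} result (or NULL).
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(quant, diff, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf_path <- file.path(dir, "proteoforms.tsv")
  dd_path <- file.path(dir, "differential.tsv")

  if (is.null(quant) || !nrow(quant$abundance)) {
    ab <- data.frame(proteoform_id = character(0), abundance = character(0),
                     attributed_intensity = character(0), n_scans = integer(0))
    utils::write.table(ab, pf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ab <- quant$abundance
    ab <- ab[order(-ab$abundance, ab$proteoform_id), , drop = FALSE]
    # per-channel mean normalized log2 signal
    cl <- quant$channel_log2
    if (!is.null(cl) && nrow(cl)) {
      agg <- stats::aggregate(log2_signal ~ proteoform_id + channel, data = cl, FUN = mean)
      for (ch in quant$design$channels) {
        v <- agg$log2_signal[agg$channel == ch]
        names(v) <- agg$proteoform_id[agg$channel == ch]
        ab[[paste0("log2_", ch)]] <- unname(v[ab$proteoform_id])
      }
    }
    num <- vapply(ab, is.numeric, logical(1)) & names(ab) != "n_scans"
    ab[num] <- lapply(ab[num], .fmt_num)
    utils::write.table(ab, pf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (is.null(diff) || !nrow(as.data.frame(diff))) {
    dd <- data.frame(proteoform_id = character(0), log2fc = character(0),
                     p_value = character(0), q_value = character(0),
                     n_vehicle = integer(0), n_treated = integer(0),
                     significant = logical(0))
    utils::write.table(dd, dd_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dd <- as.data.frame(diff)
    ord <- order(dd$p_value, dd$proteoform_id)
    dd <- dd[ord, , drop = FALSE]
    num <- vapply(dd, is.numeric, logical(1)) & !names(dd) %in% c("n_vehicle", "n_treated")
    dd[num] <- lapply(dd[num], .fmt_num)
    utils::write.table(dd, dd_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(pf_path, dd_path))
}
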