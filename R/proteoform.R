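# Proteoform: a base tail sequence (H3.1 or H3.3 surrogate, residues 1-32 of
# the H3 N-terminal tail plus the GGGH tag left by sortase ligation) plus a
# set of positioned variable modifications.

.h3_sequences <- c(
  H3.1 = "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGGH",
  H3.3 = "ARTKQTARKSTGGKAPRKQLATKAARKSAPSTGGGH"
)

# short PTM suffixes in the field's proteoform naming style (H3K9acK27me2)
.mod_short <- c(Methyl = "me1", Dimethyl = "me2", Trimethyl = "me3",
                Phospho = "ph", Acetyl = "ac", Propionyl = "pr")

#' Surrogate tail sequence for an H3 variant
#'
#' @param base_id \code{"H3.1"} or \code{"H3.3"} (they differ only at
#'   position 31, A vs S).
#' @return Residue string.
#' @export
h3_tail_sequence <- function(base_id = c("H3.1", "H3.3")) {
  base_id <- match.arg(base_id)
  unname(.h3_sequences[base_id])
}

#' Construct a proteoform
#'
#' A proteoform is a base tail sequence plus positioned variable modifications.
#' Validation enforces the search-space rules: each position carries at most
#' one variable modification, the residue at each position must be a target of
#' the modification, per-modification occurrence caps are respected, and the
#' peptide carries at most 6 common and 1 rare variable modification.
#'
#' @param base_id \code{"H3.1"} or \code{"H3.3"}.
#' @param mods Either \code{NULL} (unmodified), a data frame with columns
#'   \code{position} (1-based residue index) and \code{name} (registry
#'   modification name), or a character vector of tokens such as
#'   \code{c("K9ac", "K27me2")} / a single semicolon-separated string such as
#'   \code{"K9(Acetyl);K14(Acetyl)"}.
#' @param registry Modification registry data frame.
#' @param sequence Optional explicit residue string overriding the surrogate.
#' @return An object of class \code{"proteoform"}: a list with \code{base_id},
#'   \code{sequence} and \code{mods} (data frame of position/name/delta).
#' @examples
#' proteoform("H3.1", c("K9ac", "K14ac"))
#' @export
proteoform <- function(base_id = c("H3.1", "H3.3"), mods = NULL,
                       registry = default_modifications(), sequence = NULL) {
  base_id <- match.arg(base_id)
  if (is.null(sequence)) sequence <- h3_tail_sequence(base_id)
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.residue_masses))) {
    stop("sequence contains non-canonical residues", call. = FALSE)
  }

  if (is.character(mods)) {
    mods <- parse_mod_string(paste(mods, collapse = ";"), registry)
  }
  if (is.null(mods) || NROW(mods) == 0) {
    mods <- data.frame(position = integer(0), name = character(0),
                       delta = numeric(0), stringsAsFactors = FALSE)
  } else {
    mods <- as.data.frame(mods)[, c("position", "name")]
    mods$position <- as.integer(mods$position)
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
    if (anyDuplicated(mods$position)) {
      stop("a position may carry at most one variable modification", call. = FALSE)
    }
    if (any(mods$position < 1L | mods$position > length(res))) {
      stop("modification position outside the peptide", call. = FALSE)
    }
    info <- lapply(mods$name, modification_delta, registry = registry)
    for (k in seq_along(info)) {
      m <- info[[k]]
      if (m$mod_class == "fixed") {
        stop("fixed modification '", m$name, "' cannot be placed as a variable mod",
             call. = FALSE)
      }
      if (!res[mods$position[k]] %in% m$targets) {
        stop(m$name, " at position ", mods$position[k], " targets ",
             paste(m$targets, collapse = "/"), ", found ", res[mods$position[k]],
             call. = FALSE)
      }
    }
    classes <- vapply(info, `[[`, character(1), "mod_class")
    caps <- vapply(info, `[[`, integer(1), "max_count")
    cnt <- table(mods$name)
    for (nm in names(cnt)) {
      cap <- caps[match(nm, mods$name)]
      if (!is.na(cap) && cnt[[nm]] > cap) {
        stop("more than ", cap, " ", nm, " modifications", call. = FALSE)
      }
    }
    if (sum(classes == "common") > .max_common_mods) {
      stop("more than ", .max_common_mods, " common modifications", call. = FALSE)
    }
    if (sum(classes == "rare") > .max_rare_mods) {
      stop("more than ", .max_rare_mods, " rare modification(s)", call. = FALSE)
    }
    mods$delta <- vapply(info, `[[`, numeric(1), "delta")
  }

  structure(list(base_id = base_id, sequence = sequence, mods = mods),
            class = "proteoform")
}

#' Parse a positioned-modification string
#'
#' Accepts semicolon-separated tokens in either the verbose form
#' \code{"K9(Acetyl)"} or the short form \code{"K9ac"} (suffixes me1, me2,
#' me3, ac, ph, pr). Positions are 1-based H3 coordinates on the surrogate
#' sequence.
#'
#' @param s Modification string; empty string or NA means unmodified.
#' @param registry Modification registry.
#' @return Data frame with columns \code{position}, \code{name}.
#' @export
parse_mod_string <- function(s, registry = default_modifications()) {
  if (is.na(s) || !nzchar(trimws(s))) {
    return(data.frame(position = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  short_rev <- structure(names(.mod_short), names = .mod_short)
  out <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^([A-Z])([0-9]+)\\(([A-Za-z0-9]+)\\)$", tk))[[1]]
    if (length(m) == 4) {
      return(data.frame(position = as.integer(m[3]), name = m[4],
                        stringsAsFactors = FALSE))
    }
    m <- regmatches(tk, regexec("^([A-Z])([0-9]+)([a-z]+[0-9]*)$", tk))[[1]]
    if (length(m) == 4 && m[4] %in% names(short_rev)) {
      return(data.frame(position = as.integer(m[3]),
                        name = unname(short_rev[m[4]]), stringsAsFactors = FALSE))
    }
    stop("cannot parse modification token '", tk, "'", call. = FALSE)
  })
  do.call(rbind, out)
}

#' Canonical proteoform identifier
#'
#' Mods sorted by position, short suffix naming, e.g.
#' \code{H3K9acK14acK23acK27me2} (H3.3 proteoforms are prefixed
#' \code{H3.3}; the unmodified tail is \code{H3} / \code{H3.3}).
#'
#' @param p A \code{proteoform}.
#' @return Character id.
#' @export
proteoform_id <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  prefix <- if (p$base_id == "H3.3") "H3.3" else "H3"
  if (!nrow(p$mods)) return(prefix)
  res <- strsplit(p$sequence, "")[[1]]
  toks <- paste0(res[p$mods$position], p$mods$position,
                 .mod_short[p$mods$name])
  paste0(prefix, paste(toks, collapse = ""))
}

#' @export
print.proteoform <- function(x, ...) {
  cat("Proteoform", proteoform_id(x), sprintf("(%s)\n", x$base_id))
  cat(" sequence:", x$sequence, "\n")
  cat(sprintf(" neutral mass: %.5f Da, %d variable mod(s)\n",
              proteoform_neutral_mass(x), nrow(x$mods)))
  invisible(x)
}

# per-position residue masses including fixed TMT on His and variable deltas;
# the C-terminal ligation offset is returned separately (it travels with the
# C-terminal fragment series, not a residue position)
.position_masses <- function(p, registry = default_modifications()) {
  res <- strsplit(p$sequence, "")[[1]]
  m <- residue_mass(res)
  tmt <- modification_delta("TMT6plex", registry)
  m[res %in% tmt$targets] <- m[res %in% tmt$targets] + tmt$delta
  if (nrow(p$mods)) m[p$mods$position] <- m[p$mods$position] + p$mods$delta
  list(masses = m,
       cterm = modification_delta("CtermLigationOffset", registry)$delta)
}

#' Neutral monoisotopic mass of a proteoform
#'
#' Sum of residue masses plus water, plus the fixed modifications (TMT 6-plex
#' on every His, the C-terminal ligation offset) and all variable modification
#' deltas.
#'
#' @param p A \code{proteoform}.
#' @param registry Modification registry.
#' @return Monoisotopic neutral mass in Da.
#' @export
proteoform_neutral_mass <- function(p, registry = default_modifications()) {
  stopifnot(inherits(p, "proteoform"))
  pm <- .position_masses(p, registry)
  sum(pm$masses) + .mass_water + pm$cterm
}
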