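# Modification registry: the variable and fixed modification deltas of the
# tagged-tail search space. All compositional deltas are computed from
# elemental monoisotopic masses; the C-terminal ligation offset is a defined
# constant (mass difference between His and Lys + 2,3-diaminopropionamide
# left by the sortase tagging chemistry).

.formula_mass <- function(counts) sum(counts * .elements[names(counts)])

.default_mods <- local({
  mk <- function(name, delta, targets, mod_class, max_count) {
    data.frame(name = name, delta = delta,
               targets = paste(targets, collapse = ","),
               mod_class = mod_class, max_count = max_count,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("Methyl",    .formula_mass(c(C = 1, H = 2)),          c("K", "R"), "common", 3L),
    mk("Dimethyl",  .formula_mass(c(C = 2, H = 4)),          c("K", "R"), "common", 3L),
    mk("Trimethyl", .formula_mass(c(C = 3, H = 6)),          "K",         "common", 3L),
    mk("Phospho",   .formula_mass(c(H = 1, P = 1, O = 3)),   c("S", "T"), "common", 2L),
    mk("Acetyl",    .formula_mass(c(C = 2, H = 2, O = 1)),   "K",         "common", 5L),
    mk("Propionyl", .formula_mass(c(C = 3, H = 4, O = 1)),   "K",         "rare",   1L),
    mk("TMT6plex",  .formula_mass(c(C = 8, C13 = 4, H = 20, N = 1, N15 = 1, O = 2)),
       "H", "fixed", NA_integer_),
    mk("CtermLigationOffset", 76.1001, "Cterm", "fixed", NA_integer_)
  )
})

# per-peptide combinatorial caps across the variable classes
.max_common_mods <- 6L
.max_rare_mods <- 1L

#' Default modification registry
#'
#' The registry of modification mass deltas used for the tagged H3 tail search
#' space: the methyl series (max 3 each on K/R, trimethyl K only), phospho on
#' S/T (max 2), acetyl on K (max 5), rare propionyl on K (max 1), fixed TMT
#' 6-plex on His, and the fixed +76.1001 Da C-terminal ligation offset. At most
#' 6 common and 1 rare variable modification are allowed per peptide.
#'
#' @return A data frame with columns \code{name}, \code{delta} (monoisotopic
#'   Da), \code{targets} (comma-separated residue codes, or \code{"Cterm"}),
#'   \code{mod_class} (\code{fixed}/\code{common}/\code{rare}) and
#'   \code{max_count} (NA for fixed modifications).
#' @export
default_modifications <- function() .default_mods

#' Look up a modification by name
#'
#' @param name Modification name, e.g. \code{"Acetyl"}.
#' @param registry Modification registry data frame
#'   (default \code{\link{default_modifications}()}).
#' @return A one-row list with fields \code{name}, \code{delta}, \code{targets}
#'   (character vector), \code{mod_class}, \code{max_count}.
#' @export
modification_delta <- function(name, registry = default_modifications()) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unregistered modification: ", name, call. = FALSE)
  list(
    name      = registry$name[i],
    delta     = registry$delta[i],
    targets   = strsplit(registry$targets[i], ",", fixed = TRUE)[[1]],
    mod_class = registry$mod_class[i],
    max_count = registry$max_count[i]
  )
}

#' Read a modification registry from a YAML config
#'
#' The shipped default registry is available as
#' \code{system.file("extdata", "modifications.yaml", package = "midtail")};
#' users may extend or replace it.
#'
#' @param path Path to a YAML file: a list of entries with fields
#'   \code{name}, \code{delta}, \code{targets}, \code{mod_class},
#'   \code{max_count} (omit for fixed modifications).
#' @return Registry data frame as in \code{\link{default_modifications}}.
#' @export
read_modification_registry <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) stop("empty modification registry: ", path, call. = FALSE)
  out <- do.call(rbind, lapply(y, function(e) {
    for (f in c("name", "delta", "targets", "mod_class")) {
      if (is.null(e[[f]])) stop("registry entry missing field '", f, "'", call. = FALSE)
    }
    data.frame(
      name = as.character(e$name), delta = as.numeric(e$delta),
      targets = paste(as.character(e$targets), collapse = ","),
      mod_class = as.character(e$mod_class),
      max_count = if (is.null(e$max_count)) NA_integer_ else as.integer(e$max_count),
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(out$name)) stop("duplicate modification names in registry", call. = FALSE)
  out
}
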