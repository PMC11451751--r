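# Monoisotopic mass scale: elemental masses (IUPAC/CODATA), residue
# compositions, and physical constants used throughout the package.

.elements <- c(
  H   = 1.00782503207,
  C   = 12.0,
  N   = 14.0030740048,
  O   = 15.9949146196,
  S   = 31.97207100,
  P   = 30.97376163,
  C13 = 13.0033548378,
  N15 = 15.0001088989
)

# C, H, N, O, S atom counts of the 20 canonical amino acid residues
# (polymerized form, i.e. minus water).
.residue_composition <- list(
  A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0)
)

.residue_masses <- vapply(.residue_composition, function(x) {
  sum(x * .elements[c("C", "H", "N", "O", "S")])
}, numeric(1))

.mass_water  <- 2 * .elements[["H"]] + .elements[["O"]]
.mass_proton <- 1.00727646677
.mass_nh3    <- .elements[["N"]] + 3 * .elements[["H"]]
.mass_h2o    <- .mass_water
.mass_co     <- .elements[["C"]] + .elements[["O"]]
.c13_spacing <- .elements[["C13"]] - .elements[["C"]]
# z-dot (radical z) ion: y minus NH3 plus a hydrogen retained on the radical
.mass_zdot_offset <- .mass_nh3 - .elements[["H"]]

#' Monoisotopic mass of an amino acid residue
#'
#' Residue (polymerized, water-free) monoisotopic masses computed from
#' elemental compositions and IUPAC atomic masses.
#'
#' @param code Character vector of single-letter residue codes.
#' @return Numeric vector of monoisotopic residue masses in Da.
#' @examples
#' residue_mass("G")  # 57.02146
#' residue_mass(c("K", "H"))
#' @export
residue_mass <- function(code) {
  code <- as.character(code)
  bad <- !code %in% names(.residue_masses)
  if (any(bad)) {
    stop("unknown residue code(s): ", paste(unique(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(.residue_masses[code])
}

#' Residue mass table and mass-scale constants
#'
#' @return A list with components \code{residues} (named numeric vector of the
#'   20 canonical residue masses), \code{water_mass}, \code{proton_mass} and
#'   \code{c13_c12_spacing}, all monoisotopic Da.
#' @export
residue_table <- function() {
  list(
    residues        = .residue_masses,
    water_mass      = .mass_water,
    proton_mass     = .mass_proton,
    c13_c12_spacing = .c13_spacing
  )
}

#' Relative mass error in parts per million
#'
#' @param theoretical Theoretical mass or m/z (must be > 0).
#' @param observed Observed mass or m/z.
#' @return Signed ppm error \code{1e6 * (observed - theoretical)/theoretical}.
#' @examples
#' ppm_error(500, 500.005)  # +10 ppm
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0", call. = FALSE)
  1e6 * (observed - theoretical) / theoretical
}
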