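# Theoretical EThcD fragment ladders (a/b/c/y/z ions, neutral losses,
# multiple charges) for a proteoform.

.series_levels <- c("a", "b", "c", "y", "z")
.loss_levels <- c("none", "NH3", "H2O")
.loss_masses <- c(none = 0, NH3 = .mass_nh3, H2O = .mass_h2o)

#' Theoretical fragment ladder of a proteoform
#'
#' Generates all a/b/c/y/z fragment ions of the (fixed- and variable-)
#' modified peptide at charges \code{1..max_charge}, with and without each
#' configured neutral loss. Ion conventions: \code{b_i} is the N-terminal
#' residue sum; \code{a_i = b_i - CO}; \code{c_i = b_i + NH3};
#' \code{y_j} is the C-terminal residue sum plus water plus the fixed
#' C-terminal ligation offset; z ions are radical z-dot by default
#' (\code{z = y - (NH3 - H)}), plain \code{z = y - NH3} via
#' \code{z_radical = FALSE}. \code{m/z = (neutral + charge * proton)/charge}.
#'
#' Modifications N-terminal of the cleavage site appear in a/b/c masses,
#' modifications C-terminal of it in y/z masses, so complementary neutral
#' b/y pairs sum to the proteoform neutral mass.
#'
#' @param p A \code{proteoform}.
#' @param max_charge Highest fragment charge to generate (>= 1).
#' @param losses Character subset of \code{c("NH3", "H2O")}; the no-loss ions
#'   are always generated.
#' @param series Character subset of \code{c("a","b","c","y","z")}.
#' @param z_radical Use the z-dot convention (default TRUE, standard for ETD).
#' @param registry Modification registry.
#' @return Data frame with columns \code{series}, \code{index}, \code{charge},
#'   \code{loss}, \code{neutral} (Da) and \code{mz}, one row per ion.
#' @export
fragment_ladder <- function(p, max_charge = 1L,
                            losses = c("NH3", "H2O"),
                            series = c("a", "b", "c", "y", "z"),
                            z_radical = TRUE,
                            registry = default_modifications()) {
  stopifnot(inherits(p, "proteoform"))
  if (max_charge < 1L) stop("max_charge must be >= 1", call. = FALSE)
  series <- match.arg(series, .series_levels, several.ok = TRUE)
  if (length(losses)) losses <- match.arg(losses, c("NH3", "H2O"), several.ok = TRUE)

  pm <- .position_masses(p, registry)
  n <- length(pm$masses)
  if (n < 2L) stop("peptide too short to fragment", call. = FALSE)
  prefix <- cumsum(pm$masses)
  idx <- seq_len(n - 1L)

  b <- prefix[idx]
  y <- prefix[n] - prefix[n - idx] + .mass_water + pm$cterm
  base <- list(
    a = b - .mass_co,
    b = b,
    c = b + .mass_nh3,
    y = y,
    z = y - (if (z_radical) .mass_zdot_offset else .mass_nh3)
  )

  loss_set <- c("none", losses)
  blocks <- vector("list", length(series) * length(loss_set) * max_charge)
  k <- 0L
  for (s in series) {
    for (l in loss_set) {
      neutral <- base[[s]] - .loss_masses[[l]]
      for (ch in seq_len(max_charge)) {
        k <- k + 1L
        blocks[[k]] <- data.frame(
          series = s, index = idx, charge = ch, loss = l,
          neutral = neutral,
          mz = (neutral + ch * .mass_proton) / ch,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
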