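# Shared test fixtures, all built in code.

# a random valid proteoform: distinct positions, caps respected by construction
random_proteoform <- function() {
  base <- sample(c("H3.1", "H3.3"), 1)
  seq <- strsplit(h3_tail_sequence(base), "")[[1]]
  kpos <- which(seq == "K")
  rpos <- which(seq == "R")
  stpos <- which(seq %in% c("S", "T"))
  n_mods <- sample(0:4, 1)
  mods <- NULL
  used <- integer(0)
  caps <- c(Acetyl = 5, Methyl = 3, Dimethyl = 3, Trimethyl = 3,
            Propionyl = 1, Phospho = 2)
  counts <- caps * 0
  for (i in seq_len(n_mods)) {
    kind <- sample(c("K", "R", "ST"), 1, prob = c(0.6, 0.2, 0.2))
    pool <- setdiff(switch(kind, K = kpos, R = rpos, ST = stpos), used)
    if (!length(pool)) next
    pos <- if (length(pool) == 1) pool else sample(pool, 1)
    opts <- switch(kind,
                   K  = c("Acetyl", "Methyl", "Dimethyl", "Trimethyl",
                          "Propionyl"),
                   R  = c("Methyl", "Dimethyl"),
                   ST = "Phospho")
    opts <- opts[counts[opts] < caps[opts]]
    if (!length(opts)) next
    nm <- if (length(opts) == 1) opts else sample(opts, 1)
    counts[nm] <- counts[nm] + 1
    used <- c(used, pos)
    mods <- rbind(mods, data.frame(position = pos, name = nm))
  }
  proteoform(base, mods)
}

# deposit a proteoform's fragments (plus +1 companions) into a peak list
toy_spectrum <- function(p, scan_id = "s1", frags = NULL, intensity = 100,
                         max_charge = 1, iso_ratio = 0.5) {
  lad <- fragment_ladder(p, max_charge = max_charge, losses = character(0),
                         series = c("b", "c", "y", "z"))
  if (!is.null(frags)) {
    lad <- merge(lad, frags, by = c("series", "index"))
  }
  mz <- c(lad$mz, lad$mz + residue_table()$c13_c12_spacing / lad$charge)
  int <- c(rep(intensity, nrow(lad)), rep(intensity * iso_ratio, nrow(lad)))
  ms2_spectrum(scan_id, 500, 8L, mz, int)
}

# one-row PSM table entry
psm_row <- function(scan_id, base_id = "H3.1", mods = "", pep = 0.01,
                    delta_mod = 30) {
  data.frame(scan_id = scan_id, base_id = base_id, mods = mods, pep = pep,
             delta_mod = delta_mod, stringsAsFactors = FALSE)
}

# exhaustive all-pairs annotation oracle implementing the documented match
# rule directly (no interval search): for each peak and PSM, scan every
# theoretical ion and keep the best by (|ppm|, isotope-confirmed first,
# index, series a<b<c<y<z, charge, loss none<NH3<H2O)
brute_force_annotation <- function(spectrum, psms, tol_ppm = 15,
                                   max_charge = 4, losses = c("NH3", "H2O"),
                                   min_fragment_mz = 133) {
  series_rank <- c(a = 1, b = 2, c = 3, y = 4, z = 5)
  loss_rank <- c(none = 1, NH3 = 2, H2O = 3)
  spacing <- residue_table()$c13_c12_spacing
  has_iso <- function(mz, ch) {
    tgt <- mz + spacing / ch
    any(abs(1e6 * (spectrum$mz - tgt) / tgt) <= tol_ppm & spectrum$intensity > 0)
  }
  out <- NULL
  for (j in seq_len(nrow(psms))) {
    eff <- max(1, min(max_charge, spectrum$precursor_charge - 1))
    lad <- fragment_ladder(psms$proteoform[[j]], max_charge = eff,
                           losses = losses)
    for (i in seq_along(spectrum$mz)) {
      m <- spectrum$mz[i]
      if (m < min_fragment_mz) next
      best <- NULL
      for (r in seq_len(nrow(lad))) {
        ppm <- 1e6 * (m - lad$mz[r]) / lad$mz[r]
        if (abs(ppm) > tol_ppm) next
        key <- c(abs(ppm), as.numeric(!has_iso(m, lad$charge[r])),
                 lad$index[r], series_rank[[lad$series[r]]], lad$charge[r],
                 loss_rank[[lad$loss[r]]])
        if (is.null(best) || .lex_less(key, best$key)) {
          best <- list(key = key, row = r)
        }
      }
      if (!is.null(best)) {
        r <- best$row
        out <- rbind(out, data.frame(
          peak = i, psm = j, series = lad$series[r], index = lad$index[r],
          charge = lad$charge[r], loss = lad$loss[r],
          theoretical_mz = lad$mz[r], stringsAsFactors = FALSE))
      }
    }
  }
  out
}

.lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}
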