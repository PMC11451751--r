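# Seeded generator of ground-truth proteoform mixtures, chimeric charge-8
# EThcD spectra with TMT reporters, and matching PSM tables.

#' Default simulated proteoform mixture
#'
#' A five-proteoform H3.1 mixture spanning the dominant acetyl/methyl marks,
#' with fractions chosen so that the default 200-scan run allocates whole
#' scan counts per proteoform.
#'
#' @return Data frame with columns \code{base_id}, \code{mods}, \code{fraction}.
#' @export
default_mixture <- function() {
  data.frame(
    base_id = "H3.1",
    mods = c("", "K9ac", "K14ac;K23ac;K27me2", "K9ac;K14ac;K23ac;K27me2",
             "K18ac;K23ac"),
    fraction = c(0.35, 0.25, 0.20, 0.12, 0.08),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a ground-truth
#' proteoform mixture, chimeric charge-8 EThcD scans acquired at 480-540 m/z,
#' log-normal fragment intensities with +1 isotope companions, uniform noise
#' peaks, Gaussian ppm jitter, TMT 6-plex reporters with log-normal
#' multiplicative noise, per-channel loading factors, optional isotopic
#' impurity mixing, and a PSM score model in which a stated fraction of rows
#' is generated to fail the confidence filters.
#'
#' Condition effects are the TRUE log2 fold changes of proteoform fractions
#' in the non-reference condition(s); the remaining proteoforms are
#' renormalized so each channel's fractions sum to 1 (total tail amount per
#' channel is constant, as in the balanced 1:1 channel mixing of a 6-plex
#' run).
#'
#' @param seed Integer RNG seed; the same seed and config give byte-identical
#'   outputs.
#' @param mixture Data frame (\code{base_id}, \code{mods}, \code{fraction});
#'   fractions must sum to 1.
#' @param n_scans Number of MS2 scans.
#' @param chimera_rate Probability a scan carries a second co-isolated PSM.
#' @param n_fragments Fragments sampled per PSM from the charge 1-2 b/c/y/z
#'   ladder.
#' @param frag_meanlog,frag_sdlog Log-normal fragment intensity model.
#' @param isotope_plus1_ratio +1 isotopologue intensity as a fraction of the
#'   monoisotopic peak (0.45, typical of ~4 kDa peptides).
#' @param noise_peaks Uniform-m/z noise peaks per scan.
#' @param noise_intensity Length-2 range of noise peak intensities.
#' @param ppm_jitter_sd Gaussian m/z jitter, ppm.
#' @param condition_effects Named numeric: true log2 fraction shifts by
#'   proteoform id (default: the quadruply modified
#'   H3K9acK14acK23acK27me2 tail up 1.35 log2 units, a 155 percent increase).
#' @param reporter_base Mean reporter intensity for an average scan.
#' @param reporter_cv Coefficient of variation of reporter noise
#'   (log-normal).
#' @param channel_loading Per-channel loading factors (what channel
#'   normalization corrects).
#' @param design A \code{\link{run_design}}; its first channel's condition is
#'   the reference (vehicle).
#' @param impurity_matrix Forward isotopic-impurity mixing matrix applied to
#'   the true reporter signals (default: the design's, identity unless set).
#' @param fail_rate Fraction of additional PSM rows generated to fail the
#'   score filters.
#' @param registry Modification registry.
#' @return Object of class \code{"sim_config"}.
#' @export
simulation_config <- function(seed = 1L, mixture = default_mixture(),
                              n_scans = 200L, chimera_rate = 0.2,
                              n_fragments = 50L,
                              frag_meanlog = log(2000), frag_sdlog = 0.7,
                              isotope_plus1_ratio = 0.45,
                              noise_peaks = 30L, noise_intensity = c(10, 200),
                              ppm_jitter_sd = 3,
                              condition_effects = c(H3K9acK14acK23acK27me2 = log2(2.55)),
                              reporter_base = 5e4, reporter_cv = 0.3,
                              channel_loading = c(1, 0.9, 1.1, 0.95, 1.05, 1),
                              design = run_design(),
                              impurity_matrix = NULL,
                              fail_rate = 0.15,
                              registry = default_modifications()) {
  if (abs(sum(mixture$fraction) - 1) > 1e-8) {
    stop("mixture fractions must sum to 1", call. = FALSE)
  }
  if (any(mixture$fraction < 0)) stop("negative mixture fraction", call. = FALSE)
  for (r in c(chimera_rate, fail_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (isotope_plus1_ratio < 0 || isotope_plus1_ratio > 1) {
    stop("isotope_plus1_ratio must be in [0, 1]", call. = FALSE)
  }
  if (length(channel_loading) != length(design$channels)) {
    stop("channel_loading must match the design's channels", call. = FALSE)
  }
  if (is.null(impurity_matrix)) impurity_matrix <- design$impurity_matrix
  structure(list(
    seed = as.integer(seed), mixture = mixture, n_scans = as.integer(n_scans),
    chimera_rate = chimera_rate, n_fragments = as.integer(n_fragments),
    frag_meanlog = frag_meanlog, frag_sdlog = frag_sdlog,
    isotope_plus1_ratio = isotope_plus1_ratio,
    noise_peaks = as.integer(noise_peaks), noise_intensity = noise_intensity,
    ppm_jitter_sd = ppm_jitter_sd, condition_effects = condition_effects,
    reporter_base = reporter_base, reporter_cv = reporter_cv,
    channel_loading = channel_loading, design = design,
    impurity_matrix = as.matrix(impurity_matrix), fail_rate = fail_rate,
    registry = registry), class = "sim_config")
}

# largest-remainder apportionment of n into parts proportional to w
.apportion <- function(n, w) {
  q <- n * w / sum(w)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(q - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

#' Simulate a ground-truth middle-down dataset
#'
#' Generates centroided chimeric EThcD spectra (charge 8, precursors in
#' 480-540 m/z) of the configured proteoform mixture, with TMT reporter
#' peaks, +1 isotope companions, noise peaks and m/z jitter, plus a matching
#' PSM table with realistic pass/fail score distributions. Scan counts per
#' proteoform follow the across-channel mean fractions deterministically
#' (largest-remainder); chimeric second precursors are drawn at random from
#' the mixture.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param out_dir Optional directory: writes \code{spectra.tsv},
#'   \code{psms.tsv}, \code{design.yaml} and \code{truth.json}.
#' @param spectra_format \code{"tsv"} or \code{"mzML"} for the written
#'   spectra file.
#' @return Invisibly (visibly when \code{out_dir} is NULL) a list with
#'   \code{spectra} (list of \code{ms2_spectrum}), \code{psms} (validated PSM
#'   table), \code{design}, \code{truth} (fractions per condition, true log2
#'   fold changes, per-scan proteoforms, site marginals, rows generated to
#'   fail) and \code{paths} (when written).
#' @export
simulate_dataset <- function(config, out_dir = NULL,
                             spectra_format = c("tsv", "mzML")) {
  stopifnot(inherits(config, "sim_config"))
  spectra_format <- match.arg(spectra_format)
  set.seed(config$seed)
  design <- config$design
  registry <- config$registry

  pf <- lapply(seq_len(nrow(config$mixture)), function(i) {
    proteoform(config$mixture$base_id[i], config$mixture$mods[i],
               registry = registry)
  })
  ids <- vapply(pf, proteoform_id, character(1))
  names(pf) <- ids
  if (anyDuplicated(ids)) stop("duplicate proteoforms in mixture", call. = FALSE)

  # per-condition fractions: reference keeps the config fractions, shifted
  # proteoforms scale by 2^effect, the rest renormalize
  f_a <- stats::setNames(config$mixture$fraction, ids)
  eff <- config$condition_effects
  if (length(eff) && !all(names(eff) %in% ids)) {
    stop("condition_effects name proteoforms absent from the mixture: ",
         paste(setdiff(names(eff), ids), collapse = ", "), call. = FALSE)
  }
  f_b <- f_a
  if (length(eff)) {
    f_b[names(eff)] <- f_a[names(eff)] * 2^eff
    shifted_mass <- sum(f_b[names(eff)])
    if (shifted_mass >= 1) stop("condition effects push fractions past 1", call. = FALSE)
    others <- setdiff(ids, names(eff))
    f_b[others] <- f_a[others] * (1 - shifted_mass) / (1 - sum(f_a[names(eff)]))
  }
  fbar <- (f_a + f_b) / 2
  true_log2fc <- log2(f_b / f_a)

  ref_cond <- design$conditions[[design$channels[1]]]
  cond_frac <- function(cond, id) if (cond == ref_cond) f_a[[id]] else f_b[[id]]

  counts <- .apportion(config$n_scans, fbar)
  primary <- sample(rep(ids, counts))
  rep_sdlog <- sqrt(log(1 + config$reporter_cv^2))
  tmt_lo <- min(design$reporter_mz) * (1 - 1e-4)

  ladders <- lapply(pf, function(p) {
    l <- fragment_ladder(p, max_charge = 2L, losses = character(0),
                         series = c("b", "c", "y", "z"), registry = registry)
    # keep fragments clear of the reporter region
    l[l$mz > 140, , drop = FALSE]
  })

  spectra <- vector("list", config$n_scans)
  scan_pfs <- vector("list", config$n_scans)
  psm_rows <- list()
  verbose_mods <- function(p) {
    if (!nrow(p$mods)) return("")
    res <- strsplit(p$sequence, "")[[1]]
    paste0(res[p$mods$position], p$mods$position, "(", p$mods$name, ")",
           collapse = ";")
  }

  for (s in seq_len(config$n_scans)) {
    sid <- sprintf("scan%04d", s)
    this <- primary[s]
    if (stats::runif(1) < config$chimera_rate) {
      this <- c(this, sample(ids, 1, prob = fbar))
    }
    scan_pfs[[s]] <- this

    # fragment peaks, merged across co-isolated PSMs at identical theoretical m/z
    frag <- do.call(rbind, lapply(this, function(id) {
      l <- ladders[[id]]
      take <- sample(nrow(l), min(config$n_fragments, nrow(l)))
      data.frame(mz = l$mz[take], charge = l$charge[take],
                 intensity = stats::rlnorm(length(take), config$frag_meanlog,
                                           config$frag_sdlog))
    }))
    key <- as.character(round(frag$mz * 1e7))
    grp <- split(seq_len(nrow(frag)), key)
    agg_i <- vapply(grp, function(ii) sum(frag$intensity[ii]), numeric(1))
    agg_mz <- vapply(grp, function(ii) frag$mz[ii[1]], numeric(1))
    mono_mz <- agg_mz *
      (1 + stats::rnorm(length(agg_mz), 0, config$ppm_jitter_sd) * 1e-6)
    mono_i <- agg_i
    # one +1 companion per distinct charge present in a merged peak, so the
    # isotope check holds whichever co-incident species the annotator assigns
    iso <- do.call(rbind, lapply(seq_along(grp), function(g) {
      cbind(mz = mono_mz[g] + .c13_spacing / unique(frag$charge[grp[[g]]]),
            intensity = mono_i[g] * config$isotope_plus1_ratio)
    }))
    iso_mz <- iso[, "mz"]
    iso_i <- iso[, "intensity"]

    # reporters: true per-channel signal, forward impurity mixing
    rel <- vapply(design$channels, function(ch) {
      mean(vapply(this, function(id)
        cond_frac(design$conditions[[ch]], id) / fbar[[id]], numeric(1)))
    }, numeric(1))
    true_rep <- config$reporter_base * config$channel_loading * rel *
      exp(stats::rnorm(length(rel), 0, rep_sdlog))
    obs_rep <- as.numeric(config$impurity_matrix %*% true_rep)
    rep_mz <- design$reporter_mz *
      (1 + stats::rnorm(length(obs_rep), 0, config$ppm_jitter_sd) * 1e-6)

    noise_mz <- stats::runif(config$noise_peaks, 150, 1400)
    noise_i <- stats::runif(config$noise_peaks, config$noise_intensity[1],
                            config$noise_intensity[2])

    spectra[[s]] <- ms2_spectrum(
      sid, stats::runif(1, 480, 540), 8L,
      c(mono_mz, iso_mz, rep_mz, noise_mz),
      c(mono_i, iso_i, obs_rep, noise_i))

    for (id in this) {
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        scan_id = sid, base_id = pf[[id]]$base_id,
        mods = verbose_mods(pf[[id]]),
        pep = stats::runif(1, 0.001, 0.04),
        delta_mod = stats::runif(1, 15, 60),
        fail = FALSE, stringsAsFactors = FALSE)
    }
  }

  # extra rows generated to fail the confidence filters
  n_true <- length(psm_rows)
  n_fail <- round(config$fail_rate * n_true)
  for (k in seq_len(n_fail)) {
    id <- sample(ids, 1, prob = fbar)
    bad_pep <- stats::runif(1) < 0.5
    psm_rows[[length(psm_rows) + 1L]] <- data.frame(
      scan_id = sprintf("scan%04d", sample(config$n_scans, 1)),
      base_id = pf[[id]]$base_id, mods = verbose_mods(pf[[id]]),
      pep = if (bad_pep) stats::runif(1, 0.06, 0.5) else stats::runif(1, 0.001, 0.04),
      delta_mod = if (bad_pep) stats::runif(1, 15, 60) else stats::runif(1, 0, 9.5),
      fail = TRUE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, psm_rows)
  ord <- order(tab$scan_id, tab$fail, tab$mods)
  tab <- tab[ord, , drop = FALSE]
  fail_flag <- tab$fail
  psms <- psms_from_table(tab[, c("scan_id", "base_id", "mods", "pep",
                                  "delta_mod")], registry)

  site_truth <- marginalize_sites(
    data.frame(proteoform_id = ids, abundance = unname(fbar),
               stringsAsFactors = FALSE), proteoforms = pf)

  truth <- list(
    mixture_fractions = fbar, f_vehicle = f_a, f_treated = f_b,
    true_log2fc = true_log2fc, reference_condition = ref_cond,
    scan_proteoforms = stats::setNames(scan_pfs,
                                       sprintf("scan%04d", seq_len(config$n_scans))),
    psm_generated_to_fail = fail_flag,
    site_marginals = site_truth,
    channel_loading = stats::setNames(config$channel_loading, design$channels),
    proteoforms = pf)

  out <- list(spectra = spectra, psms = psms, design = design, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    spath <- file.path(out_dir, paste0("spectra.",
                                       if (spectra_format == "mzML") "mzML" else "tsv"))
    write_spectra(spectra, spath, format = spectra_format)
    ppath <- file.path(out_dir, "psms.tsv")
    ptab <- tab[, c("scan_id", "base_id", "mods", "pep", "delta_mod")]
    ptab$pep <- sprintf("%.10g", ptab$pep)
    ptab$delta_mod <- sprintf("%.10g", ptab$delta_mod)
    utils::write.table(ptab, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
    dpath <- file.path(out_dir, "design.yaml")
    write_run_design(design, dpath)
    tpath <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(
      mixture_fractions = as.list(fbar), f_vehicle = as.list(f_a),
      f_treated = as.list(f_b), true_log2fc = as.list(true_log2fc),
      reference_condition = ref_cond,
      scan_proteoforms = truth$scan_proteoforms,
      psm_generated_to_fail = fail_flag,
      site_marginals = site_truth,
      channel_loading = as.list(truth$channel_loading)),
      tpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- c(spectra = spath, psms = ppath, design = dpath,
                   truth = tpath)
  }
  invisible(out)
}

#' Simulate a bottom-up site-level PTM abundance table
#'
#' Site marginals of the true mixture plus Gaussian noise, clipped to [0, 1];
#' a stand-in for an external bottom-up (DIA) site-abundance export.
#'
#' @param truth Ground truth from \code{\link{simulate_dataset}}.
#' @param sigma Gaussian noise standard deviation (default 0.05).
#' @param seed Optional RNG seed.
#' @return Data frame with columns \code{label}, \code{position}, \code{mod},
#'   \code{abundance}.
#' @export
simulate_bottom_up <- function(truth, sigma = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- truth$site_marginals
  out$abundance <- pmin(1, pmax(0, out$abundance +
                                  stats::rnorm(nrow(out), 0, sigma)))
  out
}
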