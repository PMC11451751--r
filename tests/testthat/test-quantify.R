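# PSM filtering, annotation, isotope confirmation, attribution, abundance,
# reporters.

test_that("score filtering keeps boundary values and counts correctly", {
  tab <- rbind(psm_row("s1", pep = 0.05, delta_mod = 10),   # boundary: kept
               psm_row("s2", pep = 0.06, delta_mod = 50),   # pep fails
               psm_row("s3", pep = 0.01, delta_mod = 9.9))  # delta fails
  psms <- psms_from_table(tab)
  acc <- filter_psms(psms)
  expect_identical(acc$scan_id, "s1")
  expect_identical(attr(acc, "n_dropped"), 2L)

  # brute-force count on a generated table
  set.seed(31)
  tab2 <- psm_row(sprintf("t%03d", 1:100), pep = runif(100, 0, 0.1),
                  delta_mod = runif(100, 0, 20))
  psms2 <- psms_from_table(tab2)
  expected <- sum(tab2$pep <= 0.05 & tab2$delta_mod >= 10)
  expect_identical(nrow(filter_psms(psms2)), expected)
})

test_that("peaks match their fragments at the observed ppm error", {
  psms <- filter_psms(psms_from_table(psm_row("s1", mods = "K9ac")))
  p <- psms$proteoform[[1]]
  lad <- fragment_ladder(p, max_charge = 1, losses = character(0))
  c5 <- lad$mz[lad$series == "c" & lad$index == 5 & lad$charge == 1]
  spacing <- residue_table()$c13_c12_spacing
  sp <- ms2_spectrum("s1", 500, 8L,
                     c(c5 * (1 + 5e-6), c5 * (1 + 5e-6) + spacing, 900.0),
                     c(100, 40, 10))
  a <- annotate_spectrum(sp, psms)
  m <- a$matches
  expect_identical(nrow(m), 1L)  # isotope companion and far peak unmatched
  expect_identical(m$series, "c")
  expect_identical(m$index, 5L)
  expect_equal(m$ppm, 5, tolerance = 0.01)
  expect_true(m$isotope_confirmed)
})

test_that("exact ties resolve to the lower-index, earlier-series fragment", {
  # the c_i - NH3 ion coincides exactly with b_i: a peak there must be
  # reported as the b ion without neutral loss
  psms <- filter_psms(psms_from_table(psm_row("s1")))
  lad <- fragment_ladder(psms$proteoform[[1]], max_charge = 1)
  b3 <- lad$mz[lad$series == "b" & lad$index == 3 & lad$charge == 1 &
                 lad$loss == "none"]
  sp <- ms2_spectrum("s1", 500, 8L, b3, 100)
  m <- annotate_spectrum(sp, psms)$matches
  expect_identical(nrow(m), 1L)
  expect_identical(m$series, "b")
  expect_identical(m$loss, "none")
  expect_identical(m$index, 3L)
})

test_that("chimeric spectra list every PSM sharing a peak", {
  tab <- rbind(psm_row("s1", mods = "K9ac"),
               psm_row("s1", mods = "K9ac;K14ac"))
  psms <- filter_psms(psms_from_table(tab))
  # c5 is N-terminal of both mods: identical m/z in both ladders
  lad <- fragment_ladder(psms$proteoform[[1]], max_charge = 1,
                         losses = character(0))
  c5 <- lad$mz[lad$series == "c" & lad$index == 5 & lad$charge == 1]
  spacing <- residue_table()$c13_c12_spacing
  sp <- ms2_spectrum("s1", 500, 8L, c(c5, c5 + spacing), c(100, 45))
  a <- annotate_spectrum(sp, psms)
  shared <- a$matches[a$matches$peak == 1L, ]
  expect_identical(nrow(shared), 2L)
  expect_setequal(shared$psm, 1:2)
})

test_that("isotope confirmation requires the +1 companion at the spacing", {
  spacing <- residue_table()$c13_c12_spacing
  sp1 <- ms2_spectrum("s", 500, 8L, c(400, 400 + spacing), c(100, 40))
  expect_true(confirm_isotope(sp1, 400, 1L))
  sp2 <- ms2_spectrum("s", 500, 8L, 400, 100)             # lone peak
  expect_false(confirm_isotope(sp2, 400, 1L))
  sp3 <- ms2_spectrum("s", 500, 8L, c(400, 400 + 1.5 * spacing), c(100, 40))
  expect_false(confirm_isotope(sp3, 400, 1L))             # wrong spacing
  # charge-2 fragment: companion at half spacing
  sp4 <- ms2_spectrum("s", 500, 8L, c(400, 400 + spacing / 2), c(100, 40))
  expect_true(confirm_isotope(sp4, 400, 2L))
  expect_false(confirm_isotope(sp4, 400, 1L))
})

test_that("shared-ion intensity splits equally and conserves totals", {
  tab <- rbind(psm_row("s1", mods = "K9ac"),
               psm_row("s1", mods = "K14ac"))
  psms <- filter_psms(psms_from_table(tab))
  lads <- lapply(psms$proteoform, fragment_ladder, max_charge = 1,
                 losses = character(0))
  cmz <- function(l, i) l$mz[l$series == "c" & l$index == i & l$charge == 1]
  spacing <- residue_table()$c13_c12_spacing
  shared <- cmz(lads[[1]], 5)                 # identical in both (before K9)
  u1 <- cmz(lads[[1]], 11)                    # carries K9ac but not K14ac
  expect_equal(cmz(lads[[2]], 5), shared, tolerance = 1e-9)
  sp <- ms2_spectrum("s1", 500, 8L,
                     c(shared, shared + spacing, u1, u1 + spacing),
                     c(100, 45, 300, 120))
  a <- annotate_spectrum(sp, psms)
  att <- attribute_intensity(a)
  got <- setNames(att$intensity, att$proteoform_id)
  expect_equal(got[["H3K9ac"]], 350)   # 300 unique + 100/2 shared
  expect_equal(got[["H3K14ac"]], 50)
  confirmed <- a$matches[a$matches$isotope_confirmed, ]
  expect_equal(sum(att$intensity),
               sum(sp$intensity[unique(confirmed$peak)]))
})

test_that("unconfirmed matches contribute nothing and empty scans drop out", {
  psms <- filter_psms(psms_from_table(psm_row("s1")))
  lad <- fragment_ladder(psms$proteoform[[1]], max_charge = 1,
                         losses = character(0))
  c5 <- lad$mz[lad$series == "c" & lad$index == 5 & lad$charge == 1]
  sp <- ms2_spectrum("s1", 500, 8L, c5, 100)  # no +1 companion
  a <- annotate_spectrum(sp, psms)
  att <- attribute_intensity(a)
  expect_equal(att$intensity, 0)
  expect_warning(ab <- proteoform_abundance(att), "no confirmed")
  expect_identical(nrow(ab), 0L)
})

test_that("abundance is the attributed-intensity fraction", {
  att <- data.frame(scan_id = c("a", "b", "b"), psm = c(1L, 1L, 2L),
                    proteoform_id = c("H3K9ac", "H3K9ac", "H3"),
                    intensity = c(200, 100, 100))
  ab <- proteoform_abundance(att)
  expect_equal(ab$abundance[ab$proteoform_id == "H3K9ac"], 0.75)
  expect_equal(ab$abundance[ab$proteoform_id == "H3"], 0.25)
  expect_identical(ab$n_scans[ab$proteoform_id == "H3K9ac"], 2L)
  expect_equal(sum(ab$abundance), 1)
  one <- proteoform_abundance(att[1, ])
  expect_equal(one$abundance, 1)
})

test_that("reporter extraction finds channels within tolerance only", {
  d <- run_design()
  rmz <- d$reporter_mz
  mz <- c(unname(rmz[c("126", "127", "129", "130", "131")]),
          rmz[["128"]] * (1 + 30e-6))   # 128 present only as a 30 ppm decoy
  sp <- ms2_spectrum("s", 500, 8L, mz, c(10, 20, 30, 40, 50, 60))
  r <- extract_reporters(sp, d, tol_ppm = 15)
  expect_identical(names(r), d$channels)
  expect_true(is.na(r[["128"]]))
  expect_equal(unname(r[c("126", "127", "129", "130", "131")]),
               c(10, 20, 30, 40, 50))
})

test_that("impurity correction inverts forward mixing and clips negatives", {
  x <- c(100, 200, 50, 80, 120, 90)
  names(x) <- as.character(126:131)
  expect_equal(correct_impurities(x, diag(6)), x)

  m <- diag(6) * 0.9
  m[cbind(2:6, 1:5)] <- 0.05
  m[cbind(1:5, 2:6)] <- 0.05
  mixed <- as.numeric(m %*% x)
  names(mixed) <- names(x)
  rec <- correct_impurities(mixed, m)
  expect_equal(rec, x, tolerance = 1e-9)

  y <- c(0, 100); names(y) <- c("a", "b")
  m2 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2)
  expect_warning(z <- correct_impurities(y, m2), "clipped")
  expect_true(all(z >= 0))

  expect_error(correct_impurities(x, matrix(1, 6, 6)), "singular")
})

test_that("channel normalization equalizes the channel statistic", {
  mat <- rbind(c(120, 40), c(80, 60))
  colnames(mat) <- c("A", "B")
  nn <- normalize_channels(mat, "mean")
  expect_equal(unname(nn$factors), c(1, 2))  # means 100 and 50
  expect_equal(mean(nn$normalized[, "A"]), mean(nn$normalized[, "B"]))
  # balanced input is untouched
  bal <- rbind(c(10, 10), c(30, 30))
  expect_equal(normalize_channels(bal)$normalized, bal)
  # symmetric data: mean and median give identical factors
  sym <- rbind(c(10, 5), c(20, 10), c(30, 15))
  expect_equal(normalize_channels(sym, "mean")$factors,
               normalize_channels(sym, "median")$factors)
  # dead channel excluded with warning
  dead <- cbind(A = c(10, 20), B = c(NA, NA))
  expect_warning(nz <- normalize_channels(dead), "excluded")
  expect_equal(unname(nz$factors), c(1, 1))
})

test_that("reporter eligibility needs min reporters in every condition", {
  d <- run_design()
  mk <- function(present) {
    v <- rep(NA_real_, 6); names(v) <- d$channels
    v[present] <- 100
    v
  }
  mat <- rbind(mk(c("126", "127", "129", "130")),   # 2 per condition: kept
               mk(c("126", "129", "130", "131")),   # 1 vehicle: dropped
               mk(d$channels))                       # all: kept
  expect_identical(reporter_quant_filter(mat, d), c(TRUE, FALSE, TRUE))
  expect_identical(reporter_quant_filter(mat, d, min_per_condition = 3),
                   c(FALSE, FALSE, TRUE))
})

test_that("annotation agrees with an exhaustive all-pairs search", {
  set.seed(41)
  for (rep in 1:6) {
    tab <- rbind(psm_row("s1", mods = "K9ac"),
                 psm_row("s1", mods = "K14ac;K23ac"))
    psms <- filter_psms(psms_from_table(tab))
    # up to 30 peaks: some near fragments (jittered), some random
    lad <- fragment_ladder(psms$proteoform[[sample(2, 1)]], max_charge = 2)
    pick <- sample(nrow(lad), 12)
    mz <- c(lad$mz[pick] * (1 + rnorm(12, 0, 6e-6)),
            runif(10, 150, 3000))
    sp <- ms2_spectrum("s1", 500, 8L, mz, runif(length(mz), 10, 100))
    a <- annotate_spectrum(sp, psms)
    o <- brute_force_annotation(sp, psms)
    got <- a$matches[order(a$matches$peak, a$matches$psm),
                     c("peak", "psm", "series", "index", "charge", "loss")]
    if (is.null(o)) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- o[order(o$peak, o$psm),
                c("peak", "psm", "series", "index", "charge", "loss")]
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("loosening the tolerance never loses matches", {
  set.seed(51)
  psms <- filter_psms(psms_from_table(psm_row("s1", mods = "K9ac")))
  lad <- fragment_ladder(psms$proteoform[[1]], max_charge = 2)
  pick <- sample(nrow(lad), 15)
  sp <- ms2_spectrum("s1", 500, 8L,
                     lad$mz[pick] * (1 + rnorm(15, 0, 8e-6)),
                     runif(15, 10, 100))
  n_prev <- -1L
  for (tol in c(2, 5, 10, 15, 25)) {
    n <- nrow(annotate_spectrum(sp, psms, tol_ppm = tol)$matches)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})
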