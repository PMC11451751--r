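# Differential statistics, site marginalization, bottom-up comparison.

make_cl <- function(ids, vehicle, treated) {
  # one row per observation; vehicle/treated are lists of numeric vectors
  do.call(rbind, lapply(seq_along(ids), function(i) {
    rbind(
      data.frame(proteoform_id = ids[i], scan_id = "x", channel = "126",
                 condition = "vehicle", log2_signal = vehicle[[i]]),
      data.frame(proteoform_id = ids[i], scan_id = "x", channel = "129",
                 condition = "treated", log2_signal = treated[[i]]))
  }))
}

test_that("log2 fold change is the difference of condition means", {
  cl <- make_cl("H3K9ac", list(c(5, 6, 7)), list(c(5, 6, 7)))
  d <- group_and_test(cl, vehicle = "vehicle")
  expect_equal(d$log2fc, 0)

  cl2 <- make_cl("H3K9ac", list(c(5, 6, 7)), list(c(6, 7, 8)))
  d2 <- group_and_test(cl2, vehicle = "vehicle")
  expect_equal(d2$log2fc, 1)
  # textbook Welch statistic on 3v3, computed by hand in the test
  x <- c(6, 7, 8); y <- c(5, 6, 7)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  tstat <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(d2$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_identical(d2$n_vehicle, 3L)
  expect_identical(d2$n_treated, 3L)
})

test_that("swapping condition labels negates log2fc, keeps p-values", {
  set.seed(61)
  ids <- sprintf("pf%02d", 1:8)
  veh <- replicate(8, rnorm(5, 10), simplify = FALSE)
  trt <- replicate(8, rnorm(5, 10.5), simplify = FALSE)
  cl <- make_cl(ids, veh, trt)
  a <- group_and_test(cl, vehicle = "vehicle")
  b <- group_and_test(cl, vehicle = "treated")
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p_value, a$p_value)
  expect_identical(b$significant, a$significant)
})

test_that("under-observed proteoforms are excluded, not tested", {
  cl <- rbind(make_cl("ok", list(c(1, 2, 3)), list(c(2, 3, 4))),
              make_cl("thin", list(1), list(c(2, 3))))
  d <- group_and_test(cl, vehicle = "vehicle")
  expect_identical(d$proteoform_id, "ok")
  expect_identical(attr(d, "not_tested"), "thin")
})

test_that("significance flag is strict p < alpha and q is reported", {
  set.seed(62)
  ids <- sprintf("pf%02d", 1:20)
  veh <- replicate(20, rnorm(4), simplify = FALSE)
  trt <- replicate(20, rnorm(4), simplify = FALSE)
  d <- group_and_test(make_cl(ids, veh, trt), vehicle = "vehicle")
  expect_identical(d$significant, !is.na(d$p_value) & d$p_value < 0.05)
  expect_equal(d$q_value, p.adjust(d$p_value, "BH"))
  v <- volcano_table(d)
  expect_identical(nrow(v), nrow(d))
  expect_equal(v$neg_log10_p,
               -log10(d$p_value[match(v$proteoform_id, d$proteoform_id)]))
  expect_identical(nrow(volcano_table(d[0, ])), 0L)
})

test_that("site marginals sum proteoform abundances carrying each mark", {
  pf <- list(
    H3K9ac = proteoform("H3.1", "K9ac"),
    H3K9acK14ac = proteoform("H3.1", "K9ac;K14ac"),
    H3 = proteoform("H3.1"))
  ab <- data.frame(proteoform_id = names(pf), abundance = c(0.3, 0.2, 0.5))
  m <- marginalize_sites(ab, proteoforms = pf)
  expect_equal(m$abundance[m$label == "K9ac"], 0.5)
  expect_equal(m$abundance[m$label == "K14ac"], 0.2)
  mu <- marginalize_sites(ab, proteoforms = pf, include_unmodified = TRUE)
  expect_equal(mu$abundance[mu$label == "K9un"], 0.5)
  expect_equal(mu$abundance[mu$label == "K14un"], 0.8)

  # a single unmodified proteoform has no modified site levels
  m0 <- marginalize_sites(data.frame(proteoform_id = "H3", abundance = 1),
                          proteoforms = pf["H3"])
  expect_identical(nrow(m0), 0L)
})

test_that("site marginalization is linear and matches brute enumeration", {
  set.seed(63)
  pf <- list()
  while (length(pf) < 10) {
    p <- random_proteoform()
    pf[[proteoform_id(p)]] <- p
  }
  w <- runif(10); w <- w / sum(w)
  ab <- data.frame(proteoform_id = names(pf), abundance = w)
  m <- marginalize_sites(ab, proteoforms = pf)
  # oracle: expand every (proteoform, mod) pair and tapply
  rows <- do.call(rbind, lapply(seq_along(pf), function(i) {
    p <- pf[[i]]
    if (!nrow(p$mods)) return(NULL)
    res <- strsplit(p$sequence, "")[[1]]
    sh <- c(Methyl = "me1", Dimethyl = "me2", Trimethyl = "me3",
            Phospho = "ph", Acetyl = "ac", Propionyl = "pr")
    data.frame(label = paste0(res[p$mods$position], p$mods$position,
                              sh[p$mods$name]), w = w[i])
  }))
  oracle <- tapply(rows$w, rows$label, sum)
  expect_setequal(m$label, names(oracle))
  expect_equal(m$abundance, as.numeric(oracle[m$label]), tolerance = 1e-12)

  # linearity: marginals of a 50/50 blend = blend of marginals
  ab2 <- ab; ab2$abundance <- rev(w)
  blend <- ab; blend$abundance <- (w + rev(w)) / 2
  m1 <- marginalize_sites(ab, proteoforms = pf)
  m2 <- marginalize_sites(ab2, proteoforms = pf)
  mb <- marginalize_sites(blend, proteoforms = pf)
  expect_equal(mb$abundance,
               (m1$abundance[match(mb$label, m1$label)] +
                  m2$abundance[match(mb$label, m2$label)]) / 2,
               tolerance = 1e-12)
})

test_that("bottom-up comparison computes Pearson r over shared labels", {
  mid <- data.frame(label = c("K9ac", "K14ac", "K27me2", "K18ac"),
                    abundance = c(0.5, 0.3, 0.2, 0.1))
  expect_equal(compare_bottom_up(mid, mid)$r, 1)
  anti <- data.frame(label = c("K9ac", "K14ac", "K27me2"),
                     abundance = 1 - c(0.5, 0.3, 0.2))
  expect_equal(compare_bottom_up(mid[1:3, ], anti)$r, -1)
  expect_error(compare_bottom_up(mid[1:2, ], mid[1:2, ]), "fewer than 3")

  set.seed(64)
  noisy <- mid
  noisy$abundance <- pmin(1, pmax(0, mid$abundance + rnorm(4, 0, 0.05)))
  r <- compare_bottom_up(mid, noisy)$r
  expect_gt(r, 0.6)

  # per-condition when both tables carry conditions
  mid2 <- rbind(cbind(mid, condition = "vehicle"),
                cbind(mid, condition = "treated"))
  out <- compare_bottom_up(mid2, mid2)
  expect_identical(nrow(out), 2L)
  expect_equal(out$r, c(1, 1))
})
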