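test_that("polarization follows the ancestral allele and skips unusable records", {
  v <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                  af = c(0.02, 0.02, 0.3, 0.5),
                  aa = c("A", "G", ".", "T"), stringsAsFactors = FALSE)
  p <- polarize_variants(v)
  expect_equal(p$daf, c(0.02, 0.98, NA, NA))
  expect_equal(attr(p, "n_skipped"), 2)
  # symmetry: swapping ref/alt and flipping AF leaves daf unchanged
  withr::with_seed(6, {
    w <- data.frame(chrom = "chr1", pos = 1:50,
                    ref = sample(c("A", "C"), 50, TRUE), alt = "G",
                    af = round(stats::runif(50), 3),
                    stringsAsFactors = FALSE)
    w$aa <- ifelse(stats::runif(50) < 0.5, w$ref, w$alt)
  })
  flipped <- transform(w, ref = alt, alt = ref, af = 1 - af)
  expect_equal(polarize_variants(w)$daf, polarize_variants(flipped)$daf)
})

test_that("DAF spectra count low-frequency variants inside regions", {
  regions <- simple_enh(c(0, 1000), c(100, 1100), id = c("r1", "r2"))
  v <- data.frame(chrom = "chr1", pos = c(50, 1050, 5000),
                  ref = "A", alt = "G", af = c(0.01, 0.5, 0.01),
                  aa = "A", stringsAsFactors = FALSE)
  sp <- daf_spectrum(regions, polarize_variants(v))
  expect_equal(sp$total_count, 2)      # the 5000 variant is outside
  expect_equal(sp$low_freq_count, 1)
  expect_equal(sp$fraction, 0.5)
  # uniform DAF: low-frequency fraction matches the cutoff within CI
  withr::with_seed(10, {
    u <- data.frame(chrom = "chr1", pos = sample.int(2e6, 1e5),
                    ref = "A", alt = "G",
                    af = stats::runif(1e5), aa = "A",
                    stringsAsFactors = FALSE)
  })
  spu <- daf_spectrum(NULL, polarize_variants(u), cutoff = 0.05)
  expect_lt(abs(spu$fraction - 0.05), 3 * sqrt(0.05 * 0.95 / 1e5))
})

test_that("published low-frequency fractions are reproduced from their counts", {
  ref <- daf_spectrum_from_counts(192359, 281111, "pseudogenes")
  tab <- daf_table(list(
    daf_spectrum_from_counts(10640, 14311, "shared"),
    daf_spectrum_from_counts(4793, 6213, "class2"),
    daf_spectrum_from_counts(5006, 6701, "class3")), ref)
  expect_equal(tab$pct, c(74.3, 77.1, 74.7, 68.4))
  expect_true(all(tab$p_value[1:3] < 1e-20))
})

test_that("fixed differences floor at zero and MK regimes follow the index", {
  expect_equal(compute_D(10, 3), 7)
  expect_equal(compute_D(0, 0), 0)
  expect_warning(D <- compute_D(2, 5), "floored")
  expect_equal(D, 0)
  mk <- mk_test(10, 10, 100, 100)
  expect_equal(mk$neutrality_index, 1)
  expect_equal(mk$p_value, 1)
  expect_equal(mk$regime, "neutral")
  expect_equal(mk_test(20, 10, 100, 100)$regime, "negative")
  expect_equal(mk_test(5, 10, 100, 100)$regime, "positive")
  und <- mk_test(5, 0, 100, 100)
  expect_true(is.na(und$neutrality_index))
  expect_equal(und$reason, "zero denominator")
})

test_that("published neutrality indices are reproduced from their counts", {
  Pn <- 349789; Dn <- 442395
  expect_equal(round(mk_test(12893, 10148, Pn, Dn)$neutrality_index, 2), 1.61)
  expect_equal(round(mk_test(5736, 4312, Pn, Dn)$neutrality_index, 2), 1.68)
  expect_equal(round(mk_test(6283, 5400, Pn, Dn)$neutrality_index, 2), 1.47)
  expect_equal(mk_test(Pn, Dn, Pn, Dn)$neutrality_index, 1.00)
  expect_true(all(vapply(list(c(12893, 10148), c(5736, 4312),
                              c(6283, 5400)),
                         function(x) mk_test(x[1], x[2], Pn, Dn)$regime,
                         "") == "negative"))
})

test_that("Fisher's exact test matches enumeration and the stats oracle", {
  # exhaustive-enumeration value for a small fixed table
  expect_equal(fisher_exact_2x2(1, 9, 11, 3)$p_value,
               oracle_fisher_p(1, 9, 11, 3), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 9, 11, 3)$p_value, 0.0027594562,
               tolerance = 1e-7)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1.0)
  expect_equal(fisher_exact_2x2(1000, 1000, 1000, 1000)$p_value, 1.0)
  # random tables vs stats::fisher.test
  withr::with_seed(12, {
    tabs <- matrix(sample.int(60, 200, replace = TRUE) - 1, ncol = 4)
  })
  for (i in seq_len(nrow(tabs))) {
    a <- tabs[i, 1]; b <- tabs[i, 2]; c <- tabs[i, 3]; d <- tabs[i, 4]
    expect_equal(fisher_exact_2x2(a, b, c, d)$p_value,
                 stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9, info = paste(a, b, c, d))
  }
  # large-count stability
  big <- fisher_exact_2x2(12893, 10148, 349789, 442395)
  expect_true(big$p_value > 0 && big$p_value < 1e-100)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("MK counts aggregate polymorphism and divergence per region set", {
  regions <- simple_enh(c(0, 1000), c(500, 1500), id = c("r1", "r2"))
  v <- data.frame(chrom = "chr1", pos = c(10, 20, 1100, 9000),
                  ref = "A", alt = "G", af = 0.1, aa = "A",
                  stringsAsFactors = FALSE)
  dv <- data.frame(region_id = c("r1", "r2", "zz"), d = c(10, 5, 99),
                   pi = c(2, 1, 0), stringsAsFactors = FALSE)
  cnt <- mk_counts(regions, v, dv)
  expect_equal(cnt$P, 3)
  expect_equal(cnt$d, 15)
  expect_equal(cnt$D, 12)
})

test_that("neutral-vs-neutral synthetic input recovers NI near 1, constraint above 1", {
  cfg <- small_sim_config(snp_rate = 0.01)
  regions <- data.frame(
    chrom = "chr1", start = seq(0, 799) * 3500,
    end = seq(0, 799) * 3500 + 2000,
    id = sprintf("r%04d", 1:800),
    regime = rep(c("neutral", "constrained"), each = 400),
    stringsAsFactors = FALSE)
  vv <- generate_variants(cfg, regions, c(chr1 = 3e6))
  neutral <- regions[regions$regime == "neutral", ]
  constrained <- regions[regions$regime == "constrained", ]
  # split the neutral set in two: test half vs reference half
  cn1 <- mk_counts(neutral[1:200, ], vv$variants, vv$divergence)
  cn2 <- mk_counts(neutral[201:400, ], vv$variants, vv$divergence)
  ni_null <- mk_test(cn1$P, cn1$D, cn2$P, cn2$D)$neutrality_index
  expect_lt(abs(ni_null - 1), 0.1)
  cc <- mk_counts(constrained, vv$variants, vv$divergence)
  ni_con <- mk_test(cc$P, cc$D, cn2$P, cn2$D)
  expect_gt(ni_con$neutrality_index, 1.2)
  expect_equal(ni_con$regime, "negative")
})
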