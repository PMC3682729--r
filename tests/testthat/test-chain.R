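test_that("chain parser reads valid chains and rejects bad block sums", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 1000 chr1 1000 + 0 1000 chr1 1000 + 0 1000 1",
               "1000", ""), f)
  ch <- parse_chain(f)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 1)
  expect_equal(ch[[1]]$score, 1000)
  bad <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 1000 chr1 1000 + 0 1000 chr1 1000 + 0 1000 1",
               "900", ""), bad)
  expect_error(parse_chain(bad), "span mismatch")
})

test_that("write/parse round-trips generated chains structurally", {
  cfg <- small_sim_config()
  ann <- generate_annotation(cfg)
  ch <- generate_chain_file(cfg, ann)
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain(ch$query_to_ref, f)
  back <- parse_chain(f)
  expect_length(back, length(ch$query_to_ref))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$score, ch$query_to_ref[[k]]$score)
    expect_equal(back[[k]]$source_start, ch$query_to_ref[[k]]$source_start)
    expect_equal(unname(back[[k]]$blocks),
                 unname(ch$query_to_ref[[k]]$blocks))
  }
})

test_that("interval mapping follows liftOver semantics on hand-built chains", {
  idc <- identity_chain(size = 10000)
  m <- map_interval(simple_enh(100, 200), list(idc))
  expect_equal(m$status, "mapped")
  expect_equal(m$mapped_fraction, 1)
  expect_equal(c(m$target$start, m$target$end), c(100, 200))
  # interval entirely inside a source gap (planted deletion): unmapped
  gapped <- make_chain(9000, "chr1", 10000, 0, 10000, "chr1", 9000, 0, 9000,
                       list(c(4000, 1000, 0), c(5000, 0, 0)))
  m <- map_interval(simple_enh(4200, 4700), list(gapped))
  expect_equal(m$status, "unmapped")
  expect_equal(m$mapped_fraction, 0)
  # half inside the gap: fraction 0.5, threshold-dependent
  m <- map_interval(simple_enh(3500, 4500), list(gapped), min_match = 0.95)
  expect_equal(m$status, "unmapped")
  expect_equal(m$mapped_fraction, 0.5)
  m <- map_interval(simple_enh(3500, 4500), list(gapped), min_match = 0.4)
  expect_equal(m$status, "mapped")
  expect_equal(c(m$target$start, m$target$end), c(3500, 4000))
  # chromosome absent from the chain set
  m <- map_interval(simple_enh(0, 10, chrom = "chrX"), list(idc))
  expect_equal(m$status, "unmapped")
  expect_equal(m$reason, "no_chain")
})

test_that("minus-strand targets are normalized to plus-strand coordinates", {
  rev_chain <- make_chain(1000, "chr1", 1000, 100, 300,
                          "chr2", 5000, 200, 400,
                          list(c(200, 0, 0)), t_strand = "-")
  m <- map_interval(simple_enh(100, 300), list(rev_chain), min_match = 1)
  expect_equal(m$status, "mapped")
  # strand-space [200, 400) reversed in a 5000-base chromosome
  expect_equal(c(m$target$start, m$target$end), c(5000 - 400, 5000 - 200))
  pp <- project_positions(c(100, 299), rev_chain)
  expect_equal(pp, c(5000 - 1 - 200, 5000 - 1 - 399))
  expect_equal(pp, vapply(c(100, 299), oracle_project, numeric(1),
                          chain = rev_chain))
})

test_that("block-arithmetic mapping equals the per-base projection oracle", {
  cfg <- small_sim_config(seed = 9L)
  ann <- generate_annotation(cfg)
  ch <- generate_chain_file(cfg, ann)
  chains <- ch$query_to_ref
  withr::with_seed(21, {
    ivs <- data.frame(
      chrom = sample(names(ann$chrom_sizes), 300, replace = TRUE),
      start = sample.int(2.9e6, 300))
  })
  ivs$end <- ivs$start + sample(c(50, 500, 2000), 300, replace = TRUE)
  ivs$id <- sprintf("iv%03d", seq_len(300))
  got <- map_intervals(ivs, chains)
  for (i in seq_len(nrow(ivs))) {
    o <- oracle_map(ivs[i, ], chains)
    expect_equal(got$status[i], o$status, info = paste("interval", i))
    expect_equal(got$mapped_fraction[i], o$fraction, tolerance = 1e-12)
    if (o$status == "mapped") {
      expect_equal(got$target_start[i], o$start)
      expect_equal(got$target_end[i], o$end)
    }
  }
})

test_that("identity chains act as the identity and min_match is monotone", {
  idc <- identity_chain(size = 50000)
  withr::with_seed(4, {
    s <- sample.int(4e4, 50)
    ivs <- simple_enh(s, s + 1000)
  })
  m <- map_intervals(ivs, list(idc), min_match = 1)
  expect_true(all(m$status == "mapped"))
  expect_equal(m$target_start, ivs$start)
  expect_equal(m$target_end, ivs$end)
  # raising min_match never converts unmapped -> mapped
  gapped <- make_chain(9000, "chr1", 10000, 0, 10000, "chr1", 9000, 0, 9000,
                       list(c(4000, 1000, 0), c(5000, 0, 0)))
  withr::with_seed(5, {
    s2 <- sample.int(8000, 80)
    iv2 <- simple_enh(s2, s2 + 900)
  })
  for (mm in list(c(0.2, 0.5), c(0.5, 0.8), c(0.8, 0.99))) {
    lo <- map_intervals(iv2, list(gapped), min_match = mm[1])
    hi <- map_intervals(iv2, list(gapped), min_match = mm[2])
    expect_true(all(!(lo$status == "unmapped" & hi$status == "mapped")))
  }
})

test_that("the highest-scoring chain wins and split coverage is flagged", {
  main <- identity_chain(size = 10000, score = 10000)
  decoy <- make_chain(50, "chr1", 10000, 0, 2000, "chr2", 8000, 0, 2000,
                      list(c(2000, 0, 0)))
  m <- map_interval(simple_enh(500, 900), list(decoy, main))
  expect_equal(m$target$chrom, "chr1")
  expect_equal(m$target$start, 500)
  # two abutting chains, neither covering the straddling interval
  left <- make_chain(5000, "chr1", 10000, 0, 5000, "chr1", 10000, 0, 5000,
                     list(c(5000, 0, 0)))
  right <- make_chain(5000, "chr1", 10000, 5000, 10000, "chr1", 10000,
                      5000, 10000, list(c(5000, 0, 0)))
  m <- map_interval(simple_enh(4800, 5400), list(left, right))
  expect_equal(m$status, "unmapped")
  expect_equal(m$reason, "split")
})
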