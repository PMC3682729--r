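test_that("nearest TSS distance matches direct cases and a brute-force scan", {
  genes <- simple_genes(c(100, 500), c(200, 600))
  enh <- simple_enh(100, 200)           # midpoint 150
  expect_equal(nearest_tss_distance(enh, genes), 50)
  g2 <- simple_genes(150, 260)
  expect_equal(nearest_tss_distance(enh, g2), 0)
  # no gene on the chromosome -> missing
  enh2 <- simple_enh(100, 200, chrom = "chr9")
  expect_true(is.na(nearest_tss_distance(enh2, genes)))
  # random fixture vs exhaustive scan
  withr::with_seed(11, {
    g <- simple_genes(sort(sample.int(1e5, 20)) * 10,
                      sort(sample.int(1e5, 20)) * 10 + 5000)
    e <- simple_enh(sample.int(9e5, 50), sample.int(9e5, 50) + 800)
  })
  got <- nearest_tss_distance(e, g)
  mids <- floor((e$start + e$end) / 2)
  brute <- vapply(mids, function(m) min(abs(m - g$tss)), numeric(1))
  expect_equal(got, brute)
})

test_that("locus construction follows the flanking-gene rule with clipping", {
  genes <- simple_genes(c(100, 500), c(200, 600))
  # intergenic enhancer between the two genes
  loc <- build_locus(simple_enh(300, 400), genes, 1e4)
  expect_equal(loc$boundary$start, 100)
  expect_equal(loc$boundary$end, 600)
  expect_equal(loc$length, 500)
  expect_equal(loc$context, "intergenic")
  # intronic enhancer: host gene plus both flanking intergenic intervals
  g3 <- simple_genes(c(100, 300, 900), c(200, 700, 950))
  loc <- build_locus(simple_enh(400, 450), g3, 1e4)
  expect_equal(unlist(loc$boundary[c("start", "end")], use.names = FALSE),
               c(200, 900))
  expect_equal(loc$length, 700)
  expect_equal(loc$context, "intronic")
  expect_equal(loc$genes, "g002")
  # upstream of the first gene: clipped at the chromosome start
  loc <- build_locus(simple_enh(20, 60), genes, 1e4)
  expect_equal(unlist(loc$boundary[c("start", "end")], use.names = FALSE),
               c(0, 200))
  # chromosome without genes: whole chromosome, flagged
  loc <- build_locus(simple_enh(20, 60),
                     genes[0, , drop = FALSE], 1e4)
  expect_true(loc$flagged)
  expect_equal(loc$length, 1e4)
})

test_that("locus assignment partitions enhancers and matches the boundary-equality oracle", {
  withr::with_seed(5, {
    genes <- simple_genes(seq(1e4, 9e5, by = 3e4),
                          seq(1e4, 9e5, by = 3e4) + 12000)
    e <- simple_enh(sample.int(95e4, 120), sample.int(95e4, 120) + 500)
  })
  sizes <- c(chr1 = 1e6)
  asg <- assign_enhancers_to_loci(e, genes, sizes)
  expect_equal(sum(table(asg$locus_id)), nrow(e))       # partition
  expect_equal(asg$locus_size,
               as.integer(table(asg$locus_id)[asg$locus_id]))
  # pairwise oracle: co-locus iff identical boundaries from build_locus
  single <- lapply(seq_len(nrow(e)), function(i)
    build_locus(e[i, ], genes, 1e6)$boundary)
  for (i in seq_len(nrow(e))) {
    expect_equal(asg$locus_start[i], single[[i]]$start)
    expect_equal(asg$locus_end[i], single[[i]]$end)
  }
  # two enhancers in one intergenic gap share a locus, a gene separates loci
  pair <- simple_enh(c(23000, 25000, 55000), c(23400, 25400, 55400))
  pasg <- assign_enhancers_to_loci(pair, genes, sizes)
  expect_equal(pasg$locus_id[1], pasg$locus_id[2])
  expect_false(pasg$locus_id[3] == pasg$locus_id[1])
})

test_that("singletons are the complement of clustered enhancers", {
  genes <- simple_genes(c(100, 5000, 9000), c(1000, 6000, 9500))
  e <- simple_enh(c(2000, 2500, 3000, 7000), c(2200, 2700, 3200, 7200))
  asg <- assign_enhancers_to_loci(e, genes, c(chr1 = 2e4))
  s <- find_singletons(asg)
  expect_equal(s, "e004")
  clustered <- setdiff(asg$id, s)
  expect_setequal(clustered, c("e001", "e002", "e003"))
  # all singleton loci -> everything returned
  e2 <- simple_enh(c(2000, 7000), c(2200, 7200))
  asg2 <- assign_enhancers_to_loci(e2, genes, c(chr1 = 2e4))
  expect_setequal(find_singletons(asg2), e2$id)
})

test_that("GC content counts unambiguous bases only", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGCCATATANGC"))
  iv <- data.frame(chrom = "chr1", start = c(0, 4, 8), end = c(4, 8, 12))
  expect_equal(gc_content(iv, genome), c(1, 0, 2 / 3))
  expect_error(gc_content(data.frame(chrom = "chr1", start = 0, end = 99),
                          genome), "beyond")
})

test_that("CpG overlap fraction matches a brute-force scan", {
  e <- simple_enh(c(100, 300, 900), c(200, 420, 1000))
  expect_equal(cpg_overlap_fraction(e, e[0, ]), 0)
  genomewide <- data.frame(chrom = "chr1", start = 0, end = 1e4)
  expect_equal(cpg_overlap_fraction(e, genomewide), 1)
  withr::with_seed(3, {
    s <- sample.int(1000, 30)
    islands <- simple_enh(s, s + 50)
  })
  got <- cpg_overlap_fraction(e, islands)
  brute <- mean(vapply(seq_len(nrow(e)), function(i)
    any(islands$start < e$end[i] & islands$end > e$start[i]), logical(1)))
  expect_equal(got, brute)
})

test_that("clustering simulation respects degenerate locus structures", {
  genes <- simple_genes(seq(1e4, 4e5, by = 5e4),
                        seq(1e4, 4e5, by = 5e4) + 1e4)
  # all singletons: both percentages 0
  e <- simple_enh(seq(25e3, 375e3, by = 5e4), seq(25e3, 375e3, by = 5e4) + 500)
  asg <- assign_enhancers_to_loci(e, genes, c(chr1 = 5e5))
  sh <- e$id[1:4]; ln <- e$id[5:8]
  r <- clustering_simulation(asg, sh, ln, draws_per_class = 4,
                             replicates = 50, seed = 1)
  expect_equal(r$pct_clustered_with_shared, c(0, 0))
  expect_equal(r$pct_clustered_with_lineage, c(0, 0))
  # everything in one locus: both percentages 100
  e2 <- simple_enh(seq(25e3, 25e3 + 7 * 300, by = 300),
                   seq(25e3, 25e3 + 7 * 300, by = 300) + 200)
  asg2 <- assign_enhancers_to_loci(e2, genes, c(chr1 = 5e5))
  r2 <- clustering_simulation(asg2, e2$id[1:4], e2$id[5:8],
                              draws_per_class = 4, replicates = 50, seed = 1)
  expect_equal(r2$pct_clustered_with_shared, c(100, 100))
  expect_equal(r2$pct_clustered_with_lineage, c(100, 100))
  expect_error(clustering_simulation(asg2, character(0), e2$id),
               "non-empty")
})

test_that("adding an enhancer to a locus never lowers expected clustering", {
  genes <- simple_genes(seq(1e4, 4e5, by = 5e4),
                        seq(1e4, 4e5, by = 5e4) + 1e4)
  base <- simple_enh(c(25e3, 26e3, 75e3, 125e3, 175e3, 225e3),
                     c(25e3, 26e3, 75e3, 125e3, 175e3, 225e3) + 500)
  extra <- simple_enh(27e3, 27500, id = "extra")   # joins the first locus
  sh <- c("e001", "e003"); ln <- c("e002", "e004", "e005", "e006")
  asg1 <- assign_enhancers_to_loci(base, genes, c(chr1 = 5e5))
  r1 <- clustering_simulation(asg1, sh, ln, draws_per_class = 2,
                              replicates = 5000, seed = 2)
  asg2 <- assign_enhancers_to_loci(rbind(base, extra), genes, c(chr1 = 5e5))
  r2 <- clustering_simulation(asg2, c(sh, "extra"), ln,
                              draws_per_class = 2, replicates = 5000,
                              seed = 2)
  expect_gte(r2$pct_clustered_with_shared[1] + 1e-9,
             r1$pct_clustered_with_shared[1])
})

test_that("reporting bins follow the distance and locus-length conventions", {
  expect_equal(as.character(feature_bins(c(5e3, 3e4, 9e4), "tss")),
               c("<10kb", "10-50kb", ">50kb"))
  expect_equal(as.character(feature_bins(c(1e5, 3e5, 7e5), "locus")),
               c("<200kb", "200-500kb", ">500kb"))
})
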