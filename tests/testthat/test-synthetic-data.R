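test_that("config validation enforces fractions, counts and class split", {
  expect_error(sim_config(frac_shared = 1.2), "frac_shared")
  expect_error(sim_config(frac_class1 = 0.5, frac_class2 = 0.5,
                          frac_class3 = 0.5), "must equal 1")
  expect_error(sim_config(n_go_terms = 0L), "n_go_terms")
  expect_silent(validate_sim_config(small_sim_config()))
})

test_that("annotation is deterministic, non-overlapping, with strand-correct TSS", {
  cfg <- small_sim_config(n_genes = 50L, chrom_length = 1e6,
                          n_chromosomes = 1L)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  g <- a1$genes
  expect_equal(nrow(g), 50)
  # brute-force pairwise non-overlap
  for (i in seq_len(nrow(g) - 1))
    expect_true(all(g$start[-i] >= g$end[i] | g$end[-i] <= g$start[i]))
  expect_equal(g$tss, ifelse(g$strand == "+", g$start, g$end - 1))
  # empty case still yields chromosome sizes
  a0 <- generate_annotation(small_sim_config(n_genes = 0L))
  expect_equal(nrow(a0$genes), 0)
  expect_length(a0$chrom_sizes, 2)
  # infeasible sizing errors out
  expect_error(generate_annotation(
    small_sim_config(n_genes = 500L, chrom_length = 1e5,
                     n_chromosomes = 1L)), "too short")
})

test_that("degenerate shared/class fractions plant what they promise", {
  cfg <- small_sim_config(frac_shared = 1, n_enhancers_query = 60L,
                          n_enhancers_reference = 80L)
  ann <- generate_annotation(cfg)
  es <- generate_enhancer_sets(cfg, ann)
  expect_true(all(es$ground_truth$query_labels == "shared"))
  cm <- cross_map_enhancer_sets(es$query, es$reference,
                                generate_chain_file(cfg, ann,
                                                    es$alignment)$ref_to_query)
  expect_true(all(cm$query$class_label == "shared"))
  # all lineage-specific as class III: every one inside a chain gap
  cfg3 <- small_sim_config(frac_class1 = 0, frac_class2 = 0,
                           frac_class3 = 1, n_enhancers_query = 60L,
                           n_enhancers_reference = 80L)
  ann3 <- generate_annotation(cfg3)
  es3 <- generate_enhancer_sets(cfg3, ann3)
  ch3 <- generate_chain_file(cfg3, ann3, es3$alignment)
  ls <- es3$query[es3$ground_truth$query_labels[es3$query$id] != "shared", ]
  m <- map_intervals(ls, ch3$query_to_ref)
  expect_true(all(m$status == "unmapped"))
})

test_that("label counts are conserved and every enhancer has one label", {
  es <- attr_or_build <- generate_enhancer_sets(small_sim_config(),
                                                generate_annotation(small_sim_config()))
  gt <- es$ground_truth$query_labels
  expect_length(gt, 400)
  expect_setequal(names(gt), es$query$id)
  expect_true(all(gt %in% c("shared", "class1", "class2", "class3")))
  n_sh <- sum(gt == "shared")
  expect_equal(n_sh, round(small_sim_config()$frac_shared * 400))
})

test_that("chain round-trip through planted alignments restores coordinates", {
  cfg <- small_sim_config(seed = 13L)
  ann <- generate_annotation(cfg)
  es <- generate_enhancer_sets(cfg, ann)
  ch <- generate_chain_file(cfg, ann, es$alignment)
  keep <- es$query[es$ground_truth$query_labels[es$query$id] != "class3", ]
  fwd <- map_intervals(keep, ch$query_to_ref, min_match = 0.95)
  mp <- fwd[fwd$status == "mapped", ]
  back <- map_intervals(
    data.frame(chrom = mp$target_chrom, start = mp$target_start,
               end = mp$target_end, id = mp$id),
    ch$ref_to_query, min_match = 0.95)
  orig <- keep[match(back$id, keep$id), ]
  expect_true(all(back$status == "mapped"))
  expect_equal(back$target_start, orig$start)
  expect_equal(back$target_end, orig$end)
})

test_that("planted DAF contrast and null case behave as configured", {
  cfg <- small_sim_config()
  regions <- data.frame(
    chrom = "chr1",
    start = seq(0, 999) * 2500, end = seq(0, 999) * 2500 + 1200,
    id = sprintf("r%04d", 1:1000),
    regime = rep(c("neutral", "constrained"), 500),
    stringsAsFactors = FALSE)
  sizes <- c(chr1 = 3e6)
  expect_error(generate_variants(cfg, regions, c(chr1 = 1e4)),
               "outside chromosome")
  # null: selected params equal to neutral -> statistically equal spectra
  cfg0 <- small_sim_config(daf_selected_params = c(0.3, 1.2),
                           snp_rate = 0.02)
  v0 <- generate_variants(cfg0, regions, sizes)
  pol <- polarize_variants(v0$variants)
  sp_n <- daf_spectrum(regions[regions$regime == "neutral", ], pol,
                       class_label = "neutral")
  sp_c <- daf_spectrum(regions[regions$regime == "constrained", ], pol,
                       reference = sp_n, class_label = "constrained")
  expect_gt(sp_c$p_value, 0.01)
  # planted shift: constrained fraction exceeds neutral fraction
  v1 <- generate_variants(cfg, regions, sizes)
  pol1 <- polarize_variants(v1$variants)
  sp_n1 <- daf_spectrum(regions[regions$regime == "neutral", ], pol1)
  sp_c1 <- daf_spectrum(regions[regions$regime == "constrained", ], pol1)
  expect_gt(sp_c1$fraction, sp_n1$fraction)
  # zero divergence -> D floored at 0 everywhere
  cfgd <- small_sim_config(divergence_rate = 0)
  vd <- generate_variants(cfgd, regions, sizes)
  expect_true(all(vd$divergence$d == 0))
  expect_warning(D <- compute_D(sum(vd$divergence$d), sum(vd$divergence$pi)),
                 "floored")
  expect_equal(D, 0)
})

test_that("planted heart genes are recovered by the top-n ranking", {
  cfg <- small_sim_config()
  ann <- generate_annotation(cfg)
  planted <- sort(ann$genes$gene_id[seq(1, 200, by = 4)])   # 50 genes
  ex <- generate_expression_tables(cfg, ann$genes, planted)
  sc <- heart_specificity_score(ex$heart, ex$nonheart)
  top <- top_heart_genes(sc, n = 50)
  expect_gte(mean(planted %in% top), 0.9)
  # null effect: recovery compatible with chance
  cfg1 <- small_sim_config(heart_effect = 1)
  ex1 <- generate_expression_tables(cfg1, ann$genes, planted)
  sc1 <- heart_specificity_score(ex1$heart, ex1$nonheart)
  top1 <- top_heart_genes(sc1, n = 50)
  expect_lt(mean(planted %in% top1), 0.6)
  # identical profiles across species -> R^2 of 1 up to sampling noise
  qm <- setNames(sc$heart_mean, sc$gene_id)
  r2 <- profile_r2(qm, setNames(qm, sub("^g", "rg", names(qm))),
                   ex$homolog_map)
  expect_equal(r2$r_squared, 1.0)
})

test_that("GO generator plants cardiac bias and supports the uniform null", {
  cfg <- small_sim_config(frac_cardiac_terms = 0)
  ann <- generate_annotation(cfg)
  go0 <- generate_go_annotations(cfg, ann$genes, character(0))
  expect_length(cardiac_term_filter(go0), 0)
  cfg1 <- small_sim_config()
  planted <- ann$genes$gene_id[1:40]
  go1 <- generate_go_annotations(cfg1, ann$genes, planted)
  cardiac <- cardiac_term_filter(go1)
  expect_gt(length(cardiac), 0)
  # planted genes are over-represented among cardiac-term annotations
  in_cardiac <- go1$term_id %in% cardiac
  expect_gt(mean(go1$gene_id[in_cardiac] %in% planted),
            2 * mean(go1$gene_id[!in_cardiac] %in% planted))
})

test_that("signal track puts bumps where asked and stays flat otherwise", {
  cfg <- small_sim_config(n_enhancers_query = 40L,
                          n_enhancers_reference = 50L)
  ann <- generate_annotation(cfg)
  es <- generate_enhancer_sets(cfg, ann)
  flat <- generate_signal_track(cfg, es$query, character(0),
                                ann$chrom_sizes)
  p0 <- signal_metaprofile(es$query, GenomicRanges::GRanges(
    flat$chrom, IRanges::IRanges(flat$start + 1, flat$end),
    score = flat$score))
  expect_lt(diff(range(p0$mean_signal)), 0.2 * cfg$signal_background)
  bumped <- generate_signal_track(cfg, es$query, es$query$id,
                                  ann$chrom_sizes)
  gr <- GenomicRanges::GRanges(bumped$chrom,
                               IRanges::IRanges(bumped$start + 1, bumped$end),
                               score = bumped$score)
  p1 <- signal_metaprofile(es$query, gr)
  center <- which.max(p1$mean_signal)
  expect_lte(abs(p1$bin_centers[center]), 200)
  expect_gt(max(p1$mean_signal) / p1$mean_signal[1], 3)
})

test_that("fixture bundles are byte-identical under a seed and self-describing", {
  cfg <- small_sim_config(seed = 99L, n_enhancers_query = 80L,
                          n_enhancers_reference = 100L, n_genes = 80L,
                          n_pseudogenes = 40L, n_ecr = 50L,
                          n_go_terms = 40L, n_cpg_islands = 30L,
                          n_planted_heart_genes = 20L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(cfg, d1)
  write_fixture_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  bl <- read_fixture_bundle(d1)
  expect_equal(bl$manifest$seed, 99)
  expect_equal(nrow(bl$enhancers_query), 80)
  # deleting one input is reported by name
  file.remove(file.path(d1, "divergence.tsv"))
  expect_error(read_fixture_bundle(d1), "missing input: divergence.tsv")
})
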