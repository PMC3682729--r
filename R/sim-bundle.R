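# Fixture bundles: a self-describing directory of plain-text inputs
# (annotation, enhancers, chains, variants, expression, GO, signal, region
# sets) plus a JSON manifest and ground truth, generated deterministically
# from one seed and loadable by every downstream module.

.BUNDLE_FILES <- c(
  chrom_sizes = "chrom.sizes",
  ref_chrom_sizes = "ref_chrom.sizes",
  genes = "genes.tsv",
  ref_genes = "ref_genes.tsv",
  enhancers_query = "enhancers_query.bed",
  enhancers_reference = "enhancers_reference.bed",
  chain_q2r = "query_to_ref.chain",
  chain_r2q = "ref_to_query.chain",
  chain_outgroup = "outgroup1.chain",
  variants = "variants.vcf",
  divergence = "divergence.tsv",
  expr_heart = "expr_heart.tsv",
  expr_nonheart = "expr_nonheart.tsv",
  expr_ref_heart = "expr_ref_heart.tsv",
  expr_ref_nonheart = "expr_ref_nonheart.tsv",
  homolog_map = "homolog_map.tsv",
  go = "go_annotations.tsv",
  signal = "signal_h3k9ac.bedGraph",
  cpg_islands = "cpg_islands.bed",
  pseudogenes = "pseudogenes.bed",
  ref_density = "ref_density.tsv",
  ground_truth = "ground_truth.json",
  manifest = "manifest.json"
)

# reference-side gene annotation: query genes projected through the
# alignment; genes interrupted by a planted deletion are dropped
.project_genes <- function(genes, alignment) {
  r0 <- mapply(function(ch, p) .project_q2r(p, alignment$blocks[[ch]]),
               genes$chrom, genes$start)
  r1 <- mapply(function(ch, p) .project_q2r(p, alignment$blocks[[ch]]),
               genes$chrom, genes$end - 1)
  keep <- !is.na(r0) & !is.na(r1) & (r1 > r0)
  g <- genes[keep, , drop = FALSE]
  g$start <- r0[keep]
  g$end <- r1[keep] + 1
  g$gene_id <- sub("^g", "rg", g$gene_id)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  rownames(g) <- NULL
  g
}

#' Write a complete synthetic fixture bundle
#'
#' Generates every input the pipeline consumes and writes it under `dir`
#' as plain text, together with a `manifest.json` (seed, configuration,
#' file list) and `ground_truth.json` (planted labels and structure).
#' The same configuration always produces a byte-identical bundle.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; the generated objects as attribute `objects`.
#' @export
write_fixture_bundle <- function(config, dir) {
  validate_sim_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(key) file.path(dir, .BUNDLE_FILES[[key]])

  ann <- generate_annotation(config)
  es <- generate_enhancer_sets(config, ann)
  ch <- generate_chain_file(config, ann, alignment = es$alignment)
  c3 <- es$query[es$query$true_label == "class3", , drop = FALSE]
  og <- generate_outgroup_chains(config, ann, c3)
  regions <- generate_region_sets(config, ann, es)
  vr_regions <- rbind(
    data.frame(chrom = es$query$chrom, start = es$query$start,
               end = es$query$end, id = es$query$id, regime = "constrained",
               stringsAsFactors = FALSE),
    data.frame(chrom = regions$pseudogenes$chrom,
               start = regions$pseudogenes$start,
               end = regions$pseudogenes$end, id = regions$pseudogenes$id,
               regime = "neutral", stringsAsFactors = FALSE))
  vars <- generate_variants(config, vr_regions, ann$chrom_sizes)
  planted <- planted_heart_genes(config, ann, es)
  expr <- generate_expression_tables(config, ann$genes, planted)
  go <- generate_go_annotations(config, ann$genes, planted)
  shared_ids <- es$query$id[es$query$true_label == "shared"]
  sig <- generate_signal_track(config, es$query, bump_ids = shared_ids,
                               chrom_sizes = ann$chrom_sizes)
  ref_genes <- .project_genes(ann$genes, es$alignment)

  write_chrom_sizes(ann$chrom_sizes, fp("chrom_sizes"))
  write_chrom_sizes(es$alignment$ref_chrom_sizes, fp("ref_chrom_sizes"))
  write_genes(ann$genes, fp("genes"))
  write_genes(ref_genes, fp("ref_genes"))
  write_bed(es$query, fp("enhancers_query"))
  write_bed(es$reference, fp("enhancers_reference"))
  write_chain(ch$query_to_ref, fp("chain_q2r"))
  write_chain(ch$ref_to_query, fp("chain_r2q"))
  write_chain(og$chains, fp("chain_outgroup"))
  write_vcf(vars$variants, fp("variants"), ann$chrom_sizes)
  write_tsv(vars$divergence, fp("divergence"))
  write_tsv(expr$heart, fp("expr_heart"))
  write_tsv(expr$nonheart, fp("expr_nonheart"))
  write_tsv(expr$ref_heart, fp("expr_ref_heart"))
  write_tsv(expr$ref_nonheart, fp("expr_ref_nonheart"))
  write_tsv(expr$homolog_map, fp("homolog_map"))
  write_tsv(go, fp("go"))
  write_bedgraph(sig, fp("signal"))
  write_bed(regions$cpg_islands, fp("cpg_islands"))
  write_bed(regions$pseudogenes, fp("pseudogenes"))
  write_tsv(regions$ref_density, fp("ref_density"))

  gt <- list(
    query_labels = as.list(es$ground_truth$query_labels),
    reference_specific = as.list(es$ground_truth$reference_specific),
    deletions = es$ground_truth$deletions,
    planted_heart_genes = planted,
    outgroup_absent = og$absent_ids,
    signal_bump_ids = shared_ids
  )
  jsonlite::write_json(gt, fp("ground_truth"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    files = as.list(.BUNDLE_FILES[setdiff(names(.BUNDLE_FILES), "manifest")])
  )
  jsonlite::write_json(manifest, fp("manifest"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- dir
  attr(out, "objects") <- list(annotation = ann, enhancer_sets = es,
                               chains = ch, outgroup = og,
                               regions = regions, variants = vars,
                               expression = expr, go = go, signal = sig,
                               ref_genes = ref_genes)
  invisible(out)
}

#' Load a fixture bundle
#'
#' Reads the manifest and loads every input with the package's own
#' readers; a missing file is reported by name.
#'
#' @param dir Bundle directory.
#' @return Named list of loaded inputs plus `ground_truth`, `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  mf_path <- file.path(dir, .BUNDLE_FILES[["manifest"]])
  if (!file.exists(mf_path)) stop("missing input: manifest.json")
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (f in unlist(manifest$files))
    if (!file.exists(file.path(dir, f))) stop("missing input: ", f)
  fp <- function(key) file.path(dir, .BUNDLE_FILES[[key]])
  list(
    manifest = manifest,
    chrom_sizes = read_chrom_sizes(fp("chrom_sizes")),
    ref_chrom_sizes = read_chrom_sizes(fp("ref_chrom_sizes")),
    genes = read_genes(fp("genes")),
    ref_genes = read_genes(fp("ref_genes")),
    enhancers_query = read_bed(fp("enhancers_query")),
    enhancers_reference = read_bed(fp("enhancers_reference")),
    chain_q2r = parse_chain(fp("chain_q2r")),
    chain_r2q = parse_chain(fp("chain_r2q")),
    chain_outgroup = parse_chain(fp("chain_outgroup")),
    variants = read_variants(fp("variants")),
    divergence = read_tsv(fp("divergence")),
    expr_heart = read_expression(fp("expr_heart")),
    expr_nonheart = read_expression(fp("expr_nonheart")),
    expr_ref_heart = read_expression(fp("expr_ref_heart")),
    expr_ref_nonheart = read_expression(fp("expr_ref_nonheart")),
    homolog_map = read_tsv(fp("homolog_map")),
    go = read_go(fp("go")),
    signal = read_bedgraph(fp("signal")),
    cpg_islands = read_bed(fp("cpg_islands")),
    pseudogenes = read_bed(fp("pseudogenes")),
    ref_density = read_tsv(fp("ref_density")),
    ground_truth = jsonlite::read_json(file.path(dir,
                                                 .BUNDLE_FILES[["ground_truth"]]),
                                       simplifyVector = TRUE)
  )
}
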