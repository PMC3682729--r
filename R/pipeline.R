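# End-to-end orchestration over a fixture bundle (or any directory laid
# out like one): classification -> loci/clustering -> expression ->
# selection -> enrichment/signal -> compensation, with a machine-readable
# report.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions throughout the package:
#' lift-over min_match 0.95, shared overlap 1 bp, clustering simulation
#' 500 draws x 1000 replicates, expression offset 16 and top-1000 ranking,
#' DAF low-frequency cutoff 0.05.
#'
#' @param min_match,overlap_rule See [classification_config()].
#' @param draws_per_class,replicates Clustering simulation size.
#' @param offset,top_n Expression scoring parameters.
#' @param daf_cutoff Low-frequency DAF threshold.
#' @param metaprofile_window,metaprofile_bins Signal metaprofile shape.
#' @param seed Integer seed for the stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_match = 0.95, overlap_rule = 1,
                            draws_per_class = 500, replicates = 1000,
                            offset = 16, top_n = 1000, daf_cutoff = 0.05,
                            metaprofile_window = 5000,
                            metaprofile_bins = 50, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full comparative-enhancer pipeline on a bundle
#'
#' Stages run in dependency order; a subset can be selected (stages whose
#' prerequisites are missing trigger the prerequisite automatically for
#' `loci`, which `expression` and `compensate` need). Identical bundle,
#' config and seed yield an identical report.
#'
#' @param bundle A bundle directory path or the list from
#'   [read_fixture_bundle()].
#' @param config A [pipeline_config()].
#' @param stages Character vector among `classify`, `loci`, `expression`,
#'   `selection`, `enrich`, `signal`, `compensate` (default: all).
#' @return A nested report list; sections named after the stages, plus
#'   `provenance`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         stages = c("classify", "loci", "expression",
                                    "selection", "enrich", "signal",
                                    "compensate")) {
  if (is.character(bundle)) bundle <- read_fixture_bundle(bundle)
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list()
  needs_classify <- any(stages %in% c("classify", "loci", "expression",
                                      "selection", "enrich", "signal",
                                      "compensate"))
  cls <- NULL; asg <- NULL

  if (needs_classify) {
    bg <- ecr_background_density(
      bundle$ref_density[bundle$ref_density$is_ecr, , drop = FALSE])
    ccfg <- classification_config(min_match = config$min_match,
                                  overlap_rule = config$overlap_rule,
                                  background_density = bg)
    cm <- cross_map_enhancer_sets(bundle$enhancers_query,
                                  bundle$enhancers_reference,
                                  bundle$chain_r2q, ccfg)
    lin <- cm$query[cm$query$class_label == "lineage_specific", ,
                    drop = FALSE]
    sub <- classify_lineage_specific(lin, bundle$chain_q2r,
                                     bundle$ref_density, ccfg)
    lab <- cm$query$class_label
    lab[match(sub$id, cm$query$id)] <- sub$class_label
    cls <- cm$query
    cls$class_label <- lab
    cls$top_label <- cm$query$class_label
    if ("classify" %in% stages) {
      c3 <- cls[cls$class_label == "class3", , drop = FALSE]
      ogp <- outgroup_presence(c3, list(outgroup1 = bundle$chain_outgroup),
                               min_match = config$min_match)
      report$classify <- list(
        summary = classification_summary(cls$top_label),
        class_counts = as.list(table(cls$class_label)),
        n_reference_specific = sum(cm$reference$reference_specific),
        outgroup = ogp[c("n_present", "n_total", "fraction", "pct")]
      )
    }
    reference_specific <- cm$reference[cm$reference$reference_specific, ,
                                       drop = FALSE]
  }

  if (any(stages %in% c("loci", "expression", "compensate"))) {
    asg <- assign_enhancers_to_loci(bundle$enhancers_query, bundle$genes,
                                    bundle$chrom_sizes)
    if ("loci" %in% stages) {
      shared_ids <- cls$id[cls$class_label == "shared"]
      lineage_ids <- cls$id[cls$class_label != "shared"]
      sim <- clustering_simulation(asg, shared_ids, lineage_ids,
                                   draws_per_class = config$draws_per_class,
                                   replicates = config$replicates,
                                   seed = config$seed)
      tssd <- nearest_tss_distance(bundle$enhancers_query, bundle$genes)
      by_cls <- split(seq_len(nrow(cls)), cls$class_label)
      report$loci <- list(
        clustering = sim,
        tss_distance_mean = lapply(by_cls, function(i) mean(tssd[i],
                                                            na.rm = TRUE)),
        locus_length_mean = lapply(by_cls, function(i)
          mean(asg$locus_length[i])),
        cpg_overlap = lapply(by_cls, function(i) cpg_overlap_fraction(
          bundle$enhancers_query[i, , drop = FALSE], bundle$cpg_islands)),
        n_singletons = length(find_singletons(asg))
      )
    }
  }

  if ("expression" %in% stages) {
    sc <- heart_specificity_score(bundle$expr_heart, bundle$expr_nonheart,
                                  offset = config$offset)
    top <- top_heart_genes(sc, n = config$top_n)
    by_cls <- split(seq_len(nrow(cls)), cls$class_label)
    fr <- lapply(by_cls, function(i)
      fraction_in_high_expression_loci(asg[i, , drop = FALSE], top))
    hm <- .expr_means(bundle$expr_ref_heart)
    qm <- .expr_means(bundle$expr_heart)
    r2 <- profile_r2(qm, hm, bundle$homolog_map, offset = config$offset,
                     stage = "reference_heart")
    report$expression <- list(
      top_n = config$top_n,
      fraction_in_top_loci = lapply(fr, `[[`, "fraction"),
      profile_r2 = r2
    )
  }

  if ("selection" %in% stages) {
    pol <- polarize_variants(bundle$variants)
    pseudo <- bundle$pseudogenes
    ref_sp <- daf_spectrum(pseudo, pol, cutoff = config$daf_cutoff,
                           class_label = "pseudogenes")
    lab_for_daf <- cls
    classes <- c("shared", "class2", "class3")
    spectra <- lapply(classes, function(cl) {
      daf_spectrum(lab_for_daf[lab_for_daf$class_label == cl, ,
                               drop = FALSE],
                   pol, cutoff = config$daf_cutoff, reference = ref_sp,
                   class_label = cl)
    })
    mk_ref <- mk_counts(pseudo, bundle$variants, bundle$divergence)
    mk_rows <- lapply(classes, function(cl) {
      reg <- lab_for_daf[lab_for_daf$class_label == cl, , drop = FALSE]
      cnt <- mk_counts(reg, bundle$variants, bundle$divergence)
      mk <- mk_test(cnt$P, cnt$D, mk_ref$P, mk_ref$D)
      data.frame(class_label = cl, P = cnt$P, D = cnt$D,
                 neutrality_index = mk$neutrality_index,
                 p_value = mk$p_value, regime = mk$regime,
                 stringsAsFactors = FALSE)
    })
    mk_table <- do.call(rbind, c(mk_rows, list(data.frame(
      class_label = "pseudogenes", P = mk_ref$P, D = mk_ref$D,
      neutrality_index = 1, p_value = NA_real_, regime = "neutral",
      stringsAsFactors = FALSE))))
    report$selection <- list(
      n_skipped_polarization = attr(pol, "n_skipped"),
      daf_table = daf_table(spectra, ref_sp),
      mk_table = mk_table
    )
  }

  if ("enrich" %in% stages) {
    classes <- c("shared", "class2", "class3")
    ng_all <- nearest_gene(bundle$enhancers_query, bundle$genes)
    sets <- lapply(classes, function(cl) {
      g <- unique(ng_all[cls$class_label == cl])
      g[!is.na(g)]
    })
    names(sets) <- classes
    background <- unique(ng_all[!is.na(ng_all)])
    fold <- cardiac_fold_enrichment(sets, bundle$genes$gene_id, bundle$go)
    enr <- go_enrichment(sets$shared, background, bundle$go)
    report$enrich <- list(
      cardiac_fold = fold,
      n_bonferroni_significant = sum(enr$p_bonferroni < 0.05),
      top_terms = utils::head(enr[, c("term_id", "term_name",
                                      "fold_enrichment", "p_bonferroni")], 10)
    )
  }

  if ("signal" %in% stages) {
    classes <- c("shared", "class2", "class3")
    prof <- lapply(classes, function(cl) {
      e <- cls[cls$class_label == cl, , drop = FALSE]
      if (nrow(e) == 0) return(NULL)
      p <- signal_metaprofile(e, bundle$signal,
                              window = config$metaprofile_window,
                              n_bins = config$metaprofile_bins)
      list(peak = max(p$mean_signal),
           flank = mean(p$mean_signal[c(1, p$n_bins)]),
           n_regions = p$n_regions)
    })
    names(prof) <- classes
    report$signal <- prof[!vapply(prof, is.null, logical(1))]
  }

  if ("compensate" %in% stages) {
    singles <- find_singletons(asg)
    sg <- cls[cls$id %in% singles &
                cls$class_label %in% c("shared", "class2", "class3"), ,
              drop = FALSE]
    comp <- orthologous_locus_compensation(
      sg, asg, bundle$chain_q2r, bundle$ref_genes, bundle$ref_chrom_sizes,
      reference_specific, bundle$homolog_map,
      min_match = config$min_match)
    report$compensate <- comp$per_class
  }

  report$provenance <- list(
    seed = config$seed,
    config = unclass(config),
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("enhancerEvo"))
  )
  report
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.fmt_pct <- function(x) sprintf("%.1f%%", x)
.fmt_ni <- function(x) sprintf("%.2f", x)

#' Write a pipeline report to disk
#'
#' JSON always (full precision); per-table TSVs on request, with
#' percentages rendered to 1 decimal place and neutrality indices to 2.
#'
#' @param report Output of [run_pipeline()].
#' @param dir Output directory.
#' @param formats Subset of `c("json", "tsv")`.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "tsv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    emit <- function(df, name) {
      p <- file.path(dir, paste0(name, ".tsv"))
      write_tsv(df, p)
      written <<- c(written, p)
    }
    fmt_p <- function(p) ifelse(is.na(p), "NA", sprintf("%.3g", p))
    if (!is.null(report$selection$daf_table)) {
      t1 <- report$selection$daf_table
      t1$pct <- .fmt_pct(100 * t1$fraction)
      t1$p_value <- fmt_p(t1$p_value)
      emit(t1, "daf_table")
    }
    if (!is.null(report$selection$mk_table)) {
      t2 <- report$selection$mk_table
      t2$neutrality_index <- .fmt_ni(t2$neutrality_index)
      t2$p_value <- fmt_p(t2$p_value)
      emit(t2, "mk_table")
    }
    if (!is.null(report$loci$clustering))
      emit(report$loci$clustering, "clustering")
    if (!is.null(report$compensate)) emit(report$compensate, "compensation")
    if (!is.null(report$enrich$cardiac_fold))
      emit(report$enrich$cardiac_fold, "cardiac_fold")
    if (!is.null(report$classify)) {
      s <- report$classify$summary
      emit(data.frame(n_total = s$n_total, n_shared = s$n_shared,
                      pct_lineage_specific = s$pct_lineage_specific,
                      outgroup_pct = report$classify$outgroup$pct),
           "classification_summary")
    }
    skipped <- setdiff(c("classify", "loci", "selection", "compensate",
                         "enrich"), names(report))
    if (length(skipped) > 0)
      message("sections not present, omitted: ",
              paste(skipped, collapse = ", "))
  }
  invisible(written)
}
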