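# Singleton-compensation analysis: for singleton query enhancers of each
# class, does the orthologous reference locus hold at least one
# reference-specific enhancer, and how far is it?

#' Compensation of singleton enhancers in orthologous loci
#'
#' Each singleton's position is lifted into the reference genome and the
#' reference-side regulatory locus around the lifted point is built. A
#' class III singleton has no orthologous sequence, so its locus is lifted
#' through the orthology of its flanking genes (homolog map) instead, and
#' the anchor point is the midpoint of the span of those homologs.
#' Singletons whose locus cannot be lifted either way are excluded from the
#' denominator and counted.
#'
#' @param singletons Enhancer data.frame (`id`, `chrom`, `start`, `end`,
#'   `class_label`).
#' @param query_assignment Locus assignment of the singletons in the query
#'   genome ([assign_enhancers_to_loci()] output; supplies flanking genes).
#' @param chains_query_to_ref Chains lifting query coordinates to the
#'   reference genome.
#' @param ref_genes,ref_chrom_sizes Reference-side annotation.
#' @param ref_specific Reference-specific enhancer data.frame.
#' @param homolog_map data.frame (`query_gene_id`, `reference_gene_id`).
#' @param min_match Minimum lifted fraction (default 0.95).
#' @return List with `per_class` data.frame (`class_label`, `n_used`,
#'   `n_excluded`, `n_compensated`, `fraction_compensated`,
#'   `mean_distance`) and `per_enhancer` detail.
#' @export
orthologous_locus_compensation <- function(singletons, query_assignment,
                                           chains_query_to_ref,
                                           ref_genes, ref_chrom_sizes,
                                           ref_specific, homolog_map,
                                           min_match = 0.95) {
  rs_mid <- interval_midpoint(ref_specific)
  n <- nrow(singletons)
  comp <- rep(NA, n); dist <- rep(NA_real_, n); excluded <- rep(FALSE, n)
  by_chrom <- split(chains_query_to_ref,
                    vapply(chains_query_to_ref, `[[`, character(1),
                           "source_chrom"))
  for (i in seq_len(n)) {
    enh <- singletons[i, , drop = FALSE]
    cc <- by_chrom[[enh$chrom]]
    m <- if (is.null(cc)) list(status = "unmapped")
         else map_interval(enh, cc, min_match)
    if (m$status == "mapped") {
      chr <- m$target$chrom
      point <- floor((m$target$start + m$target$end) / 2)
    } else {
      # lift the locus through flanking-gene orthology
      qa <- query_assignment[query_assignment$id == enh$id, , drop = FALSE]
      qgenes <- if (nrow(qa) == 1) strsplit(qa$genes, ",", fixed = TRUE)[[1]]
                else character(0)
      rgenes <- homolog_map$reference_gene_id[
        homolog_map$query_gene_id %in% qgenes]
      rg <- ref_genes[ref_genes$gene_id %in% rgenes, , drop = FALSE]
      if (nrow(rg) == 0 || length(unique(rg$chrom)) != 1) {
        excluded[i] <- TRUE
        next
      }
      chr <- rg$chrom[1]
      point <- floor((min(rg$start) + max(rg$end)) / 2)
    }
    if (!chr %in% names(ref_chrom_sizes)) { excluded[i] <- TRUE; next }
    point <- min(max(point, 0), ref_chrom_sizes[[chr]] - 1)
    anchor <- data.frame(chrom = chr, start = point, end = point + 1,
                         id = enh$id, stringsAsFactors = FALSE)
    loc <- build_locus(anchor, ref_genes, ref_chrom_sizes[[chr]])
    in_locus <- which(ref_specific$chrom == chr &
                        rs_mid >= loc$boundary$start &
                        rs_mid < loc$boundary$end)
    comp[i] <- length(in_locus) >= 1
    if (comp[i]) dist[i] <- min(abs(rs_mid[in_locus] - point))
  }
  detail <- data.frame(id = singletons$id,
                       class_label = singletons$class_label,
                       excluded = excluded, compensated = comp,
                       distance = dist, stringsAsFactors = FALSE)
  per_class <- do.call(rbind, lapply(split(detail, detail$class_label),
    function(d) {
      used <- d[!d$excluded, , drop = FALSE]
      data.frame(class_label = d$class_label[1],
                 n_used = nrow(used), n_excluded = sum(d$excluded),
                 n_compensated = sum(used$compensated),
                 fraction_compensated =
                   if (nrow(used) > 0) mean(used$compensated) else NA_real_,
                 mean_distance = if (any(used$compensated))
                   mean(used$distance[used$compensated]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_class) <- NULL
  list(per_class = per_class, per_enhancer = detail)
}
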