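# Nearest-gene assignment and cardiac GO-term enrichment. Annotations are a
# flat term-gene map (term_id, term_name, gene_id); no DAG propagation.

#' Read a GO annotation table
#'
#' @param path TSV with columns `term_id`, `term_name`, `gene_id`.
#' @return data.frame of annotations.
#' @export
read_go <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("term_id", "term_name", "gene_id")
  if (!all(need %in% names(x)))
    stop("GO table must have columns: ", paste(need, collapse = ", "))
  x
}

#' Nearest gene (by TSS) for each enhancer
#'
#' The gene minimizing the midpoint-to-TSS distance; exact ties are broken
#' by lexicographic gene id.
#'
#' @param enhancers Enhancer data.frame.
#' @param genes Gene data.frame.
#' @return Character vector of gene ids (`NA` when the chromosome has no
#'   gene).
#' @export
nearest_gene <- function(enhancers, genes) {
  mids <- interval_midpoint(enhancers)
  out <- rep(NA_character_, nrow(enhancers))
  for (chr in unique(enhancers$chrom)) {
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    ei <- which(enhancers$chrom == chr)
    idx <- findInterval(mids[ei], g$tss)
    for (k in seq_along(ei)) {
      j <- idx[k]
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), nrow(g)))
      dd <- abs(mids[ei[k]] - g$tss[cand])
      best <- cand[dd == min(dd)]
      out[ei[k]] <- sort(g$gene_id[best])[1]
    }
  }
  out
}

#' Cardiac GO terms
#'
#' Terms whose name contains "heart", "cardiac" or "cardio"
#' (case-insensitive substring match).
#'
#' @param annotations GO annotation data.frame.
#' @return Character vector of term ids.
#' @export
cardiac_term_filter <- function(annotations) {
  terms <- unique(annotations[, c("term_id", "term_name")])
  keep <- grepl("heart|cardiac|cardio", terms$term_name, ignore.case = TRUE)
  terms$term_id[keep]
}

#' GO term enrichment of a test gene set against a background
#'
#' Per term with at least one annotated background gene, a two-sided
#' Fisher's exact test under the draws-without-replacement model: the test
#' set T (a subset of the background B) is contrasted with the rest of the
#' background, i.e. the table `[[a, |T|-a], [c-a, (|B|-|T|)-(c-a)]]` with
#' `a` = test genes in the term and `c` = background genes in the term.
#' The reported counts `a`, `b`, `c`, `d` are the test/background
#' membership counts themselves. Bonferroni correction over the terms
#' actually tested. Fold enrichment is `(a/|T|)/(c/|B|)`.
#'
#' @param test_genes Character vector (must be a subset of the background).
#' @param background_genes Character vector.
#' @param annotations GO annotation data.frame.
#' @return data.frame: `term_id`, `term_name`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `fold_enrichment`, `p_value`, `p_bonferroni`.
#' @export
go_enrichment <- function(test_genes, background_genes, annotations) {
  test_genes <- unique(test_genes)
  background_genes <- unique(background_genes)
  if (!all(test_genes %in% background_genes))
    stop("test genes must be a subset of the background")
  if (length(test_genes) == 0 || length(background_genes) <= length(test_genes))
    stop("need |background| > |test| > 0")
  by_term <- split(annotations$gene_id, annotations$term_id)
  term_name <- annotations$term_name[!duplicated(annotations$term_id)]
  names(term_name) <- annotations$term_id[!duplicated(annotations$term_id)]
  nT <- length(test_genes); nB <- length(background_genes)
  rows <- lapply(names(by_term), function(tid) {
    gset <- unique(by_term[[tid]])
    cc <- sum(background_genes %in% gset)
    if (cc == 0) return(NULL)  # term absent from background: not tested
    a <- sum(test_genes %in% gset)
    ft <- fisher_exact_2x2(a, nT - a, cc - a, (nB - nT) - (cc - a))
    data.frame(term_id = tid, term_name = unname(term_name[tid]),
               a = a, b = nT - a, c = cc, d = nB - cc,
               odds_ratio = ft$odds_ratio,
               fold_enrichment = (a / nT) / (cc / nB),
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out[order(out$p_value, out$term_id), ]
}

#' Cardiac fold-enrichment per enhancer class
#'
#' For each class, the fraction of its (deduplicated) nearest genes
#' annotated to at least one cardiac term, divided by the same fraction in
#' a control gene set. Classes are contrasted pairwise against the first
#' class with a binomial test.
#'
#' @param class_gene_sets Named list of character vectors (nearest genes per
#'   enhancer class).
#' @param control_genes Character vector (control gene set).
#' @param annotations GO annotation data.frame.
#' @return data.frame: `class_label`, `n_genes`, `n_cardiac`, `fraction`,
#'   `fold_enrichment`, `p_vs_first` (binomial test against the first
#'   class's fraction; NA for the first class).
#' @export
cardiac_fold_enrichment <- function(class_gene_sets, control_genes,
                                    annotations) {
  cardiac_terms <- cardiac_term_filter(annotations)
  cardiac_genes <- unique(
    annotations$gene_id[annotations$term_id %in% cardiac_terms])
  frac <- function(g) {
    g <- unique(g[!is.na(g)])
    c(n = length(g), x = sum(g %in% cardiac_genes))
  }
  ctl <- frac(control_genes)
  ctl_frac <- if (ctl["n"] > 0) ctl["x"] / ctl["n"] else NA_real_
  rows <- lapply(names(class_gene_sets), function(lbl) {
    f <- frac(class_gene_sets[[lbl]])
    data.frame(class_label = lbl, n_genes = unname(f["n"]),
               n_cardiac = unname(f["x"]),
               fraction = unname(if (f["n"] > 0) f["x"] / f["n"] else NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fold_enrichment <- if (is.na(ctl_frac) || ctl_frac == 0) {
    ifelse(out$fraction > 0, Inf, 0)
  } else out$fraction / ctl_frac
  ref <- out[1, ]
  out$p_vs_first <- vapply(seq_len(nrow(out)), function(i) {
    if (i == 1 || out$n_genes[i] == 0 || is.na(ref$fraction)) return(NA_real_)
    stats::binom.test(out$n_cardiac[i], out$n_genes[i],
                      p = max(min(ref$fraction, 1 - 1e-12), 1e-12))$p.value
  }, numeric(1))
  out
}
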