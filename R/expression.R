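# Heart-specificity scoring and expression-related comparisons. Expression
# tables are processed values (gene_id + one column per sample); a small
# offset (default 16) is added before log-transformation to stabilize low
# readings.

#' Read an expression table (gene_id + one column per sample)
#'
#' @param path TSV path.
#' @return data.frame with a `gene_id` column and numeric sample columns.
#' @export
read_expression <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(x)) stop("expression table needs a gene_id column")
  x
}

.expr_means <- function(df) {
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (any(m < 0)) stop("negative expression values are not allowed")
  stats::setNames(rowMeans(m), df$gene_id)
}

#' Heart-specificity score per gene
#'
#' `score = log2(mean_heart + offset) - log2(mean_nonheart + offset)`, with
#' arithmetic means across samples taken before the offset. Gene universes
#' are intersected.
#'
#' @param heart,nonheart Expression data.frames (see [read_expression()]).
#' @param offset Pseudo-value added before the log (default 16); must be
#'   positive when zero means are present.
#' @return data.frame: `gene_id`, `heart_mean`, `nonheart_mean`, `score`.
#' @export
heart_specificity_score <- function(heart, nonheart, offset = 16) {
  hm <- .expr_means(heart)
  nm <- .expr_means(nonheart)
  genes <- intersect(names(hm), names(nm))
  if (length(genes) == 0) stop("no genes shared between the two tables")
  hm <- hm[genes]; nm <- nm[genes]
  if (offset <= 0 && any(c(hm, nm) == 0))
    stop("offset must be > 0 when zero expression values are present")
  data.frame(gene_id = genes, heart_mean = unname(hm),
             nonheart_mean = unname(nm),
             score = log2(hm + offset) - log2(nm + offset),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top heart-specific genes
#'
#' The `n` genes with the highest heart-specificity score; boundary ties are
#' broken deterministically by gene identifier order.
#'
#' @param records Output of [heart_specificity_score()].
#' @param n Number of genes to keep (default 1000).
#' @return Character vector of gene ids.
#' @export
top_heart_genes <- function(records, n = 1000) {
  ord <- order(-records$score, records$gene_id)
  records$gene_id[ord][seq_len(min(n, nrow(records)))]
}

#' Fraction of enhancers in loci of highly expressed genes
#'
#' An enhancer counts iff at least one member gene of its regulatory locus
#' belongs to the top gene set. When a second enhancer set (or its locus
#' assignment) is supplied, a two-sided Fisher's exact test contrasts the
#' two in/out splits.
#'
#' @param assignment Locus assignment of the focal enhancer class (rows of
#'   [assign_enhancers_to_loci()] output).
#' @param top_genes Character vector of top gene ids.
#' @param compare_to Optional second assignment to test against.
#' @return List: `fraction`, `n`, and when compared `odds_ratio`, `p_value`,
#'   `fraction_other`.
#' @export
fraction_in_high_expression_loci <- function(assignment, top_genes,
                                             compare_to = NULL) {
  hit <- function(a) {
    vapply(strsplit(a$genes, ",", fixed = TRUE),
           function(g) any(g %in% top_genes), logical(1))
  }
  h <- hit(assignment)
  out <- list(fraction = mean(h), n = length(h))
  if (!is.null(compare_to)) {
    h2 <- hit(compare_to)
    ft <- fisher_exact_2x2(sum(h), sum(!h), sum(h2), sum(!h2))
    out$fraction_other <- mean(h2)
    out$odds_ratio <- ft$odds_ratio
    out$p_value <- ft$p_value
  }
  out
}

#' Coefficient of determination between two expression profiles
#'
#' Squared Pearson correlation over log-transformed (offset 16) expression
#' values of matched homolog pairs.
#'
#' @param query_expr,reference_expr Named numeric vectors of per-gene
#'   expression (e.g. sample means), names = gene ids.
#' @param homolog_map data.frame (`query_gene_id`, `reference_gene_id`).
#' @param offset Offset added before the log (default 16).
#' @param log Log-transform before correlating (default TRUE).
#' @param stage Label for reporting.
#' @return List: `stage`, `r_squared` (NA with fewer than 3 pairs),
#'   `n_genes`.
#' @export
profile_r2 <- function(query_expr, reference_expr, homolog_map, offset = 16,
                       log = TRUE, stage = "") {
  q <- query_expr[homolog_map$query_gene_id]
  r <- reference_expr[homolog_map$reference_gene_id]
  ok <- !is.na(q) & !is.na(r)
  if (sum(ok) < 3)
    return(list(stage = stage, r_squared = NA_real_, n_genes = sum(ok)))
  q <- q[ok]; r <- r[ok]
  if (log) { q <- log2(q + offset); r <- log2(r + offset) }
  list(stage = stage, r_squared = stats::cor(q, r)^2, n_genes = sum(ok))
}
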