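# Regulatory-locus model: for an intergenic enhancer the locus spans the two
# flanking genes plus the intergenic interval between them; for an intronic
# enhancer it spans from the end of the previous gene to the start of the
# next gene (host gene plus both flanking intergenic intervals). An enhancer
# overlapping any gene body counts as intronic (no exon model); loci are
# clipped to [0, chrom_size]; two enhancers share a locus iff their locus
# boundaries are identical.

.locus_for_positions <- function(enh_start, enh_end, genes_chr, chrom_size) {
  # genes_chr sorted by start, assumed non-overlapping (generator guarantees;
  # overlapping annotations fall back to first-overlap-as-host)
  n <- length(enh_start)
  gs <- genes_chr$start
  ge <- genes_chr$end
  ng <- nrow(genes_chr)
  out <- data.frame(
    locus_start = numeric(n), locus_end = numeric(n),
    context = character(n), genes = character(n),
    flagged = logical(n), stringsAsFactors = FALSE
  )
  if (ng == 0) {
    out$locus_start <- 0
    out$locus_end <- chrom_size
    out$context <- "intergenic"
    out$genes <- ""
    out$flagged <- TRUE
    return(out)
  }
  # host gene: first gene overlapping [enh_start, enh_end)
  idx_last_start <- findInterval(enh_end - 1L, gs)  # last gene with start <= end-1
  host <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- idx_last_start[i]
    # walk back over genes starting before the enhancer end; bodies are
    # non-overlapping so at most a couple of candidates
    while (j >= 1) {
      if (ge[j] > enh_start[i] && gs[j] < enh_end[i]) { host[i] <- j; break }
      if (ge[j] <= enh_start[i]) break
      j <- j - 1L
    }
  }
  intronic <- !is.na(host)
  # intronic: [end of previous gene, start of next gene]
  if (any(intronic)) {
    h <- host[intronic]
    out$locus_start[intronic] <- ifelse(h > 1, ge[h - 1L], 0)
    out$locus_end[intronic] <- ifelse(h < ng, gs[h + 1L], chrom_size)
    out$context[intronic] <- "intronic"
    out$genes[intronic] <- genes_chr$gene_id[h]
  }
  # intergenic: [start of upstream gene, end of downstream gene]
  if (any(!intronic)) {
    ii <- which(!intronic)
    prev <- findInterval(enh_start[ii], gs)  # last gene with start <= enh start
    # no overlap, so that gene (if any) ends at or before enh_start
    nxt <- prev + 1L
    out$locus_start[ii] <- ifelse(prev >= 1, gs[pmax(prev, 1L)], 0)
    out$locus_end[ii] <- ifelse(nxt <= ng, ge[pmin(nxt, ng)], chrom_size)
    out$context[ii] <- "intergenic"
    gl <- ifelse(prev >= 1, genes_chr$gene_id[pmax(prev, 1L)], "")
    gr <- ifelse(nxt <= ng, genes_chr$gene_id[pmin(nxt, ng)], "")
    out$genes[ii] <- sub("^,|,$", "", paste(gl, gr, sep = ","))
  }
  out$locus_start <- pmax(out$locus_start, 0)
  out$locus_end <- pmin(out$locus_end, chrom_size)
  out
}

#' Assign enhancers to regulatory loci
#'
#' Builds the locus of every enhancer and groups enhancers whose locus
#' boundaries are identical (same flanking-gene pair or same host gene).
#'
#' @param enhancers Enhancer data.frame (`chrom`, `start`, `end`, `id`).
#' @param genes Gene data.frame.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return data.frame with one row per enhancer: `id`, `chrom`, `locus_id`,
#'   `locus_start`, `locus_end`, `locus_length`, `context`, `genes`
#'   (comma-separated member gene ids), `flagged` (no gene on chromosome),
#'   `locus_size` (number of enhancers sharing the locus).
#' @export
assign_enhancers_to_loci <- function(enhancers, genes, chrom_sizes) {
  stopifnot(all(enhancers$chrom %in% names(chrom_sizes)))
  res <- vector("list", length(unique(enhancers$chrom)))
  pieces <- lapply(unique(enhancers$chrom), function(chr) {
    ei <- which(enhancers$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    loc <- .locus_for_positions(enhancers$start[ei], enhancers$end[ei], g,
                                chrom_sizes[[chr]])
    data.frame(id = enhancers$id[ei], chrom = chr, loc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[match(enhancers$id, out$id), ]
  rownames(out) <- NULL
  out$locus_id <- paste0(out$chrom, ":", out$locus_start, "-", out$locus_end)
  out$locus_length <- out$locus_end - out$locus_start
  tab <- table(out$locus_id)
  out$locus_size <- as.integer(tab[out$locus_id])
  out
}

#' Build the regulatory locus of a single enhancer
#'
#' @param enhancer One-row enhancer data.frame.
#' @param genes Gene data.frame.
#' @param chrom_size Length of the enhancer's chromosome.
#' @return A list with `boundary` (chrom/start/end), `length`, `context`,
#'   `genes` (member gene ids) and `flagged`.
#' @export
build_locus <- function(enhancer, genes, chrom_size) {
  a <- assign_enhancers_to_loci(enhancer, genes,
                                stats::setNames(chrom_size, enhancer$chrom))
  list(
    boundary = data.frame(chrom = a$chrom, start = a$locus_start,
                          end = a$locus_end, stringsAsFactors = FALSE),
    length = a$locus_length,
    context = a$context,
    genes = strsplit(a$genes, ",")[[1]],
    flagged = a$flagged
  )
}

#' Singleton enhancers
#'
#' Enhancers that are the only enhancer in their locus.
#'
#' @param assignment Output of [assign_enhancers_to_loci()].
#' @return Character vector of enhancer ids.
#' @export
find_singletons <- function(assignment) {
  assignment$id[assignment$locus_size == 1L]
}
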