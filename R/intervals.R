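#' Interval midpoints
#'
#' @param df Interval data.frame (0-based half-open).
#' @return Integer vector of midpoints, `floor((start + end) / 2)`.
#' @keywords internal
interval_midpoint <- function(df) as.integer(floor((df$start + df$end) / 2))

#' Distance from each enhancer midpoint to the nearest TSS
#'
#' Distances are measured from the enhancer midpoint to the closest
#' transcription start site on the same chromosome. Enhancers on a
#' chromosome with no annotated gene get `NA`.
#'
#' @param enhancers Interval data.frame of enhancers.
#' @param genes Gene data.frame (see [read_genes()]).
#' @return Numeric vector, one non-negative distance (bp) per enhancer.
#' @export
nearest_tss_distance <- function(enhancers, genes) {
  mids <- interval_midpoint(enhancers)
  out <- rep(NA_real_, nrow(enhancers))
  for (chr in unique(enhancers$chrom)) {
    gi <- genes$chrom == chr
    if (!any(gi)) next
    tss <- sort(genes$tss[gi])
    ei <- which(enhancers$chrom == chr)
    idx <- findInterval(mids[ei], tss)
    left <- ifelse(idx >= 1, tss[pmax(idx, 1L)], Inf)
    right <- ifelse(idx < length(tss), tss[pmin(idx + 1L, length(tss))], Inf)
    out[ei] <- pmin(abs(mids[ei] - left), abs(right - mids[ei]))
  }
  out
}

#' GC content of intervals
#'
#' (G+C) / (A+C+G+T) over each interval; ambiguous bases are excluded from
#' the denominator. An interval whose denominator is empty yields `NA`.
#'
#' @param intervals Interval data.frame.
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a path to a FASTA file.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
gc_content <- function(intervals, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  # FASTA headers may carry descriptions; keep the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  vapply(seq_len(nrow(intervals)), function(i) {
    chr <- intervals$chrom[i]
    if (!chr %in% names(genome)) stop("chromosome not in genome: ", chr)
    if (intervals$end[i] > Biostrings::nchar(genome[[chr]]))
      stop("interval beyond sequence end on ", chr)
    s <- Biostrings::subseq(genome[[chr]], intervals$start[i] + 1L,
                            intervals$end[i])
    f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    den <- sum(f)
    if (den == 0) return(NA_real_)
    unname((f[["C"]] + f[["G"]]) / den)
  }, numeric(1))
}

#' Fraction of enhancers overlapping at least one CpG island
#'
#' An overlap of one or more bases counts.
#'
#' @param enhancers Interval data.frame.
#' @param cpg_islands Interval data.frame of islands (may be empty).
#' @return Proportion in `[0, 1]`.
#' @export
cpg_overlap_fraction <- function(enhancers, cpg_islands) {
  if (nrow(enhancers) == 0) return(NA_real_)
  if (is.null(cpg_islands) || nrow(cpg_islands) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(as_granges(enhancers),
                                       as_granges(cpg_islands))
  mean(hits >= 1)
}

#' Bin TSS distances and locus lengths for reporting
#'
#' Distance bins: <10 kb, 10-50 kb, >50 kb. Locus-length bins: <200 kb,
#' 200-500 kb, >500 kb.
#'
#' @param x Numeric vector of distances or lengths (bp).
#' @param what `"tss"` or `"locus"`.
#' @return Factor with three ordered levels; NA preserved.
#' @export
feature_bins <- function(x, what = c("tss", "locus")) {
  what <- match.arg(what)
  br <- if (what == "tss") c(-Inf, 1e4, 5e4, Inf) else c(-Inf, 2e5, 5e5, Inf)
  lb <- if (what == "tss") c("<10kb", "10-50kb", ">50kb")
        else c("<200kb", "200-500kb", ">500kb")
  cut(x, breaks = br, labels = lb, right = TRUE)
}
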