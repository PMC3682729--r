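#' @importFrom utils read.delim write.table head tail
NULL

# Internal convention: all coordinates are 0-based half-open (BED), on plain
# data.frames. GRanges (1-based closed) are used transiently for overlap ops.

#' Convert an interval data.frame to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return A [GenomicRanges::GRanges] (1-based closed coordinates).
#' @keywords internal
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a BED file into a 0-based interval data.frame
#'
#' @param path Path to a BED3+ file.
#' @return data.frame with `chrom`, `start`, `end` and, when present in the
#'   file, `id`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_df(gr)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$id <- as.character(mc$name)
  if (!is.null(mc$score)) df$score <- as.numeric(mc$score)
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- ifelse(s == "*", ".", s)
  df
}

#' Write an interval data.frame as BED
#'
#' @param df data.frame with `chrom`, `start`, `end`, optional `id`, `score`,
#'   `strand`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end)
  out$id <- if (!is.null(df$id)) df$id else "."
  out$score <- if (!is.null(df$score)) df$score else 0
  out$strand <- if (!is.null(df$strand)) df$strand else "."
  withr::with_options(list(scipen = 999),
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE))
  invisible(path)
}

#' Read/write the gene annotation table
#'
#' Tab-separated with header: chrom, start, end, strand, gene_id, tss.
#' Coordinates 0-based half-open; `tss` is the 0-based position of the
#' transcription start site (start for `+` genes, end-1 for `-` genes).
#'
#' @param path File path.
#' @return data.frame of genes.
#' @export
read_genes <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "tss")
  if (!all(need %in% names(g)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  g
}

#' @rdname read_genes
#' @param genes data.frame of genes.
#' @export
write_genes <- function(genes, path) {
  withr::with_options(list(scipen = 999),
    write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read/write a chrom.sizes file
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(x[[2]]), x[[1]])
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  withr::with_options(list(scipen = 999),
    write.table(data.frame(names(sizes), unname(sizes)), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE))
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

write_tsv <- function(df, path) {
  withr::with_options(list(scipen = 999),
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
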