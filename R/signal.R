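# Aggregate signal metaprofiles around enhancer midpoints and peak-overlap
# contrasts between enhancer classes.

#' Read a bedGraph track
#'
#' @param path bedGraph path.
#' @return A [GenomicRanges::GRanges] with a `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Mean signal metaprofile around enhancer midpoints
#'
#' For each enhancer, the track signal is averaged per bin over
#' `[midpoint - window, midpoint + window)`; the profile is the mean over
#' enhancers. Positions absent from the track read as 0; window parts
#' beyond a chromosome end also read as 0.
#'
#' @param enhancers Enhancer data.frame.
#' @param track A GRanges with `score` (see [read_bedgraph()]) or a bedGraph
#'   path.
#' @param window Half-window in bases (default 5000).
#' @param n_bins Number of bins (default 50); `2 * window` must be a
#'   multiple of `n_bins`.
#' @return List (`meta_profile`): `bin_centers` (offsets from the midpoint),
#'   `mean_signal`, `n_regions`, `window`, `n_bins`.
#' @export
signal_metaprofile <- function(enhancers, track, window = 5000, n_bins = 50) {
  stopifnot(n_bins >= 3, (2 * window) %% n_bins == 0)
  if (is.character(track)) track <- read_bedgraph(track)
  cov <- GenomicRanges::coverage(track, weight = "score")
  binw <- (2 * window) / n_bins
  mids <- interval_midpoint(enhancers)
  total <- numeric(n_bins)
  for (i in seq_len(nrow(enhancers))) {
    chr <- enhancers$chrom[i]
    vals <- numeric(2 * window)
    if (chr %in% names(cov)) {
      rl <- cov[[chr]]
      clen <- length(rl)
      w0 <- mids[i] - window          # 0-based window start
      lo <- max(w0, 0); hi <- min(mids[i] + window, clen)
      if (hi > lo) {
        seg <- as.numeric(S4Vectors::window(rl, start = lo + 1L, end = hi))
        vals[(lo - w0 + 1):(hi - w0)] <- seg
      }
    }
    total <- total + colMeans(matrix(vals, nrow = binw))
  }
  structure(list(
    bin_centers = seq(-window + binw / 2, window - binw / 2, by = binw),
    mean_signal = total / nrow(enhancers),
    n_regions = nrow(enhancers), window = window, n_bins = n_bins
  ), class = "meta_profile")
}

#' Peak-overlap contrast between two enhancer classes
#'
#' Counts enhancers of each class overlapping at least one peak and
#' contrasts the two splits with a two-sided Fisher's exact test.
#'
#' @param class_a,class_b Enhancer data.frames.
#' @param peaks Interval data.frame of peaks.
#' @return List: `n_overlap_a`, `n_a`, `n_overlap_b`, `n_b`, `odds_ratio`,
#'   `p_value`.
#' @export
mark_overlap_test <- function(class_a, class_b, peaks) {
  ov <- function(x) {
    if (nrow(peaks) == 0) return(rep(FALSE, nrow(x)))
    GenomicRanges::countOverlaps(as_granges(x), as_granges(peaks)) >= 1
  }
  a <- ov(class_a); b <- ov(class_b)
  ft <- fisher_exact_2x2(sum(a), sum(!a), sum(b), sum(!b))
  list(n_overlap_a = sum(a), n_a = length(a),
       n_overlap_b = sum(b), n_b = length(b),
       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}
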