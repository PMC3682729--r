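# Selection-pressure machinery: variant polarization by ancestral allele,
# derived-allele-frequency (DAF) spectra per region class, and the
# McDonald-Kreitman (MK) test with the neutrality index against a neutral
# (pseudogene) reference.

#' Read a VCF into a flat variant table
#'
#' Uses the INFO fields `AF` (alternate allele frequency) and `AA`
#' (ancestral allele). Multi-allelic records are split into bi-allelic
#' records before polarization.
#'
#' @param path Path to a VCF (4.x) file.
#' @return data.frame: `chrom`, `pos` (1-based), `ref`, `alt`, `af`, `aa`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  aa <- vcfR::extract.info(v, "AA")
  af <- vcfR::extract.info(v, "AF")
  alt <- strsplit(as.character(fx[, "ALT"]), ",", fixed = TRUE)
  afs <- strsplit(as.character(af), ",", fixed = TRUE)
  nalt <- lengths(alt)
  idx <- rep(seq_len(nrow(fx)), nalt)
  data.frame(
    chrom = as.character(fx[idx, "CHROM"]),
    pos = as.integer(fx[idx, "POS"]),
    ref = as.character(fx[idx, "REF"]),
    alt = unlist(alt),
    af = as.numeric(unlist(afs)),
    aa = ifelse(is.na(aa[idx]), ".", as.character(aa[idx])),
    stringsAsFactors = FALSE
  )
}

#' Polarize variants to derived allele frequencies
#'
#' `daf = af` when the ancestral allele equals the reference allele and
#' `1 - af` when it equals the alternate allele. Records whose ancestral
#' state is missing (".") or matches neither allele are skipped (`daf = NA`)
#' and counted.
#'
#' @param variants data.frame as returned by [read_variants()].
#' @return The input with a `daf` column; the number of skipped records is
#'   attached as attribute `n_skipped`.
#' @export
polarize_variants <- function(variants) {
  aa <- toupper(variants$aa)
  daf <- rep(NA_real_, nrow(variants))
  daf[aa == toupper(variants$ref)] <- variants$af[aa == toupper(variants$ref)]
  is_alt <- aa == toupper(variants$alt)
  daf[is_alt] <- 1 - variants$af[is_alt]
  variants$daf <- daf
  attr(variants, "n_skipped") <- sum(is.na(daf))
  variants
}

#' Subset variants to those falling inside a region set
#'
#' @param variants Variant data.frame (1-based `pos`).
#' @param regions Interval data.frame (0-based half-open).
#' @return The variants whose position lies inside any region.
#' @export
variants_in_regions <- function(variants, regions) {
  if (nrow(regions) == 0 || nrow(variants) == 0)
    return(variants[integer(0), , drop = FALSE])
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  hit <- GenomicRanges::countOverlaps(vgr, as_granges(regions)) >= 1
  variants[hit, , drop = FALSE]
}

#' DAF spectrum of a region class
#'
#' Counts polarizable variants inside the region set and the fraction with
#' `daf <= cutoff` (low-frequency variants). When a reference spectrum is
#' supplied, a two-sided Fisher's exact test contrasts the two
#' low-frequency/common splits.
#'
#' @param regions Interval data.frame, or NULL to use all variants.
#' @param variants Polarized variant data.frame (see [polarize_variants()]).
#' @param cutoff Low-frequency threshold on DAF (default 0.05).
#' @param reference Optional `daf_spectrum_result` to test against.
#' @param class_label Label for reporting.
#' @return A `daf_spectrum_result`: `class_label`, `low_freq_count`,
#'   `total_count`, `fraction`, `cutoff`, `p_value`.
#' @export
daf_spectrum <- function(regions, variants, cutoff = 0.05, reference = NULL,
                         class_label = "") {
  v <- if (is.null(regions)) variants else variants_in_regions(variants, regions)
  daf <- v$daf[!is.na(v$daf)]
  daf_spectrum_from_counts(sum(daf <= cutoff), length(daf),
                           class_label = class_label, cutoff = cutoff,
                           reference = reference)
}

#' DAF spectrum result from printed counts
#'
#' Builds the same result object from already-tabulated counts (e.g. the
#' published low-frequency/total counts of a study).
#'
#' @param low_freq_count Variants with `daf <= cutoff`.
#' @param total_count All polarizable variants.
#' @param class_label Label for reporting.
#' @param cutoff DAF threshold the counts were tabulated at.
#' @param reference Optional reference `daf_spectrum_result`.
#' @return A `daf_spectrum_result`.
#' @export
daf_spectrum_from_counts <- function(low_freq_count, total_count,
                                     class_label = "", cutoff = 0.05,
                                     reference = NULL) {
  stopifnot(low_freq_count <= total_count)
  p <- NA_real_
  if (!is.null(reference)) {
    p <- fisher_exact_2x2(low_freq_count, total_count - low_freq_count,
                          reference$low_freq_count,
                          reference$total_count - reference$low_freq_count)$p_value
  }
  structure(list(class_label = class_label, low_freq_count = low_freq_count,
                 total_count = total_count,
                 fraction = if (total_count > 0) low_freq_count / total_count
                            else NA_real_,
                 cutoff = cutoff, p_value = p),
            class = "daf_spectrum_result")
}

#' Assemble a DAF table over several region classes
#'
#' @param spectra List of `daf_spectrum_result` (test classes).
#' @param reference Reference `daf_spectrum_result` (appended as last row).
#' @return data.frame: `class_label`, `low_freq_count`, `total_count`,
#'   `fraction`, `pct` (percent, 1 d.p.), `p_value` vs the reference.
#' @export
daf_table <- function(spectra, reference) {
  rows <- lapply(spectra, function(sp) {
    p <- sp$p_value
    if (is.na(p))
      p <- fisher_exact_2x2(sp$low_freq_count,
                            sp$total_count - sp$low_freq_count,
                            reference$low_freq_count,
                            reference$total_count - reference$low_freq_count)$p_value
    data.frame(class_label = sp$class_label,
               low_freq_count = sp$low_freq_count,
               total_count = sp$total_count, fraction = sp$fraction,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    class_label = reference$class_label,
    low_freq_count = reference$low_freq_count,
    total_count = reference$total_count, fraction = reference$fraction,
    p_value = NA_real_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$pct <- round(100 * out$fraction, 1)
  out
}

#' Fixed differences from divergence and heterozygosity
#'
#' `D = d - pi`: nucleotide differences to the sister species minus
#' heterozygous sites. Negative values (noisy input) are floored at 0 with
#' a warning.
#'
#' @param d Nucleotide difference count(s).
#' @param pi Heterozygous site count(s).
#' @return Non-negative fixed-difference count(s).
#' @export
compute_D <- function(d, pi) {
  D <- d - pi
  if (any(D < 0)) {
    warning("pi exceeds d for ", sum(D < 0), " region(s); D floored at 0")
    D <- pmax(D, 0)
  }
  D
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than that of the observed
#' table, computed in log space (stable for counts up to ~1e6). The odds
#' ratio reported is the sample odds ratio `(a d)/(b c)`.
#'
#' @param a,b,c,d Non-negative integer cells, rows `(a, b)` and `(c, d)`.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop("cells must be non-negative integers")
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  lp <- lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
        lgamma(n + 1) - lgamma(k - x + 1) - lgamma(n - k + x + 1) -
        (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1))
  lobs <- lp[x == a]
  p <- sum(exp(lp[lp <= lobs + 1e-7]))
  list(p_value = min(1, p),
       odds_ratio = (a * d) / (b * c))
}

#' McDonald-Kreitman test with neutrality index
#'
#' Contrasts polymorphism/fixed-difference counts of a test region class
#' (`Pe`, `De`) with a neutral reference (`Pn`, `Dn`). The neutrality index
#' is `(Pe/De)/(Pn/Dn)`; NI > 1 indicates negative selection, NI < 1
#' positive selection. Significance by a two-sided Fisher's exact test on
#' `[[Pe, De], [Pn, Dn]]`.
#'
#' @param Pe,De Test polymorphism and fixed-difference counts.
#' @param Pn,Dn Reference polymorphism and fixed-difference counts.
#' @return An `mk_result`: counts, `neutrality_index`, `p_value`, `regime`
#'   (`negative`/`neutral`/`positive`), and `reason` when undefined.
#' @export
mk_test <- function(Pe, De, Pn, Dn) {
  stopifnot(all(c(Pe, De, Pn, Dn) >= 0))
  if (De == 0 || Dn == 0 || Pn == 0) {
    return(structure(list(Pe = Pe, De = De, Pn = Pn, Dn = Dn,
                          neutrality_index = NA_real_, p_value = NA_real_,
                          regime = NA_character_,
                          reason = "zero denominator"),
                     class = "mk_result"))
  }
  ni <- (Pe / De) / (Pn / Dn)
  p <- fisher_exact_2x2(Pe, De, Pn, Dn)$p_value
  regime <- if (ni > 1) "negative" else if (ni < 1) "positive" else "neutral"
  structure(list(Pe = Pe, De = De, Pn = Pn, Dn = Dn, neutrality_index = ni,
                 p_value = p, regime = regime, reason = ""),
            class = "mk_result")
}

#' MK counts for a region class
#'
#' `P` = polymorphic (polarizable or not) SNP sites inside the regions;
#' `d` and `pi` are summed from a per-region divergence/heterozygosity
#' table; `D` via [compute_D()] on the summed counts.
#'
#' @param regions Interval data.frame with an `id` column.
#' @param variants Variant data.frame.
#' @param divergence data.frame (`region_id`, `d`, `pi`).
#' @return List with `P`, `d`, `pi`, `D`.
#' @export
mk_counts <- function(regions, variants, divergence) {
  P <- nrow(variants_in_regions(variants, regions))
  dv <- divergence[divergence$region_id %in% regions$id, , drop = FALSE]
  d <- sum(dv$d); pi <- sum(dv$pi)
  list(P = P, d = d, pi = pi, D = compute_D(d, pi))
}
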