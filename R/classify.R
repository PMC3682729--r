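# Cross-species enhancer classification: shared vs lineage-specific by
# lift-over and overlap, and the class I/II/III partition of
# lineage-specific enhancers by orthologous sequence presence and ChIP-Seq
# read density relative to the conserved-region background.

#' Classification parameters
#'
#' @param min_match Minimum lifted fraction for an interval to map
#'   (default 0.95, the liftOver default).
#' @param overlap_rule Minimum overlap in bases for a query enhancer and a
#'   lifted reference enhancer to be called shared (default 1).
#' @param background_density Mean ChIP-Seq read density over
#'   evolutionarily conserved regions (ECRs); the class I/II threshold.
#' @return List of class `classification_config`.
#' @export
classification_config <- function(min_match = 0.95, overlap_rule = 1,
                                  background_density = NULL) {
  stopifnot(min_match > 0, min_match <= 1, overlap_rule >= 1)
  structure(list(min_match = min_match, overlap_rule = overlap_rule,
                 background_density = background_density),
            class = "classification_config")
}

#' Shared vs lineage-specific classification by cross-mapping
#'
#' Reference enhancers are lifted into query coordinates; every query
#' enhancer overlapping (>= `overlap_rule` bases) at least one lifted
#' reference enhancer is labeled `shared`, the rest `lineage_specific`.
#' Reference enhancers whose lifted position overlaps no query enhancer are
#' flagged `reference_specific` (functional non-conservation; their
#' sequence may still be conserved).
#'
#' @param query_enh,reference_enh Enhancer data.frames with `id`.
#' @param chains_ref_to_query Chains lifting reference coordinates into the
#'   query genome.
#' @param config A [classification_config()].
#' @return List: `query` (input + `class_label`), `reference` (input +
#'   `reference_specific` logical + lifted coordinates), `lifted` (the raw
#'   mapping table).
#' @export
cross_map_enhancer_sets <- function(query_enh, reference_enh,
                                    chains_ref_to_query,
                                    config = classification_config()) {
  lift <- map_intervals(reference_enh, chains_ref_to_query,
                        min_match = config$min_match)
  mapped <- lift[lift$status == "mapped", , drop = FALSE]
  qlab <- rep("lineage_specific", nrow(query_enh))
  rspec <- rep(TRUE, nrow(reference_enh))
  if (nrow(mapped) > 0) {
    lgr <- GenomicRanges::GRanges(
      mapped$target_chrom,
      IRanges::IRanges(mapped$target_start + 1L, mapped$target_end))
    qgr <- as_granges(query_enh)
    hits <- GenomicRanges::findOverlaps(qgr, lgr,
                                        minoverlap = config$overlap_rule)
    qlab[unique(S4Vectors::queryHits(hits))] <- "shared"
    hit_ref_ids <- mapped$id[unique(S4Vectors::subjectHits(hits))]
    rspec[reference_enh$id %in% hit_ref_ids] <- FALSE
  }
  query <- query_enh
  query$class_label <- qlab
  reference <- reference_enh
  reference$reference_specific <- rspec
  m <- match(reference$id, lift$id)
  reference$lifted_chrom <- lift$target_chrom[m]
  reference$lifted_start <- lift$target_start[m]
  reference$lifted_end <- lift$target_end[m]
  reference$lift_status <- lift$status[m]
  list(query = query, reference = reference, lifted = lift)
}

#' Mean read density over an interval
#'
#' Looks an interval up in a precomputed density table (`chrom`, `start`,
#' `end`, `density`, reads per base); the value is the overlap-length
#' weighted mean over intersecting rows. Intervals with no density
#' information yield 0 with a warning from the caller.
#'
#' @param intervals Interval data.frame.
#' @param density_source data.frame (`chrom`, `start`, `end`, `density`).
#' @return Numeric vector (NA where no overlap).
#' @export
density_lookup <- function(intervals, density_source) {
  out <- rep(NA_real_, nrow(intervals))
  if (nrow(intervals) == 0 || nrow(density_source) == 0) return(out)
  igr <- as_granges(intervals)
  dgr <- as_granges(density_source)
  hits <- GenomicRanges::findOverlaps(igr, dgr)
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(IRanges::pintersect(igr[qh], dgr[sh]))
  num <- tapply(w * density_source$density[sh], qh, sum)
  den <- tapply(w, qh, sum)
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  out
}

#' Mean ECR background read density
#'
#' @param ecr_density data.frame (`chrom`, `start`, `end`, `density`).
#' @return Scalar mean density over ECRs.
#' @export
ecr_background_density <- function(ecr_density) {
  mean(ecr_density$density)
}

#' Partition lineage-specific enhancers into classes I/II/III
#'
#' Enhancers that cannot be lifted into the reference genome are class III
#' (no orthologous sequence). Lifted enhancers whose orthologue ChIP-Seq
#' read density exceeds the ECR background are class I (equivocal: possibly
#' weak reference enhancers); the rest are class II (sequence conserved, no
#' reference signal).
#'
#' @param lineage_enh Lineage-specific enhancer data.frame with `id`.
#' @param chains_query_to_ref Chains lifting query coordinates into the
#'   reference genome.
#' @param density_source Reference-genome density table (see
#'   [density_lookup()]).
#' @param config A [classification_config()] with `background_density` set.
#' @return data.frame: `id`, `class_label` (`class1`/`class2`/`class3`),
#'   `ortho_chrom`, `ortho_start`, `ortho_end`, `ortho_density`,
#'   `mapped_fraction`.
#' @export
classify_lineage_specific <- function(lineage_enh, chains_query_to_ref,
                                      density_source, config) {
  if (is.null(config$background_density))
    stop("config$background_density must be set (see ecr_background_density)")
  lift <- map_intervals(lineage_enh, chains_query_to_ref,
                        min_match = config$min_match)
  cls <- rep("class3", nrow(lineage_enh))
  dens <- rep(NA_real_, nrow(lineage_enh))
  mp <- which(lift$status == "mapped")
  if (length(mp) > 0) {
    ortho <- data.frame(chrom = lift$target_chrom[mp],
                        start = lift$target_start[mp],
                        end = lift$target_end[mp], stringsAsFactors = FALSE)
    d <- density_lookup(ortho, density_source)
    if (anyNA(d)) {
      warning(sum(is.na(d)),
              " mapped orthologue(s) without density information; treated as 0")
      d[is.na(d)] <- 0
    }
    dens[mp] <- d
    cls[mp] <- ifelse(d > config$background_density, "class1", "class2")
  }
  data.frame(id = lineage_enh$id, class_label = cls,
             ortho_chrom = lift$target_chrom, ortho_start = lift$target_start,
             ortho_end = lift$target_end, ortho_density = dens,
             mapped_fraction = lift$mapped_fraction, stringsAsFactors = FALSE)
}

#' Classification summary with lineage-specific percentage
#'
#' @param class_labels Character vector of per-enhancer labels, or NULL if
#'   `n_total`/`n_shared` are given directly.
#' @param n_total,n_shared Direct counts (used when `class_labels` is NULL).
#' @return List: `counts` (table), `n_total`, `n_shared`,
#'   `pct_lineage_specific` (nearest integer).
#' @export
classification_summary <- function(class_labels = NULL, n_total = NULL,
                                   n_shared = NULL) {
  if (!is.null(class_labels)) {
    counts <- table(class_labels)
    n_total <- length(class_labels)
    n_shared <- sum(class_labels == "shared")
  } else {
    stopifnot(!is.null(n_total), !is.null(n_shared))
    counts <- c(shared = n_shared, lineage_specific = n_total - n_shared)
  }
  list(counts = counts, n_total = n_total, n_shared = n_shared,
       pct_lineage_specific = round(100 * (n_total - n_shared) / n_total))
}

#' Out-group presence of class III enhancers
#'
#' A class III enhancer is "present" in the out-groups if its sequence can
#' be lifted (per [map_interval()]) into at least one out-group genome;
#' presence in an out-group implies the sequence is ancestral and was
#' deleted in the reference lineage rather than inserted in the query
#' lineage.
#'
#' @param class3_enh Enhancer data.frame with `id`.
#' @param outgroup_chains Named list; one chain list per out-group species.
#' @param min_match Minimum lifted fraction (default 0.95).
#' @return List: `present` (named logical per enhancer), `n_present`,
#'   `n_total`, `fraction`, `pct` (nearest integer).
#' @export
outgroup_presence <- function(class3_enh, outgroup_chains, min_match = 0.95) {
  n <- nrow(class3_enh)
  if (length(outgroup_chains) == 0) {
    warning("no out-group chain sets supplied; presence fraction is 0")
    present <- stats::setNames(rep(FALSE, n), class3_enh$id)
  } else {
    present <- rep(FALSE, n)
    for (chains in outgroup_chains) {
      if (all(present)) break
      todo <- which(!present)
      m <- map_intervals(class3_enh[todo, , drop = FALSE], chains,
                         min_match = min_match)
      present[todo[m$status == "mapped"]] <- TRUE
    }
    present <- stats::setNames(present, class3_enh$id)
  }
  list(present = present, n_present = sum(present), n_total = n,
       fraction = if (n > 0) sum(present) / n else NA_real_,
       pct = if (n > 0) round(100 * sum(present) / n) else NA_real_)
}

#' Out-group presence summary from printed counts
#'
#' @param n_present,n_total Counts of present and total regions.
#' @return Same summary fields as [outgroup_presence()].
#' @export
outgroup_presence_summary <- function(n_present, n_total) {
  stopifnot(n_present <= n_total, n_total > 0)
  list(n_present = n_present, n_total = n_total,
       fraction = n_present / n_total, pct = round(100 * n_present / n_total))
}
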