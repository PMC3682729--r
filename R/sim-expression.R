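# Expression tables, GO annotations and signal tracks with planted
# structure: heart-high genes (boosted heart_effect-fold in heart samples)
# are drawn from loci of shared enhancers; cardiac-named GO terms
# preferentially annotate those genes; signal bumps sit on a chosen
# enhancer subset.

#' Pick the planted heart-high genes
#'
#' Member genes of shared-enhancer loci, topped up with random genes when
#' fewer than requested exist.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @param enhancer_sets Output of [generate_enhancer_sets()].
#' @return Character vector of gene ids.
#' @export
planted_heart_genes <- function(config, annotation, enhancer_sets) {
  q <- enhancer_sets$query
  sh <- q[q$true_label == "shared", , drop = FALSE]
  asg <- assign_enhancers_to_loci(sh, annotation$genes,
                                  annotation$chrom_sizes)
  pool <- unique(unlist(strsplit(asg$genes, ",", fixed = TRUE)))
  pool <- pool[pool != ""]
  withr::with_seed(.sim_seed(config, "expression") - 1L, {
    n <- min(config$n_planted_heart_genes, nrow(annotation$genes))
    if (length(pool) >= n) {
      planted <- sample(pool, n)
    } else {
      extra <- sample(setdiff(annotation$genes$gene_id, pool),
                      n - length(pool))
      planted <- c(pool, extra)
    }
  })
  sort(planted)
}

#' Generate heart / non-heart expression tables for both species
#'
#' Per-gene baselines are log-normal; planted heart genes are boosted
#' `heart_effect`-fold in heart samples; every value carries log-normal
#' sample noise. The reference species mirrors the query profiles (with
#' fresh noise) through a one-to-one homolog map.
#'
#' @param config A [sim_config()].
#' @param genes Gene data.frame.
#' @param planted Character vector of planted heart-high gene ids.
#' @return List: `heart`, `nonheart`, `ref_heart`, `ref_nonheart`
#'   (gene_id + sample columns), `homolog_map`, `planted`.
#' @export
generate_expression_tables <- function(config, genes, planted) {
  validate_sim_config(config)
  ng <- nrow(genes)
  gid <- genes$gene_id
  rid <- sub("^g", "rg", gid)
  noise <- function(n) stats::rlnorm(n, 0, 0.15)
  tab <- function(base, ids, n_samp, prefix) {
    m <- vapply(seq_len(n_samp), function(s) base * noise(length(base)),
                numeric(length(base)))
    colnames(m) <- paste0(prefix, seq_len(n_samp))
    data.frame(gene_id = ids, round(m, 3), stringsAsFactors = FALSE)
  }
  withr::with_seed(.sim_seed(config, "expression"), {
    base <- stats::rlnorm(ng, log(100), 1)
    boost <- ifelse(gid %in% planted, config$heart_effect, 1)
    heart <- tab(base * boost, gid, config$n_heart_samples, "heart_s")
    nonheart <- tab(base, gid, config$n_nonheart_samples, "nh_s")
    ref_heart <- tab(base * boost, rid, config$n_heart_samples, "heart_s")
    ref_nonheart <- tab(base, rid, config$n_nonheart_samples, "nh_s")
  })
  list(heart = heart, nonheart = nonheart, ref_heart = ref_heart,
       ref_nonheart = ref_nonheart,
       homolog_map = data.frame(query_gene_id = gid, reference_gene_id = rid,
                                stringsAsFactors = FALSE),
       planted = planted)
}

#' Generate a flat GO annotation table
#'
#' `frac_cardiac_terms` of the terms get cardiac names (containing
#' "heart", "cardiac" or "cardio"); cardiac terms draw their genes with a
#' 10x weight on the planted heart genes, other terms annotate uniformly.
#'
#' @param config A [sim_config()].
#' @param genes Gene data.frame.
#' @param planted Planted heart-high gene ids (the cardiac bias target).
#' @param uniform When TRUE, ignore the bias (null annotation).
#' @return data.frame: `term_id`, `term_name`, `gene_id`.
#' @export
generate_go_annotations <- function(config, genes, planted,
                                    uniform = FALSE) {
  validate_sim_config(config)
  nt <- config$n_go_terms
  nc <- round(config$frac_cardiac_terms * nt)
  cardiac_stems <- c("heart morphogenesis", "cardiac muscle development",
                     "cardiovascular system process", "heart contraction",
                     "cardiac septum formation", "cardioblast migration")
  other_stems <- c("ribosome biogenesis", "axon guidance",
                   "lipid metabolic process", "chromatin remodeling",
                   "immune response regulation", "kidney development")
  gid <- genes$gene_id
  w <- rep(1, length(gid))
  if (!uniform) w[gid %in% planted] <- 10
  withr::with_seed(.sim_seed(config, "go"), {
    rows <- lapply(seq_len(nt), function(t) {
      cardiac <- t <= nc
      stem <- if (cardiac) cardiac_stems[1 + (t %% length(cardiac_stems))]
              else other_stems[1 + (t %% length(other_stems))]
      k <- sample(5:30, 1)
      k <- min(k, length(gid))
      g <- sample(gid, k, prob = if (cardiac) w else NULL)
      data.frame(term_id = sprintf("GO:%06d", t),
                 term_name = paste(stem, "variant", t),
                 gene_id = g, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Generate a bedGraph signal track with planted bumps
#'
#' Uniform background over windows around every enhancer plus
#' Gaussian-shaped bumps centered on a chosen enhancer subset.
#'
#' @param config A [sim_config()].
#' @param enhancers Enhancer data.frame.
#' @param bump_ids Enhancer ids receiving a bump (default: none).
#' @param chrom_sizes Named chromosome lengths.
#' @param window Half-window emitted around each enhancer (default 6000).
#' @param bin Bin width in bases (default 100).
#' @return data.frame (`chrom`, `start`, `end`, `score`) in bedGraph order.
#' @export
generate_signal_track <- function(config, enhancers, bump_ids = character(0),
                                  chrom_sizes, window = 6000, bin = 100) {
  validate_sim_config(config)
  mids <- interval_midpoint(enhancers)
  sigma <- config$signal_bump_sigma
  withr::with_seed(.sim_seed(config, "signal"), {
    pieces <- lapply(unique(enhancers$chrom), function(ch) {
      ei <- which(enhancers$chrom == ch)
      L <- chrom_sizes[[ch]]
      bidx <- sort(unique(unlist(lapply(mids[ei], function(m) {
        lo <- max(floor((m - window) / bin), 0)
        hi <- min(ceiling((m + window) / bin), floor(L / bin) - 1)
        lo:hi
      }))))
      centers <- bidx * bin + bin / 2
      score <- rep(config$signal_background, length(bidx)) +
        stats::rnorm(length(bidx), 0, 0.02 * config$signal_background)
      for (j in ei[enhancers$id[ei] %in% bump_ids]) {
        if (sigma <= 0) {
          hit <- which(bidx == floor(mids[j] / bin))
          score[hit] <- score[hit] + config$signal_bump_height
        } else {
          contrib <- config$signal_bump_height *
            exp(-(centers - mids[j])^2 / (2 * sigma^2))
          score <- score + contrib
        }
      }
      data.frame(chrom = ch, start = bidx * bin, end = (bidx + 1) * bin,
                 score = round(pmax(score, 0), 4), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, pieces)
}

#' Write a bedGraph file
#'
#' @param track data.frame (`chrom`, `start`, `end`, `score`).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  withr::with_options(list(scipen = 999),
    write.table(track, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE))
  invisible(path)
}
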