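# Synthetic genome, annotation, enhancer sets and pairwise alignment with
# planted ground truth. The reference genome is modelled as the query
# genome with planted deletions removed (class III enhancer loss) plus
# small reference-only insertions and short unaligned (mutual-gap)
# segments, so the chain mapper's gap logic is exercised.

#' Generate a gene annotation and chromosome sizes
#'
#' Genes are non-overlapping intervals with random strand; the TSS is the
#' strand-appropriate end (start for `+`, end-1 for `-`).
#'
#' @param config A [sim_config()].
#' @return List: `genes` (data.frame), `chrom_sizes` (named vector).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                           chroms)
  if (config$n_genes == 0)
    return(list(genes = data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), strand = character(0),
                                   gene_id = character(0), tss = numeric(0),
                                   stringsAsFactors = FALSE),
                chrom_sizes = sizes))
  per <- diff(round(seq(0, config$n_genes,
                        length.out = config$n_chromosomes + 1)))
  min_gap <- 2000
  withr::with_seed(.sim_seed(config, "annotation"), {
    pieces <- lapply(seq_along(chroms), function(ci) {
      n <- per[ci]
      if (n == 0) return(NULL)
      len <- round(stats::runif(n, config$gene_length_range[1],
                                config$gene_length_range[2]))
      leftover <- config$chrom_length - sum(len) - (n + 1) * min_gap
      if (leftover < 0)
        stop("chromosome too short to place ", n,
             " non-overlapping genes of the configured lengths")
      w <- stats::runif(n + 1)
      gaps <- min_gap + floor(leftover * w / sum(w))
      starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(len))[seq_len(n)]
      strand <- sample(c("+", "-"), n, replace = TRUE)
      data.frame(chrom = chroms[ci], start = starts, end = starts + len,
                 strand = strand, stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, pieces)
  })
  g$gene_id <- sprintf("g%05d", seq_len(nrow(g)))
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  list(genes = g, chrom_sizes = sizes)
}

# ---- placement helpers -----------------------------------------------------

.overlaps_any <- function(s, e, starts, ends, pad = 0) {
  length(starts) > 0 && any(starts < e + pad & ends > s - pad)
}

# intergenic gap or host-gene interval containing/flanking a position
.home_region <- function(s, e, gs, ge) {
  if (length(gs) == 0) return(c(NA, NA))
  k <- findInterval(e - 1, gs)
  j <- NA_integer_
  while (k >= 1) {
    if (ge[k] > s && gs[k] < e) { j <- k; break }
    if (ge[k] <= s) break
    k <- k - 1L
  }
  if (!is.na(j)) return(c(gs[j], ge[j]))           # intronic: host gene
  p <- findInterval(s, gs)                         # intergenic gap
  c(if (p >= 1) ge[p] else 0, if (p < length(gs)) gs[p + 1] else NA)
}

#' Generate query and reference enhancer sets with planted ground truth
#'
#' Query enhancers receive true labels (shared, class1, class2, class3)
#' in the configured proportions. Shared enhancers get an aligned,
#' overlapping counterpart in the reference set; class III enhancers fall
#' inside planted alignment deletions; class I orthologues get reference
#' read density above the ECR background, class II at or below it.
#' `clustering_bias` is the probability that an enhancer is placed into a
#' locus already occupied by its own group (shared vs lineage-specific),
#' planting the assortative clustering signal.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List: `query` and `reference` enhancer data.frames, `alignment`
#'   (block structure reused by [generate_chain_file()]), and
#'   `ground_truth` (query labels, reference-specific flags, planted
#'   deletions, reference chromosome sizes).
#' @export
generate_enhancer_sets <- function(config, annotation) {
  validate_sim_config(config)
  genes <- annotation$genes
  sizes <- annotation$chrom_sizes
  chroms <- names(sizes)
  nq <- config$n_enhancers_query
  n_shared <- round(config$frac_shared * nq)
  n_ls <- nq - n_shared
  n_c1 <- round(config$frac_class1 * n_ls)
  n_c2 <- round(config$frac_class2 * n_ls)
  n_c3 <- n_ls - n_c1 - n_c2
  if (n_c3 < 0) stop("infeasible class fractions")
  n_rspec <- config$n_enhancers_reference - n_shared
  if (n_rspec < 0) stop("n_enhancers_reference < planted shared count")
  gs <- lapply(chroms, function(ch) sort(genes$start[genes$chrom == ch]))
  ge <- lapply(chroms, function(ch) {
    g <- genes[genes$chrom == ch, ]
    g$end[order(g$start)]
  })
  names(gs) <- names(ge) <- chroms
  pad <- 2000
  occ <- lapply(chroms, function(ch) list(s = numeric(0), e = numeric(0)))
  names(occ) <- chroms
  withr::with_seed(.sim_seed(config, "enhancers"), {
    lab <- c(rep("shared", n_shared),
             sample(c(rep("class1", n_c1), rep("class2", n_c2),
                      rep("class3", n_c3))))
    len <- round(stats::runif(nq, config$enhancer_length_range[1],
                              config$enhancer_length_range[2]))
    chrom <- character(nq); start <- numeric(nq)
    grp <- ifelse(lab == "shared", "shared", "lineage")
    placed_by_grp <- list(shared = integer(0), lineage = integer(0))
    pick_random <- function(l) {
      for (try in 1:200) {
        ch <- sample(chroms, 1)
        s <- floor(stats::runif(1, pad, sizes[[ch]] - l - pad))
        if (!.overlaps_any(s, s + l, occ[[ch]]$s, occ[[ch]]$e, pad))
          return(list(ch = ch, s = s))
      }
      stop("could not place enhancer; genome too crowded")
    }
    for (i in seq_len(nq)) {
      pos <- NULL
      anchors <- placed_by_grp[[grp[i]]]
      if (length(anchors) > 0 && stats::runif(1) < config$clustering_bias) {
        a <- anchors[sample.int(length(anchors), 1)]
        hr <- .home_region(start[a], start[a] + len[a],
                           gs[[chrom[a]]], ge[[chrom[a]]])
        lo <- if (is.na(hr[1])) 0 else hr[1]
        hi <- if (is.na(hr[2])) sizes[[chrom[a]]] else hr[2]
        if (hi - lo > len[i] + 2) {
          for (try in 1:25) {
            s <- floor(stats::runif(1, lo + 1, hi - len[i] - 1))
            if (!.overlaps_any(s, s + len[i], occ[[chrom[a]]]$s,
                               occ[[chrom[a]]]$e, pad)) {
              pos <- list(ch = chrom[a], s = s)
              break
            }
          }
        }
      }
      if (is.null(pos)) pos <- pick_random(len[i])
      chrom[i] <- pos$ch; start[i] <- pos$s
      occ[[pos$ch]]$s <- c(occ[[pos$ch]]$s, pos$s)
      occ[[pos$ch]]$e <- c(occ[[pos$ch]]$e, pos$s + len[i])
      placed_by_grp[[grp[i]]] <- c(placed_by_grp[[grp[i]]], i)
    }
    query <- data.frame(chrom = chrom, start = start, end = start + len,
                        true_label = lab, stringsAsFactors = FALSE)
    ord <- order(match(query$chrom, chroms), query$start)
    query <- query[ord, ]
    query$id <- sprintf("q_e%05d", seq_len(nq))
    query$species <- "query"
    rownames(query) <- NULL
    # planted deletions around class III enhancers
    del_pad <- 300
    c3 <- query[query$true_label == "class3", , drop = FALSE]
    deletions <- data.frame(chrom = c3$chrom, start = c3$start - del_pad,
                            end = c3$end + del_pad, stringsAsFactors = FALSE)
    # alignment (own seed inside; nesting restores this op's RNG stream)
    avoid <- query[, c("chrom", "start", "end")]
    alignment <- .sim_alignment(config, sizes, deletions, avoid)
    # reference-specific enhancers: placed in query coordinate space away
    # from query enhancers and alignment discontinuities, then projected
    rs_len <- round(stats::runif(n_rspec, config$enhancer_length_range[1],
                                 config$enhancer_length_range[2]))
    ev_avoid <- alignment$event_intervals
    rs_chrom <- character(n_rspec); rs_q_start <- numeric(n_rspec)
    for (i in seq_len(n_rspec)) {
      repeat {
        ch <- sample(chroms, 1)
        s <- floor(stats::runif(1, pad, sizes[[ch]] - rs_len[i] - pad))
        ev <- ev_avoid[[ch]]
        if (!.overlaps_any(s, s + rs_len[i], occ[[ch]]$s, occ[[ch]]$e, 500) &&
            !.overlaps_any(s, s + rs_len[i], ev$s, ev$e, 500)) break
      }
      rs_chrom[i] <- ch; rs_q_start[i] <- s
      occ[[ch]]$s <- c(occ[[ch]]$s, s)
      occ[[ch]]$e <- c(occ[[ch]]$e, s + rs_len[i])
    }
    jitter <- round(stats::runif(n_shared, -150, 150))
  })
  # project shared counterparts and reference-specific enhancers to the
  # reference genome
  proj <- function(ch, p) .project_q2r(p, alignment$blocks[[ch]])
  sh <- query[query$true_label == "shared", , drop = FALSE]
  sh_r_start <- mapply(proj, sh$chrom, sh$start) + jitter
  sh_r_end <- mapply(proj, sh$chrom, sh$end - 1) + 1 + jitter
  rs_r_start <- mapply(proj, rs_chrom, rs_q_start)
  rs_r_end <- mapply(proj, rs_chrom, rs_q_start + rs_len - 1) + 1
  if (anyNA(c(sh_r_start, rs_r_start)))
    stop("internal: planted enhancer fell into an alignment gap")
  reference <- data.frame(
    chrom = c(sh$chrom, rs_chrom),
    start = c(sh_r_start, rs_r_start),
    end = c(sh_r_end, rs_r_end),
    counterpart_of = c(sh$id, rep(NA_character_, n_rspec)),
    true_reference_specific = c(rep(FALSE, nrow(sh)), rep(TRUE, n_rspec)),
    stringsAsFactors = FALSE)
  ord <- order(match(reference$chrom, chroms), reference$start)
  reference <- reference[ord, ]
  reference$id <- sprintf("r_e%05d", seq_len(nrow(reference)))
  reference$species <- "reference"
  rownames(reference) <- NULL
  list(
    query = query[, c("chrom", "start", "end", "id", "species", "true_label")],
    reference = reference[, c("chrom", "start", "end", "id", "species",
                              "counterpart_of", "true_reference_specific")],
    alignment = alignment,
    ground_truth = list(
      query_labels = stats::setNames(query$true_label, query$id),
      reference_specific = stats::setNames(reference$true_reference_specific,
                                           reference$id),
      deletions = deletions,
      ref_chrom_sizes = alignment$ref_chrom_sizes)
  )
}

# ---- alignment model -------------------------------------------------------

# events: per-chromosome data.frame(pos, dt, dq, type); dt consumes query
# bases with no reference counterpart, dq inserts reference-only bases.
.sim_alignment <- function(config, chrom_sizes, deletions, avoid) {
  chroms <- names(chrom_sizes)
  av <- lapply(chroms, function(ch) {
    a <- avoid[avoid$chrom == ch, , drop = FALSE]
    d <- deletions[deletions$chrom == ch, , drop = FALSE]
    list(s = c(a$start, d$start), e = c(a$end, d$end))
  })
  names(av) <- chroms
  withr::with_seed(.sim_seed(config, "alignment"), {
    events <- lapply(chroms, function(ch) {
      L <- chrom_sizes[[ch]]
      d <- deletions[deletions$chrom == ch, , drop = FALSE]
      ev <- if (nrow(d) > 0)
        data.frame(pos = d$start, dt = d$end - d$start, dq = 0,
                   type = "deletion", stringsAsFactors = FALSE)
      else data.frame(pos = numeric(0), dt = numeric(0), dq = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
      taken <- list(s = c(av[[ch]]$s, ev$pos), e = c(av[[ch]]$e, ev$pos + ev$dt))
      draw <- function(w) {
        for (try in 1:1000) {
          p <- floor(stats::runif(1, 5000, L - 5000 - w))
          if (!.overlaps_any(p, p + w, taken$s, taken$e, 3000)) {
            taken$s <<- c(taken$s, p); taken$e <<- c(taken$e, p + w)
            return(p)
          }
        }
        NA_real_
      }
      for (k in 1:3) {                      # reference-only insertions
        w <- round(stats::runif(1, 100, 500))
        p <- draw(1)
        if (!is.na(p)) ev <- rbind(ev, data.frame(pos = p, dt = 0, dq = w,
                                                  type = "insertion"))
      }
      for (k in 1:2) {                      # interleaved mutual gaps
        w1 <- round(stats::runif(1, 50, 200))
        w2 <- round(stats::runif(1, 50, 200))
        p <- draw(w1)
        if (!is.na(p)) ev <- rbind(ev, data.frame(pos = p, dt = w1, dq = w2,
                                                  type = "mutual"))
      }
      p <- draw(1)                          # chain split point
      if (!is.na(p)) ev <- rbind(ev, data.frame(pos = p, dt = 0, dq = 0,
                                                type = "split"))
      ev[order(ev$pos), , drop = FALSE]
    })
  })
  names(events) <- chroms
  blocks <- lapply(chroms, function(ch) {
    L <- chrom_sizes[[ch]]
    ev <- events[[ch]]
    qs <- numeric(0); qe <- numeric(0); rs <- numeric(0); re <- numeric(0)
    grp <- integer(0)
    q <- 0; r <- 0; g <- 1L
    for (j in seq_len(nrow(ev))) {
      p <- ev$pos[j]
      if (p > q) {
        qs <- c(qs, q); qe <- c(qe, p)
        rs <- c(rs, r); re <- c(re, r + (p - q))
        grp <- c(grp, g)
        r <- r + (p - q)
      }
      q <- p + ev$dt[j]
      r <- r + ev$dq[j]
      if (ev$type[j] == "split") g <- g + 1L
    }
    if (L > q) {
      qs <- c(qs, q); qe <- c(qe, L)
      rs <- c(rs, r); re <- c(re, r + (L - q))
      grp <- c(grp, g)
      r <- r + (L - q)
    }
    data.frame(q_start = qs, q_end = qe, r_start = rs, r_end = re,
               chain_group = grp, ref_len = r, stringsAsFactors = FALSE)
  })
  names(blocks) <- chroms
  ref_sizes <- vapply(blocks, function(b)
    if (nrow(b) > 0) b$ref_len[1] else 0, numeric(1))
  names(ref_sizes) <- chroms
  event_intervals <- lapply(chroms, function(ch) {
    ev <- events[[ch]]
    list(s = ev$pos, e = ev$pos + pmax(ev$dt, 1))
  })
  names(event_intervals) <- chroms
  list(blocks = blocks, events = events, ref_chrom_sizes = ref_sizes,
       event_intervals = event_intervals)
}

.project_q2r <- function(pos, blocks_chr) {
  k <- findInterval(pos, blocks_chr$q_start)
  if (k < 1 || pos >= blocks_chr$q_end[k]) return(NA_real_)
  blocks_chr$r_start[k] + (pos - blocks_chr$q_start[k])
}

# assemble chain objects from per-chromosome block tables
.chains_from_blocks <- function(blocks, chrom_sizes, ref_sizes,
                                direction = c("q2r", "r2q")) {
  direction <- match.arg(direction)
  chains <- list()
  for (ch in names(blocks)) {
    b <- blocks[[ch]]
    if (nrow(b) == 0) next
    for (g in unique(b$chain_group)) {
      bb <- b[b$chain_group == g, , drop = FALSE]
      n <- nrow(bb)
      size <- bb$q_end - bb$q_start
      dtq <- c(bb$q_start[-1] - bb$q_end[-n], 0)
      dtr <- c(bb$r_start[-1] - bb$r_end[-n], 0)
      if (direction == "q2r") {
        ch_obj <- list(score = sum(size), source_chrom = ch,
                       source_size = unname(chrom_sizes[[ch]]),
                       source_strand = "+",
                       source_start = bb$q_start[1], source_end = bb$q_end[n],
                       target_chrom = ch, target_size = unname(ref_sizes[[ch]]),
                       target_strand = "+",
                       target_start = bb$r_start[1], target_end = bb$r_end[n],
                       id = paste0(ch, ".", g))
        ch_obj$blocks <- cbind(size = size, source_gap = dtq,
                               target_gap = dtr)
      } else {
        ch_obj <- list(score = sum(size), source_chrom = ch,
                       source_size = unname(ref_sizes[[ch]]),
                       source_strand = "+",
                       source_start = bb$r_start[1], source_end = bb$r_end[n],
                       target_chrom = ch, target_size = unname(chrom_sizes[[ch]]),
                       target_strand = "+",
                       target_start = bb$q_start[1], target_end = bb$q_end[n],
                       id = paste0(ch, ".", g))
        ch_obj$blocks <- cbind(size = size, source_gap = dtr,
                               target_gap = dtq)
      }
      chains[[length(chains) + 1L]] <- ch_obj
    }
  }
  chains
}

# a low-score off-diagonal chain (minus-strand target) that a correct
# highest-score-first mapper must ignore wherever a genuine chain overlaps
.decoy_chain <- function(src_chrom, src_size, tgt_chrom, tgt_size) {
  list(score = 50, source_chrom = src_chrom, source_size = unname(src_size),
       source_strand = "+", source_start = 0, source_end = 2000,
       target_chrom = tgt_chrom, target_size = unname(tgt_size),
       target_strand = "-", target_start = 0, target_end = 2000,
       id = "decoy",
       blocks = cbind(size = 2000, source_gap = 0, target_gap = 0))
}

#' Generate the pairwise chain files
#'
#' Produces chains in both directions (query to reference and reference to
#' query) over the planted alignment: identity off by the planted deletions,
#' small reference-only insertions, short mutual gaps, one chain split per
#' chromosome, and one low-score off-diagonal decoy chain per direction
#' (minus-strand target) exercising chain-selection order.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @param alignment Optional alignment from [generate_enhancer_sets()]; when
#'   absent it is rebuilt from `deletions`/`avoid` (or, with neither, from
#'   seed-derived deletions).
#' @param deletions Optional planted-deletion data.frame.
#' @param avoid Optional intervals alignment discontinuities must avoid.
#' @return List: `query_to_ref`, `ref_to_query` (chain lists),
#'   `ref_chrom_sizes`, `alignment`.
#' @export
generate_chain_file <- function(config, annotation, alignment = NULL,
                                deletions = NULL, avoid = NULL) {
  sizes <- annotation$chrom_sizes
  if (is.null(alignment)) {
    if (is.null(deletions)) {
      withr::with_seed(.sim_seed(config, "alignment") + 1L, {
        deletions <- do.call(rbind, lapply(names(sizes), function(ch) {
          s <- floor(stats::runif(2, 1e4, sizes[[ch]] - 2e4))
          data.frame(chrom = ch, start = s,
                     end = s + round(stats::runif(2, 5e3, 1.5e4)),
                     stringsAsFactors = FALSE)
        }))
      })
    }
    if (is.null(avoid))
      avoid <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0))
    alignment <- .sim_alignment(config, sizes, deletions, avoid)
  }
  q2r <- .chains_from_blocks(alignment$blocks, sizes,
                             alignment$ref_chrom_sizes, "q2r")
  r2q <- .chains_from_blocks(alignment$blocks, sizes,
                             alignment$ref_chrom_sizes, "r2q")
  if (length(sizes) >= 2) {
    q2r[[length(q2r) + 1L]] <- .decoy_chain(
      names(sizes)[1], sizes[[1]], names(sizes)[2],
      alignment$ref_chrom_sizes[[2]])
    r2q[[length(r2q) + 1L]] <- .decoy_chain(
      names(sizes)[1], alignment$ref_chrom_sizes[[1]], names(sizes)[2],
      sizes[[2]])
  }
  list(query_to_ref = q2r, ref_to_query = r2q,
       ref_chrom_sizes = alignment$ref_chrom_sizes, alignment = alignment)
}

#' Generate an out-group chain set for class III ancestry calls
#'
#' The synthetic out-group genome retains `frac_class3_outgroup` of the
#' class III regions (identity alignment) and lacks the rest, so the
#' expected out-group presence fraction is planted.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @param class3_enh Class III enhancer data.frame.
#' @return List: `chains` (single out-group chain list), `absent_ids`
#'   (class III enhancers deleted from the out-group).
#' @export
generate_outgroup_chains <- function(config, annotation, class3_enh) {
  sizes <- annotation$chrom_sizes
  n_absent <- round((1 - config$frac_class3_outgroup) * nrow(class3_enh))
  withr::with_seed(.sim_seed(config, "outgroup"), {
    absent <- if (n_absent > 0)
      sample(class3_enh$id, n_absent) else character(0)
  })
  ab <- class3_enh[class3_enh$id %in% absent, , drop = FALSE]
  deletions <- data.frame(chrom = ab$chrom, start = ab$start - 100,
                          end = ab$end + 100, stringsAsFactors = FALSE)
  # plain deletion-only alignment, no extra noise events
  blocks <- lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    d <- deletions[deletions$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    qs <- c(0, d$end); qe <- c(d$start, L)
    keep <- qe > qs
    qs <- qs[keep]; qe <- qe[keep]
    rs <- cumsum(c(0, (qe - qs)[-length(qs)]))
    data.frame(q_start = qs, q_end = qe, r_start = rs,
               r_end = rs + (qe - qs), chain_group = 1L,
               ref_len = sum(qe - qs), stringsAsFactors = FALSE)
  })
  names(blocks) <- names(sizes)
  ref_sizes <- vapply(blocks, function(b) b$ref_len[1], numeric(1))
  list(chains = .chains_from_blocks(blocks, sizes, ref_sizes, "q2r"),
       absent_ids = absent)
}
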