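# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (linear scans, closed forms) and share no code with
# the implementation paths they check.

small_sim_config <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 2L, chrom_length = 3e6,
         n_genes = 200L, n_enhancers_query = 400L,
         n_enhancers_reference = 520L, n_pseudogenes = 150L,
         n_ecr = 120L, n_go_terms = 100L, n_cpg_islands = 80L,
         n_planted_heart_genes = 60L),
    list(...))
  do.call(sim_config, args)
}

small_bundle_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "enhancerEvo_small_bundle")
      if (!file.exists(file.path(d, "manifest.json")))
        write_fixture_bundle(small_sim_config(), d)
      cache <<- d
    }
    cache
  }
})

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_fixture_bundle(small_bundle_dir())
    cache
  }
})

# one chain built directly from its header fields and block triples
make_chain <- function(score, s_chrom, s_size, s_start, s_end,
                       t_chrom, t_size, t_start, t_end, blocks,
                       t_strand = "+") {
  b <- matrix(unlist(blocks), ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("size", "source_gap", "target_gap")))
  list(score = score, source_chrom = s_chrom, source_size = s_size,
       source_strand = "+", source_start = s_start, source_end = s_end,
       target_chrom = t_chrom, target_size = t_size,
       target_strand = t_strand, target_start = t_start,
       target_end = t_end, id = "t", blocks = b)
}

identity_chain <- function(chrom = "chr1", size = 1000, score = 1000) {
  make_chain(score, chrom, size, 0, size, chrom, size, 0, size,
             list(c(size, 0, 0)))
}

# naive per-base projection: walk the block list accumulating coordinates
oracle_project <- function(pos, chain) {
  s <- chain$source_start
  t <- chain$target_start
  for (k in seq_len(nrow(chain$blocks))) {
    sz <- chain$blocks[k, "size"]
    if (pos >= s && pos < s + sz) {
      q <- t + (pos - s)
      if (chain$target_strand == "-") q <- chain$target_size - 1 - q
      return(q)
    }
    s <- s + sz + chain$blocks[k, "source_gap"]
    t <- t + sz + chain$blocks[k, "target_gap"]
  }
  NA_real_
}

# naive interval mapping on the best-scoring overlapping chain
oracle_map <- function(interval, chains, min_match = 0.95) {
  ov <- vapply(chains, function(ch)
    ch$source_chrom == interval$chrom &&
      ch$source_start < interval$end && ch$source_end > interval$start,
    logical(1))
  if (!any(ov)) return(list(status = "unmapped", fraction = 0))
  cand <- chains[ov]
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "score"))]]
  proj <- vapply(interval$start:(interval$end - 1), oracle_project,
                 numeric(1), chain = best)
  frac <- mean(!is.na(proj))
  if (frac == 0 || frac < min_match)
    return(list(status = "unmapped", fraction = frac))
  list(status = "mapped", fraction = frac,
       chrom = best$target_chrom,
       start = min(proj, na.rm = TRUE), end = max(proj, na.rm = TRUE) + 1)
}

# exhaustive hypergeometric enumeration via choose()
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- choose(m, x) * choose(n, k - x)
  probs <- probs / sum(probs)
  pobs <- probs[a - lo + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

simple_genes <- function(starts, ends, chrom = "chr1", strand = NULL) {
  n <- length(starts)
  if (is.null(strand)) strand <- rep("+", n)
  data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
             gene_id = sprintf("g%03d", seq_len(n)),
             tss = ifelse(strand == "+", starts, ends - 1),
             stringsAsFactors = FALSE)
}

simple_enh <- function(starts, ends, chrom = "chr1", id = NULL) {
  n <- length(starts)
  data.frame(chrom = chrom, start = starts, end = ends,
             id = if (is.null(id)) sprintf("e%03d", seq_len(n)) else id,
             stringsAsFactors = FALSE)
}
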