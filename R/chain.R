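# UCSC chain files and liftOver-style interval mapping.
#
# A chain maps a "source" genome (the t-side of the header) onto a "target"
# genome (the q-side) through an ordered list of aligned blocks
# (size, source_gap, target_gap). All parsing and mapping is done in 0-based
# half-open coordinates, matching the format itself.

.chain_block_coords <- function(chain) {
  b <- chain$blocks
  n <- nrow(b)
  src0 <- chain$source_start + c(0, cumsum(b[, "size"] + b[, "source_gap"]))[seq_len(n)]
  tgt0 <- chain$target_start + c(0, cumsum(b[, "size"] + b[, "target_gap"]))[seq_len(n)]
  list(src0 = src0, tgt0 = tgt0, size = b[, "size"])
}

#' Parse a UCSC chain file
#'
#' Header fields: `chain score tName tSize tStrand tStart tEnd qName qSize
#' qStrand qStart qEnd id`, followed by `size dt dq` block lines and a final
#' bare `size`. Block arithmetic is validated against the header spans; a
#' mismatch is a parse error naming the offending line.
#'
#' @param path Path to a chain file.
#' @return List of chain objects: `score`, `source_chrom/size/strand/start/end`
#'   (t-side), `target_chrom/size/strand/start/end` (q-side), `id`, and a
#'   `blocks` matrix with columns `size`, `source_gap`, `target_gap`.
#' @export
parse_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12)
      stop("malformed chain header at line ", i)
    ch <- list(
      score = as.numeric(f[2]),
      source_chrom = f[3], source_size = as.numeric(f[4]),
      source_strand = f[5], source_start = as.numeric(f[6]),
      source_end = as.numeric(f[7]),
      target_chrom = f[8], target_size = as.numeric(f[9]),
      target_strand = f[10], target_start = as.numeric(f[11]),
      target_end = as.numeric(f[12]),
      id = if (length(f) >= 13) f[13] else NA_character_
    )
    hdr_line <- i
    i <- i + 1L
    blocks <- list()
    repeat {
      if (i > length(lines)) stop("unterminated chain starting at line ", hdr_line)
      bl <- trimws(lines[i])
      if (bl == "") stop("empty line inside chain block list at line ", i)
      v <- suppressWarnings(as.numeric(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(v)) stop("malformed block line at line ", i)
      if (length(v) == 1) {
        blocks[[length(blocks) + 1L]] <- c(v, 0, 0)
        i <- i + 1L
        break
      } else if (length(v) == 3) {
        blocks[[length(blocks) + 1L]] <- v
        i <- i + 1L
      } else stop("malformed block line at line ", i)
    }
    b <- do.call(rbind, blocks)
    colnames(b) <- c("size", "source_gap", "target_gap")
    if (any(b[, "size"] < 1)) stop("block size < 1 in chain at line ", hdr_line)
    if (sum(b[, "size"] + b[, "source_gap"]) != ch$source_end - ch$source_start)
      stop("source span mismatch in chain at line ", hdr_line)
    if (sum(b[, "size"] + b[, "target_gap"]) != ch$target_end - ch$target_start)
      stop("target span mismatch in chain at line ", hdr_line)
    ch$blocks <- b
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Write chains in UCSC chain format
#'
#' @param chains List of chain objects (see [parse_chain()]).
#' @param path Output path.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    id <- if (is.null(ch$id) || is.na(ch$id)) k else ch$id
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$source_chrom, format(ch$source_size, scientific = FALSE),
                     ch$source_strand,
                     format(ch$source_start, scientific = FALSE),
                     format(ch$source_end, scientific = FALSE),
                     ch$target_chrom, format(ch$target_size, scientific = FALSE),
                     ch$target_strand,
                     format(ch$target_start, scientific = FALSE),
                     format(ch$target_end, scientific = FALSE), id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1)
      writeLines(paste(b[-n, "size"], b[-n, "source_gap"], b[-n, "target_gap"]),
                 con)
    writeLines(format(b[n, "size"], scientific = FALSE), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Project single source positions through one chain
#'
#' @param pos 0-based source positions.
#' @param chain A chain object.
#' @return Numeric vector of 0-based plus-strand target positions, `NA`
#'   where the position is unaligned.
#' @export
project_positions <- function(pos, chain) {
  bc <- .chain_block_coords(chain)
  k <- findInterval(pos, bc$src0)
  ok <- k >= 1 & pos < bc$src0[pmax(k, 1L)] + bc$size[pmax(k, 1L)]
  q <- rep(NA_real_, length(pos))
  kk <- pmax(k, 1L)
  q[ok] <- bc$tgt0[kk[ok]] + (pos[ok] - bc$src0[kk[ok]])
  if (chain$target_strand == "-") q[ok] <- chain$target_size - 1 - q[ok]
  q
}

#' Map one interval between genomes through a chain set
#'
#' Mirrors liftOver semantics: the highest-scoring chain overlapping the
#' interval is chosen; source bases falling in aligned blocks are counted;
#' if the aligned fraction reaches `min_match` the target is the span from
#' the first to the last mapped base (normalized to plus strand), otherwise
#' the interval is unmapped. Bases in source gaps never map.
#'
#' @param interval One-row data.frame (`chrom`, `start`, `end`).
#' @param chains List of chains (see [parse_chain()]).
#' @param min_match Minimum aligned fraction, in (0, 1] (default 0.95).
#' @return List: `source`, `status` (`mapped`/`unmapped`), `reason`
#'   (`no_chain`, `gap`, `split` or `""`), `target` (or NULL),
#'   `mapped_fraction`.
#' @export
map_interval <- function(interval, chains, min_match = 0.95) {
  stopifnot(min_match > 0, min_match <= 1)
  s <- interval$start[1]; e <- interval$end[1]; chr <- interval$chrom[1]
  len <- e - s
  cand <- Filter(function(ch) ch$source_chrom == chr &&
                   ch$source_start < e && ch$source_end > s, chains)
  unmapped <- function(reason, frac = 0)
    list(source = interval, status = "unmapped", reason = reason,
         target = NULL, mapped_fraction = frac)
  if (length(cand) == 0) return(unmapped("no_chain"))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "score"))]]
  bc <- .chain_block_coords(best)
  ov_s <- pmax(s, bc$src0)
  ov_e <- pmin(e, bc$src0 + bc$size)
  ov <- pmax(0, ov_e - ov_s)
  aligned <- sum(ov)
  frac <- aligned / len
  if (aligned == 0 || frac < min_match) {
    reason <- if (frac >= min_match) "gap"
      else if (length(cand) >= 2) "split" else "gap"
    return(unmapped(reason, frac))
  }
  hit <- which(ov > 0)
  first <- hit[1]; last <- hit[length(hit)]
  q1 <- bc$tgt0[first] + (ov_s[first] - bc$src0[first])
  qL <- bc$tgt0[last] + (ov_e[last] - 1 - bc$src0[last])
  if (best$target_strand == "-") {
    t_start <- best$target_size - (qL + 1)
    t_end <- best$target_size - q1
  } else {
    t_start <- q1
    t_end <- qL + 1
  }
  list(
    source = interval, status = "mapped", reason = "",
    target = data.frame(chrom = best$target_chrom, start = t_start,
                        end = t_end, stringsAsFactors = FALSE),
    mapped_fraction = frac
  )
}

#' Map many intervals through a chain set
#'
#' @param intervals Interval data.frame with an `id` column.
#' @param chains List of chains.
#' @param min_match Minimum aligned fraction (default 0.95).
#' @return data.frame: `id`, `status`, `reason`, `target_chrom`,
#'   `target_start`, `target_end`, `mapped_fraction`.
#' @export
map_intervals <- function(intervals, chains, min_match = 0.95) {
  # pre-index by source chromosome to avoid a full scan per interval
  by_chrom <- split(chains,
                    vapply(chains, `[[`, character(1), "source_chrom"))
  n <- nrow(intervals)
  status <- character(n); reason <- character(n)
  tchrom <- rep(NA_character_, n)
  tstart <- rep(NA_real_, n); tend <- rep(NA_real_, n)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    cc <- by_chrom[[intervals$chrom[i]]]
    if (is.null(cc)) cc <- list()
    m <- map_interval(intervals[i, , drop = FALSE], cc, min_match)
    status[i] <- m$status; reason[i] <- m$reason
    frac[i] <- m$mapped_fraction
    if (m$status == "mapped") {
      tchrom[i] <- m$target$chrom
      tstart[i] <- m$target$start
      tend[i] <- m$target$end
    }
  }
  data.frame(id = if (!is.null(intervals$id)) intervals$id else seq_len(n),
             status = status, reason = reason, target_chrom = tchrom,
             target_start = tstart, target_end = tend,
             mapped_fraction = frac, stringsAsFactors = FALSE)
}
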