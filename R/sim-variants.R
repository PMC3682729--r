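# Variant simulation: polarized SNPs with a Beta-distributed derived
# allele frequency (heavy low-frequency mass; constrained regions shifted
# further toward 0), a stated fraction of unusable ancestral alleles, and
# a per-region divergence/heterozygosity table for the MK test.

.BASES <- c("A", "C", "G", "T")

#' Generate variants and a divergence table for labeled regions
#'
#' Each region carries a selection `regime` (`neutral` or `constrained`).
#' Polymorphic sites are placed at `snp_rate` per base; DAF is drawn from
#' the regime's Beta distribution; the ancestral allele is the reference
#' or the alternate allele with equal probability (so `AF` alone carries
#' no regime signal), and `frac_aa_missing` of records get AA "." to
#' exercise the polarization-skip rule. Divergence `d` is binomial at
#' `divergence_rate` (times `constrained_divergence_factor` in constrained
#' regions) and heterozygous-site counts `pi` binomial at `het_rate`.
#'
#' @param config A [sim_config()].
#' @param regions Interval data.frame with `id` and `regime` columns.
#' @param chrom_sizes Named chromosome lengths (regions are bounds-checked
#'   against them).
#' @return List: `variants` (chrom, pos, ref, alt, af, aa, region_id),
#'   `divergence` (region_id, regime, length, d, pi).
#' @export
generate_variants <- function(config, regions, chrom_sizes) {
  validate_sim_config(config)
  stopifnot(all(c("id", "regime") %in% names(regions)))
  if (!all(regions$chrom %in% names(chrom_sizes)))
    stop("region on unknown chromosome")
  if (any(regions$start < 0 | regions$end > chrom_sizes[regions$chrom]))
    stop("region outside chromosome bounds")
  withr::with_seed(.sim_seed(config, "variants"), {
    len <- regions$end - regions$start
    n_snp <- stats::rbinom(nrow(regions), len, config$snp_rate)
    idx <- rep(seq_len(nrow(regions)), n_snp)
    total <- sum(n_snp)
    pos0 <- regions$start[idx] +
      floor(stats::runif(total) * len[idx])              # 0-based
    constrained <- regions$regime[idx] == "constrained"
    daf <- numeric(total)
    daf[!constrained] <- stats::rbeta(sum(!constrained),
                                      config$daf_neutral_params[1],
                                      config$daf_neutral_params[2])
    daf[constrained] <- stats::rbeta(sum(constrained),
                                     config$daf_selected_params[1],
                                     config$daf_selected_params[2])
    ref <- sample(.BASES, total, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1), "",
                  USE.NAMES = FALSE)
    anc_is_ref <- stats::runif(total) < 0.5
    af <- ifelse(anc_is_ref, daf, 1 - daf)
    aa <- ifelse(anc_is_ref, ref, alt)
    aa[stats::runif(total) < config$frac_aa_missing] <- "."
    v <- data.frame(chrom = regions$chrom[idx], pos = pos0 + 1L,
                    ref = ref, alt = alt, af = round(af, 6), aa = aa,
                    region_id = regions$id[idx], stringsAsFactors = FALSE)
    v <- v[!duplicated(v[, c("chrom", "pos")]), , drop = FALSE]
    v <- v[order(match(v$chrom, names(chrom_sizes)), v$pos), , drop = FALSE]
    rownames(v) <- NULL
    rate_d <- config$divergence_rate *
      ifelse(regions$regime == "constrained",
             config$constrained_divergence_factor, 1)
    divergence <- data.frame(
      region_id = regions$id, regime = regions$regime, length = len,
      d = stats::rbinom(nrow(regions), len, rate_d),
      pi = stats::rbinom(nrow(regions), len, config$het_rate),
      stringsAsFactors = FALSE)
  })
  list(variants = v, divergence = divergence)
}

#' Write a variant table as VCF 4.2
#'
#' INFO carries `AF` (alternate allele frequency) and `AA` (ancestral
#' allele, "." when unknown).
#'
#' @param variants Variant data.frame (see [generate_variants()]).
#' @param path Output path.
#' @param chrom_sizes Named chromosome lengths for contig headers.
#' @export
write_vcf <- function(variants, path, chrom_sizes) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(chrom_sizes), ",length=",
                  format(unname(chrom_sizes), scientific = FALSE), ">"),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- withr::with_options(list(scipen = 999),
    paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS",
                paste0("AF=", variants$af, ";AA=", variants$aa),
                sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate pseudogene, ECR, CpG-island region sets and the density table
#'
#' Pseudogenes are neutral reference regions placed away from enhancers.
#' ECRs (evolutionarily conserved regions) carry the background ChIP read
#' density; orthologues of class I enhancers are written with density above
#' that background, class II orthologues at or below it. CpG islands
#' preferentially overlap shared enhancers.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @param enhancer_sets Output of [generate_enhancer_sets()].
#' @return List: `pseudogenes` (BED-style df), `cpg_islands`,
#'   `ref_density` (chrom, start, end, density in reference coordinates),
#'   `ecr_ref` (the ECR rows alone).
#' @export
generate_region_sets <- function(config, annotation, enhancer_sets) {
  sizes <- annotation$chrom_sizes
  chroms <- names(sizes)
  q <- enhancer_sets$query
  al <- enhancer_sets$alignment
  withr::with_seed(.sim_seed(config, "regions"), {
    occ <- lapply(chroms, function(ch) {
      e <- q[q$chrom == ch, ]
      list(s = e$start, e = e$end)
    })
    names(occ) <- chroms
    place_away <- function(n, w) {
      ch <- character(n); s <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          cc <- sample(chroms, 1)
          p <- floor(stats::runif(1, 2000, sizes[[cc]] - w - 2000))
          if (!.overlaps_any(p, p + w, occ[[cc]]$s, occ[[cc]]$e, 500)) break
        }
        ch[i] <- cc; s[i] <- p
        occ[[cc]]$s <- c(occ[[cc]]$s, p); occ[[cc]]$e <- c(occ[[cc]]$e, p + w)
      }
      data.frame(chrom = ch, start = s, end = s + w, stringsAsFactors = FALSE)
    }
    pseudo <- place_away(config$n_pseudogenes, config$pseudogene_length)
    pseudo$id <- sprintf("pg%05d", seq_len(nrow(pseudo)))
    # CpG islands: over 60% of shared, 15% of lineage-specific midpoints
    sh <- q[q$true_label == "shared", ]
    ls <- q[q$true_label != "shared", ]
    n_sh <- min(round(0.6 * nrow(sh)), config$n_cpg_islands)
    n_ls <- min(round(0.15 * nrow(ls)),
                max(config$n_cpg_islands - n_sh, 0))
    pick <- function(df, n) df[sample.int(nrow(df), n), , drop = FALSE]
    cg1 <- pick(sh, n_sh); cg2 <- pick(ls, n_ls)
    cpg <- data.frame(
      chrom = c(cg1$chrom, cg2$chrom),
      start = pmax(interval_midpoint(rbind(cg1, cg2)[, c("start", "end")]) - 250, 0),
      stringsAsFactors = FALSE)
    cpg$end <- cpg$start + 500
    cpg$id <- sprintf("cpg%05d", seq_len(nrow(cpg)))
    # ECRs in query space, projected to reference coordinates
    ecr_q <- place_away(config$n_ecr, 500)
    ecr_r_start <- mapply(function(ch, p) .project_q2r(p, al$blocks[[ch]]),
                          ecr_q$chrom, ecr_q$start)
    ok <- !is.na(ecr_r_start)
    ecr_ref <- data.frame(chrom = ecr_q$chrom[ok],
                          start = ecr_r_start[ok],
                          end = ecr_r_start[ok] + 500,
                          density = pmax(stats::rnorm(sum(ok), 1, 0.15), 0.05),
                          stringsAsFactors = FALSE)
    background <- mean(ecr_ref$density)
    # orthologue densities for class I (above background) and II (below)
    ortho_density <- function(sub, lo, hi) {
      if (nrow(sub) == 0) return(NULL)
      r0 <- mapply(function(ch, p) .project_q2r(p, al$blocks[[ch]]),
                   sub$chrom, sub$start)
      r1 <- mapply(function(ch, p) .project_q2r(p, al$blocks[[ch]]),
                   sub$chrom, sub$end - 1)
      keep <- !is.na(r0) & !is.na(r1)
      data.frame(chrom = sub$chrom[keep], start = r0[keep],
                 end = r1[keep] + 1,
                 density = background * stats::runif(sum(keep), lo, hi),
                 stringsAsFactors = FALSE)
    }
    d1 <- ortho_density(q[q$true_label == "class1", ], 1.5, 4)
    d2 <- ortho_density(q[q$true_label == "class2", ], 0.05, 0.8)
  })
  ecr_ref$is_ecr <- TRUE
  dens <- rbind(ecr_ref,
                if (!is.null(d1)) cbind(d1, is_ecr = FALSE),
                if (!is.null(d2)) cbind(d2, is_ecr = FALSE))
  list(pseudogenes = pseudo, cpg_islands = cpg,
       ref_density = dens, ecr_ref = ecr_ref)
}
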