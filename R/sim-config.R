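# Simulation configuration for the synthetic fixture bundles. Defaults
# emulate the study conditions of the real two-species heart-enhancer
# comparison: 5042 query / 6564 reference enhancers, 1066 shared
# (frac_shared ~ 0.211), lineage-specific split 3114/417/445 into classes
# I/II/III, 500/1000 clustering simulation, DAF low-frequency cutoff 5%,
# heart-specificity offset 16, top-1000 gene ranking.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generators. All
#' randomness downstream derives from `seed` alone: the same configuration
#' always yields a byte-identical fixture bundle.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes,chrom_length Genome shape (every chromosome has the
#'   same length, in bases).
#' @param n_genes Number of non-overlapping genes to place.
#' @param n_enhancers_query,n_enhancers_reference Enhancer counts per
#'   species.
#' @param frac_shared Fraction of query enhancers with a functional
#'   reference counterpart.
#' @param frac_class1,frac_class2,frac_class3 Split of lineage-specific
#'   query enhancers (must sum to 1).
#' @param clustering_bias Probability that an enhancer is placed into a
#'   locus already occupied by an enhancer of its own group (shared vs
#'   lineage-specific).
#' @param enhancer_length_range Enhancer lengths are drawn uniformly from
#'   this range (bases).
#' @param gene_length_range Gene lengths drawn uniformly from this range.
#' @param daf_neutral_params,daf_selected_params `c(shape1, shape2)` of the
#'   Beta distribution the derived allele frequency is drawn from in
#'   neutral vs constrained regions; the constrained shape puts extra mass
#'   at low frequencies.
#' @param snp_rate Polymorphic sites per base.
#' @param het_rate Heterozygous sites per base (the pi of the MK test).
#' @param divergence_rate Substitutions per base vs the sister species.
#' @param constrained_divergence_factor Multiplier on `divergence_rate` in
#'   constrained regions (< 1: divergence is suppressed by selection).
#' @param frac_aa_missing Fraction of variant records emitted with an
#'   unusable ancestral allele (AA ".").
#' @param n_heart_samples,n_nonheart_samples Expression sample counts.
#' @param heart_effect Multiplicative heart-expression boost for planted
#'   heart genes.
#' @param n_planted_heart_genes Number of genes (drawn from shared-enhancer
#'   loci where possible) planted as heart-high.
#' @param n_go_terms,frac_cardiac_terms GO term counts and the fraction
#'   whose names carry a cardiac substring.
#' @param n_pseudogenes,pseudogene_length Neutral reference region set.
#' @param n_ecr ECR count for the read-density background.
#' @param n_cpg_islands CpG island count.
#' @param frac_class3_outgroup Fraction of class III regions present in the
#'   synthetic out-group genome.
#' @param signal_background,signal_bump_height,signal_bump_sigma bedGraph
#'   track parameters (uniform background; Gaussian bumps).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chrom_length = 25e6,
                       n_genes = 2000L,
                       n_enhancers_query = 5042L,
                       n_enhancers_reference = 6564L,
                       frac_shared = 1066 / 5042,
                       frac_class1 = 3114 / 3976,
                       frac_class2 = 417 / 3976,
                       frac_class3 = 445 / 3976,
                       clustering_bias = 0.3,
                       enhancer_length_range = c(600L, 1400L),
                       gene_length_range = c(5000L, 30000L),
                       daf_neutral_params = c(0.3, 1.2),
                       daf_selected_params = c(0.2, 1.8),
                       snp_rate = 0.008,
                       het_rate = 0.005,
                       divergence_rate = 0.012,
                       constrained_divergence_factor = 0.6,
                       frac_aa_missing = 0.05,
                       n_heart_samples = 5L,
                       n_nonheart_samples = 10L,
                       heart_effect = 8,
                       n_planted_heart_genes = 300L,
                       n_go_terms = 400L,
                       frac_cardiac_terms = 0.25,
                       n_pseudogenes = 800L,
                       pseudogene_length = 1500L,
                       n_ecr = 500L,
                       n_cpg_islands = 300L,
                       frac_class3_outgroup = 0.98,
                       signal_background = 1,
                       signal_bump_height = 10,
                       signal_bump_sigma = 500) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config`.
#' @return The config, invisibly; errors on violation.
#' @export
validate_sim_config <- function(cfg) {
  props <- c("frac_shared", "clustering_bias", "frac_aa_missing",
             "frac_cardiac_terms", "frac_class3_outgroup")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  fsum <- cfg$frac_class1 + cfg$frac_class2 + cfg$frac_class3
  if (any(c(cfg$frac_class1, cfg$frac_class2, cfg$frac_class3) < 0) ||
      abs(fsum - 1) > 1e-9)
    stop("frac_class1 + frac_class2 + frac_class3 must equal 1")
  counts <- c("n_chromosomes", "chrom_length", "n_enhancers_query",
              "n_enhancers_reference", "n_heart_samples",
              "n_nonheart_samples", "n_go_terms")
  for (p in counts) if (cfg[[p]] <= 0) stop(p, " must be > 0")
  if (cfg$n_genes < 0) stop("n_genes must be >= 0")
  if (cfg$seed != round(cfg$seed)) stop("seed must be an integer")
  invisible(cfg)
}

# fixed per-operation seed offsets so each generator is independently
# deterministic under the master seed
.sim_seed <- function(cfg, op) {
  off <- c(annotation = 1L, enhancers = 2L, alignment = 3L, variants = 4L,
           expression = 5L, go = 6L, signal = 7L, regions = 8L,
           outgroup = 9L)
  as.integer((cfg$seed + off[[op]]) %% .Machine$integer.max)
}
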