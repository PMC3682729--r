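#' Stochastic clustering simulation between enhancer classes
#'
#' Per replicate, `draws_per_class` enhancers are sampled without
#' replacement from each class. A focal enhancer is "clustered with class X"
#' iff at least one sampled enhancer of class X other than itself shares its
#' locus. Reported per focal class: the mean percentage over replicates and
#' its standard deviation.
#'
#' @param assignment Output of [assign_enhancers_to_loci()].
#' @param shared_ids,lineage_ids Enhancer ids of the two classes.
#' @param draws_per_class Sample size per class per replicate (default 500).
#' @param replicates Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param min_others Minimum number of sampled co-locus enhancers of the
#'   partner class (besides the focal enhancer) required to call the focal
#'   enhancer clustered (default 1; raise to demand larger clusters).
#' @return data.frame with rows `focal_class` in (shared, lineage) and
#'   columns `pct_clustered_with_shared`, `pct_clustered_with_lineage`,
#'   `sd_with_shared`, `sd_with_lineage`, `replicates`, `draws_per_class`.
#' @export
clustering_simulation <- function(assignment, shared_ids, lineage_ids,
                                  draws_per_class = 500, replicates = 1000,
                                  seed = 1L, min_others = 1L) {
  stopifnot(min_others >= 1)
  if (length(shared_ids) == 0 || length(lineage_ids) == 0)
    stop("both classes must be non-empty")
  locus <- factor(assignment$locus_id)
  loc_of <- stats::setNames(as.integer(locus), assignment$id)
  if (!all(c(shared_ids, lineage_ids) %in% assignment$id))
    stop("all class members must appear in the locus assignment")
  nloc <- nlevels(locus)
  ds <- min(draws_per_class, length(shared_ids))
  dl <- min(draws_per_class, length(lineage_ids))
  if (ds < draws_per_class || dl < draws_per_class)
    warning("draws_per_class reduced to class size (", ds, "/", dl, ")")
  ls_all <- loc_of[shared_ids]
  ll_all <- loc_of[lineage_ids]
  acc <- matrix(NA_real_, nrow = replicates, ncol = 4)
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      ls <- ls_all[sample.int(length(ls_all), ds)]
      ll <- ll_all[sample.int(length(ll_all), dl)]
      cs <- tabulate(ls, nbins = nloc)
      cl <- tabulate(ll, nbins = nloc)
      acc[r, 1] <- 100 * mean(cs[ls] >= min_others + 1L)  # shared w/ shared
      acc[r, 2] <- 100 * mean(cl[ls] >= min_others)       # shared w/ lineage
      acc[r, 3] <- 100 * mean(cs[ll] >= min_others)       # lineage w/ shared
      acc[r, 4] <- 100 * mean(cl[ll] >= min_others + 1L)  # lineage w/ lineage
    }
  })
  data.frame(
    focal_class = c("shared", "lineage"),
    pct_clustered_with_shared = c(mean(acc[, 1]), mean(acc[, 3])),
    pct_clustered_with_lineage = c(mean(acc[, 2]), mean(acc[, 4])),
    sd_with_shared = c(stats::sd(acc[, 1]), stats::sd(acc[, 3])),
    sd_with_lineage = c(stats::sd(acc[, 2]), stats::sd(acc[, 4])),
    replicates = replicates,
    draws_per_class = c(ds, dl),
    stringsAsFactors = FALSE
  )
}
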