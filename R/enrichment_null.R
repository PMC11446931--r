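#' Define the SNP sampling pool for the enrichment null
#'
#' The pool is the set of SNPs from which random sets are drawn to build the
#' null distribution of significant-association counts. In `all_snps` mode
#' the pool is every SNP present in the summary statistics minus the
#' exclusions (always including the target SNPs and their proxies); in
#' `cross_disorder` mode it is additionally restricted to SNPs whose
#' cross-disorder association p-value is at or below `cross_disorder_max_p`.
#'
#' @param sumstats_ids Character vector of rsIDs present in the
#'   summary-statistics source.
#' @param mode `"all_snps"` or `"cross_disorder"`.
#' @param cross_disorder_p Named numeric vector of per-SNP cross-disorder
#'   p-values (required in `cross_disorder` mode).
#' @param exclusions rsIDs never sampled (target SNPs and their proxies).
#' @param cross_disorder_max_p Threshold for `cross_disorder` mode
#'   (default 1e-6).
#' @return Character vector of pool rsIDs (with attribute `pool_id`).
#' @export
define_pool <- function(sumstats_ids, mode = c("all_snps", "cross_disorder"),
                        cross_disorder_p = NULL, exclusions = character(),
                        cross_disorder_max_p = 1e-6) {
  mode <- match.arg(mode)
  pool <- setdiff(unique(sumstats_ids), exclusions)
  if (mode == "cross_disorder") {
    if (is.null(cross_disorder_p)) {
      stop("cross_disorder mode requires per-SNP cross-disorder p-values",
           call. = FALSE)
    }
    keep <- names(cross_disorder_p)[cross_disorder_p <= cross_disorder_max_p]
    pool <- intersect(pool, keep)
  }
  if (length(pool) == 0L) stop("sampling pool is empty", call. = FALSE)
  attr(pool, "pool_id") <- mode
  pool
}

#' Sample the null distribution of significant-association counts
#'
#' Each replicate draws `set_size` SNPs from the pool without replacement,
#' rebuilds the association grid for the drawn set via `grid_builder`, and
#' records the number of cells significant after the identical BH procedure
#' (same m convention as the observed analysis). Replicate r uses a
#' deterministic seed derived from `(seed, r)` so results do not depend on
#' evaluation order.
#'
#' @param pool Character vector of candidate rsIDs (see [define_pool()]).
#' @param set_size Number of SNPs per drawn set (the size of the observed
#'   antagonistic set, 11).
#' @param B Number of replicates.
#' @param grid_builder Function taking a character vector of SNP ids and
#'   returning the vector of grid p-values for that set (one value per
#'   attempted, resolved cell).
#' @param seed Integer RNG seed.
#' @param alpha FDR level applied within each replicate's grid.
#' @param m_extra Number of additional tests beyond the returned p-values to
#'   include in each replicate's m (use to mirror a count-missing-as-tests
#'   convention); default 0.
#' @return Integer vector of per-replicate significant counts, with
#'   attributes `B`, `seed`, `pool_id`.
#' @export
sample_null_counts <- function(pool, set_size = 11, B, grid_builder, seed,
                               alpha = 0.05, m_extra = 0L) {
  if (length(pool) < set_size) {
    stop("pool smaller than set_size", call. = FALSE)
  }
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  counts <- integer(B)
  for (r in seq_len(B)) {
    set.seed(replicate_seed(seed, r))
    ids <- sample(pool, set_size, replace = FALSE)
    p <- grid_builder(ids)
    counts[r] <- if (length(p)) {
      sum(bh_adjust(p, m = length(p) + m_extra) < alpha)
    } else 0L
  }
  attr(counts, "B") <- B
  attr(counts, "seed") <- seed
  attr(counts, "pool_id") <- attr(pool, "pool_id")
  counts
}

# Deterministic per-replicate seed substream; kept below 2^31 - 1.
replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + as.double(r) * 16807) %% 2147483647)
}

#' Upper-tail empirical p-value with add-one correction
#'
#' `(1 + #\{count_i >= observed\}) / (1 + B)`: the permutation-style
#' estimator that never returns zero, so the smallest attainable p at
#' B replicates is `1/(B + 1)` (e.g. 1e-4 at B = 9,999).
#'
#' @param counts Integer vector of null counts.
#' @param observed Observed count for the target set.
#' @return The one-sided empirical p-value.
#' @examples
#' empirical_pvalue(c(0, 1, 2), observed = 5)  # 1/4
#' @export
empirical_pvalue <- function(counts, observed) {
  if (length(counts) == 0L) stop("counts must be non-empty", call. = FALSE)
  (1 + sum(counts >= observed)) / (1 + length(counts))
}

#' Bootstrap enrichment test for the antagonistic SNP set
#'
#' Convenience wrapper: computes the observed significant-association count
#' for the target ids, samples the null with [sample_null_counts()], and
#' returns the null distribution together with the add-one empirical
#' p-value.
#'
#' @param target_ids rsIDs of the observed (antagonistic) set.
#' @param pool Sampling pool (must not contain the targets).
#' @param grid_builder As in [sample_null_counts()].
#' @param B Replicates (default 10000).
#' @param seed RNG seed.
#' @param alpha FDR level.
#' @param m_extra See [sample_null_counts()].
#' @return A list of class `enrichment_null`: `observed`, `counts`, `B`,
#'   `empirical_p`, `seed`, `pool_id`.
#' @export
enrichment_test <- function(target_ids, pool, grid_builder, B = 10000,
                            seed = 1L, alpha = 0.05, m_extra = 0L) {
  p_obs <- grid_builder(target_ids)
  observed <- if (length(p_obs)) {
    sum(bh_adjust(p_obs, m = length(p_obs) + m_extra) < alpha)
  } else 0L
  counts <- sample_null_counts(pool, set_size = length(target_ids), B = B,
                               grid_builder = grid_builder, seed = seed,
                               alpha = alpha, m_extra = m_extra)
  structure(list(observed = observed,
                 counts = as.integer(counts),
                 B = B,
                 empirical_p = empirical_pvalue(counts, observed),
                 seed = seed,
                 pool_id = attr(counts, "pool_id")),
            class = "enrichment_null")
}

#' @export
print.enrichment_null <- function(x, ...) {
  cat("Enrichment null: observed =", x$observed,
      "significant associations; B =", x$B, "\n")
  cat("empirical p =", format(x$empirical_p, digits = 3),
      "(add-one, upper tail)\n")
  invisible(x)
}

#' Write an enrichment-test report as JSON
#'
#' @param x An `enrichment_null` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_report <- function(x, path) {
  stopifnot(inherits(x, "enrichment_null"))
  h <- table(x$counts)
  jsonlite::write_json(
    list(observed = x$observed, B = x$B, seed = x$seed,
         pool_id = x$pool_id, empirical_p = x$empirical_p,
         counts_histogram = list(count = as.integer(names(h)),
                                 replicates = as.integer(h))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
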