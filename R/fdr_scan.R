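#' Benjamini-Hochberg step-up adjusted p-values over a grid of m tests
#'
#' Classical step-up FDR adjustment,
#' `adj_(i) = min_{j >= i} min(1, m * p_(j) / j)` on the sorted p-values,
#' returned in the input order. `m` may exceed the number of supplied
#' p-values: the remaining cells of the grid are treated as p = 1, which
#' inflates the numerator for the supplied values without otherwise entering
#' the minimum (m * 1 / j >= 1 for all padded ranks). Ties share one
#' adjusted value.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Total number of tests used for adjustment; must be at least
#'   `length(p)` (default).
#' @return Adjusted p-values in the order of `p`.
#'
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.04), m = 3)
#' bh_adjust(0.04, m = 1)   # 0.04: identity at m = 1
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must be finite and in (0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("m must be at least the number of supplied p-values", call. = FALSE)
  }
  o <- order(p)
  sp <- p[o]
  k <- length(sp)
  adj_sorted <- pmin(1, rev(cummin(rev(m * sp / seq_len(k)))))
  adj <- numeric(k)
  adj[o] <- adj_sorted
  adj
}

#' Build the target-SNP by IDP association grid
#'
#' For every (target SNP, IDP) pair, looks the SNP up in the IDP's
#' summary-statistics table (falling back to the target's LD proxy where the
#' target id is absent and the proxy meets the r-squared threshold),
#' harmonizes the record to the target's risk allele, and collects effect
#' and p-value. Pairs with no usable lookup are recorded as missing cells.
#'
#' @param targets Target-SNP table (see [read_target_snps()]).
#' @param sumstats_by_idp Named list mapping `idp_id` to a canonical
#'   summary-statistics `data.frame` (see [read_sumstats()]).
#' @param idp_catalog Optional IDP catalog; when supplied, the grid entries
#'   carry the IDP's `region` and `measure`.
#' @param min_proxy_r2 Minimum LD r-squared for proxy substitution.
#' @param ambiguous Strand-ambiguity policy passed to
#'   [harmonize_to_target()].
#'
#' @return An object of class `association_grid`: a list with `entries`
#'   (data.frame: `snp_id`, `used_id`, `idp_id`, `region`, `measure`,
#'   `effect`, `p`), `missing` (data.frame of unresolved `snp_id`,
#'   `idp_id`), `targets`, and `m` (unset until [fdr_grid()]).
#' @export
build_grid <- function(targets, sumstats_by_idp, idp_catalog = NULL,
                       min_proxy_r2 = 0.8, ambiguous = "warn") {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1L,
            is.list(sumstats_by_idp), length(sumstats_by_idp) >= 1L)
  idp_ids <- names(sumstats_by_idp)
  if (is.null(idp_ids) || any(!nzchar(idp_ids))) {
    stop("sumstats_by_idp must be a named list keyed by idp_id", call. = FALSE)
  }

  region_of <- measure_of <- NULL
  if (!is.null(idp_catalog)) {
    region_of <- stats::setNames(idp_catalog$region, idp_catalog$idp_id)
    measure_of <- stats::setNames(idp_catalog$measure, idp_catalog$idp_id)
  }

  entries <- vector("list", length(idp_ids))
  missing <- list()
  for (k in seq_along(idp_ids)) {
    idp <- idp_ids[k]
    ss <- sumstats_by_idp[[idp]]
    res <- proxy_substitute(targets, ss$snp_id, min_r2 = min_proxy_r2)
    rows <- list()
    for (i in seq_len(nrow(targets))) {
      if (res$status[i] == "unresolvable") {
        missing[[length(missing) + 1L]] <-
          data.frame(snp_id = targets$snp_id[i], idp_id = idp,
                     stringsAsFactors = FALSE)
        next
      }
      rec <- ss[match(res$used_id[i], ss$snp_id), , drop = FALSE]
      rec <- suppressWarnings(
        harmonize_to_target(rec, targets$effect_allele[i], ambiguous = ambiguous))
      if (nrow(rec) == 0L) {  # excluded as strand-ambiguous
        missing[[length(missing) + 1L]] <-
          data.frame(snp_id = targets$snp_id[i], idp_id = idp,
                     stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = targets$snp_id[i],
        used_id = res$used_id[i],
        idp_id = idp,
        region = if (!is.null(region_of)) unname(region_of[idp]) else NA_character_,
        measure = if (!is.null(measure_of)) unname(measure_of[idp]) else NA_character_,
        effect = rec$effect,
        p = rec$pvalue,
        stringsAsFactors = FALSE)
    }
    entries[[k]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  entries <- do.call(rbind, entries[!vapply(entries, is.null, logical(1))])
  missing <- if (length(missing)) do.call(rbind, missing) else
    data.frame(snp_id = character(), idp_id = character(),
               stringsAsFactors = FALSE)
  rownames(entries) <- NULL

  structure(list(entries = entries, missing = missing, targets = targets,
                 m = NA_integer_, alpha = NA_real_),
            class = "association_grid")
}

#' Apply grid-wide FDR adjustment to an association grid
#'
#' Computes BH step-up adjusted p-values across the full grid and flags
#' significant entries. By default the number of tests `m` is the number of
#' non-missing cells actually attempted; missing cells can optionally be
#' counted as tests at p = 1 (`count_missing = TRUE`), and `m` can be pinned
#' explicitly (e.g. to reproduce a published grid size).
#'
#' @param grid An `association_grid` from [build_grid()].
#' @param alpha FDR level (default 0.05).
#' @param m Number of tests; default `nrow(entries)` plus, when
#'   `count_missing`, the number of missing cells.
#' @param count_missing Count missing cells as tests at p = 1.
#' @return The grid with `p_fdr` and `significant` columns added to
#'   `entries`, and `m`, `alpha` set.
#' @export
fdr_grid <- function(grid, alpha = 0.05, m = NULL, count_missing = FALSE) {
  stopifnot(inherits(grid, "association_grid"))
  n <- nrow(grid$entries)
  if (is.null(m)) {
    m <- n + if (count_missing) nrow(grid$missing) else 0L
  }
  grid$entries$p_fdr <- bh_adjust(grid$entries$p, m = m)
  grid$entries$significant <- grid$entries$p_fdr < alpha
  grid$m <- m
  grid$alpha <- alpha
  grid
}

#' Extract the table of significant associations
#'
#' Rows with `p_fdr < alpha`, grouped by SNP (in target order) and sorted by
#' raw p within SNP, mirroring the layout of a published
#' significant-association table. P-values are retained at full precision;
#' presentation rounding is left to the caller.
#'
#' @param grid An `association_grid` with `p_fdr` computed (see
#'   [fdr_grid()]).
#' @param alpha Significance level on the adjusted p-values (defaults to the
#'   level stored in the grid).
#' @return A `data.frame` with columns `snp_id`, `used_id`, plus target
#'   annotation columns present in the grid's target table (`chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `disorder_risk`,
#'   `disorder_protective`), and `idp_id`, `region`, `measure`, `p`,
#'   `p_fdr`, `effect`.
#' @export
significant_table <- function(grid, alpha = NULL) {
  stopifnot(inherits(grid, "association_grid"))
  if (!"p_fdr" %in% names(grid$entries)) {
    stop("grid has no p_fdr column; run fdr_grid() first", call. = FALSE)
  }
  if (is.null(alpha)) alpha <- grid$alpha
  sig <- grid$entries[grid$entries$p_fdr < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    sig$snp_order <- integer(0)
    return(sig[, setdiff(names(sig), "snp_order"), drop = FALSE])
  }
  ann_cols <- intersect(c("chrom", "pos", "effect_allele", "other_allele",
                          "disorder_risk", "disorder_protective"),
                        names(grid$targets))
  ann <- grid$targets[match(sig$snp_id, grid$targets$snp_id), ann_cols,
                      drop = FALSE]
  out <- cbind(sig[, c("snp_id", "used_id")], ann,
               sig[, c("idp_id", "region", "measure", "p", "p_fdr", "effect")])
  snp_order <- match(out$snp_id, grid$targets$snp_id)
  out <- out[order(snp_order, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.association_grid <- function(x, ...) {
  cat("Association grid:", nrow(x$entries), "entries,",
      nrow(x$missing), "missing cells\n")
  if (!is.na(x$m)) {
    nsig <- sum(x$entries$significant)
    cat("FDR: m =", x$m, ", alpha =", x$alpha, ",", nsig, "significant\n")
  }
  invisible(x)
}

#' Write an association grid report
#'
#' Writes the significant-association table as TSV and, optionally, the full
#' grid (including missing cells and the m convention) as JSON.
#'
#' @param grid An `association_grid` with FDR computed.
#' @param tsv_path Output path for the significant-association TSV.
#' @param json_path Optional path for the full-grid JSON.
#' @param digits Significant digits used for p-values in the TSV (default 3,
#'   matching conventional presentation; internal precision is unaffected).
#' @return Invisibly, the significant table.
#' @export
write_grid_report <- function(grid, tsv_path, json_path = NULL, digits = 3) {
  tab <- significant_table(grid)
  out <- tab
  if (nrow(out)) {
    out$p <- signif(out$p, digits)
    out$p_fdr <- signif(out$p_fdr, digits)
  }
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(m = grid$m, alpha = grid$alpha, entries = grid$entries,
           missing = grid$missing),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tab)
}
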