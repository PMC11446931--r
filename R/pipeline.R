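#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file with the same structure)
#' with an `output_dir` and any of the stage sections `scan`, `bootstrap`,
#' `concord`, `annotate`, `vbm`; omitted stages are skipped. Every
#' referenced input path must exist at validation time.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$output_dir)) stop("config needs output_dir", call. = FALSE)
  paths <- c(config$scan$targets, config$scan$sumstats_dir,
             config$concord$case_control, config$annotate$eqtl,
             config$annotate$traits, config$vbm$images,
             config$vbm$covariates, config$vbm$mask)
  for (p in paths) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input path does not exist: ", p, call. = FALSE)
    }
  }
  for (a in c(config$scan$alpha, config$concord$alpha, config$annotate$alpha)) {
    if (!is.null(a) && (a <= 0 || a >= 1)) {
      stop("alpha must lie in (0, 1)", call. = FALSE)
    }
  }
  config
}

# Load the per-IDP sumstats tables referenced by a scan config: a directory
# holding idp_catalog.tsv (with a `file` column) and one table per IDP.
.load_scan_inputs <- function(scan) {
  cat_path <- file.path(scan$sumstats_dir, "idp_catalog.tsv")
  if (!file.exists(cat_path)) {
    stop("idp_catalog.tsv not found in ", scan$sumstats_dir, call. = FALSE)
  }
  cat_ <- data.table::fread(cat_path, data.table = FALSE, showProgress = FALSE)
  sumstats <- lapply(seq_len(nrow(cat_)), function(j) {
    read_sumstats(file.path(scan$sumstats_dir, cat_$file[j]))
  })
  names(sumstats) <- cat_$idp_id
  list(catalog = cat_[, c("idp_id", "region", "measure", "source")],
       sumstats = sumstats)
}

#' Run the full antagonistic-SNP characterization pipeline
#'
#' Executes, in order and as configured: (1) the SNP-to-IDP association
#' scan with grid-wide FDR, (2) the bootstrap enrichment test against
#' random SNP sets, (3) the effect-direction concordance analysis against
#' case-control tables, (4) the eQTL/trait annotation filters, and (5) the
#' voxel-wise gray-matter analysis. Writes per-stage TSV/JSON reports and a
#' run manifest (package version, seeds, m convention, hemisphere policy)
#' into `output_dir`. Empty results are valid outcomes, not errors.
#'
#' @param config See [validate_config()].
#' @return Invisibly, a list of the per-stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(package = "antagmap",
                   version = as.character(utils::packageVersion("antagmap")),
                   stages = character(0))

  grid <- NULL
  scan_inputs <- NULL
  if (!is.null(config$scan)) {
    message("[scan] building association grid")
    sc <- config$scan
    targets <- read_target_snps(sc$targets)
    scan_inputs <- .load_scan_inputs(sc)
    alpha <- if (is.null(sc$alpha)) 0.05 else sc$alpha
    grid <- build_grid(targets, scan_inputs$sumstats,
                       idp_catalog = scan_inputs$catalog,
                       min_proxy_r2 = if (is.null(sc$min_proxy_r2)) 0.8
                                      else sc$min_proxy_r2)
    grid <- fdr_grid(grid, alpha = alpha, m = sc$m,
                     count_missing = isTRUE(sc$count_missing))
    write_grid_report(grid, file.path(out_dir, "associations.tsv"),
                      json_path = file.path(out_dir, "association_grid.json"))
    results$scan <- grid
    manifest$stages <- c(manifest$stages, "scan")
    manifest$scan <- list(alpha = alpha, m = grid$m,
                          n_significant = sum(grid$entries$significant))
  }

  if (!is.null(config$bootstrap)) {
    if (is.null(grid) || is.null(scan_inputs)) {
      stop("[bootstrap] requires the scan stage", call. = FALSE)
    }
    message("[bootstrap] sampling enrichment null")
    bc <- config$bootstrap
    B <- if (is.null(bc$B)) 10000 else bc$B
    seed <- if (is.null(bc$seed)) 1L else bc$seed
    alpha <- if (is.null(bc$alpha)) 0.05 else bc$alpha
    pmat <- vapply(scan_inputs$sumstats, function(ss) {
      ss$pvalue[match(sort(unique(scan_inputs$sumstats[[1]]$snp_id)),
                      ss$snp_id)]
    }, numeric(length(unique(scan_inputs$sumstats[[1]]$snp_id))))
    rownames(pmat) <- sort(unique(scan_inputs$sumstats[[1]]$snp_id))
    builder <- function(ids) as.numeric(stats::na.omit(as.numeric(pmat[ids, ])))
    targets <- grid$targets
    excl <- unique(stats::na.omit(c(targets$snp_id, targets$proxy_id)))
    pool <- define_pool(rownames(pmat), mode = "all_snps", exclusions = excl)
    res <- enrichment_test(intersect(targets$snp_id, rownames(pmat)),
                           pool, builder, B = B, seed = seed, alpha = alpha)
    write_enrichment_report(res, file.path(out_dir, "enrichment.json"))
    results$bootstrap <- res
    manifest$stages <- c(manifest$stages, "bootstrap")
    manifest$bootstrap <- list(B = B, seed = seed,
                               empirical_p = res$empirical_p)
  }

  if (!is.null(config$concord)) {
    if (is.null(grid)) stop("[concord] requires the scan stage", call. = FALSE)
    message("[concord] effect-direction triangulation")
    cf <- config$concord
    policy <- if (is.null(cf$hemisphere_policy)) "both-required"
              else cf$hemisphere_policy
    alpha <- if (is.null(cf$alpha)) 0.05 else cf$alpha
    cc <- read_case_control(cf$case_control,
                            exclude_subphenotypes =
                              cf$exclude_subphenotypes %||% character())
    merged <- hemisphere_merge(cc, policy = policy, alpha = alpha)
    sig <- significant_table(grid)
    tri <- concordance_table(sig, merged, alpha = alpha)
    opp <- find_opposed_idps(sig, merged, alpha = alpha)
    utils::write.table(tri, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(opp, file.path(out_dir, "opposed_idps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$concord <- list(triplets = tri, opposed = opp)
    manifest$stages <- c(manifest$stages, "concord")
    manifest$concord <- list(hemisphere_policy = policy,
                             n_opposed = nrow(opp))
  }

  if (!is.null(config$annotate)) {
    message("[annotate] eQTL and trait filters")
    an <- config$annotate
    alpha <- if (is.null(an$alpha)) 0.05 else an$alpha
    res_a <- list()
    if (!is.null(an$eqtl)) {
      eq <- read_eqtl(an$eqtl)
      if (is.null(an$n_snps) || is.null(an$n_tissues)) {
        stop("[annotate] n_snps and n_tissues are required explicit choices",
             call. = FALSE)
      }
      eq_sig <- eqtl_filter(eq, n_snps = an$n_snps, n_tissues = an$n_tissues,
                            alpha = alpha, threshold = an$threshold)
      utils::write.table(eq_sig, file.path(out_dir, "eqtl_significant.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res_a$eqtl <- eq_sig
    }
    if (!is.null(an$traits)) {
      tr <- read_traits(an$traits)
      tr_sig <- trait_filter(tr, threshold = an$trait_threshold %||% 5e-8)
      utils::write.table(tr_sig, file.path(out_dir, "traits_retained.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res_a$traits <- tr_sig
    }
    results$annotate <- res_a
    manifest$stages <- c(manifest$stages, "annotate")
  }

  if (!is.null(config$vbm)) {
    message("[vbm] voxel-wise gray-matter analysis")
    vb <- config$vbm
    cohort <- read_imaging_cohort(vb$images, vb$covariates, vb$dosage_col,
                                  mask_path = vb$mask)
    cl <- vbm_scan(cohort,
                   direction = vb$direction %||% "both",
                   p_cluster_forming = vb$cf_p %||% 0.001,
                   k_min = vb$k_min %||% 11,
                   connectivity = vb$connectivity %||% 18,
                   n_perm = vb$n_perm %||% 1000,
                   seed = vb$seed %||% 1L)
    utils::write.table(cl, file.path(out_dir, "vbm_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$vbm <- cl
    manifest$stages <- c(manifest$stages, "vbm")
    manifest$vbm <- list(n_perm = vb$n_perm %||% 1000, seed = vb$seed %||% 1L,
                         connectivity = vb$connectivity %||% 18)
  }

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
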