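#' Canonical summary-statistics column names
#'
#' The internal schema every summary-statistics table is mapped onto:
#' `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `effect`,
#' `se`, `pvalue`, `n`. Only `snp_id`, `effect_allele`, `other_allele`,
#' `effect` and `pvalue` are mandatory; `se` may be absent for tables whose
#' effect column is a Z-score (subcortical volume GWAS).
#'
#' @keywords internal
#' @noRd
.sumstats_canonical <- c("snp_id", "chrom", "pos", "effect_allele",
                         "other_allele", "effect", "se", "pvalue", "n")

.sumstats_mandatory <- c("snp_id", "effect_allele", "other_allele",
                         "effect", "pvalue")

#' Tokens treated as missing values in summary-statistics tables
#' @noRd
.missing_tokens <- c("NA", "NaN", "nan", ".", "")

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited summary-statistics file (optionally
#' gzip-compressed, with a header line), maps its columns onto the canonical
#' schema, validates p-values and drops rows whose p-value or effect size is
#' missing or non-finite. Duplicated rsIDs keep their first occurrence with a
#' warning: multi-allelic or duplicated rows cannot be disambiguated from
#' summary data alone.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping canonical names
#'   (`snp_id`, `effect_allele`, `other_allele`, `effect`, `pvalue` and
#'   optionally `chrom`, `pos`, `se`, `n`) to the column names used in the
#'   file. Canonical names already present in the file need not be mapped.
#' @param idp Optional IDP descriptor (see [idp_catalog()]) recorded as an
#'   attribute of the returned table.
#'
#' @return A `data.frame` with the canonical columns, one row per retained
#'   record, with attributes `n_dropped` (rows removed for missing or
#'   non-finite p/effect) and `idp`.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tA1\tA2\tBETA\tP",
#'              "rs1\tA\tG\t0.1\t0.5",
#'              "rs2\tT\tC\t-0.2\t0.01"), tf)
#' ss <- read_sumstats(tf, column_map = c(snp_id = "SNP", effect_allele = "A1",
#'   other_allele = "A2", effect = "BETA", pvalue = "P"))
#' nrow(ss)
#' @export
read_sumstats <- function(path, column_map = NULL, idp = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.gz$", path)) {
    dt <- utils::read.table(gzfile(path), header = TRUE,
                            na.strings = .missing_tokens,
                            stringsAsFactors = FALSE, comment.char = "")
  } else {
    dt <- data.table::fread(path, header = TRUE, na.strings = .missing_tokens,
                            data.table = FALSE, showProgress = FALSE)
  }
  if (nrow(dt) == 0L) stop("empty summary-statistics table: ", path, call. = FALSE)

  # apply the column mapping: names(column_map) are canonical, values are file columns
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(dt))
    if (length(bad)) {
      stop("mapped column(s) not present in ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(dt)[names(dt) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.sumstats_mandatory, names(dt))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  out <- data.frame(
    snp_id        = as.character(dt$snp_id),
    chrom         = if ("chrom" %in% names(dt)) as.character(dt$chrom) else NA_character_,
    pos           = if ("pos" %in% names(dt)) as.integer(dt$pos) else NA_integer_,
    effect_allele = toupper(as.character(dt$effect_allele)),
    other_allele  = toupper(as.character(dt$other_allele)),
    effect        = suppressWarnings(as.numeric(dt$effect)),
    se            = if ("se" %in% names(dt)) suppressWarnings(as.numeric(dt$se)) else NA_real_,
    pvalue        = suppressWarnings(as.numeric(dt$pvalue)),
    n             = if ("n" %in% names(dt)) suppressWarnings(as.numeric(dt$n)) else NA_real_,
    stringsAsFactors = FALSE
  )

  keep <- is.finite(out$pvalue) & is.finite(out$effect)
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no usable rows in ", path, call. = FALSE)
  if (any(out$pvalue <= 0 | out$pvalue > 1)) {
    stop("p-values outside (0, 1] in ", path, call. = FALSE)
  }
  dup <- duplicated(out$snp_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated rsID row(s) in ", basename(path),
            "; keeping first occurrence", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "idp") <- idp
  out
}

#' Harmonize summary-statistics records to a target risk allele
#'
#' Aligns records so that the signed effect refers to the target's risk
#' allele: if the record's effect allele already is the risk allele the
#' record is unchanged; if the record's *other* allele is the risk allele,
#' the alleles are swapped and the effect sign is negated; the p-value is
#' never changed. Strand-ambiguous allele pairs (A/T, C/G) cannot be
#' resolved without frequency information and are either flagged with a
#' warning (default) or excluded.
#'
#' @param records A `data.frame` of summary-statistics records (canonical
#'   columns, see [read_sumstats()]); may be a single row.
#' @param risk_allele The allele the effect should refer to (single
#'   character string, recycled across rows).
#' @param ambiguous Policy for strand-ambiguous pairs: `"warn"` accepts them
#'   as-is with a warning, `"exclude"` drops them.
#'
#' @return The harmonized records with an added logical column
#'   `strand_ambiguous`. Throws an error if, for any row, neither allele
#'   matches the risk allele (the error message carries both allele pairs).
#'
#' @examples
#' rec <- data.frame(snp_id = "rs9329221", effect_allele = "G",
#'                   other_allele = "T", effect = 12.496, pvalue = 7.93e-12)
#' harmonize_to_target(rec, risk_allele = "T")$effect  # -12.496
#' @export
harmonize_to_target <- function(records, risk_allele,
                                ambiguous = c("warn", "exclude")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  risk <- toupper(rep_len(as.character(risk_allele), nrow(records)))
  ea <- toupper(records$effect_allele)
  oa <- toupper(records$other_allele)

  match_ea <- ea == risk
  match_oa <- oa == risk
  bad <- !match_ea & !match_oa
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "allele mismatch for %s: record alleles %s/%s, target risk allele %s",
      records$snp_id[i], ea[i], oa[i], risk[i]), call. = FALSE)
  }

  flip <- match_oa & !match_ea
  records$effect_allele <- ifelse(flip, oa, ea)
  records$other_allele  <- ifelse(flip, ea, oa)
  records$effect        <- ifelse(flip, -records$effect, records$effect)

  amb <- is_strand_ambiguous(records$effect_allele, records$other_allele)
  records$strand_ambiguous <- amb
  if (any(amb)) {
    if (ambiguous == "exclude") {
      records <- records[!amb, , drop = FALSE]
    } else {
      warning(sum(amb), " strand-ambiguous (A/T or C/G) record(s) accepted as-is",
              call. = FALSE)
    }
  }
  rownames(records) <- NULL
  records
}

#' Detect strand-ambiguous allele pairs (A/T and C/G)
#' @param a,b Allele character vectors.
#' @return Logical vector.
#' @export
is_strand_ambiguous <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Resolve target SNPs against an available rsID set via LD proxies
#'
#' For each target SNP absent from `available_ids` with a proxy whose LD
#' r-squared meets `min_r2`, the proxy id is used for lookups. Targets
#' present directly keep their own id; targets absent with no admissible
#' proxy are marked unresolvable (a reported state, not an error).
#'
#' @param targets Target-SNP table (see [read_target_snps()]): columns
#'   `snp_id` and optionally `proxy_id`, `proxy_r2`.
#' @param available_ids Character vector of rsIDs present in the source.
#' @param min_r2 Minimum proxy LD r-squared (default 0.8).
#'
#' @return A `data.frame` with columns `snp_id`, `used_id`, `r2`, `status`
#'   (`"direct"`, `"proxy"`, `"unresolvable"`), one row per target.
#' @export
proxy_substitute <- function(targets, available_ids, min_r2 = 0.8) {
  stopifnot(is.data.frame(targets), "snp_id" %in% names(targets))
  has_proxy <- "proxy_id" %in% names(targets)
  out <- data.frame(snp_id = targets$snp_id,
                    used_id = targets$snp_id,
                    r2 = 1,
                    status = "direct",
                    stringsAsFactors = FALSE)
  absent <- !(targets$snp_id %in% available_ids)
  for (i in which(absent)) {
    pid <- if (has_proxy) targets$proxy_id[i] else NA_character_
    pr2 <- if ("proxy_r2" %in% names(targets)) targets$proxy_r2[i] else NA_real_
    if (!is.na(pid) && nzchar(pid) && !is.na(pr2) && pr2 >= min_r2 &&
        pid %in% available_ids) {
      out$used_id[i] <- pid
      out$r2[i] <- pr2
      out$status[i] <- "proxy"
    } else {
      out$used_id[i] <- NA_character_
      out$r2[i] <- NA_real_
      out$status[i] <- "unresolvable"
    }
  }
  out
}

#' Read a target-SNP table
#'
#' The table mirrors the fields of the antagonistic-SNP listing: rsID,
#' chromosome, position, effect/other allele, risk and protective disorder
#' codes, and an optional LD proxy with its r-squared.
#'
#' @param path Path to a TSV with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele` (risk allele), `other_allele`, `disorder_risk`,
#'   `disorder_protective`, and optionally `proxy_id`, `proxy_r2`.
#' @return A validated `data.frame`.
#' @export
read_target_snps <- function(path) {
  t <- data.table::fread(path, header = TRUE, na.strings = .missing_tokens,
                         data.table = FALSE, showProgress = FALSE)
  req <- c("snp_id", "effect_allele", "other_allele",
           "disorder_risk", "disorder_protective")
  missing_cols <- setdiff(req, names(t))
  if (length(missing_cols)) {
    stop("target-SNP table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("proxy_r2" %in% names(t)) {
    r2 <- t$proxy_r2[!is.na(t$proxy_r2)]
    if (any(r2 < 0 | r2 > 1)) stop("proxy_r2 outside [0, 1]", call. = FALSE)
  }
  t
}

#' Read an IDP catalog
#'
#' @param path TSV with columns `idp_id`, `region`, `measure`
#'   (one of SA, CT, VOL), `source`.
#' @return A validated `data.frame`.
#' @export
read_idp_catalog <- function(path) {
  cat <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  req <- c("idp_id", "region", "measure", "source")
  missing_cols <- setdiff(req, names(cat))
  if (length(missing_cols)) {
    stop("IDP catalog missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cat$idp_id)) stop("duplicated idp_id in catalog", call. = FALSE)
  if (!all(cat$measure %in% c("SA", "CT", "VOL"))) {
    stop("measure must be one of SA, CT, VOL", call. = FALSE)
  }
  cat
}

#' Read a case-control effect table
#'
#' Patient-versus-control standardized mean differences per region, measure
#' and hemisphere, with published multiplicity-adjusted p-values (the schema
#' that large consortium case-control exports reduce to).
#'
#' @param path TSV with columns `disorder`, `region`, `measure`,
#'   `hemisphere` (left/right/both), `d` (Cohen's d, negative = smaller in
#'   cases), `p_adjusted`, and optionally `source`.
#' @param exclude_subphenotypes Character vector of disorder/subphenotype
#'   labels to drop at ingestion (disorder-specific subphenotypes such as
#'   recurrence or subtype strata).
#' @return A `data.frame`.
#' @export
read_case_control <- function(path, exclude_subphenotypes = character()) {
  cc <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  req <- c("disorder", "region", "measure", "hemisphere", "d", "p_adjusted")
  missing_cols <- setdiff(req, names(cc))
  if (length(missing_cols)) {
    stop("case-control table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(cc$p_adjusted <= 0 | cc$p_adjusted > 1)) {
    stop("p_adjusted outside (0, 1]", call. = FALSE)
  }
  if (length(exclude_subphenotypes)) {
    cc <- cc[!(tolower(cc$disorder) %in% tolower(exclude_subphenotypes)), ,
             drop = FALSE]
  }
  cc
}

#' Read an eQTL table
#' @param path TSV with columns `snp_id`, `gene`, `locus_type`, `tissue`,
#'   `nes` (normalized effect size), `p`.
#' @return A `data.frame`.
#' @export
read_eqtl <- function(path) {
  e <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         showProgress = FALSE)
  req <- c("snp_id", "gene", "locus_type", "tissue", "nes", "p")
  missing_cols <- setdiff(req, names(e))
  if (length(missing_cols)) {
    stop("eQTL table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  e
}

#' Read a trait-association table
#' @param path TSV with columns `snp_id`, `trait`, `p`, and optionally
#'   `source`.
#' @return A `data.frame`.
#' @export
read_traits <- function(path) {
  t <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         showProgress = FALSE)
  req <- c("snp_id", "trait", "p")
  missing_cols <- setdiff(req, names(t))
  if (length(missing_cols)) {
    stop("trait table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  t
}
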