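#' Bonferroni-style eQTL significance filter
#'
#' Retains eQTL records whose nominal p-value falls below
#' `alpha / (n_snps * n_tissues)`, after first removing records whose HGNC
#' locus type marks a pseudogene (any locus-type string containing
#' "pseudogene", case-insensitively — HGNC distinguishes several pseudogene
#' subtypes). The threshold is computed exactly (e.g. 0.05/128 =
#' 3.90625e-4 for 8 SNPs and 16 brain tissues); a pre-rounded published
#' threshold can be imposed via `threshold`, which overrides the
#' denominator arithmetic.
#'
#' @param records eQTL table (see [read_eqtl()]).
#' @param n_snps,n_tissues Bonferroni denominator factors. The SNP count is
#'   a required explicit choice, never inferred from the table.
#' @param alpha Family-wise level (default 0.05).
#' @param threshold Optional explicit p threshold overriding
#'   `alpha / (n_snps * n_tissues)`.
#' @return The retained records, with the applied threshold as attribute
#'   `threshold`.
#' @examples
#' eq <- data.frame(snp_id = "rs2921036", gene = "FAM85B",
#'   locus_type = "RNA, long non-coding", tissue = "cortex",
#'   nes = -0.67, p = 3.0e-16)
#' nrow(eqtl_filter(eq, n_snps = 8, n_tissues = 16))
#' @export
eqtl_filter <- function(records, n_snps, n_tissues, alpha = 0.05,
                        threshold = NULL) {
  stopifnot(n_snps >= 1, n_tissues >= 1)
  if (is.null(threshold)) threshold <- alpha / (n_snps * n_tissues)
  keep <- !grepl("pseudogene", records$locus_type, ignore.case = TRUE)
  out <- records[keep & records$p < threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Disorder label synonyms for trait-association exclusion
#'
#' Shipped synonym table for the eight neuropsychiatric disorders of the
#' cross-disorder GWAS; used to exclude trait associations that merely
#' restate a disorder association. User-extensible: pass a modified list to
#' [trait_filter()].
#'
#' @return Named list mapping disorder code to a character vector of label
#'   substrings matched case-insensitively.
#' @export
disorder_synonyms <- function() {
  list(
    ADHD = c("adhd", "attention deficit", "attention-deficit", "hyperactivity disorder"),
    ANO  = c("anorexia"),
    ASD  = c("autism", "asperger"),
    BIP  = c("bipolar"),
    MDD  = c("major depressive", "major depression", "depressive disorder",
             "unipolar depression"),
    OCD  = c("obsessive-compulsive", "obsessive compulsive"),
    SCZ  = c("schizophrenia"),
    TS   = c("tourette")
  )
}

#' Genome-wide trait-association filter with disorder exclusion
#'
#' Retains trait associations below the genome-wide threshold whose trait
#' label does not match any excluded-disorder synonym (case-insensitive
#' substring match), so that the surviving annotations describe cognitive
#' and behavioral phenotypes beyond the disorders themselves.
#'
#' @param records Trait table (see [read_traits()]).
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @param excluded_traits Synonym table as produced by
#'   [disorder_synonyms()], or a plain character vector of substrings.
#' @return The retained records, with excluded-by-label rows available via
#'   attribute `n_excluded_disorder`.
#' @export
trait_filter <- function(records, threshold = 5e-8,
                         excluded_traits = disorder_synonyms()) {
  syn <- tolower(unlist(excluded_traits, use.names = FALSE))
  lab <- tolower(records$trait)
  is_disorder <- vapply(lab, function(x) any(vapply(
    syn, function(s) grepl(s, x, fixed = TRUE), logical(1))), logical(1))
  out <- records[!is_disorder & records$p < threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_disorder") <- sum(is_disorder & records$p < threshold)
  out
}
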