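#' Merge left/right hemisphere case-control effects
#'
#' The SNP-to-IDP grid uses hemisphere-averaged phenotypes while published
#' case-control tables report effects per hemisphere, so a merged quantity
#' is needed before comparing directions. Under the `both-required` policy a
#' merged effect is significant only when both hemispheres are significant
#' with the same sign (the merged d is the mean of the two); under `either`
#' it is significant when either hemisphere is, taking the sign of the more
#' significant one. Rows already tagged `both` pass through unchanged;
#' single-hemisphere rows pass through under `either` and are
#' non-significant under `both-required`.
#'
#' @param cc Case-control table (see [read_case_control()]).
#' @param policy `"both-required"` (default) or `"either"`.
#' @param alpha Significance level on the published adjusted p.
#' @return A case-control table with `hemisphere == "both"`, a logical
#'   `significant` column, and a `flag` column noting sign disagreements
#'   ("sign-disagreement") or missing hemispheres ("single-hemisphere").
#' @export
hemisphere_merge <- function(cc, policy = c("both-required", "either"),
                             alpha = 0.05) {
  policy <- match.arg(policy)
  key <- interaction(cc$disorder, cc$region, cc$measure, drop = TRUE)
  merged <- lapply(split(cc, key), function(g) {
    pre <- g[g$hemisphere == "both", , drop = FALSE]
    if (nrow(pre)) {          # already merged upstream
      pre$significant <- pre$p_adjusted < alpha
      pre$flag <- ""
      return(pre[1L, c("disorder", "region", "measure", "hemisphere", "d",
                       "p_adjusted", "significant", "flag")])
    }
    left <- g[g$hemisphere == "left", , drop = FALSE]
    right <- g[g$hemisphere == "right", , drop = FALSE]
    out <- data.frame(disorder = g$disorder[1L], region = g$region[1L],
                      measure = g$measure[1L], hemisphere = "both",
                      d = NA_real_, p_adjusted = NA_real_,
                      significant = FALSE, flag = "",
                      stringsAsFactors = FALSE)
    if (nrow(left) && nrow(right)) {
      sig_l <- left$p_adjusted[1L] < alpha
      sig_r <- right$p_adjusted[1L] < alpha
      same_sign <- sign(left$d[1L]) == sign(right$d[1L])
      out$d <- mean(c(left$d[1L], right$d[1L]))
      out$p_adjusted <- max(left$p_adjusted[1L], right$p_adjusted[1L])
      if (policy == "both-required") {
        out$significant <- sig_l && sig_r && same_sign
        if (sig_l && sig_r && !same_sign) {
          out$flag <- "sign-disagreement"
          out$significant <- FALSE
        }
      } else {
        out$significant <- sig_l || sig_r
        if (out$significant) {
          src <- if (left$p_adjusted[1L] <= right$p_adjusted[1L]) left else right
          out$d <- src$d[1L]
          out$p_adjusted <- src$p_adjusted[1L]
        }
      }
    } else {
      one <- if (nrow(left)) left else right
      out$d <- one$d[1L]
      out$p_adjusted <- one$p_adjusted[1L]
      out$flag <- "single-hemisphere"
      out$significant <- policy == "either" && one$p_adjusted[1L] < alpha
    }
    out
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

# Disorders with no large-scale case-control imaging table available.
.no_case_control_disorders <- c("ANO", "TS")

#' Classify the effect-direction triplet for one (SNP, IDP, disorder pair)
#'
#' Triangulates three effect directions: the harmonized SNP-to-IDP effect of
#' the risk allele, the allele's direction on disorder risk (risk for one
#' disorder, protective for the other), and the patient-versus-control
#' alteration of the same brain measure in each disorder. An allele that
#' raises an IDP and raises risk for disorder D is mediation-consistent when
#' patients with D show a raised measure; for the disorder the allele
#' protects against, the expected patient alteration has the opposite sign.
#'
#' Calls, in precedence order:
#' \describe{
#'   \item{opposed_idp}{both disorders show significant case-control effects
#'     of opposite sign,}
#'   \item{consistent_mediation}{every disorder with a significant
#'     case-control effect matches its expected sign,}
#'   \item{inconsistent}{some significant case-control effect conflicts with
#'     its expected sign,}
#'   \item{indeterminate}{no disorder has significant case-control data
#'     (including disorders with no published case-control study, or
#'     region/measure missing from the table).}
#' }
#'
#' @param snp_effect Harmonized (risk-allele) SNP-to-IDP effect size.
#' @param disorder_risk,disorder_protective Disorder codes for the allele's
#'   risk and protective directions.
#' @param cc_merged Hemisphere-merged case-control table
#'   ([hemisphere_merge()]) with a `significant` column.
#' @param region,measure The IDP's region and measure, used to match
#'   case-control rows.
#' @param alpha Significance level (only used if `cc_merged` lacks a
#'   `significant` column).
#' @return A one-row `data.frame`: the inputs' identifiers, the three sign
#'   fields (`sign_snp_idp`, `sign_cc_risk`, `sign_cc_protective`, each
#'   `"+"`, `"-"` or `"ns"`), the `call`, and a `reason` string for
#'   indeterminate calls.
#' @export
classify_triplet <- function(snp_effect, disorder_risk, disorder_protective,
                             cc_merged, region, measure, alpha = 0.05) {
  stopifnot(length(snp_effect) == 1L, is.finite(snp_effect))
  if (!"significant" %in% names(cc_merged)) {
    cc_merged$significant <- cc_merged$p_adjusted < alpha
  }
  s_snp <- if (snp_effect >= 0) 1 else -1

  cc_sign <- function(disorder) {
    if (disorder %in% .no_case_control_disorders) {
      return(list(sign = "ns", num = NA_real_, reason = "no-case-control-data"))
    }
    row <- cc_merged[cc_merged$disorder == disorder &
                     cc_merged$region == region &
                     cc_merged$measure == measure, , drop = FALSE]
    if (nrow(row) == 0L) {
      return(list(sign = "ns", num = NA_real_, reason = "missing-data"))
    }
    if (!row$significant[1L]) return(list(sign = "ns", num = NA_real_, reason = ""))
    list(sign = if (row$d[1L] >= 0) "+" else "-",
         num = if (row$d[1L] >= 0) 1 else -1, reason = "")
  }

  risk_cc <- cc_sign(disorder_risk)
  prot_cc <- cc_sign(disorder_protective)

  # expected patient-alteration signs under a mediation-consistent pattern
  exp_risk <- s_snp       # risk allele shifts the measure like patients do
  exp_prot <- -s_snp      # protective direction: patients shifted opposite

  call <- "indeterminate"
  reason <- ""
  if (!is.na(risk_cc$num) && !is.na(prot_cc$num) &&
      risk_cc$num != prot_cc$num) {
    call <- "opposed_idp"
  } else if (!is.na(risk_cc$num) || !is.na(prot_cc$num)) {
    ok_risk <- is.na(risk_cc$num) || risk_cc$num == exp_risk
    ok_prot <- is.na(prot_cc$num) || prot_cc$num == exp_prot
    call <- if (ok_risk && ok_prot) "consistent_mediation" else "inconsistent"
  } else {
    reason <- paste(unique(c(risk_cc$reason, prot_cc$reason)[
      nzchar(c(risk_cc$reason, prot_cc$reason))]), collapse = ";")
    if (!nzchar(reason)) reason <- "non-significant"
  }

  data.frame(disorder_risk = disorder_risk,
             disorder_protective = disorder_protective,
             region = region, measure = measure,
             sign_snp_idp = if (s_snp > 0) "+" else "-",
             sign_cc_risk = risk_cc$sign,
             sign_cc_protective = prot_cc$sign,
             call = call, reason = reason,
             stringsAsFactors = FALSE)
}

#' Triangulate all significant grid associations against case-control data
#'
#' Runs [classify_triplet()] for every row of a significant-association
#' table, matching case-control effects on region and measure.
#'
#' @param sig_table Output of [significant_table()] (must carry
#'   `disorder_risk`, `disorder_protective`, `region`, `measure`, `effect`).
#' @param cc_merged Hemisphere-merged case-control table.
#' @param alpha Significance level for case-control effects.
#' @return A `data.frame` with one row per (association, triplet), carrying
#'   `snp_id` and `idp_id` alongside the triplet fields.
#' @export
concordance_table <- function(sig_table, cc_merged, alpha = 0.05) {
  if (nrow(sig_table) == 0L) {
    return(data.frame(snp_id = character(), idp_id = character(),
                      call = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(sig_table)), function(i) {
    r <- sig_table[i, ]
    tri <- classify_triplet(r$effect, r$disorder_risk, r$disorder_protective,
                            cc_merged, r$region, r$measure, alpha = alpha)
    cbind(data.frame(snp_id = r$snp_id, idp_id = r$idp_id,
                     stringsAsFactors = FALSE), tri)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find IDPs with opposed case-control alterations between a disorder pair
#'
#' Scans the significantly associated IDPs for measures that are
#' significantly increased in patients of one disorder of an antagonistic
#' pair and significantly decreased in patients of the other. An empty
#' result is a valid, reportable outcome. The result is symmetric in the
#' disorder pair.
#'
#' @param sig_table Significant-association table with `region`, `measure`,
#'   `disorder_risk`, `disorder_protective` columns.
#' @param cc_merged Hemisphere-merged case-control table with a
#'   `significant` column.
#' @param alpha Significance level (only used if `significant` is absent).
#' @return `data.frame` with columns `idp_id`, `region`, `measure`,
#'   `disorder_a`, `disorder_b`, `d_a`, `d_b` (possibly zero rows).
#' @export
find_opposed_idps <- function(sig_table, cc_merged, alpha = 0.05) {
  empty <- data.frame(idp_id = character(), region = character(),
                      measure = character(), disorder_a = character(),
                      disorder_b = character(), d_a = numeric(),
                      d_b = numeric(), stringsAsFactors = FALSE)
  if (nrow(sig_table) == 0L) return(empty)
  if (!"significant" %in% names(cc_merged)) {
    cc_merged$significant <- cc_merged$p_adjusted < alpha
  }
  rows <- list()
  for (i in seq_len(nrow(sig_table))) {
    r <- sig_table[i, ]
    pair <- sort(c(r$disorder_risk, r$disorder_protective))
    get <- function(dis) {
      cc_merged[cc_merged$disorder == dis & cc_merged$region == r$region &
                cc_merged$measure == r$measure & cc_merged$significant, ,
                drop = FALSE]
    }
    a <- get(pair[1L]); b <- get(pair[2L])
    if (nrow(a) && nrow(b) && sign(a$d[1L]) != sign(b$d[1L])) {
      rows[[length(rows) + 1L]] <- data.frame(
        idp_id = r$idp_id, region = r$region, measure = r$measure,
        disorder_a = pair[1L], disorder_b = pair[2L],
        d_a = a$d[1L], d_b = b$d[1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
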