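cc_row <- function(disorder, region, measure, d, p, hemi = "both") {
  data.frame(disorder = disorder, region = region, measure = measure,
             hemisphere = hemi, d = d, p_adjusted = p,
             significant = p < 0.05, stringsAsFactors = FALSE)
}

test_that("hemisphere merge averages d under both-required", {
  cc <- rbind(cc_row("SCZ", "superior temporal", "SA", -0.196, 9.2e-9, "left"),
              cc_row("SCZ", "superior temporal", "SA", -0.195, 9.3e-7, "right"))
  m <- hemisphere_merge(cc[, 1:6], policy = "both-required")
  expect_equal(m$d, -0.1955)
  expect_true(m$significant)
  expect_equal(m$hemisphere, "both")
})

test_that("hemisphere sign disagreement and single hemispheres are flagged", {
  cc <- rbind(cc_row("MDD", "insula", "CT", -0.1, 0.01, "left"),
              cc_row("MDD", "insula", "CT", 0.1, 0.01, "right"))
  m <- hemisphere_merge(cc[, 1:6], policy = "both-required")
  expect_false(m$significant)
  expect_equal(m$flag, "sign-disagreement")

  solo <- cc_row("BIP", "fusiform", "SA", -0.2, 0.001, "left")[, 1:6]
  m_both <- hemisphere_merge(solo, policy = "both-required")
  expect_false(m_both$significant)
  expect_equal(m_both$flag, "single-hemisphere")
  m_either <- hemisphere_merge(solo, policy = "either")
  expect_true(m_either$significant)
  expect_equal(m_either$d, -0.2)
})

test_that("either policy takes sign from the more significant hemisphere", {
  cc <- rbind(cc_row("SCZ", "insula", "SA", -0.3, 1e-6, "left"),
              cc_row("SCZ", "insula", "SA", 0.05, 0.2, "right"))
  m <- hemisphere_merge(cc[, 1:6], policy = "either")
  expect_true(m$significant)
  expect_equal(m$d, -0.3)
})

test_that("the published worked example classifies as consistent mediation", {
  fx <- table1_fixture()
  merged <- hemisphere_merge(fx$case_control)
  tri <- classify_triplet(-12.496, "SCZ", "ASD", merged,
                          "superior temporal", "SA")
  expect_equal(tri$call, "consistent_mediation")
  expect_equal(tri$sign_snp_idp, "-")
  expect_equal(tri$sign_cc_risk, "-")
  expect_equal(tri$sign_cc_protective, "ns")
})

test_that("the triplet rule table covers conflict, opposition, and gaps", {
  merged <- rbind(cc_row("SCZ", "insula", "SA", -0.2, 0.001),
                  cc_row("MDD", "insula", "SA", 0.2, 0.001),
                  cc_row("BIP", "insula", "SA", 0.2, 0.8))
  # risk-allele effect + but risk disorder significantly decreased
  expect_equal(classify_triplet(1.5, "SCZ", "BIP", merged,
                                "insula", "SA")$call, "inconsistent")
  # both disorders significant with opposite signs
  expect_equal(classify_triplet(1.5, "SCZ", "MDD", merged,
                                "insula", "SA")$call, "opposed_idp")
  # no significant case-control data at all
  ind <- classify_triplet(1.5, "BIP", "OCD", merged, "insula", "SA")
  expect_equal(ind$call, "indeterminate")
  # disorders without any published case-control study
  no_cc <- classify_triplet(1.5, "ANO", "TS", merged, "insula", "SA")
  expect_equal(no_cc$call, "indeterminate")
  expect_match(no_cc$reason, "no-case-control-data")
  # region absent from the table
  miss <- classify_triplet(1.5, "SCZ", "MDD", merged, "cuneus", "SA")
  expect_equal(miss$call, "indeterminate")
  expect_match(miss$reason, "missing-data")
})

test_that("triplet calls are invariant to allele re-harmonization", {
  merged <- rbind(cc_row("SCZ", "insula", "SA", -0.2, 0.001),
                  cc_row("MDD", "insula", "SA", 0.2, 0.001),
                  cc_row("BIP", "insula", "SA", -0.1, 0.01),
                  cc_row("ASD", "insula", "SA", 0.1, 0.5))
  set.seed(13)
  pairs <- list(c("SCZ", "MDD"), c("SCZ", "ASD"), c("BIP", "MDD"),
                c("MDD", "BIP"))
  for (pair in pairs) {
    for (eff in c(-2, 2)) {
      a <- classify_triplet(eff, pair[1], pair[2], merged, "insula", "SA")
      # flipping to the other allele negates the effect and swaps roles
      b <- classify_triplet(-eff, pair[2], pair[1], merged, "insula", "SA")
      expect_equal(a$call, b$call)
    }
  }
})

test_that("no opposed IDPs are found in the published mirror fixture", {
  fx <- table1_fixture()
  g <- fdr_grid(fx$grid, alpha = 0.05, m = 869)
  sig <- significant_table(g)
  merged <- hemisphere_merge(fx$case_control)
  opp <- find_opposed_idps(sig, merged)
  expect_equal(nrow(opp), 0L)
  # and the triangulation yields at least one consistent-mediation SNP
  tri <- concordance_table(sig, merged)
  cm <- tri$snp_id[tri$call == "consistent_mediation"]
  expect_true("rs9329221" %in% cm)
})

test_that("planted opposition is detected and symmetric in the pair", {
  sig <- data.frame(snp_id = "rsX", idp_id = "SA:insula", region = "insula",
                    measure = "SA", effect = 1, p = 1e-6, p_fdr = 1e-4,
                    disorder_risk = "SCZ", disorder_protective = "MDD",
                    stringsAsFactors = FALSE)
  merged <- rbind(cc_row("SCZ", "insula", "SA", 0.2, 0.001),
                  cc_row("MDD", "insula", "SA", -0.2, 0.001))
  opp <- find_opposed_idps(sig, merged)
  expect_equal(nrow(opp), 1L)
  expect_equal(opp$region, "insula")

  sig_swapped <- transform(sig, disorder_risk = "MDD",
                           disorder_protective = "SCZ")
  opp2 <- find_opposed_idps(sig_swapped, merged)
  expect_equal(opp[, c("disorder_a", "disorder_b")],
               opp2[, c("disorder_a", "disorder_b")])

  merged_ns <- transform(merged, p_adjusted = 1, significant = FALSE)
  expect_equal(nrow(find_opposed_idps(sig, merged_ns)), 0L)
})
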