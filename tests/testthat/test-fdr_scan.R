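test_that("bh_adjust matches the brute-force definition on random vectors", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    p <- runif(n)^sample(1:3, 1)
    p[p == 0] <- 1e-12
    m <- n + sample(0:20, 1)
    expect_equal(bh_adjust(p, m), bh_oracle(p, m), tolerance = 1e-12)
  }
})

test_that("bh_adjust agrees with the stats library at m = n", {
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("bh_adjust is monotone and stable under p = 1 padding", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    p <- runif(n)
    adj <- bh_adjust(p, m = n)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # monotone in p
    # appending k ones while incrementing m leaves earlier values unchanged
    k <- sample(1:20, 1)
    padded <- bh_adjust(c(p, rep(1, k)), m = n + k)
    direct <- bh_adjust(p, m = n + k)
    expect_equal(padded[seq_len(n)], direct, tolerance = 1e-12)
  }
})

test_that("bh_adjust validates its domain", {
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "at least")
  expect_equal(bh_adjust(0.04, m = 1), 0.04)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("step-up propagation pulls later ranks down as published", {
  fx <- table1_fixture()
  p <- fx$grid$entries$p
  adj <- bh_adjust(p, m = 869)
  ent <- fx$grid$entries
  # raw 1.64e-5 must inherit the rank-6 value, not its own rank-4 quotient
  a <- adj[ent$p == 1.64e-5]
  expect_false(isTRUE(all.equal(a, 1.64e-5 * 869 / 4)))
  expect_equal(signif(a, 3), 3.13e-3)
  expect_equal(signif(adj[ent$p == 2.87e-5], 3), 3.14e-3)
  expect_equal(signif(adj[ent$p == 3.84e-4], 3), 1.77e-2)
})

test_that("build_grid assembles one entry per resolvable (target, IDP) pair", {
  sim <- gen_sumstats(sumstats_scenario(n_snps = 20, seed = 5))
  targets <- data.frame(snp_id = sim$snp_ids[1:3],
                        effect_allele = sim$sumstats[[1]]$effect_allele[1:3],
                        other_allele = sim$sumstats[[1]]$other_allele[1:3],
                        disorder_risk = "SCZ", disorder_protective = "MDD")
  ss3 <- sim$sumstats[1:3]
  grid <- build_grid(targets, ss3, idp_catalog = sim$catalog)
  expect_s3_class(grid, "association_grid")
  expect_equal(nrow(grid$entries), 9L)
  expect_equal(nrow(grid$missing), 0L)

  # remove one target from one table -> 8 entries, 1 missing
  ss3[[2]] <- ss3[[2]][ss3[[2]]$snp_id != targets$snp_id[1], ]
  grid2 <- build_grid(targets, ss3, idp_catalog = sim$catalog)
  expect_equal(nrow(grid2$entries), 8L)
  expect_equal(nrow(grid2$missing), 1L)
  expect_equal(grid2$missing$snp_id, targets$snp_id[1])

  grid1 <- build_grid(targets[1, ], ss3[3], idp_catalog = sim$catalog)
  expect_equal(nrow(grid1$entries), 1L)
})

test_that("build_grid routes lookups through admissible proxies", {
  sim <- gen_sumstats(sumstats_scenario(n_snps = 10, seed = 9))
  ss <- sim$sumstats[1:2]
  targets <- data.frame(snp_id = "rs_absent",
                        effect_allele = ss[[1]]$effect_allele[4],
                        other_allele = ss[[1]]$other_allele[4],
                        disorder_risk = "SCZ", disorder_protective = "MDD",
                        proxy_id = sim$snp_ids[4], proxy_r2 = 1)
  grid <- build_grid(targets, ss)
  expect_equal(nrow(grid$entries), 2L)
  expect_equal(unique(grid$entries$used_id), sim$snp_ids[4])
  expect_equal(unique(grid$entries$snp_id), "rs_absent")
})

test_that("fdr_grid enforces the grid invariants", {
  sim <- gen_sumstats(sumstats_scenario(n_snps = 15, seed = 2))
  targets <- data.frame(snp_id = sim$snp_ids[1:4],
                        effect_allele = sim$sumstats[[1]]$effect_allele[1:4],
                        other_allele = sim$sumstats[[1]]$other_allele[1:4],
                        disorder_risk = "BIP", disorder_protective = "MDD")
  grid <- fdr_grid(build_grid(targets, sim$sumstats[1:5]), alpha = 0.05)
  e <- grid$entries
  expect_true(all(e$p_fdr >= e$p - 1e-15))
  expect_true(all(e$p_fdr > 0 & e$p_fdr <= 1))
  expect_identical(e$significant, e$p_fdr < grid$alpha)
  expect_gte(grid$m, nrow(e))
})

test_that("significant_table groups by SNP, sorts by p, handles extremes", {
  fx <- table1_fixture()
  g <- fdr_grid(fx$grid, alpha = 0.05, m = 869)
  tab <- significant_table(g)
  expect_equal(nrow(tab), 27L)
  expect_equal(length(unique(tab$snp_id)), 8L)
  # sorted by p within each SNP block
  for (s in unique(tab$snp_id)) {
    expect_true(!is.unsorted(tab$p[tab$snp_id == s]))
  }
  # annotation columns mirror the target table
  expect_true(all(c("chrom", "pos", "effect_allele", "disorder_risk",
                    "disorder_protective") %in% names(tab)))

  g_all1 <- g
  g_all1$entries$p_fdr <- 1
  expect_equal(nrow(significant_table(g_all1)), 0L)

  one <- g
  one$entries$p_fdr <- c(1e-10, rep(1, nrow(g$entries) - 1))
  expect_equal(nrow(significant_table(one)), 1L)
})

test_that("grid reports round-trip to disk", {
  fx <- table1_fixture()
  g <- fdr_grid(fx$grid, alpha = 0.05, m = 869)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_grid_report(g, tsv, json_path = js)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 27L)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$m, 869L)
  expect_equal(nrow(j$entries), 869L)
})
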