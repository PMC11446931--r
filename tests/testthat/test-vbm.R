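tiny_cohort <- function(n = 12, shape = c(4, 4, 4), seed = 1) {
  set.seed(seed)
  vols <- array(rnorm(prod(shape) * n), dim = c(shape, n))
  cov <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  imaging_cohort(vols, cov, dosage = rbinom(n, 2, 0.4),
                 affine = diag(c(2, 2, 2, 1)))
}

test_that("voxel-wise t equals the normal-equations oracle", {
  set.seed(21)
  for (trial in 1:100) {
    n <- sample(8:12, 1)
    ncov <- sample(0:2, 1)
    cov <- if (ncov > 0) {
      as.data.frame(matrix(rnorm(n * ncov), n,
                           dimnames = list(NULL, paste0("c", seq_len(ncov)))))
    } else data.frame(row.names = seq_len(n))
    dosage <- rbinom(n, 2, 0.5) + runif(n, 0, 0.1)  # fractional dosages
    vols <- array(rnorm(8 * n), dim = c(2, 2, 2, n))
    cohort <- imaging_cohort(vols, cov, dosage)
    fit <- fit_voxelwise_glm(cohort)
    X <- cbind(1, dosage, as.matrix(cov))
    for (v in sample(8, 3)) {
      ijk <- arrayInd(v, c(2, 2, 2))
      y <- vols[ijk[1], ijk[2], ijk[3], ]
      expect_equal(fit$t[ijk[1], ijk[2], ijk[3]], ols_t_oracle(X, y)[2],
                   tolerance = 1e-8)
    }
    expect_equal(fit$df, n - ncol(X))
  }
})

test_that("single-voxel mask reproduces the closed-form OLS t", {
  n <- 5
  y <- c(1.2, 0.7, 1.9, 2.4, 0.3)
  dosage <- c(0, 1, 1, 2, 0)
  vols <- array(rep(y, each = 8), dim = c(2, 2, 2, n))
  mask <- array(FALSE, c(2, 2, 2)); mask[1, 1, 1] <- TRUE
  cohort <- imaging_cohort(vols, data.frame(row.names = 1:n), dosage,
                           mask = mask)
  fit <- fit_voxelwise_glm(cohort)
  expect_equal(fit$t[1, 1, 1], ols_t_oracle(cbind(1, dosage), y)[2],
               tolerance = 1e-10)
  expect_true(all(is.na(fit$t[-1])))
})

test_that("degenerate designs raise informative errors", {
  cohort <- tiny_cohort()
  cohort$dosage <- rep(1, dim(cohort$volumes)[4])
  expect_error(fit_voxelwise_glm(cohort), "collinear.*dosage")

  c2 <- tiny_cohort()
  c2$covariates$dup <- c2$dosage
  expect_error(fit_voxelwise_glm(c2), "collinear")

  expect_error(imaging_cohort(array(0, c(2, 2, 2, 3)),
                              data.frame(x = 1:3), dosage = 1:3,
                              mask = array(FALSE, c(2, 2, 2))),
               "mask")
})

test_that("planted dosage effects raise t inside the effect region", {
  hits <- 0
  for (s in 1:20) {
    region <- as.matrix(expand.grid(7:9, 7:9, 7:9))
    sim <- gen_imaging_cohort(imaging_scenario(
      n_subjects = 20, effect_region = region, effect_size = 0.5, seed = s))
    fit <- fit_voxelwise_glm(sim$cohort)
    lin <- (region[, 3] - 1) * 256 + (region[, 2] - 1) * 16 + region[, 1]
    if (mean(fit$t[lin]) > mean(fit$t[-lin], na.rm = TRUE)) hits <- hits + 1
  }
  expect_gte(hits, 17)  # paired sign check across seeds
})

test_that("the negative-contrast map is the negation of the positive one", {
  cohort <- tiny_cohort(n = 14, seed = 5)
  fit <- fit_voxelwise_glm(cohort)
  fit_neg <- fit
  fit_neg$t <- -fit$t
  cl_pos <- threshold_clusters(fit, "positive", p_cluster_forming = 0.1,
                               k_min = 1)
  cl_neg <- threshold_clusters(fit_neg, "negative", p_cluster_forming = 0.1,
                               k_min = 1)
  expect_equal(cl_pos$k, cl_neg$k)
  expect_equal(cl_pos$peak_t, -cl_neg$peak_t)
  expect_equal(cl_pos$peak_p_uncorrected, cl_neg$peak_p_uncorrected)
})

test_that("connected components match the flood-fill oracle", {
  set.seed(33)
  for (trial in 1:15) {
    supra <- array(runif(8^3) < 0.25, dim = c(8, 8, 8))
    for (conn in c(6, 18, 26)) {
      lab <- connected_components(supra, conn)
      oracle <- flood_fill_components(supra, conn)
      expect_true(same_partition(lab, oracle))
      expect_equal(component_size_multiset(lab),
                   component_size_multiset(oracle))
    }
  }
})

test_that("corner-touching blobs split under 6- but join under 26-connectivity", {
  supra <- array(FALSE, c(6, 6, 6))
  supra[1:2, 1:2, 1:2] <- TRUE
  supra[3, 3, 3] <- TRUE   # touches (2,2,2) only at a corner
  lab6 <- connected_components(supra, 6)
  lab26 <- connected_components(supra, 26)
  expect_equal(max(lab6), 2L)
  expect_equal(max(lab26), 1L)
})

test_that("the extent rule k > 10 is strict", {
  fit <- list(t = array(0, c(8, 8, 8)), df = 30,
              mask = array(TRUE, c(8, 8, 8)), affine = diag(4))
  # an 10-voxel bar and a 12-voxel bar above threshold
  fit$t[1:5, 1:2, 1] <- 10
  fit$t[1:6, 5:6, 3] <- 10
  cl <- threshold_clusters(fit, "positive", k_min = 11)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$k, 12L)
  cl_all <- threshold_clusters(fit, "positive", k_min = 1)
  expect_setequal(cl_all$k, c(10L, 12L))
})

test_that("cluster peaks carry grid and world coordinates", {
  fit <- list(t = array(0, c(8, 8, 8)), df = 30,
              mask = array(TRUE, c(8, 8, 8)),
              affine = rbind(c(2, 0, 0, -8), c(0, 2, 0, -8),
                             c(0, 0, 2, -8), c(0, 0, 0, 1)))
  fit$t[2:4, 2:4, 2:4] <- 5
  fit$t[3, 3, 3] <- 9
  cl <- threshold_clusters(fit, "positive", k_min = 11)
  expect_equal(cl$k, 27L)
  expect_equal(c(cl$peak_i, cl$peak_j, cl$peak_k), c(2, 2, 2))  # 0-based
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), c(-4, -4, -4))
  expect_equal(cl$peak_t, 9)
})

test_that("permutation peak-FWE is deterministic and add-one bounded", {
  sim <- gen_imaging_cohort(imaging_scenario(grid_shape = c(6, 6, 6),
                                             n_subjects = 16, seed = 3))
  fit <- fit_voxelwise_glm(sim$cohort)
  cl <- threshold_clusters(fit, "positive", p_cluster_forming = 0.05,
                           k_min = 1)
  expect_gt(nrow(cl), 0)   # liberal forming threshold guarantees clusters
  a <- permutation_peak_fwe(fit, cl, n_perm = 50, seed = 9)
  b <- permutation_peak_fwe(fit, cl, n_perm = 50, seed = 9)
  expect_identical(a$peak_p_fwe, b$peak_p_fwe)
  expect_true(all(a$peak_p_fwe >= 1 / 51 & a$peak_p_fwe <= 1))

  one <- permutation_peak_fwe(fit, cl, n_perm = 1, seed = 2)
  expect_true(all(one$peak_p_fwe %in% c(0.5, 1)))
  expect_error(permutation_peak_fwe(fit, cl, n_perm = 0), "n_perm")
})

test_that("the t-map is invariant to subject ordering", {
  sim <- gen_imaging_cohort(imaging_scenario(grid_shape = c(6, 6, 6),
                                             n_subjects = 18, seed = 4))
  cohort <- sim$cohort
  perm <- sample(18)
  shuffled <- imaging_cohort(cohort$volumes[, , , perm],
                             cohort$covariates[perm, ],
                             cohort$dosage[perm],
                             mask = cohort$mask, affine = cohort$affine)
  f1 <- fit_voxelwise_glm(cohort)
  f2 <- fit_voxelwise_glm(shuffled)
  expect_equal(f1$t, f2$t, tolerance = 1e-10)
  expect_equal(f1$df, f2$df)
})

test_that("peaks are labeled through the atlas affine", {
  lut <- data.frame(value = c(5, 7), label = c("regionA", "regionB"))
  vol <- array(0L, c(4, 4, 4))
  vol[2, 3, 4] <- 5L
  affine <- diag(c(2, 2, 2, 1))
  expect_equal(label_peak(c(2, 4, 6), vol, affine, lut), "regionA")
  expect_equal(as.character(label_peak(c(0, 0, 0), vol, affine, lut)),
               "unlabeled")
  out <- label_peak(c(100, 0, 0), vol, affine, lut)
  expect_equal(as.character(out), "unlabeled")
  expect_true(attr(out, "out_of_field"))
})

test_that("imaging cohorts round-trip through NIfTI files", {
  sim <- gen_imaging_cohort(imaging_scenario(grid_shape = c(6, 6, 6),
                                             n_subjects = 12, seed = 6))
  dir <- tempfile(); dir.create(dir)
  img_path <- file.path(dir, "gmv4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(sim$cohort$volumes), img_path)
  cov_path <- file.path(dir, "covariates.tsv")
  cov <- cbind(sim$cohort$covariates, dosage = sim$cohort$dosage)
  write.table(cov, cov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_imaging_cohort(img_path, cov_path, "dosage")
  expect_equal(unclass(back$volumes), unclass(sim$cohort$volumes),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$dosage, sim$cohort$dosage)
  f1 <- fit_voxelwise_glm(sim$cohort)
  f2 <- fit_voxelwise_glm(back)
  expect_equal(f1$t, f2$t, tolerance = 1e-4)
})
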