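#' Construct an imaging cohort
#'
#' Bundles per-subject gray-matter-volume grids with the analysis mask,
#' covariates, allele dosage, and the grid-to-world affine.
#'
#' @param volumes 4D numeric array (x, y, z, subject) of modulated
#'   gray-matter volume in arbitrary consistent units.
#' @param covariates `data.frame` with one row per subject; categorical
#'   columns are dummy-coded into the design.
#' @param dosage Numeric vector of allele dosages in \[0, 2\] (fractional
#'   imputed dosages allowed), or a named list/data.frame of dosage columns
#'   per SNP.
#' @param mask Logical 3D array of analyzable voxels (default: voxels
#'   finite in every subject).
#' @param affine 4x4 matrix mapping 0-based grid indices to world mm
#'   (default: identity spacing of 1 mm).
#' @return An object of class `imaging_cohort`.
#' @export
imaging_cohort <- function(volumes, covariates, dosage, mask = NULL,
                           affine = diag(4)) {
  stopifnot(length(dim(volumes)) == 4L)
  n <- dim(volumes)[4L]
  stopifnot(nrow(covariates) == n)
  if (is.null(mask)) {
    mask <- apply(is.finite(volumes), c(1, 2, 3), all)
  }
  stopifnot(identical(dim(mask), dim(volumes)[1:3]))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (is.numeric(dosage)) {
    stopifnot(length(dosage) == n)
  } else {
    stopifnot(all(vapply(dosage, length, integer(1)) == n))
  }
  structure(list(volumes = volumes, mask = mask, covariates = covariates,
                 dosage = dosage, affine = affine),
            class = "imaging_cohort")
}

#' @export
print.imaging_cohort <- function(x, ...) {
  d <- dim(x$volumes)
  cat("Imaging cohort:", d[4], "subjects,", paste(d[1:3], collapse = "x"),
      "grid,", sum(x$mask), "masked voxels\n")
  invisible(x)
}

#' Read an imaging cohort from NIfTI files
#'
#' @param image_paths Either one 4D NIfTI path or a character vector of 3D
#'   per-subject NIfTI paths (order must match the covariate table).
#' @param covariates_path TSV covariate table, one row per subject.
#' @param dosage_col Name of the dosage column inside the covariate table.
#' @param mask_path Optional binary NIfTI mask.
#' @return An `imaging_cohort`; the affine is taken from the first image.
#' @export
read_imaging_cohort <- function(image_paths, covariates_path, dosage_col,
                                mask_path = NULL) {
  imgs <- lapply(image_paths, RNifti::readNifti)
  affine <- structure(RNifti::xform(imgs[[1L]]), class = "matrix")
  if (length(imgs) == 1L && length(dim(imgs[[1L]])) == 4L) {
    vols <- unclass(imgs[[1L]])
  } else {
    vols <- array(unlist(lapply(imgs, as.numeric)),
                  dim = c(dim(imgs[[1L]]), length(imgs)))
  }
  cov <- data.table::fread(covariates_path, header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  if (!dosage_col %in% names(cov)) {
    stop("dosage column not found: ", dosage_col, call. = FALSE)
  }
  dosage <- cov[[dosage_col]]
  cov <- cov[, setdiff(names(cov), dosage_col), drop = FALSE]
  mask <- if (!is.null(mask_path)) {
    unclass(RNifti::readNifti(mask_path)) > 0
  } else NULL
  imaging_cohort(vols, cov, dosage, mask = mask, affine = affine)
}

# Build the full design matrix: intercept + dosage + dummy-coded covariates.
.vbm_design <- function(covariates, dosage) {
  if (ncol(covariates) > 0) {
    mm <- stats::model.matrix(~ ., data = covariates)
  } else {
    mm <- matrix(1, nrow = length(dosage), dimnames = list(NULL, "(Intercept)"))
  }
  X <- cbind(mm[, "(Intercept)", drop = FALSE], dosage = dosage,
             mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE])
  X
}

# Flag rank deficiency, naming the pivoted-out columns.
.check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qrX
}

#' Voxel-wise general linear model of gray-matter volume on allele dosage
#'
#' Per masked voxel, ordinary least squares of the voxel value on a design
#' of intercept, dosage, and dummy-coded covariates. The returned t-map is
#' the dosage coefficient divided by its standard error; the negative
#' contrast's map is exactly the negation of the positive one.
#'
#' @param cohort An `imaging_cohort`.
#' @param dosage Dosage vector (defaults to `cohort$dosage`; pass one
#'   column when the cohort carries several SNPs).
#' @return List of class `vbm_fit`: `t`, `beta`, `se` (3D arrays, `NA`
#'   outside the mask), `df` (n minus design rank), `design`, `mask`,
#'   `affine`, and the partialled internals used by the permutation engine.
#' @export
fit_voxelwise_glm <- function(cohort, dosage = NULL) {
  stopifnot(inherits(cohort, "imaging_cohort"))
  if (is.null(dosage)) dosage <- cohort$dosage
  if (!is.numeric(dosage)) {
    stop("dosage must be a numeric vector; select one SNP column",
         call. = FALSE)
  }
  n <- dim(cohort$volumes)[4L]
  X <- .vbm_design(cohort$covariates, dosage)
  if (n < ncol(X) + 2L) {
    stop("need at least 2 more subjects than design columns", call. = FALSE)
  }
  .check_rank(X)

  vox <- which(cohort$mask)
  V <- length(vox)
  Y <- matrix(cohort$volumes, nrow = prod(dim(cohort$volumes)[1:3]))[vox, ,
                                                                     drop = FALSE]
  Y <- t(Y)  # n x V

  # Frisch-Waugh partialling: residualize Y and dosage on the nuisance block
  Z <- X[, setdiff(colnames(X), "dosage"), drop = FALSE]
  ZtZinv_Zt <- solve(crossprod(Z), t(Z))
  Ytil <- Y - Z %*% (ZtZinv_Zt %*% Y)
  dtil <- as.numeric(dosage - Z %*% (ZtZinv_Zt %*% dosage))
  df <- n - ncol(X)

  xx <- sum(dtil^2)
  beta <- as.numeric(crossprod(dtil, Ytil)) / xx
  rss <- colSums(Ytil^2) - beta^2 * xx
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / xx)
  tval <- beta / se

  shape <- dim(cohort$volumes)[1:3]
  as_map <- function(v) {
    m <- array(NA_real_, dim = shape)
    m[vox] <- v
    m
  }
  structure(list(t = as_map(tval), beta = as_map(beta), se = as_map(se),
                 df = df, design = X, mask = cohort$mask,
                 affine = cohort$affine,
                 partialled = list(Ytil = Ytil, dtil = dtil, Z = Z,
                                   ZtZinv_Zt = ZtZinv_Zt,
                                   yy = colSums(Ytil^2), vox = vox)),
            class = "vbm_fit")
}

# Neighbor offsets for 6-, 18-, or 26-connectivity.
.connectivity_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  nz <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

#' Label connected components of a logical 3D array
#'
#' Components are computed on the voxel adjacency graph under the given
#' connectivity (6 = faces, 18 = faces + edges, 26 = faces + edges +
#' corners).
#'
#' @param supra Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array: 0 outside components, 1..K component labels.
#' @export
connected_components <- function(supra, connectivity = 18) {
  stopifnot(length(dim(supra)) == 3L)
  off <- .connectivity_offsets(connectivity)
  shape <- dim(supra)
  vox_lin <- which(supra)
  lab <- array(0L, dim = shape)
  if (length(vox_lin) == 0L) return(lab)
  node_of <- integer(prod(shape))
  node_of[vox_lin] <- seq_along(vox_lin)
  ijk <- arrayInd(vox_lin, shape)

  edges <- list()
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2L, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * shape[1] * shape[2] +
              (nb[ok, 2] - 1L) * shape[1] + nb[ok, 1]
    hit <- node_of[nb_lin] > 0L
    if (!any(hit)) next
    from <- node_of[vox_lin[ok]][hit]
    to <- node_of[nb_lin][hit]
    edges[[length(edges) + 1L]] <- cbind(from, to)
  }
  g <- igraph::make_empty_graph(n = length(vox_lin), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  memb <- igraph::components(g)$membership
  lab[vox_lin] <- as.integer(memb)
  lab
}

#' Threshold a t-map into suprathreshold clusters
#'
#' Applies the one-sided cluster-forming threshold in the requested
#' direction, labels connected components, and retains components whose
#' size strictly exceeds `k_min - 1` voxels (the conventional "k > 10"
#' extent rule corresponds to the default `k_min = 11`).
#'
#' @param fit A `vbm_fit` (or a list with `t`, `df`, `mask`, `affine`).
#' @param direction `"positive"` or `"negative"`.
#' @param p_cluster_forming One-sided uncorrected cluster-forming p
#'   (default 0.001).
#' @param k_min Minimum retained cluster size in voxels (default 11).
#' @param connectivity 6, 18 (default) or 26.
#' @return `data.frame` of class `cluster_result`: `cluster_id`, `k`,
#'   0-based peak grid indices (`peak_i`, `peak_j`, `peak_k`), world-mm
#'   peak coordinates (`peak_x`, `peak_y`, `peak_z`), `peak_t`,
#'   `peak_p_uncorrected`, `peak_p_fwe` (`NA` until
#'   [permutation_peak_fwe()]), `direction`, `label`. May have zero rows.
#' @export
threshold_clusters <- function(fit, direction = c("positive", "negative"),
                               p_cluster_forming = 0.001, k_min = 11,
                               connectivity = 18) {
  direction <- match.arg(direction)
  tmap <- fit$t
  df <- fit$df
  tcrit <- stats::qt(p_cluster_forming, df, lower.tail = FALSE)
  supra <- if (direction == "positive") {
    !is.na(tmap) & tmap > tcrit
  } else {
    !is.na(tmap) & tmap < -tcrit
  }
  empty <- data.frame(cluster_id = integer(), k = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      peak_t = numeric(), peak_p_uncorrected = numeric(),
                      peak_p_fwe = numeric(), direction = character(),
                      label = character(), stringsAsFactors = FALSE)
  class(empty) <- c("cluster_result", "data.frame")
  if (!any(supra)) return(empty)

  lab <- connected_components(supra, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= k_min)
  if (!length(keep)) return(empty)

  rows <- lapply(seq_along(keep), function(i) {
    comp <- keep[i]
    lin <- which(lab == comp)
    tv <- tmap[lin]
    pk <- if (direction == "positive") which.max(tv) else which.min(tv)
    peak_lin <- lin[pk]
    ijk1 <- arrayInd(peak_lin, dim(tmap))
    world <- as.numeric(fit$affine %*% c(ijk1 - 1L, 1))[1:3]
    peak_t <- tv[pk]
    data.frame(cluster_id = i, k = sizes[comp],
               peak_i = ijk1[1] - 1L, peak_j = ijk1[2] - 1L,
               peak_k = ijk1[3] - 1L,
               peak_x = world[1], peak_y = world[2], peak_z = world[3],
               peak_t = peak_t,
               peak_p_uncorrected = stats::pt(abs(peak_t), df,
                                              lower.tail = FALSE),
               peak_p_fwe = NA_real_, direction = direction,
               label = "unlabeled", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$k), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cluster_result", "data.frame")
  out
}

#' Permutation-based peak-level family-wise-error correction
#'
#' Freedman-Lane max-statistic scheme: gray-matter volume and dosage are
#' residualized on the nuisance covariates, the dosage residuals are
#' permuted, the voxel-wise t-map is rebuilt for each permutation, and the
#' global maximum |t| over the mask is recorded. Each cluster peak's
#' `peak_p_fwe` is the add-one tail probability of its |t| under that
#' max-|t| null, giving family-wise control over the whole mask.
#'
#' @param fit The `vbm_fit` the clusters came from.
#' @param clusters Output of [threshold_clusters()] on the same fit.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed; permutation r uses a deterministic substream of
#'   `(seed, r)`.
#' @return `clusters` with `peak_p_fwe` filled in, and the null max-|t|
#'   vector as attribute `max_t_null`.
#' @export
permutation_peak_fwe <- function(fit, clusters, n_perm, seed = 1L) {
  stopifnot(inherits(fit, "vbm_fit"))
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  pt <- fit$partialled
  n <- nrow(pt$Ytil)
  df <- fit$df
  max_t <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    set.seed(replicate_seed(seed, r))
    x <- pt$dtil[sample.int(n)]
    xt <- x - pt$Z %*% (pt$ZtZinv_Zt %*% x)
    xx <- sum(xt^2)
    beta <- as.numeric(crossprod(xt, pt$Ytil)) / xx
    rss <- pt$yy - beta^2 * xx
    rss[rss < 0] <- 0
    tv <- beta / sqrt(rss / df / xx)
    max_t[r] <- max(abs(tv))
  }
  if (nrow(clusters)) {
    clusters$peak_p_fwe <- vapply(clusters$peak_t, function(tpeak) {
      (1 + sum(max_t >= abs(tpeak))) / (1 + n_perm)
    }, numeric(1))
  }
  attr(clusters, "max_t_null") <- max_t
  clusters
}

#' Annotate a world-mm peak coordinate against a label volume
#'
#' Maps the coordinate through the label volume's inverse affine with
#' nearest-voxel rounding. Label value 0 and coordinates outside the label
#' grid return "unlabeled" (the latter with attribute
#' `out_of_field = TRUE`).
#'
#' @param peak_mni Numeric length-3 world coordinate (mm).
#' @param label_volume Integer 3D array of region labels.
#' @param affine 4x4 grid-to-world affine of the label volume.
#' @param lut Lookup `data.frame` with columns `value`, `label`.
#' @return The label string.
#' @export
label_peak <- function(peak_mni, label_volume, affine, lut) {
  ijk <- round(solve(affine, c(peak_mni, 1))[1:3])
  shape <- dim(label_volume)
  if (any(ijk < 0) || any(ijk > shape - 1L)) {
    return(structure("unlabeled", out_of_field = TRUE))
  }
  val <- label_volume[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
  if (is.na(val) || val == 0) return("unlabeled")
  hit <- lut$label[match(val, lut$value)]
  if (is.na(hit)) "unlabeled" else hit
}

#' One-stop voxel-wise scan for one SNP
#'
#' Fits the GLM, thresholds clusters in the requested direction(s), applies
#' permutation peak-FWE, and optionally labels the peaks against an atlas
#' volume.
#'
#' @param cohort An `imaging_cohort`.
#' @param dosage Dosage vector (defaults to the cohort's).
#' @param direction `"positive"`, `"negative"` or `"both"`.
#' @param p_cluster_forming,k_min,connectivity See
#'   [threshold_clusters()].
#' @param n_perm,seed See [permutation_peak_fwe()].
#' @param atlas Optional list with `volume`, `affine`, `lut` for peak
#'   labeling.
#' @return A `cluster_result` data.frame covering the requested
#'   direction(s).
#' @export
vbm_scan <- function(cohort, dosage = NULL, direction = "both",
                     p_cluster_forming = 0.001, k_min = 11,
                     connectivity = 18, n_perm = 1000, seed = 1L,
                     atlas = NULL) {
  fit <- fit_voxelwise_glm(cohort, dosage)
  dirs <- if (direction == "both") c("positive", "negative") else direction
  out <- lapply(dirs, function(d) {
    cl <- threshold_clusters(fit, direction = d,
                             p_cluster_forming = p_cluster_forming,
                             k_min = k_min, connectivity = connectivity)
    permutation_peak_fwe(fit, cl, n_perm = n_perm, seed = seed)
  })
  out <- do.call(rbind, out)
  if (!is.null(atlas) && nrow(out)) {
    out$label <- vapply(seq_len(nrow(out)), function(i) {
      as.character(label_peak(c(out$peak_x[i], out$peak_y[i], out$peak_z[i]),
                              atlas$volume, atlas$affine, atlas$lut))
    }, character(1))
  }
  rownames(out) <- NULL
  class(out) <- c("cluster_result", "data.frame")
  out
}
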