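# Independent brute-force oracles used to validate the implementation.

# Step-up FDR adjustment straight from the definition, O(n^2):
# adj(p_i) = min over sorted positions j with p_(j) >= p_i of
#            min(1, m * p_(j) / j).
bh_oracle <- function(p, m = length(p)) {
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-300)
    min(pmin(1, m * sp[js] / js))
  }, numeric(1))
}

# Flood-fill connected-component labeling with an explicit stack,
# independent of the graph-based implementation.
flood_fill_components <- function(supra, connectivity) {
  shape <- dim(supra)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  nz <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- as.matrix(off[switch(as.character(connectivity),
                              "6" = nz == 1, "18" = nz <= 2,
                              "26" = rep(TRUE, nrow(off))), ])
  lab <- array(0L, dim = shape)
  next_lab <- 0L
  todo <- which(supra, arr.ind = TRUE)
  for (s in seq_len(nrow(todo))) {
    start <- todo[s, ]
    if (lab[start[1], start[2], start[3]] != 0L) next
    next_lab <- next_lab + 1L
    stack <- list(start)
    lab[start[1], start[2], start[3]] <- next_lab
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(off))) {
        nb <- cur + off[r, ]
        if (any(nb < 1) || any(nb > shape)) next
        if (supra[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- next_lab
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# Partition sizes of a labeling, invariant to label numbering.
component_size_multiset <- function(lab) {
  sort(as.integer(table(lab[lab > 0L])))
}

# Check two labelings define the same partition of the foreground voxels.
same_partition <- function(a, b) {
  fa <- which(a > 0L); fb <- which(b > 0L)
  if (!identical(fa, fb)) return(FALSE)
  ta <- as.integer(factor(a[fa], levels = unique(a[fa])))
  tb <- as.integer(factor(b[fb], levels = unique(b[fb])))
  all(tapply(tb, ta, function(x) length(unique(x))) == 1L) &&
    all(tapply(ta, tb, function(x) length(unique(x))) == 1L)
}

# OLS t-statistics via an explicit normal-equations solve.
ols_t_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  sigma2 <- sum(r^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(XtX)))
  unname(as.numeric(b) / se)
}

# Write a small canonical sumstats table to a temp file.
write_sumstats_fixture <- function(df, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# Printed-value comparison at 3 significant figures, accepting either
# round-to-nearest or truncation as the printing convention.
matches_printed_3sf <- function(x, printed) {
  e <- floor(log10(x)) - 2
  rounded <- signif(x, 3)
  truncated <- floor(x / 10^e) * 10^e
  abs(rounded - printed) < 1e-12 * abs(printed) |
    abs(truncated - printed) < 1e-12 * abs(printed)
}
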