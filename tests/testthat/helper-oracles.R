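# Independent brute-force oracles. These deliberately avoid the package's
# production code paths: plain loops and naive formulas only.

# Naive per-cell maximum scan matching rasterize_dsm's binning contract.
oracle_dsm_cell_max <- function(m, nx, ny, ix, iy) {
  vals <- matrix(NA_real_, nx, ny)
  for (k in seq_len(nrow(m))) {
    vals[ix[k], iy[k]] <- max(vals[ix[k], iy[k]], m[k, 3], na.rm = TRUE)
  }
  vals
}

# Double-loop bin counting for the density matrix.
oracle_bin_counts <- function(u, v, u0, v0, eps, nu, nv) {
  counts <- matrix(0L, nu, nv)
  for (k in seq_along(u)) {
    iu <- min(max(floor((u[k] - u0) / eps), 0) + 1L, nu)
    iv <- min(max(floor((v[k] - v0) / eps), 0) + 1L, nv)
    counts[iu, iv] <- counts[iu, iv] + 1L
  }
  counts
}

# Orthogonal plane-fit objective (normalized squared residuals) for a unit
# normal through the centroid.
oracle_plane_objective <- function(m, normal) {
  ctr <- colMeans(m)
  d <- sweep(m, 2, ctr) %*% normal
  sum(d^2) / sum(normal^2)
}

# Coarse spherical grid search over unit normals, then local refinement.
oracle_plane_search <- function(m, coarse = 0.02, refine_tol = 1e-10) {
  best <- NULL; best_obj <- Inf
  for (theta in seq(0, pi, by = coarse)) {
    for (phi in seq(0, pi, by = coarse)) {
      nrm <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      obj <- oracle_plane_objective(m, nrm)
      if (obj < best_obj) { best_obj <- obj; best <- c(theta, phi) }
    }
  }
  opt <- optim(best, function(a) {
    nrm <- c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
    oracle_plane_objective(m, nrm)
  }, method = "Nelder-Mead",
  control = list(reltol = refine_tol, maxit = 5000))
  opt$value
}

# All-pairs diameter scan.
oracle_diameter <- function(xy) {
  best <- 0
  for (i in seq_len(nrow(xy) - 1)) {
    for (k in (i + 1):nrow(xy)) {
      d <- sqrt(sum((xy[i, ] - xy[k, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

# Sorted-order linear-interpolation percentile.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Naive-loop metrics.
oracle_mae <- function(c_, e_) {
  s <- 0
  for (i in seq_along(c_)) s <- s + abs(c_[i] - e_[i])
  s / length(c_)
}
oracle_rmse <- function(c_, e_) {
  s <- 0
  for (i in seq_along(c_)) s <- s + (c_[i] - e_[i])^2
  sqrt(s / length(c_))
}
oracle_r2_ratio <- function(c_, e_) {
  hb <- mean(c_)
  num <- 0; den <- 0
  for (i in seq_along(c_)) {
    num <- num + (e_[i] - hb)^2
    den <- den + (c_[i] - hb)^2
  }
  num / den
}
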