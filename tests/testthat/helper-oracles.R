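# Shared oracles and fixture builders.

# Monte-Carlo estimate of a facet-represented hull's volume: uniform points
# in the cloud's bounding box, inside iff every facet inequality holds.
# Chunked so the sample x facet product stays small.
mc_hull_volume <- function(cloud, n = 100000L, seed = 1L, chunk = 2000L) {
  hull <- saltFCE:::convex_hull3d(cloud)
  p <- cloud$points
  lo <- apply(p, 2, min); hi <- apply(p, 2, max)
  box_vol <- prod(hi - lo)
  set.seed(seed)
  n_inside <- 0L
  done <- 0L
  tN <- t(hull$normals)
  while (done < n) {
    m <- min(chunk, n - done)
    s <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
               runif(m, lo[3], hi[3]))
    viol <- (s %*% tN) > matrix(hull$offsets, m, ncol(tN), byrow = TRUE)
    n_inside <- n_inside + sum(rowSums(viol) == 0L)
    done <- done + m
  }
  frac <- n_inside / n
  list(volume = frac * box_vol,
       se = box_vol * sqrt(frac * (1 - frac) / n),
       exact = hull$volume)
}

# Labelled outlier fixture: dense unit cube + far-away planted outliers.
unit_cube_with_outliers <- function(n_dense = 1000L, n_out = 10L,
                                    dist = 100, seed = 7L) {
  set.seed(seed)
  dense <- matrix(runif(3 * n_dense), ncol = 3)
  dirs <- matrix(rnorm(3 * n_out), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  outs <- 0.5 + dirs * dist
  list(cloud = point_cloud(rbind(dense, outs)),
       outlier_idx = n_dense + seq_len(n_out))
}

# Brute-force kNN mean-distance statistic (R double loop via dist()).
brute_knn_stat <- function(pts, k) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  unname(apply(d, 1, function(r) mean(sort(r)[seq_len(k)])))
}
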