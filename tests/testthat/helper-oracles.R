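# Independent oracles used by the module and acceptance suites.  Each is a
# direct, brute-force restatement of the contract it checks and never calls
# the implementation under test.

# Pearson chi-square, direct textbook formula.
chisq_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Dense sampling of every polyline; `resolution` (max sample spacing, m)
# bounds the oracle's own discretization error.
dense_road_sampler <- function(roads, k = 600) {
  pts <- list(); seg <- list(); max_step <- 0
  for (i in seq_len(nrow(roads))) {
    m <- roads$coords[[i]]
    for (e in seq_len(nrow(m) - 1)) {
      t <- seq(0, 1, length.out = k)
      p <- cbind(lon = m[e, "lon"] + t * (m[e + 1, "lon"] - m[e, "lon"]),
                 lat = m[e, "lat"] + t * (m[e + 1, "lat"] - m[e, "lat"]))
      pts[[length(pts) + 1]] <- p
      seg[[length(seg) + 1]] <- rep(i, nrow(p))
      max_step <- max(max_step, geosphere::distHaversine(p[1, ], p[2, ]))
    }
  }
  list(pts = do.call(rbind, pts), seg = unlist(seg), resolution = max_step)
}

dense_road_oracle <- function(lat, lon, sampler) {
  d_all <- geosphere::distHaversine(c(lon, lat), sampler$pts)
  d <- as.numeric(tapply(d_all, sampler$seg, min))
  list(index = which.min(d), dist = d)
}

# Empirical quantiles by sorted-order index interpolation.
quantile_oracle <- function(v, probs) {
  s <- sort(v); n <- length(s)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, 0)
}

random_segments <- function(n, lat_range, lon_range) {
  lapply(seq_len(n), function(i) {
    nv <- sample(2:4, 1)
    list(id = sprintf("s%03d", i),
         coords = cbind(lon = runif(nv, lon_range[1], lon_range[2]),
                        lat = runif(nv, lat_range[1], lat_range[2])))
  })
}

make_roads <- function(segs) {
  dplyr::bind_rows(lapply(segs, function(s) {
    tibble::tibble(segment_id = s$id, coords = list(s$coords),
                   road_class = s$class %||% "residential")
  }))
}
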