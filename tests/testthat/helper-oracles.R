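# Independent oracles used across the suite. These deliberately use the
# most naive correct formulation (dense sampling, double loops) so they do
# not share code paths with the package implementation.

# ellipse contour with semi-axes a, b as a polygon
ellipse_poly <- function(a, b, n = 4096, rot = 0, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  p <- cbind(a * cos(th), b * sin(th))
  R <- rbind(c(cos(rot), -sin(rot)), c(sin(rot), cos(rot)))
  sweep(p %*% t(R), 2, center, "+")
}

# ellipse perimeter by dense chord summation (independent of integrate())
ellipse_perimeter_oracle <- function(a, b, n = 2e5) {
  p <- ellipse_poly(a, b, n)
  sum(sqrt(rowSums((p[c(2:n, 1), ] - p)^2)))
}

# minimum support width by brute-force projection over many directions;
# the candidate set includes every edge direction's normal (the width
# minimum of a convex region is attained flush with an edge, where the
# width function has a kink a uniform grid alone straddles)
brute_min_width <- function(poly, n_dir = 3600) {
  th <- pi * (seq_len(n_dir) - 1) / n_dir
  e <- poly[c(2:nrow(poly), 1), ] - poly
  th <- c(th, atan2(e[, 1], -e[, 2]))
  w <- Inf
  for (t in th) {
    d <- poly[, 1] * cos(t) + poly[, 2] * sin(t)
    w <- min(w, max(d) - min(d))
  }
  w
}

# random convex polygon (convex hull of random points), seeded by caller
random_convex_poly <- function(k = 12, scale = 10) {
  p <- matrix(stats::rnorm(2 * 4 * k, sd = scale), ncol = 2)
  h <- grDevices::chull(p)
  p[h, , drop = FALSE]
}

# ICC(2,1) mean squares by explicit double loops
icc_bruteforce <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + g)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

random_unit_vec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# a random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
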