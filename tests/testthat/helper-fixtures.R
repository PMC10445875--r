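# geometric fixtures built in code

# regular n-gon approximating a circle of diameter d (um), centred at (cx, cy)
circle_poly <- function(d = 20, n = 256, cx = 0, cy = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cx + d / 2 * cos(phi), cy + d / 2 * sin(phi))
}

rect_poly <- function(l = 100, w = 50) {
  cbind(c(0, l, l, 0), c(0, 0, w, w))
}

ellipse_poly <- function(a = 50, b = 25, n = 256) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(a * cos(phi), b * sin(phi))
}

# 4-pointed star: outer radius R on the axes, inner radius r on the diagonals;
# its convex hull is the square through the outer points, so both perimeters
# have closed forms
star_poly <- function(R = 10, r = 3) {
  ang <- pi / 4 * (0:7)
  rad <- rep(c(R, r), 4)
  cbind(rad * cos(ang), rad * sin(ang))
}

star_convexity_closed_form <- function(R = 10, r = 3) {
  edge <- sqrt(R^2 + r^2 - 2 * R * r * cos(pi / 4))
  (4 * R * sqrt(2)) / (8 * edge)
}

rotate_poly <- function(poly, theta, dx = 0, dy = 0) {
  cs <- cos(theta); sn <- sin(theta)
  cbind(poly[, 1] * cs - poly[, 2] * sn + dx,
        poly[, 1] * sn + poly[, 2] * cs + dy)
}

# independent convex hull (Andrew monotone chain) + perimeter, used as an
# oracle against the package's chull-based convexity
oracle_hull_perimeter <- function(poly) {
  p <- unique(poly[order(poly[, 1], poly[, 2]), , drop = FALSE])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(pts) {
    h <- list()
    for (i in seq_len(nrow(pts))) {
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], pts[i, ]) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- pts[i, ]
    }
    h
  }
  lower <- build(p)
  upper <- build(p[nrow(p):1, , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), , drop = FALSE])^2)))
}

# brute-force quantile oracle: refine each bin into `k` log-spaced sub-bins
# (volume apportioned by log width) and read the quantile off the dense
# cumulative curve
oracle_quantile <- function(p, prob, k = 100) {
  edges <- p$bin_edges
  fine <- unlist(lapply(seq_along(p$volume_pct), function(i) {
    exp(seq(log(edges[i]), log(edges[i + 1]), length.out = k + 1))[-(k + 1)]
  }))
  fine <- c(fine, edges[length(edges)])
  vol <- rep(p$volume_pct / k, each = k)
  cum <- c(0, cumsum(vol)) / 100
  exp(stats::approx(cum, log(fine), xout = prob,
                    ties = list("ordered", min))$y)
}

expect_psd_valid <- function(p) {
  expect_s3_class(p, "psd")
  expect_equal(sum(p$volume_pct), 100, tolerance = 1e-9)
  expect_true(all(p$volume_pct >= 0))
  expect_true(all(diff(p$bin_edges) > 0))
}
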