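# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately use formulations different from the package internals
# (explicit loops, solve() on 2x2 systems, direct ANOVA sums).

# lat-long sphere mesh
sphere_mesh <- function(radius = 50, center = c(0, 0, 0),
                        n_theta = 128L, n_psi = 64L) {
  phi <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  psi <- pi * seq_len(n_psi - 1) / n_psi
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  verts <- matrix(0, (n_psi - 1) * n_theta + 2, 3)
  for (i in seq_len(n_psi - 1)) {
    rows <- (i - 1L) * n_theta + seq_len(n_theta)
    verts[rows, ] <- cbind(radius * sin(psi[i]) * cos(phi),
                           radius * sin(psi[i]) * sin(phi),
                           radius * cos(psi[i]))
  }
  top <- (n_psi - 1L) * n_theta + 1L; bot <- top + 1L
  verts[top, ] <- c(0, 0, radius); verts[bot, ] <- c(0, 0, -radius)
  faces <- list(cbind(top, vid(1, seq_len(n_theta)), vid(1, seq_len(n_theta) + 1L)))
  for (i in seq_len(n_psi - 2)) {
    j <- seq_len(n_theta)
    faces[[i + 1]] <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                            cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }
  faces[[n_psi]] <- cbind(bot, vid(n_psi - 1L, seq_len(n_theta) + 1L),
                          vid(n_psi - 1L, seq_len(n_theta)))
  tri_mesh(sweep(verts, 2, center, "+"), do.call(rbind, faces))
}

# axis-aligned cube as 12 triangles
cube_mesh <- function(side = 60, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6)    # x+
  )
  tri_mesh(v, f)
}

regular_polygon <- function(r = 1, n = 256, center = c(0, 0)) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

ellipse_polygon <- function(a = 2, b = 1, n = 256, center = c(0, 0)) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + a * cos(t), center[2] + b * sin(t))
}

# independent ray-casting oracle: per-ray loop, solve() on the 2x2 system
raycast_oracle <- function(poly, center, dirs) {
  n <- nrow(poly)
  vapply(seq_len(nrow(dirs)), function(k) {
    d <- dirs[k, ]
    best <- -Inf
    for (i in seq_len(n)) {
      p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
      A <- cbind(d, p - q)
      if (abs(det(A)) < 1e-14) next
      ts <- solve(A, p - center)
      if (ts[1] > 1e-9 && ts[2] >= 0 && ts[2] < 1) best <- max(best, ts[1])
    }
    best
  }, 0)
}

# direct two-way ANOVA sums ICC(2,1) oracle (explicit loops)
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x); m <- mean(x)
  ssr <- ssc <- sse <- 0
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  for (i in seq_len(n)) ssr <- ssr + k * (rm_[i] - m)^2
  for (j in seq_len(k)) ssc <- ssc + n * (cm_[j] - m)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - rm_[i] - cm_[j] + m)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# unit-degree relative curve from a radius function of theta (degrees)
toy_curve <- function(radius_fun) {
  r <- radius_fun(0:359)
  normalize_curve(r)
}

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
}

rot3z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
}

rot3x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
}
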