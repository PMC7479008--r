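plane_z <- function(z) structure(
  list(origin = c(0, 0, z), normal = c(0, 0, 1),
       u_axis = c(1, 0, 0), v_axis = c(0, 1, 0)),
  class = "cranio_plane")

test_that("slicing a sphere gives the Pythagorean circle", {
  m <- sphere_mesh(radius = 50)
  ol <- slice_surface(m, plane_z(30))
  area <- abs(craniocurve:::.polygon_area(ol$vertices))
  expect_lt(abs(area - pi * 40^2) / (pi * 40^2), 0.01)
  rad <- sqrt(rowSums(ol$vertices^2))
  expect_lt(max(abs(rad - 40)) / 40, 0.01)
  # vertices lie on the plane and are ordered counter-clockwise
  expect_gt(craniocurve:::.polygon_area(ol$vertices), 0)
})

test_that("a plane missing the mesh raises an empty-slice error", {
  m <- sphere_mesh(radius = 50)
  expect_error(slice_surface(m, plane_z(60)), class = "cranio_empty_slice")
})

test_that("slicing a cube gives the square cross-section", {
  m <- cube_mesh(side = 60)
  ol <- slice_surface(m, plane_z(0))
  area <- abs(craniocurve:::.polygon_area(ol$vertices))
  expect_equal(area, 3600, tolerance = 1e-9)
  expect_equal(max(abs(ol$vertices)), 30, tolerance = 1e-9)
})

test_that("sphere slice area converges with mesh resolution", {
  errs <- vapply(c(32, 64, 128), function(nt) {
    ol <- slice_surface(sphere_mesh(50, n_theta = nt, n_psi = nt / 2), plane_z(30))
    abs(abs(craniocurve:::.polygon_area(ol$vertices)) - pi * 1600) / (pi * 1600)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("the largest loop is selected when the slice cuts several components", {
  big <- sphere_mesh(radius = 50)
  small <- sphere_mesh(radius = 10, center = c(90, 0, 0))
  both <- tri_mesh(rbind(big$vertices, small$vertices),
                   rbind(big$faces, small$faces + nrow(big$vertices)))
  ol <- slice_surface(both, plane_z(0))
  expect_lt(max(sqrt(rowSums(ol$vertices^2))), 51)
})

test_that("area centroid uses the region, not the vertex cloud", {
  sq <- rbind(c(-30, -30), c(30, -30), c(30, 30), c(-30, 30))
  expect_equal(area_centroid(outline(sq)), c(0, 0), tolerance = 1e-12)
  tri <- rbind(c(0, 0), c(6, 0), c(0, 6))
  expect_equal(area_centroid(outline(tri)), c(2, 2), tolerance = 1e-12)
  # one edge subdivided into 100 collinear pieces: vertex mean would move
  xs <- seq(-30, 30, length.out = 101)
  dense <- rbind(cbind(xs, -30), c(30, 30), c(-30, 30))
  expect_equal(area_centroid(outline(dense)), c(0, 0), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(colMeans(dense), c(0, 0), tolerance = 0.1)))
})

test_that("degenerate outlines are rejected", {
  expect_error(outline(rbind(c(0, 0), c(1, 1))), class = "cranio_degenerate_outline")
  expect_error(outline(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "cranio_degenerate_outline")
})

test_that("the occipital start point is the posterior bisector intersection", {
  circ <- outline(regular_polygon(r = 80, n = 720))
  fr <- locate_start(circ, ex_uv = rbind(c(60, 40), c(60, -40)))
  # anterior is +u here; start is the posterior point on the u-axis
  expect_equal(fr$start_point, c(-80, 0), tolerance = 1e-3)
  expect_equal(fr$start_direction, c(-1, 0), tolerance = 1e-3)
  # swapping left and right ex flips the sweep orientation, not the start
  fr2 <- locate_start(circ, ex_uv = rbind(c(60, -40), c(60, 40)))
  expect_equal(fr2$start_point, fr$start_point, tolerance = 1e-9)
  expect_identical(fr2$right_first_sign, -fr$right_first_sign)
})

test_that("start point on an ellipse matches a brute-force line intersection oracle", {
  ell <- outline(ellipse_polygon(a = 100, b = 80, n = 1024))
  ex_uv <- rbind(c(55, 40), c(55, -40))
  fr <- locate_start(ell, ex_uv = ex_uv)
  # oracle: intersect the bisector line with every edge via solve()
  mid <- colMeans(ex_uv)
  bis <- c(55, -40) - c(55, 40); bis <- c(-bis[2], bis[1]) / sqrt(sum(bis^2))
  v <- ell$vertices; n <- nrow(v); hits <- NULL
  for (i in seq_len(n)) {
    p <- v[i, ]; q <- v[if (i == n) 1 else i + 1, ]
    A <- cbind(bis, p - q)
    if (abs(det(A)) < 1e-14) next
    ts <- solve(A, p - mid)
    if (ts[2] >= 0 && ts[2] < 1) hits <- rbind(hits, mid + ts[1] * bis)
  }
  post <- hits[hits[, 1] < mid[1], , drop = FALSE]
  oracle <- post[which.max(rowSums(sweep(post, 2, mid)^2)), ]
  expect_equal(fr$start_point, oracle, tolerance = 1e-9)
  # the start lies on the polygon boundary
  seg_d <- min(vapply(seq_len(n), function(i) {
    p <- v[i, ]; q <- v[if (i == n) 1 else i + 1, ]
    e <- q - p; t <- sum((fr$start_point - p) * e) / sum(e^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p + t * e - fr$start_point)^2))
  }, 0))
  expect_lt(seg_d, 1e-6)
})

test_that("locate_start is invariant to in-plane rotation of the configuration", {
  ell <- ellipse_polygon(a = 100, b = 80, n = 512)
  ex_uv <- rbind(c(55, 38), c(55, -42))  # slightly asymmetric
  fr <- locate_start(outline(ell), ex_uv = ex_uv)
  R <- rot2(37.3)
  fr2 <- locate_start(outline(ell %*% t(R)), ex_uv = ex_uv %*% t(R))
  expect_equal(fr2$start_point, as.vector(R %*% fr$start_point), tolerance = 1e-6)
  expect_identical(fr2$right_first_sign, fr$right_first_sign)
})

test_that("outline CSV round-trips", {
  ol <- outline(ellipse_polygon(a = 90, b = 70, n = 128))
  f <- withr::local_tempfile(fileext = ".csv")
  write_outline_csv(ol, f)
  ol2 <- read_outline_csv(f)
  expect_equal(ol2$vertices, ol$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
})
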