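# Triangulation, affine homographies, barycentric points, incenters,
# epipolar clipping, patch NCC.

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  tri3 <- delaunay_triangles(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(nrow(tri3), 1)
  sq <- delaunay_triangles(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(sq), 2)
  expect_error(delaunay_triangles(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  for (seed in 1:3) {
    set.seed(seed)
    pts <- cbind(runif(30, 0, 100), runif(30, 0, 80))
    tr <- delaunay_triangles(pts)
    for (k in seq_len(nrow(tr))) {
      v <- pts[tr[k, ], ]
      # circumcenter via perpendicular bisectors
      A <- 2 * rbind(v[2, ] - v[1, ], v[3, ] - v[1, ])
      b <- c(sum(v[2, ]^2) - sum(v[1, ]^2), sum(v[3, ]^2) - sum(v[1, ]^2))
      cc <- solve(A, b)
      r2 <- sum((v[1, ] - cc)^2)
      d2 <- (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2
      inside <- which(d2 < r2 - 1e-7)
      expect_true(all(inside %in% tr[k, ]))
    }
  }
})

test_that("affine estimation is exact and matches a 6x6 linear solve", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(affine_from_triangles(tri, tri), diag(3))
  H <- affine_from_triangles(tri, rbind(c(2, 3), c(3, 3), c(2, 4)))
  expect_equal(H[1:2, 1:2], diag(2))
  expect_equal(H[1:2, 3], c(2, 3))
  expect_error(affine_from_triangles(rbind(c(0, 0), c(1, 1), c(2, 2)), tri),
               "degenerate")
  # oracle: solve the 6x6 system for the affine coefficients directly
  set.seed(8)
  for (i in 1:200) {
    src <- matrix(runif(6, 0, 100), 3, 2)
    dst <- matrix(runif(6, 0, 100), 3, 2)
    if (abs(hpft:::tri_area2(src)) < 40) next   # exclude sliver triangles
    A6 <- matrix(0, 6, 6)
    for (r in 1:3) {
      A6[2 * r - 1, 1:3] <- c(src[r, ], 1)
      A6[2 * r, 4:6] <- c(src[r, ], 1)
    }
    coef <- solve(A6, as.numeric(t(dst)))
    Ho <- rbind(coef[1:3], coef[4:6], c(0, 0, 1))
    expect_lt(max(abs(affine_from_triangles(src, dst) - Ho)), 1e-9)
  }
})

test_that("barycentric points obey the convex-combination contract", {
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  expect_equal(barycentric_point(tri, 1 / 3, 1 / 3), colMeans(tri))
  eps <- 1e-9
  expect_equal(barycentric_point(tri, 1 - 2 * eps, eps), tri[1, ],
               tolerance = 1e-6)
  expect_error(barycentric_point(tri, 0.7, 0.5), "s \\+ t < 1")
  # interior half-plane oracle
  set.seed(9)
  for (i in 1:50) {
    tr <- matrix(runif(6, 0, 50), 3, 2)
    if (abs(hpft:::tri_area2(tr)) < 1) next
    s <- runif(1, 0.05, 0.9); t <- runif(1, 0.05, 0.95 - s)
    p <- barycentric_point(tr, s, t)
    sgn <- sign(hpft:::tri_area2(tr))
    for (e in 1:3) {
      a <- tr[e, ]; b <- tr[e %% 3 + 1, ]
      cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      expect_gt(sgn * cr, 0)
    }
  }
})

test_that("incircle centers match the closed form and stay interior", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(incircle_center(eq), colMeans(eq), tolerance = 1e-12)
  # sides 5, 3, 4 opposite the vertices give (a A + b B + c C)/(a + b + c)
  expect_equal(incircle_center(rbind(c(0, 0), c(4, 0), c(0, 3))), c(1, 1))
  set.seed(10)
  for (i in 1:20) {
    tr <- matrix(runif(6, 0, 50), 3, 2)
    if (abs(hpft:::tri_area2(tr)) < 1) next
    ic <- incircle_center(tr)
    w <- hpft:::barycentric_weights(tr, ic[1], ic[2])
    expect_true(all(w > 0))
  }
  expect_error(incircle_center(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("epipolar segments agree with a dense line-sampling oracle", {
  tri <- rbind(c(10, 10), c(50, 12), c(28, 45))
  # a horizontal line through the interior: endpoints on the boundary
  seg <- hpft:::clip_line_to_triangle(c(0, 1, -20), tri)
  expect_false(is.null(seg))
  for (r in 1:2) {
    p <- seg[r, ]
    edge_d <- sapply(1:3, function(e) {
      a <- tri[e, ]; b <- tri[e %% 3 + 1, ]
      t <- clamp(sum((p - a) * (b - a)) / sum((b - a)^2), 0, 1)
      sqrt(sum((a + t * (b - a) - p)^2))
    })
    expect_lt(min(edge_d), 1e-6)
  }
  expect_null(hpft:::clip_line_to_triangle(c(0, 1, -200), tri))
  set.seed(11)
  for (i in 1:40) {
    tr <- matrix(runif(6, 0, 100), 3, 2)
    if (abs(hpft:::tri_area2(tr)) < 10) next
    th <- runif(1, 0, pi)
    l <- c(cos(th), sin(th), -runif(1, 0, 100))
    got <- hpft:::clip_line_to_triangle(l, tr)
    # oracle: march along the line and test membership densely
    d <- c(-l[2], l[1]); p0 <- c(-l[1] * l[3], -l[2] * l[3])
    ts <- seq(-200, 200, length.out = 4001)
    pts <- cbind(p0[1] + ts * d[1], p0[2] + ts * d[2])
    w <- hpft:::barycentric_weights(tr, pts[, 1], pts[, 2])
    inside <- w[, 1] >= 0 & w[, 2] >= 0 & w[, 3] >= 0
    if (!any(inside)) {
      if (!is.null(got)) {
        expect_lt(sqrt(sum((got[1, ] - got[2, ])^2)), 0.5)
      }
    } else {
      expect_false(is.null(got))
      t_in <- range(ts[inside])
      got_t <- sort(c(sum((got[1, ] - p0) * d), sum((got[2, ] - p0) * d)))
      expect_lt(max(abs(got_t - t_in)), 0.5)
    }
  }
})

test_that("patch NCC validates identical patches and rejects flat ones", {
  tex <- fx_texture(128, 96, 12)
  tri <- rbind(c(20, 20), c(80, 25), c(45, 70))
  expect_equal(patch_ncc(tex, tex, tri, diag(3)), 1, tolerance = 1e-9)
  expect_equal(patch_ncc(tex, 255 - tex, tri, diag(3)), -1, tolerance = 1e-9)
  expect_true(is.na(patch_ncc(tex, matrix(7, 96, 128), tri, diag(3))))
  tiny <- rbind(c(10, 10), c(13, 10), c(10, 13))
  expect_true(is.na(patch_ncc(tex, tex, tiny, diag(3))))
})

test_that("patch NCC equals an explicit pixel-loop oracle", {
  tex <- fx_texture(128, 96, 12)
  sc <- warp_scene(tex, fx_affine_H(), noise_sigma = 2, seed = 4)
  tri <- rbind(c(25, 20), c(85, 30), c(50, 70))
  H <- fx_affine_H()
  got <- patch_ncc(sc$reference, sc$target, tri, H)
  a <- c(); b <- c()
  for (yy in 0:95) {
    for (xx in 0:127) {
      w <- hpft:::barycentric_weights(tri, xx, yy)
      if (all(w > 1e-9)) {
        q <- H %*% c(xx, yy, 1)
        v <- oracle_bilinear(sc$target, q[1] / q[3], q[2] / q[3])
        if (!is.na(v)) {
          a <- c(a, sc$reference[yy + 1, xx + 1]); b <- c(b, v)
        }
      }
    }
  }
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("independent textures decorrelate", {
  t1 <- fx_texture(128, 96, 21)
  difs <- sapply(1:100, function(s) {
    t2 <- generate_textured_plane(128, 96, 100 + s)
    tri <- rbind(c(15, 15), c(100, 25), c(50, 80))
    patch_ncc(t1, t2, tri, diag(3))
  })
  expect_gte(mean(abs(difs) < 0.3), 0.99)
})
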