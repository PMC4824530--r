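# Synthetic-scene generator: determinism, texture contrast, warp ground
# truth, piecewise continuity, specular blobs.

test_that("texture generation is seeded, contrasty, and bounds-checked", {
  t1 <- generate_textured_plane(560, 480, seed = 1)
  expect_identical(t1, generate_textured_plane(560, 480, seed = 1))
  expect_false(identical(t1, generate_textured_plane(560, 480, seed = 2)))
  expect_true(min(t1) >= 0 && max(t1) <= 255)
  # every 64x64 tile keeps enough contrast for dense feature detection
  stds <- c()
  for (r in seq(1, 480 - 63, 64)) {
    for (c in seq(1, 560 - 63, 64)) {
      stds <- c(stds, stats::sd(t1[r:(r + 63), c:(c + 63)]))
    }
  }
  expect_true(min(stds) >= 10)
  expect_error(generate_textured_plane(32, 480), "at least 64")
})

test_that("warp_scene reproduces the homography as ground truth", {
  tex <- fx_texture(200, 160, 1)
  sc <- warp_scene(tex, diag(3), noise_sigma = 0, seed = 1)
  expect_identical(sc$target, sc$reference)
  H <- rbind(c(1, 0, 10), c(0, 1, 0), c(0, 0, 1))
  sc2 <- warp_scene(tex, H, noise_sigma = 0, seed = 1)
  # truth_map[x, y] = (x + 10, y) wherever visible
  expect_equal(sc2$truth_map[21, 31, 1], 30 + 10)
  expect_equal(sc2$truth_map[21, 31, 2], 20)
  expect_error(warp_scene(tex, matrix(0, 3, 3)), "invertible")
})

test_that("warped target agrees with an independent resampling oracle", {
  tex <- fx_texture(200, 160, 2)
  H <- fx_affine_H()
  sc <- warp_scene(tex, H, noise_sigma = 0, seed = 1)
  Hi <- solve(H)
  set.seed(42)
  xs <- round(runif(60, 40, 160)); ys <- round(runif(60, 30, 130))
  src <- cbind(xs, ys, 1) %*% t(Hi)
  v <- oracle_bilinear(tex, src[, 1] / src[, 3], src[, 2] / src[, 3])
  got <- sc$target[cbind(ys + 1, xs + 1)]
  ok <- !is.na(v)
  expect_true(mean(abs(got[ok] - v[ok])) < 1)   # rounding is the only error
})

test_that("piecewise scenes are continuous with exact per-patch truth", {
  ps <- generate_piecewise_planar_scene(200, 160, n_patches = 2, seed = 3)
  expect_length(ps$patch_truth, 2)
  expect_identical(generate_piecewise_planar_scene(200, 160, 2, seed = 3)$target,
                   ps$target)
  H1 <- ps$patch_truth[[1]]$H; H2 <- ps$patch_truth[[2]]$H
  expect_false(isTRUE(all.equal(H1, H2)))
  # the two affines agree exactly on the shared edge (continuity), so the
  # truth map is C0 with a derivative discontinuity only across that edge
  shared <- NULL
  p1 <- ps$patch_truth[[1]]$polygon; p2 <- ps$patch_truth[[2]]$polygon
  for (i in 1:3) {
    for (j in 1:3) {
      if (all(abs(p1[i, ] - p2[j, ]) < 1e-9)) shared <- rbind(shared, p1[i, ])
    }
  }
  expect_equal(nrow(shared), 2)
  for (t in seq(0, 1, 0.25)) {
    pt <- shared[1, ] + t * (shared[2, ] - shared[1, ])
    q1 <- H1 %*% c(pt, 1); q2 <- H2 %*% c(pt, 1)
    expect_lt(max(abs(q1 - q2)), 1e-9)
  }
  # off the edge the maps differ
  ctr1 <- colMeans(p1)
  expect_gt(max(abs(H1 %*% c(ctr1, 1) - H2 %*% c(ctr1, 1))), 1e-3)
  # single-region scene degenerates to one global affine
  one <- generate_piecewise_planar_scene(128, 96, n_patches = 1, seed = 4)
  expect_length(one$patch_truth, 1)
})

test_that("patch_truth matrices reproduce the dense truth map", {
  ps <- generate_piecewise_planar_scene(200, 160, n_patches = 6, seed = 9)
  expect_length(ps$patch_truth, 6)
  for (p in ps$patch_truth) {
    ctr <- round(colMeans(p$polygon))
    q <- p$H %*% c(ctr, 1)
    tm <- c(ps$truth_map[ctr[2] + 1, ctr[1] + 1, 1],
            ps$truth_map[ctr[2] + 1, ctr[1] + 1, 2])
    if (!anyNA(tm)) expect_lt(max(abs(q[1:2] - tm)), 1e-6)
    expect_identical(p$H[3, ], c(0, 0, 1))
  }
})

test_that("specular blobs are saturated, masked exactly, and seeded", {
  tex <- fx_texture(200, 160, 5)
  b0 <- add_specular_blobs(tex, 0, seed = 1)
  expect_identical(b0$image, tex)
  expect_equal(sum(b0$mask), 0)
  b5 <- add_specular_blobs(tex, 5, seed = 2)
  expect_gt(sum(b5$mask), 0)
  expect_true(all(b5$image[b5$mask] == 255))
  expect_identical(add_specular_blobs(tex, 5, seed = 2)$image, b5$image)
})

test_that("affine sequences carry exact cumulative truth", {
  sq <- generate_affine_sequence(4, 128, 96, seed = 6, noise_sigma = 0)
  expect_length(sq$frames, 4)
  expect_identical(sq$truth[[1]], diag(3))
  # frame 1 without noise is the base texture itself
  expect_identical(sq$frames[[1]], generate_textured_plane(128, 96, 6))
  # determinism
  sq2 <- generate_affine_sequence(4, 128, 96, seed = 6, noise_sigma = 0)
  expect_identical(sq$frames, sq2$frames)
})
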