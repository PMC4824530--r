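# Feature detection, the 32-element descriptor, distances, initial matching.

test_that("detection fails on untextured input and is seeded under budget", {
  expect_error(detect_features(matrix(100, 100, 100)), "untextured")
  f1 <- detect_features(fx_texture(240, 180, 7), budget = 200, seed = 1)
  f2 <- detect_features(fx_texture(240, 180, 7), budget = 200, seed = 1)
  expect_identical(f1, f2)
  expect_lte(nrow(f1$points), 200)
  expect_error(detect_features(fx_texture(240, 180, 7), budget = 2),
               "at least 4")
})

test_that("a study-sized textured plane yields hundreds of keypoints", {
  f <- fx_features_560()
  expect_gte(nrow(f$points), 200)
  expect_true(all(abs(sqrt(rowSums(f$desc^2)) - 1) < 1e-6))
  expect_true(all(f$points$x >= 0 & f$points$x <= 559))
  expect_true(all(f$points$y >= 0 & f$points$y <= 479))
})

test_that("masked regions are kept free of features", {
  tex <- fx_texture(240, 180, 7)
  mask <- matrix(FALSE, 180, 240)
  mask[, 1:120] <- TRUE
  f <- detect_features(tex, mask = mask, budget = Inf, seed = 1)
  expect_true(all(round(f$points$x) >= 120))
})

test_that("descriptor pooling matches a brute-force index oracle", {
  expect_error(simplify_descriptor(rep(1, 64)), "128")
  d <- simplify_descriptor(rep(1, 128))
  expect_equal(d, rep(1 / sqrt(32), 32))
  # all mass in one spatial cell lands in exactly one pooled cell
  one <- numeric(128)
  one[(2 * 4 + 3) * 8 + 5 + 1] <- 7        # row cell 2, col cell 3, bin 5
  s <- simplify_descriptor(one)
  expect_equal(sum(s > 0), 1)
  expect_equal(s[((1 * 2 + 1) * 8 + 5) + 1], 1)
  # brute-force oracle over the 4x4x8 layout
  set.seed(10)
  d128 <- runif(128)
  pooled <- numeric(32)
  for (iy in 0:3) for (ix in 0:3) for (io in 0:7) {
    src <- (iy * 4 + ix) * 8 + io + 1
    dst <- ((iy %/% 2) * 2 + (ix %/% 2)) * 8 + io + 1
    pooled[dst] <- pooled[dst] + d128[src]
  }
  pooled <- pooled / sqrt(sum(pooled^2))
  expect_equal(simplify_descriptor(d128), pooled, tolerance = 1e-12)
})

test_that("descriptor distance is the squared (no square root) form", {
  a <- rep(1 / sqrt(32), 32)
  expect_equal(descriptor_distance(a, a), 0)
  e1 <- c(1, rep(0, 31)); e2 <- c(0, 1, rep(0, 30))
  expect_equal(descriptor_distance(e1, e2), 2)
  set.seed(4)
  x <- abs(rnorm(32)); x <- x / sqrt(sum(x^2))
  y <- abs(rnorm(32)); y <- y / sqrt(sum(y^2))
  loop <- 0
  for (i in 1:32) loop <- loop + (x[i] - y[i])^2
  expect_equal(descriptor_distance(x, y), loop, tolerance = 1e-12)
  expect_equal(descriptor_distance(x, y), descriptor_distance(y, x))
  expect_equal(descriptor_distance(x, y), 2 - 2 * sum(x * y),
               tolerance = 1e-12)
  expect_error(descriptor_distance(x, y[1:16]), "equal length")
})

test_that("compiled descriptor kernels agree with the plain-R reference", {
  set.seed(3)
  g <- matrix(rnorm(90 * 110), 90, 110)
  gg <- hpft:::grad_xy(g)
  x <- runif(40, 10, 100); y <- runif(40, 10, 80)
  sr <- runif(40, 1.2, 3); th <- runif(40, 0, 2 * pi)
  a <- hpft:::descriptors_from_gradients(gg$gx, gg$gy, x, y, sr, th)
  b <- hpft:::descriptors_from_gradients_ref(gg$gx, gg$gy, x, y, sr, th)
  expect_lt(max(abs(a - b)), 1e-12)
  oa <- hpft:::assign_orientations(gg$gx, gg$gy, x, y, sr)
  ob <- hpft:::assign_orientations_ref(gg$gx, gg$gy, x, y, sr)
  expect_identical(lengths(oa), lengths(ob))
  expect_lt(max(abs(unlist(oa) - unlist(ob))), 1e-12)
})

test_that("matching is injective, mutual-best and ratio-gated", {
  f <- detect_features(fx_texture(240, 180, 7), budget = 100, seed = 1)
  m <- initial_match(f, f)
  expect_gt(nrow(m), 50)
  expect_true(all(m$distance < 1e-9))
  expect_true(all(m$ref_id == m$tgt_id))
  expect_false(any(duplicated(m$ref_id)))
  expect_false(any(duplicated(m$tgt_id)))
  # equidistant nearest and second-nearest: ratio 1 > 0.8, rejected
  mk <- function(desc, x) {
    structure(list(points = data.frame(x = x, y = x, scale = 1.6,
                                       orientation = 0),
                   desc = desc), class = "hpft_features")
  }
  e1 <- c(1, rep(0, 31))
  eq <- sqrt(c(0.5, 0.5, rep(0, 30)))
  eq2 <- sqrt(c(0.5, 0, 0.5, rep(0, 29)))
  m2 <- initial_match(mk(rbind(e1), 1), mk(rbind(eq, eq2), c(1, 2)))
  expect_equal(nrow(m2), 0)
})

test_that("matches on a known warp agree with the ground truth", {
  sc <- fx_small_pair()
  fr <- detect_features(sc$reference, budget = 200, seed = 1)
  ft <- detect_features(sc$target, budget = Inf, seed = 2)
  m <- initial_match(fr, ft)
  expect_gt(nrow(m), 30)
  truth <- cbind(m$x_ref, m$y_ref, 1) %*% t(fx_affine_H())
  err <- sqrt((truth[, 1] - m$x_tgt)^2 + (truth[, 2] - m$y_tgt)^2)
  expect_gte(mean(err < 2), 0.9)
})

test_that("matches serialize to the six-column CSV format", {
  sc <- fx_small_pair()
  fit <- fx_small_fit()
  path <- tempfile(fileext = ".csv")
  write_matches(fit$matches, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "x_ref,y_ref,x_tgt,y_tgt,distance,source")
  back <- read_matches(path)
  expect_equal(nrow(back), nrow(fit$matches))
  expect_equal(back$x_ref, as.numeric(sprintf("%.3f", fit$matches$x_ref)))
})
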