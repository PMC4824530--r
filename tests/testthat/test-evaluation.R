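# The evaluation statistics: PPV, KL divergence, robustness covariance,
# RPV, uniformity.

test_that("ppv divides reliable counts by the initial budget", {
  expect_equal(ppv(numeric(0), 200), 0)
  expect_equal(ppv(rep(1, 200), 200), 1)
  fb <- c(rep(2, 120), rep(4, 20), rep(9, 60))
  expect_equal(ppv(fb, 200), 0.7)               # the <= boundary counts
  # monotone non-increasing in the threshold
  expect_gte(ppv(fb, 200, 4), ppv(fb, 200, 3))
  expect_error(ppv(fb, 0), "positive")
})

test_that("kl_divergence matches direct summation and is non-negative", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-6)
  # 0.5 ln 2 + 0.5 ln(2/3)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-3)
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "bin structure")
  set.seed(20)
  for (i in 1:20) {
    P <- runif(16); Q <- runif(16)
    d <- kl_divergence(P / sum(P), Q / sum(Q))
    expect_gte(d, 0)
  }
})

test_that("the trajectory divergence check applies the gating rules", {
  fwd <- cbind(runif(10, 40, 60), runif(10, 40, 60))
  chk <- dkl_trajectory_check(fwd, fwd, frame_size = c(320, 240))
  expect_true(chk$pass)
  expect_equal(chk$dkl1, 0, tolerance = 1e-6)
  # backward confined to a different grid cell: disjoint support
  bwd <- cbind(runif(10, 200, 220), runif(10, 200, 220))
  chk2 <- dkl_trajectory_check(fwd, bwd, frame_size = c(320, 240))
  expect_false(chk2$pass)
  expect_gt(chk2$dkl1, 0.1)
  # lost trajectory fails outright
  lost <- fwd; lost[3, 1] <- NA
  expect_false(dkl_trajectory_check(fwd, lost, c(320, 240))$pass)
  # the order rule: both small but two orders apart
  expect_true(hpft:::dkl_rule(0.05, 0.02))
  expect_false(hpft:::dkl_rule(0.05, 0.0004))   # ratio 125 > 10
  expect_false(hpft:::dkl_rule(0.2, 0.05))
  expect_true(hpft:::dkl_rule(0, 0))            # 0/0 defined as 1
})

test_that("stability covariance matches a two-pass oracle and the score map", {
  set.seed(21)
  s <- cbind(rnorm(1000, 5, 1), rnorm(1000, -3, 1))
  st <- hpft:::stability_summary(s)
  # two-pass textbook covariance
  mx <- mean(s[, 1]); my <- mean(s[, 2])
  oxx <- sum((s[, 1] - mx)^2) / (nrow(s) - 1)
  oyy <- sum((s[, 2] - my)^2) / (nrow(s) - 1)
  oxy <- sum((s[, 1] - mx) * (s[, 2] - my)) / (nrow(s) - 1)
  expect_lt(max(abs(st$cov - rbind(c(oxx, oxy), c(oxy, oyy)))), 1e-9)
  # isotropic unit Gaussian: both variances recover 1 within 3 sigma
  expect_lt(abs(st$cov[1, 1] - 1), 0.15)
  expect_lt(abs(st$cov[2, 2] - 1), 0.15)
  # order invariance
  st2 <- hpft:::stability_summary(s[sample(nrow(s)), ])
  expect_equal(st$cov, st2$cov, tolerance = 1e-9)
  # identical samples give the perfect score; rms 0.25 maps to 0.8 exactly
  same <- matrix(c(3, 3, 3, 7, 7, 7), 3, 2)
  expect_equal(hpft:::stability_summary(same)$score, 1)
  quart <- cbind(c(0.25, -0.25), c(0, 0))      # var_xx 0.125, var_yy 0
  expect_equal(hpft:::stability_summary(quart)$score, 1 / 1.25)
})

test_that("rpv is the robust fraction of the FB-reliable count", {
  samples <- data.frame(score = c(rep(0.9, 140), rep(0.5, 25)))
  expect_equal(rpv(samples, 170), 140 / 170)
  expect_equal(rpv(data.frame(score = rep(1, 10)), 10), 1)
  expect_equal(rpv(data.frame(score = rep(0, 10)), 10), 0)
  expect_gte(rpv(samples, 170, 0.8), rpv(samples, 170, 0.95))
  expect_error(rpv(samples, 0), "positive")
})

test_that("robustness ensemble scores perfect repeatability as 1", {
  tex <- fx_texture(200, 160, 22)
  sc <- warp_scene(tex, fx_affine_H(), noise_sigma = 0, seed = 1)
  pts <- cbind(runif(10, 50, 150), runif(10, 40, 120))
  # zero injected noise: every realization is the same registration
  rob <- robustness_ensemble(sc$reference, sc$target,
                             hpft_control(seed = 1), points = pts,
                             sigmas = 0, M = 2, seed = 1)
  expect_true(all(rob$samples$score > 1 - 1e-9))
  expect_error(robustness_ensemble(sc$reference, sc$target, M = 1),
               "at least 2")
})

test_that("uniformity is the chi-square deviation from uniform", {
  pts <- matrix(rep(c(37, 53), each = 200), 200, 2)
  u <- uniformity(pts, c(560, 480), bins = 10)
  # all mass in one bin: (200-20)^2/20 + 9 * 20 = 1800 per axis
  expect_equal(unname(u), c(1800, 1800))
  even <- cbind(rep(seq(5, 95, 10), each = 20), rep(seq(5, 95, 10), 20))
  expect_equal(unname(uniformity(even, c(100, 100), bins = 10)), c(0, 0))
  set.seed(23)
  p <- cbind(runif(100, 0, 99), runif(100, 0, 99))
  u1 <- uniformity(p, c(100, 100))
  u2 <- uniformity(p[sample(100), ], c(100, 100))
  expect_equal(u1, u2)
  expect_error(uniformity(p[0, , drop = FALSE], c(100, 100)), "at least one")
})
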