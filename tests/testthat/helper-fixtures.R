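# Shared fixtures, memoized so expensive scenes and fits are built once per
# test run. Everything is generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_texture <- function(w = 200, h = 160, seed = 1) {
  memo(paste("tex", w, h, seed), generate_textured_plane(w, h, seed))
}

# the study-scale single-plane scene: 560x480, mild affine, noise sigma 5
fx_affine_H <- function() {
  th <- 3 * pi / 180
  rbind(c(cos(th) * 1.03, -sin(th), 8),
        c(sin(th), cos(th) * 1.03, -5),
        c(0, 0, 1))
}

fx_plane_scene <- function() {
  memo("plane560", warp_scene(fx_texture(560, 480, 1), fx_affine_H(),
                              noise_sigma = 5, seed = 2))
}

fx_plane_fit <- function() {
  memo("plane560_fit", {
    sc <- fx_plane_scene()
    hpft(sc$reference, sc$target, control = hpft_control(seed = 1))
  })
}

fx_piecewise_scene <- function() {
  memo("pw560", generate_piecewise_planar_scene(560, 480, n_patches = 2,
                                                seed = 5, noise_sigma = 0))
}

fx_piecewise_fit <- function() {
  memo("pw560_fit", {
    sc <- fx_piecewise_scene()
    hpft(sc$reference, sc$target, control = hpft_control(seed = 1))
  })
}

# small noisy pair for fast registration tests
fx_small_pair <- function() {
  memo("small_pair", {
    tex <- fx_texture(240, 180, 7)
    warp_scene(tex, fx_affine_H(), noise_sigma = 3, seed = 3)
  })
}

fx_small_fit <- function() {
  memo("small_fit", {
    sc <- fx_small_pair()
    hpft(sc$reference, sc$target, control = hpft_control(seed = 1))
  })
}

fx_features_560 <- function() {
  memo("feat560", detect_features(fx_texture(560, 480, 1), budget = Inf,
                                  seed = 1))
}

# the desk-scale evaluation sequence: 10 frames, 320x240, per-frame noise 5
fx_sequence <- function() {
  memo("seq10", generate_affine_sequence(10, 320, 240, seed = 11,
                                         noise_sigma = 5))
}

fx_evaluation <- function() {
  memo("eval10", evaluate_sequence(fx_sequence(), hpft_control(seed = 1),
                                   sigmas = c(2, 5, 10), M = 9))
}

# reference bilinear sampler used by resampling oracles (independent of the
# package's internal sampler)
oracle_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || x[i] < 0 || y[i] < 0 || x[i] > w - 1 || y[i] > h - 1) {
      out[i] <- NA
      next
    }
    x0 <- min(floor(x[i]), w - 2); y0 <- min(floor(y[i]), h - 2)
    fx <- x[i] - x0; fy <- y[i] - y0
    out[i] <- img[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
      img[y0 + 1, x0 + 2] * fx * (1 - fy) +
      img[y0 + 2, x0 + 1] * (1 - fx) * fy +
      img[y0 + 2, x0 + 2] * fx * fy
  }
  out
}
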