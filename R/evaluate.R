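# The evaluation scheme: precision percent validation (PPV) from FB errors,
# Kullback-Leibler divergence of forward vs backward trajectory
# distributions, covariance-based robustness under injected Gaussian noise
# (RPV), and the coordinate-uniformity statistic.

#' Precision percent validation
#'
#' The fraction of the initial feature budget whose forward-backward error
#' does not exceed `threshold` px:
#' `PPV = count(FB error <= threshold) / initial_count`.
#'
#' @param fb numeric vector of FB errors (px), `Inf` for lost trajectories.
#' @param initial_count number of initially detected features.
#' @param threshold reliability threshold in pixels.
#' @return fraction in \[0, 1\].
#' @export
ppv <- function(fb, initial_count, threshold = 4) {
  if (initial_count <= 0) stop("initial_count must be positive")
  sum(fb <= threshold) / initial_count
}

#' Kullback-Leibler divergence of two histograms
#'
#' `sum(P * log(P / Q))` after additive smoothing and renormalization.
#' Non-symmetric by design: the trajectory check uses both directions.
#'
#' @param P,Q non-negative histograms with the same bin structure.
#' @param smooth additive smoothing constant.
#' @return non-negative divergence (nats).
#' @export
kl_divergence <- function(P, Q, smooth = 1e-9) {
  if (length(P) != length(Q)) stop("histograms must share bin structure")
  P <- P + smooth; Q <- Q + smooth
  P <- P / sum(P); Q <- Q / sum(Q)
  sum(P * log(P / Q))
}

# Bin a k x 2 matrix of positions onto a bins x bins grid over the frame.
#' @keywords internal
position_histogram <- function(pos, frame_size, bins) {
  w <- frame_size[1]; h <- frame_size[2]
  bx <- clamp(floor(pos[, 1] / w * bins), 0, bins - 1)
  by <- clamp(floor(pos[, 2] / h * bins), 0, bins - 1)
  counts <- numeric(bins * bins)
  agg <- rowsum(rep(1, nrow(pos)), by * bins + bx)
  counts[as.integer(rownames(agg)) + 1] <- agg[, 1]
  counts
}

#' KL-divergence check of a forward/backward trajectory pair
#'
#' Bins each trajectory's positions onto a `bins` x `bins` grid over the
#' frame and computes both divergences. The pair passes when
#' `dkl1 < 0.1`, `dkl2 < 0.1`, and the two are of the same order
#' (`max / min <= 10`; a 0/0 ratio is defined as 1). A lost trajectory
#' fails.
#'
#' @param forward,backward k x 2 position matrices for one feature (rows may
#'   contain NA once lost).
#' @param frame_size c(width, height) in pixels.
#' @param bins grid size per axis.
#' @return list with `pass`, `dkl1` (backward from forward), `dkl2`.
#' @export
dkl_trajectory_check <- function(forward, backward, frame_size, bins = 8) {
  forward <- matrix(as.numeric(forward), ncol = 2)
  backward <- matrix(as.numeric(backward), ncol = 2)
  if (anyNA(forward) || anyNA(backward)) {
    return(list(pass = FALSE, dkl1 = Inf, dkl2 = Inf))
  }
  Pf <- position_histogram(forward, frame_size, bins)
  Pb <- position_histogram(backward, frame_size, bins)
  d1 <- kl_divergence(Pb, Pf)
  d2 <- kl_divergence(Pf, Pb)
  list(pass = dkl_rule(d1, d2), dkl1 = d1, dkl2 = d2)
}

# The trajectory acceptance rule: both divergences below 0.1 and of the same
# order (ratio <= 10, with 0/0 defined as 1).
#' @keywords internal
dkl_rule <- function(d1, d2, thresh = 0.1, order_ratio = 10) {
  ratio <- if (d1 == 0 && d2 == 0) 1 else max(d1, d2) / max(min(d1, d2), 1e-300)
  d1 < thresh && d2 < thresh && ratio <= order_ratio
}

# Sample covariance (1/(M-1)) of target positions and the scalar stability
# score 1/(1 + rms), rms = sqrt((var_xx + var_yy)/2).
#' @keywords internal
stability_summary <- function(s) {
  cv <- stats::cov(s)
  rms <- sqrt((cv[1, 1] + cv[2, 2]) / 2)
  list(cov = cv, score = 1 / (1 + rms))
}

#' Robustness of registration under injected noise
#'
#' Re-runs the registration `M` times with zero-mean Gaussian noise added to
#' both images (cycling through `sigmas`), maps the given reference points
#' through each noisy fit, and summarizes every point matched in at least
#' two realizations by the sample mean and covariance (1/(M-1)
#' normalization) of its target positions. The scalar stability score is
#' `1 / (1 + rms)` with `rms = sqrt((var_xx + var_yy) / 2)`, so perfectly
#' repeatable localization scores 1.
#'
#' @param img_ref,img_tgt grayscale images.
#' @param control an [hpft_control()].
#' @param points n x 2 matrix of reference points to follow; defaults to the
#'   matched points of the clean fit.
#' @param sigmas noise standard deviations in gray levels, cycled over
#'   realizations.
#' @param M number of noise realizations (at least 2).
#' @param seed integer seed for the noise streams.
#' @return object of class `hpft_robustness`: data.frame `samples` with
#'   per-feature `n_samples`, covariance entries and `score`, plus the
#'   count of points `excluded` (matched in fewer than 2 realizations).
#' @export
robustness_ensemble <- function(img_ref, img_tgt, control = hpft_control(),
                                points = NULL, sigmas = c(2, 5, 10), M = 30,
                                seed = 1) {
  if (M < 2) stop("M must be at least 2")
  ref <- as_gray(img_ref); tgt <- as_gray(img_tgt)
  if (is.null(points)) {
    fit0 <- hpft(ref, tgt, control = control)
    points <- cbind(fit0$matches$x_ref, fit0$matches$y_ref)
  }
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  h <- nrow(ref); w <- ncol(ref)
  obs <- array(NA_real_, c(n, M, 2))
  for (k in seq_len(M)) {
    sg <- sigmas[(k - 1) %% length(sigmas) + 1]
    nr <- with_substream(seed, paste0("robust_ref", k),
                         matrix(stats::rnorm(h * w, 0, sg), h, w))
    nt <- with_substream(seed, paste0("robust_tgt", k),
                         matrix(stats::rnorm(h * w, 0, sg), h, w))
    fit <- tryCatch(
      hpft(clamp(ref + nr, 0, 255), clamp(tgt + nt, 0, 255), control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    mapped <- predict(fit, points)
    obs[, k, ] <- mapped
  }
  rows <- vector("list", n)
  excluded <- 0L
  for (i in seq_len(n)) {
    s <- cbind(obs[i, , 1], obs[i, , 2])
    s <- s[!is.na(s[, 1]), , drop = FALSE]
    if (nrow(s) < 2) { excluded <- excluded + 1L; next }
    st <- stability_summary(s)
    cv <- st$cov
    rows[[i]] <- data.frame(feature_id = i, n_samples = nrow(s),
                            mean_x = mean(s[, 1]), mean_y = mean(s[, 2]),
                            var_xx = cv[1, 1], cov_xy = cv[1, 2],
                            var_yy = cv[2, 2], score = st$score)
  }
  samples <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(samples)) {
    samples <- data.frame(feature_id = integer(0), n_samples = integer(0),
                          mean_x = numeric(0), mean_y = numeric(0),
                          var_xx = numeric(0), cov_xy = numeric(0),
                          var_yy = numeric(0), score = numeric(0))
  }
  structure(list(samples = samples, excluded = excluded, M = M,
                 sigmas = sigmas), class = "hpft_robustness")
}

#' @export
print.hpft_robustness <- function(x, ...) {
  cat(sprintf("Robustness ensemble: %d realizations (sigma %s), %d features, %d excluded\n",
              x$M, paste(x$sigmas, collapse = "/"), nrow(x$samples),
              x$excluded))
  if (nrow(x$samples)) {
    cat(sprintf("  median score %.3f, robust (>= 0.8): %d\n",
                stats::median(x$samples$score), sum(x$samples$score >= 0.8)))
  }
  invisible(x)
}

#' Robustness percent validation
#'
#' The fraction of FB-reliable matches whose stability score stays at or
#' above `score_threshold` across the injected-noise re-registrations:
#' `RPV = count(score >= threshold) / reliable_count`.
#'
#' @param samples an `hpft_robustness` or its `samples` data.frame.
#' @param reliable_count the FB-reliable match count (the PPV numerator).
#' @param score_threshold stability cutoff.
#' @return fraction in \[0, 1\].
#' @export
rpv <- function(samples, reliable_count, score_threshold = 0.8) {
  if (reliable_count <= 0) stop("reliable_count must be positive")
  if (inherits(samples, "hpft_robustness")) samples <- samples$samples
  sum(samples$score >= score_threshold) / reliable_count
}

#' Coordinate-uniformity statistic
#'
#' Per axis, histograms the coordinates into `bins` equal intervals and
#' returns the chi-square deviation from the uniform expectation,
#' `sum_b (count_b - N/bins)^2 / (N/bins)`; lower values mean a more uniform
#' spatial distribution of matches.
#'
#' @param points n x 2 matrix of (x, y) positions, n >= 1.
#' @param frame_size c(width, height) in pixels.
#' @param bins intervals per axis.
#' @return named vector `c(ux, uy)`.
#' @export
uniformity <- function(points, frame_size, bins = 10) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 1) stop("need at least one point")
  one_axis <- function(v, extent) {
    b <- clamp(floor(v / extent * bins), 0, bins - 1)
    counts <- tabulate(b + 1, nbins = bins)
    e <- length(v) / bins
    sum((counts - e)^2) / e
  }
  c(ux = one_axis(points[, 1], frame_size[1]),
    uy = one_axis(points[, 2], frame_size[2]))
}

#' End-to-end evaluation of a sequence
#'
#' Runs the full evaluation scheme on an image sequence: detects the initial
#' feature set in the first frame (inside a region of interest that keeps
#' features visible throughout), tracks it forward and backward, computes FB
#' errors and PPV, the per-feature KL-divergence check among the FB-reliable
#' trajectories, the injected-noise robustness ensemble on the first frame
#' pair (RPV over the FB-reliable count), and the uniformity of the initial
#' feature coordinates.
#'
#' @param frames list of grayscale images or an `hpft_sequence`.
#' @param control an [hpft_control()].
#' @param sigmas,M robustness ensemble settings (see
#'   [robustness_ensemble()]).
#' @param roi region of interest `c(x0, y0, x1, y1)` restricting the initial
#'   features; default keeps a 12.5% margin off every border.
#' @param dkl_bins,unif_bins histogram resolutions.
#' @return object of class `hpft_eval` with elements `ppv`, `rpv`,
#'   `dkl_pass_count`, `dkl_fb_ratio`, `dkl1`, `dkl2`, `fb_errors`,
#'   `uniformity`, `reliable_count`, `initial_count` and the thresholds
#'   used.
#' @export
evaluate_sequence <- function(frames, control = hpft_control(),
                              sigmas = c(2, 5, 10), M = 30, roi = NULL,
                              dkl_bins = 8, unif_bins = 10) {
  frames <- frames_of(frames)
  f1 <- as_gray(frames[[1]])
  h <- nrow(f1); w <- ncol(f1)
  if (is.null(roi)) roi <- c(w / 8, h / 8, 7 * w / 8, 7 * h / 8)
  feats <- detect_features(f1,
                           mask = detect_specular_mask(f1,
                                                       gray_thresh = control$specular_gray),
                           budget = Inf, seed = control$seed)
  inside <- feats$points$x >= roi[1] & feats$points$x <= roi[3] &
    feats$points$y >= roi[2] & feats$points$y <= roi[4]
  pts <- cbind(feats$points$x[inside], feats$points$y[inside])
  if (nrow(pts) > control$budget) {
    sel <- with_substream(control$seed, "eval_budget",
                          sort(sample.int(nrow(pts), control$budget)))
    pts <- pts[sel, , drop = FALSE]
  }
  initial_count <- nrow(pts)
  fb <- fb_track(frames, control, init_positions = pts)
  p <- ppv(fb$fb_errors, initial_count, threshold = control$fb_threshold)
  reliable <- which(fb$fb_errors <= control$fb_threshold)
  dkl1 <- dkl2 <- rep(NA_real_, initial_count)
  pass <- rep(FALSE, initial_count)
  for (i in reliable) {
    chk <- dkl_trajectory_check(fb$forward$positions[i, , ],
                                fb$backward$positions[i, , ],
                                frame_size = c(w, h), bins = dkl_bins)
    dkl1[i] <- chk$dkl1; dkl2[i] <- chk$dkl2; pass[i] <- chk$pass
  }
  rob <- robustness_ensemble(frames[[1]], frames[[2]], control,
                             points = pts[reliable, , drop = FALSE],
                             sigmas = sigmas, M = M, seed = control$seed)
  r <- if (length(reliable)) rpv(rob, length(reliable)) else NA_real_
  u <- uniformity(pts, c(w, h), bins = unif_bins)
  structure(list(ppv = p, rpv = r,
                 dkl_pass_count = sum(pass),
                 dkl_fb_ratio = if (length(reliable)) sum(pass) / length(reliable) else NA_real_,
                 dkl1 = dkl1, dkl2 = dkl2, fb_errors = fb$fb_errors,
                 uniformity = u, reliable_count = length(reliable),
                 initial_count = initial_count, robustness = rob,
                 fb = fb,
                 thresholds = list(fb = control$fb_threshold, dkl = 0.1,
                                   score = 0.8, sigmas = sigmas, M = M)),
            class = "hpft_eval")
}

#' @export
print.hpft_eval <- function(x, ...) {
  cat("HPFT sequence evaluation\n")
  cat(sprintf("  initial features: %d; FB-reliable (<= %g px): %d\n",
              x$initial_count, x$thresholds$fb, x$reliable_count))
  cat(sprintf("  PPV: %.3f   RPV: %.3f\n", x$ppv, x$rpv))
  cat(sprintf("  D_KL pass: %d (D_KL / FB ratio %.2f)\n",
              x$dkl_pass_count, x$dkl_fb_ratio))
  cat(sprintf("  uniformity: ux %.1f, uy %.1f\n",
              x$uniformity[1], x$uniformity[2]))
  invisible(x)
}
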