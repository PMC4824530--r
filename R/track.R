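# Sequence tracking: consecutive-pair HPFT registrations propagate each
# initial feature frame to frame, forward and backward, yielding the
# trajectories behind the forward-backward (FB) error and the KL-divergence
# precision check.

#' @keywords internal
frames_of <- function(frames) {
  if (inherits(frames, "hpft_sequence")) frames$frames else frames
}

#' Track features through an image sequence
#'
#' Registers every consecutive frame pair with [hpft()] and propagates each
#' initial position through [predict.hpft()]: by its containing accepted
#' patch's homography when inside one, else by the translation of the
#' nearest matched point within `control$nn_radius` px, else the trajectory
#' is lost. A registration failure on a pair loses all surviving
#' trajectories at that frame.
#'
#' @param frames list of grayscale images (or an `hpft_sequence`), at least
#'   two.
#' @param control an [hpft_control()].
#' @param direction `"forward"` or `"backward"` (a label recorded on the
#'   result; pass the frames already reversed for a backward pass).
#' @param init_positions n x 2 matrix of positions in the first frame;
#'   defaults to the detected feature positions under the control's budget.
#' @return object of class `hpft_trajectories`: `positions` is an
#'   n x frames x 2 array (NA once lost), plus `feature_id`, `lost_at` and
#'   `direction`.
#' @export
track_sequence <- function(frames, control = hpft_control(),
                           direction = c("forward", "backward"),
                           init_positions = NULL) {
  direction <- match.arg(direction)
  frames <- frames_of(frames)
  nf <- length(frames)
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(init_positions)) {
    f1 <- detect_features(as_gray(frames[[1]]),
                          mask = detect_specular_mask(frames[[1]],
                                                      gray_thresh = control$specular_gray),
                          budget = control$budget, seed = control$seed)
    init_positions <- cbind(f1$points$x, f1$points$y)
  }
  init_positions <- matrix(as.numeric(init_positions), ncol = 2)
  n <- nrow(init_positions)
  pos <- array(NA_real_, c(n, nf, 2))
  pos[, 1, ] <- init_positions
  alive <- rep(TRUE, n)
  lost_at <- rep(NA_integer_, n)
  for (k in seq_len(nf - 1)) {
    if (!any(alive)) break
    fit <- tryCatch(hpft(frames[[k]], frames[[k + 1]], control = control),
                    error = function(e) NULL)
    if (is.null(fit)) {
      lost_at[alive] <- k + 1L
      alive[] <- FALSE
      break
    }
    cur <- pos[, k, , drop = FALSE]
    idx <- which(alive)
    mapped <- predict(fit, cbind(cur[idx, 1, 1], cur[idx, 1, 2]))
    h <- nrow(fit$reference); w <- ncol(fit$reference)
    ok <- !is.na(mapped[, 1]) & mapped[, 1] >= 0 & mapped[, 1] <= w - 1 &
      mapped[, 2] >= 0 & mapped[, 2] <= h - 1
    pos[idx[ok], k + 1, 1] <- mapped[ok, 1]
    pos[idx[ok], k + 1, 2] <- mapped[ok, 2]
    lost_at[idx[!ok]] <- k + 1L
    alive[idx[!ok]] <- FALSE
  }
  structure(list(positions = pos, feature_id = seq_len(n),
                 lost_at = lost_at, direction = direction),
            class = "hpft_trajectories")
}

#' @export
print.hpft_trajectories <- function(x, ...) {
  cat(sprintf("%s trajectories: %d features over %d frames, %d lost\n",
              x$direction, dim(x$positions)[1], dim(x$positions)[2],
              sum(!is.na(x$lost_at))))
  invisible(x)
}

#' Forward-backward tracking of a sequence
#'
#' Tracks the initial features forward to the last frame, then tracks the
#' surviving endpoints backward to the first frame. A feature detected and
#' matched accurately returns to its initial location; the FB error is the
#' deviation between the two.
#'
#' @param frames list of grayscale images or an `hpft_sequence`.
#' @param control an [hpft_control()].
#' @param init_positions optional n x 2 matrix of initial positions.
#' @return object of class `hpft_fb`: `forward` and `backward` trajectories
#'   (backward stored in reverse frame order), `initial` positions, and
#'   `fb_errors` (`Inf` for lost trajectories).
#' @export
fb_track <- function(frames, control = hpft_control(), init_positions = NULL) {
  frames <- frames_of(frames)
  fwd <- track_sequence(frames, control, "forward", init_positions)
  nf <- dim(fwd$positions)[2]
  endpoints <- cbind(fwd$positions[, nf, 1], fwd$positions[, nf, 2])
  # lost forward trajectories cannot be tracked back; park them outside
  ok <- !is.na(endpoints[, 1])
  bwd_pos <- array(NA_real_, dim(fwd$positions))
  lost_at <- rep(NA_integer_, nrow(endpoints))
  if (any(ok)) {
    bwd <- track_sequence(rev(frames), control, "backward",
                          endpoints[ok, , drop = FALSE])
    bwd_pos[ok, , ] <- bwd$positions
    lost_at[ok] <- bwd$lost_at
  }
  lost_at[!ok] <- 1L
  backward <- structure(list(positions = bwd_pos,
                             feature_id = fwd$feature_id,
                             lost_at = lost_at, direction = "backward"),
                        class = "hpft_trajectories")
  err <- fb_errors(fwd, backward)
  structure(list(forward = fwd, backward = backward,
                 initial = fwd$positions[, 1, , drop = TRUE],
                 fb_errors = err),
            class = "hpft_fb")
}

#' Forward-backward errors of aligned trajectories
#'
#' Per feature, the Euclidean distance between the initial position in the
#' first frame and the backward-tracked return position; lost trajectories
#' get `Inf`.
#'
#' @param forward,backward `hpft_trajectories` aligned by feature id (the
#'   backward pass in reverse frame order, so its last frame is the first
#'   frame of the sequence).
#' @return numeric vector of FB errors in pixels.
#' @export
fb_errors <- function(forward, backward) {
  if (!identical(forward$feature_id, backward$feature_id)) {
    stop("trajectories must be aligned by feature_id")
  }
  nf <- dim(forward$positions)[2]
  ret <- cbind(backward$positions[, nf, 1], backward$positions[, nf, 2])
  ini <- cbind(forward$positions[, 1, 1], forward$positions[, 1, 2])
  e <- sqrt((ret[, 1] - ini[, 1])^2 + (ret[, 2] - ini[, 2])^2)
  e[is.na(e)] <- Inf
  e
}

#' @export
print.hpft_fb <- function(x, ...) {
  fin <- x$fb_errors[is.finite(x$fb_errors)]
  cat(sprintf("FB tracking: %d features, %d returned (median FB error %.2f px)\n",
              length(x$fb_errors), length(fin),
              if (length(fin)) stats::median(fin) else NA))
  invisible(x)
}
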