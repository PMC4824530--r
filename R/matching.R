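# Initial descriptor matching between the reference and target feature sets.

#' Match features between a reference and a target image
#'
#' For each reference feature the nearest and second-nearest target
#' descriptors are found under [descriptor_distance()]. A pair is kept only
#' if the nearest-to-second-nearest ratio is below `ratio` and the pair is a
#' mutual best (symmetric check), which makes the output injective on both
#' sides.
#'
#' @param feats_ref,feats_tgt `hpft_features` objects.
#' @param ratio rejection threshold on `V_min / V_second_min`.
#' @return data.frame of class `hpft_matches` with columns `ref_id`,
#'   `tgt_id`, `x_ref`, `y_ref`, `x_tgt`, `y_tgt`, `distance`, `source`
#'   (may have zero rows).
#' @export
initial_match <- function(feats_ref, feats_tgt, ratio = 0.8) {
  A <- feats_ref$desc; B <- feats_tgt$desc
  if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0) {
    stop("both feature sets must be non-empty")
  }
  D <- pmax(2 - 2 * A %*% t(B), 0)         # squared distances on unit vectors
  nn1 <- max.col(-D, ties.method = "first")
  v1 <- D[cbind(seq_len(nrow(D)), nn1)]
  D2 <- D
  D2[cbind(seq_len(nrow(D)), nn1)] <- Inf
  v2 <- D2[cbind(seq_len(nrow(D)), max.col(-D2, ties.method = "first"))]
  pass <- if (ncol(D) >= 2) v1 / v2 < ratio & is.finite(v1 / v2) else rep(TRUE, nrow(D))
  # mutual best
  rev_nn <- max.col(-t(D), ties.method = "first")
  mutual <- rev_nn[nn1] == seq_len(nrow(D))
  keep <- which(pass & mutual)
  out <- data.frame(
    ref_id = keep,
    tgt_id = nn1[keep],
    x_ref = feats_ref$points$x[keep],
    y_ref = feats_ref$points$y[keep],
    x_tgt = feats_tgt$points$x[nn1[keep]],
    y_tgt = feats_tgt$points$y[nn1[keep]],
    distance = v1[keep],
    source = rep("initial", length(keep)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hpft_matches", "data.frame")
  out
}

#' Write matches to CSV
#'
#' Six columns (`x_ref, y_ref, x_tgt, y_tgt, distance, source`) with a header
#' row; coordinates and distances printed with 3 decimals.
#'
#' @param matches an `hpft_matches` data.frame.
#' @param path output file.
#' @export
write_matches <- function(matches, path) {
  out <- data.frame(
    x_ref = sprintf("%.3f", matches$x_ref),
    y_ref = sprintf("%.3f", matches$y_ref),
    x_tgt = sprintf("%.3f", matches$x_tgt),
    y_tgt = sprintf("%.3f", matches$y_tgt),
    distance = sprintf("%.3f", matches$distance),
    source = matches$source
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read matches from CSV
#'
#' @param path file written by [write_matches()].
#' @return data.frame with the six match columns.
#' @export
read_matches <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(m) <- c("hpft_matches", "data.frame")
  m
}
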