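#' Modality ablation of the 35-column feature matrix
#'
#' Removes or isolates one modality block by exact column partition:
#' `mode = "remove"` leaves 23 (without spatial), 20 (without human pose) or
#' 27 (without equine pose) columns; `mode = "single"` keeps just the 12-, 15-
#' or 8-column block.
#'
#' @param features Feature matrix/data.frame with the canonical 35 columns of
#'   [feature_names()].
#' @param mode `"remove"` or `"single"`.
#' @param modality `"spatial"`, `"human_pose"` or `"equine_pose"`.
#' @return The reduced matrix/data.frame.
#' @export
#' @examples
#' ncol(ablate(as.data.frame(matrix(0, 1, 35,
#'   dimnames = list(NULL, feature_names()))), "remove", "equine_pose"))  # 27
ablate <- function(features, mode = c("remove", "single"),
                   modality = c("spatial", "human_pose", "equine_pose")) {
  mode <- match.arg(mode)
  modality <- match.arg(modality)
  if (ncol(features) != 35) stop("expected the canonical 35-column matrix")
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), feature_names())) {
    stop("columns are not in the canonical feature order")
  }
  block <- feature_blocks()[[modality]]
  keep <- if (mode == "single") block else setdiff(seq_len(35), block)
  features[, keep, drop = FALSE]
}

.coord_cols <- function(frames, species = c("both", "human", "horse")) {
  species <- match.arg(species)
  cols <- character(0)
  if (species %in% c("both", "human")) {
    cols <- c(cols, paste0("human_", rep(human_landmark_names(), each = 2),
                           c("_x", "_y")))
  }
  if (species %in% c("both", "horse")) {
    cols <- c(cols, paste0("horse_", rep(horse_keypoint_names(), each = 2),
                           c("_x", "_y")))
  }
  intersect(cols, names(frames))
}

#' Gaussian perturbation of landmark/keypoint coordinates
#'
#' Adds independent Gaussian noise with standard deviation
#' `sigma_fraction * frame_width` to every x coordinate and
#' `sigma_fraction * frame_height` to every y coordinate of the human landmarks
#' and equine keypoints, emulating pose-estimation error. Bounding boxes are
#' untouched; missing coordinates stay missing. Deterministic for a given seed.
#'
#' @param frames Frame table.
#' @param sigma_fraction Noise scale as a fraction of the frame dimension
#'   (>= 0).
#' @param seed Integer seed.
#' @return Perturbed frame table.
#' @export
perturb_keypoints <- function(frames, sigma_fraction, seed = 1) {
  stopifnot(sigma_fraction >= 0)
  if (sigma_fraction == 0) return(frames)
  set.seed(seed)
  for (col in .coord_cols(frames)) {
    dim_px <- if (endsWith(col, "_x")) frames$frame_width else frames$frame_height
    frames[[col]] <- frames[[col]] +
      stats::rnorm(nrow(frames), 0, sigma_fraction * dim_px)
  }
  frames
}

#' Random landmark dropout
#'
#' Independently removes each landmark/keypoint (both coordinates, and the
#' confidence for equine keypoints) with probability `rate`, per frame.
#' Missingness then flows through feature extraction and the scaler's
#' zero-imputation as for genuine detection failures.
#'
#' @param frames Frame table.
#' @param rate Dropout probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param species Drop landmarks of `"both"` (default), `"human"` or
#'   `"horse"`.
#' @return Frame table with dropped landmarks set to `NA`.
#' @export
dropout_landmarks <- function(frames, rate, seed = 1,
                              species = c("both", "human", "horse")) {
  species <- match.arg(species)
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(frames)
  set.seed(seed)
  n <- nrow(frames)
  pts <- character(0)
  if (species %in% c("both", "human")) {
    pts <- c(pts, paste0("human_", human_landmark_names()))
  }
  if (species %in% c("both", "horse")) {
    pts <- c(pts, paste0("horse_", horse_keypoint_names()))
  }
  for (pt in pts) {
    drop <- stats::runif(n) < rate
    if (!any(drop)) next
    for (suffix in c("_x", "_y", "_conf")) {
      col <- paste0(pt, suffix)
      if (col %in% names(frames)) frames[[col]][drop] <- NA_real_
    }
  }
  frames
}

#' Temporal majority-vote smoothing of frame predictions
#'
#' Replaces each prediction by the modal label of a centered sliding window
#' within its video (the window shrinks at video boundaries; no padding). Ties
#' are broken toward the original unsmoothed label, which makes `window = 1`
#' the identity, and a run of at least `ceiling(window / 2)` identical labels
#' is never changed inside the run.
#'
#' @param predictions Label vector, time-ordered within each video.
#' @param video_id Video id per prediction (single video when `NULL`).
#' @param window Odd window size >= 1 (default 5 frames, i.e. 1.67 s at 3 fps).
#' @return Smoothed label vector (same type as input).
#' @export
#' @examples
#' temporal_majority_vote(c("A", "A", "B", "A", "A"), window = 5)
temporal_majority_vote <- function(predictions, video_id = NULL, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(predictions)
  was_factor <- is.factor(predictions)
  lev <- if (was_factor) levels(predictions) else sort(unique(as.character(predictions)))
  p <- as.character(predictions)
  if (is.null(video_id)) video_id <- rep("v", length(p))
  h <- (window - 1) / 2
  out <- p
  for (v in unique(video_id)) {
    ix <- which(video_id == v)
    pv <- p[ix]
    n <- length(pv)
    for (i in seq_len(n)) {
      win <- pv[max(1, i - h):min(n, i + h)]
      tab <- table(factor(win, levels = lev))
      top <- names(tab)[tab == max(tab)]
      out[ix[i]] <- if (pv[i] %in% top) pv[i] else top[1]
    }
  }
  if (was_factor) factor(out, levels = lev) else out
}
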