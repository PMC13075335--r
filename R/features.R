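#' Canonical names and modality blocks of the 35-dimensional feature vector
#'
#' The fused descriptor concatenates 12 spatial features (detection geometry),
#' 15 human pose features and 8 equine pose features, in this fixed order.
#' `feature_blocks()` gives the column indices of each modality block.
#'
#' @return `feature_names()`: character vector of length 35;
#'   `feature_blocks()`: named list of integer index vectors.
#' @export
#' @examples
#' length(feature_names())              # 35
#' lengths(feature_blocks())            # 12, 15, 8
feature_names <- function() {
  c(
    # spatial (12)
    "dist_norm", "delta_x", "delta_y", "human_cx", "human_cy",
    "horse_cx", "horse_cy", "area_human", "area_horse",
    "conf_human", "conf_horse", "both_detected",
    # human pose (15)
    "nose_x", "nose_y", "lshoulder_x", "lshoulder_y",
    "rshoulder_x", "rshoulder_y", "shoulder_width",
    "lwrist_x", "lwrist_y", "rwrist_x", "rwrist_y",
    "body_center_x", "body_center_y", "body_height", "speed",
    # equine pose (8)
    "head_centroid_y", "head_elevation", "body_angle", "ear_angle",
    "ear_spread", "alertness", "mean_kp_confidence", "visible_fraction"
  )
}

#' @rdname feature_names
#' @export
feature_blocks <- function() {
  list(spatial = 1:12, human_pose = 13:27, equine_pose = 28:35)
}

.col <- function(frames, name) {
  if (name %in% names(frames)) frames[[name]] else rep(NA_real_, nrow(frames))
}

# spatial block, vectorized over a frame table
.spatial_block <- function(frames) {
  W <- frames$frame_width; H <- frames$frame_height
  diag_px <- sqrt(W^2 + H^2)
  hcx <- (frames$human_xmin + frames$human_xmax) / 2
  hcy <- (frames$human_ymin + frames$human_ymax) / 2
  ecx <- (frames$horse_xmin + frames$horse_xmax) / 2
  ecy <- (frames$horse_ymin + frames$horse_ymax) / 2
  a_h <- (frames$human_xmax - frames$human_xmin) *
    (frames$human_ymax - frames$human_ymin) / (W * H)
  a_e <- (frames$horse_xmax - frames$horse_xmin) *
    (frames$horse_ymax - frames$horse_ymin) / (W * H)
  if (any(stats::na.omit(c(a_h, a_e)) == 0)) {
    warning("degenerate zero-area bounding box; area computed as 0")
  }
  data.frame(
    dist_norm = sqrt((hcx - ecx)^2 + (hcy - ecy)^2) / diag_px,
    delta_x = (ecx - hcx) / W,
    delta_y = (ecy - hcy) / H,
    human_cx = hcx / W, human_cy = hcy / H,
    horse_cx = ecx / W, horse_cy = ecy / H,
    area_human = a_h, area_horse = a_e,
    conf_human = .col(frames, "human_conf"),
    conf_horse = .col(frames, "horse_conf"),
    both_detected = as.numeric(!is.na(hcx) & !is.na(ecx))
  )
}

# human pose block; speed is filled in by extract_features (needs stream order)
.human_block <- function(frames) {
  W <- frames$frame_width; H <- frames$frame_height
  g <- function(lm, ax) .col(frames, paste0("human_", lm, "_", ax)) /
    (if (ax == "x") W else H)
  lsx <- g("left_shoulder", "x"); lsy <- g("left_shoulder", "y")
  rsx <- g("right_shoulder", "x"); rsy <- g("right_shoulder", "y")
  lhx <- g("left_hip", "x"); lhy <- g("left_hip", "y")
  rhy <- g("right_hip", "y")
  bcx <- (lsx + rsx) / 2; bcy <- (lsy + rsy) / 2
  data.frame(
    nose_x = g("nose", "x"), nose_y = g("nose", "y"),
    lshoulder_x = lsx, lshoulder_y = lsy,
    rshoulder_x = rsx, rshoulder_y = rsy,
    shoulder_width = sqrt((lsx - rsx)^2 + (lsy - rsy)^2),
    lwrist_x = g("left_wrist", "x"), lwrist_y = g("left_wrist", "y"),
    rwrist_x = g("right_wrist", "x"), rwrist_y = g("right_wrist", "y"),
    body_center_x = bcx, body_center_y = bcy,
    body_height = abs(bcy - (lhy + rhy) / 2),
    speed = rep(NA_real_, nrow(frames))
  )
}

# equine pose block
.equine_block <- function(frames) {
  n <- nrow(frames)
  kn <- horse_keypoint_names()
  W <- frames$frame_width; H <- frames$frame_height
  kx <- sapply(kn, function(k) .col(frames, paste0("horse_", k, "_x")))
  ky <- sapply(kn, function(k) .col(frames, paste0("horse_", k, "_y")))
  kc <- sapply(kn, function(k) .col(frames, paste0("horse_", k, "_conf")))
  if (n == 1) { kx <- rbind(kx); ky <- rbind(ky); kc <- rbind(kc) }
  vis <- !is.na(kx) & !is.na(ky)
  visible_fraction <- rowMeans(vis)
  mean_conf <- rowMeans(kc, na.rm = TRUE)
  mean_conf[visible_fraction == 0] <- NA_real_

  head_kp <- c("left_eye", "right_eye", "left_ear_base", "right_ear_base")
  hx <- kx[, head_kp, drop = FALSE]; hy <- ky[, head_kp, drop = FALSE]
  n_head <- rowSums(!is.na(hx))
  cx <- rowMeans(hx, na.rm = TRUE); cy <- rowMeans(hy, na.rm = TRUE)
  cx[n_head < 2] <- NA_real_; cy[n_head < 2] <- NA_real_

  nx <- kx[, "nose"]; ny <- ky[, "nose"]
  dx <- nx - cx; dy <- ny - cy
  elev <- atan2(-dy, abs(dx)) * 180 / pi
  # forward (head-axis) unit vector and its upward perpendicular
  nrm <- sqrt(dx^2 + dy^2)
  fx <- dx / nrm; fy <- dy / nrm
  ux <- fy; uy <- -fx
  flip <- !is.na(uy) & uy > 0
  ux[flip] <- -ux[flip]; uy[flip] <- -uy[flip]

  ear_one <- function(side) {
    vx <- kx[, paste0(side, "_ear_tip")] - kx[, paste0(side, "_ear_base")]
    vy <- ky[, paste0(side, "_ear_tip")] - ky[, paste0(side, "_ear_base")]
    atan2(vx * fx + vy * fy, vx * ux + vy * uy) * 180 / pi
  }
  ear_l <- ear_one("left"); ear_r <- ear_one("right")
  ear <- rowMeans(cbind(ear_l, ear_r), na.rm = TRUE)
  ear[is.nan(ear)] <- NA_real_

  spread <- sqrt((kx[, "left_ear_tip"] - kx[, "right_ear_tip"])^2 +
                 (ky[, "left_ear_tip"] - ky[, "right_ear_tip"])^2) / nrm

  smx <- rowMeans(kx[, c("left_shoulder", "right_shoulder"), drop = FALSE],
                  na.rm = TRUE)
  smy <- rowMeans(ky[, c("left_shoulder", "right_shoulder"), drop = FALSE],
                  na.rm = TRUE)
  hmx <- rowMeans(kx[, c("left_hip", "right_hip"), drop = FALSE], na.rm = TRUE)
  hmy <- rowMeans(ky[, c("left_hip", "right_hip"), drop = FALSE], na.rm = TRUE)
  body <- atan2(-(hmy - smy), hmx - smx) * 180 / pi
  body[is.nan(smx) | is.nan(hmx)] <- NA_real_

  alert <- 0.5 * stats::plogis(elev / 45) + 0.5 * stats::plogis(ear / 30)
  data.frame(
    head_centroid_y = cy / H,
    head_elevation = elev, body_angle = body, ear_angle = ear,
    ear_spread = spread, alertness = alert,
    mean_kp_confidence = mean_conf, visible_fraction = visible_fraction
  )
}

#' Extract the 35-dimensional fused feature matrix from a frame stream
#'
#' Computes, per frame, the spatial block (normalized center distance, offsets,
#' positions, areas, confidences, both-detected flag), the human pose block
#' (frame-normalized landmark coordinates, shoulder width, body center/height,
#' movement speed) and the equine pose block (head centroid height, head
#' elevation, body angle, ear angle, ear spread, alertness composite, keypoint
#' confidence and visibility). Movement speed is the frame-to-frame body-center
#' displacement computed within each video only; it is 0 on the first frame of
#' a video (or after a gap where the body center was unobserved). Missing
#' detections yield `NA` entries; whole-modality absence is additionally
#' flagged in the `missing_mask` attribute (one logical column per modality).
#'
#' Angles are measured in image coordinates (origin top-left, y down) with
#' elevation sign flipped so a raised head is positive. The head centroid is
#' the mean of the visible eye and ear-base keypoints (at least 2 required);
#' the ear angle is the signed angle of the ear-base-to-tip vector from the
#' upward perpendicular of the head axis (centroid-to-nose), positive when
#' tipped toward the nose (forward) and negative when swept back. The
#' alertness composite is
#' `0.5 * logistic(elevation / 45) + 0.5 * logistic(ear_angle / 30)`.
#'
#' @param frames Frame table as produced by [simulate_dyads()] /
#'   [read_frame_table()]; rows are re-ordered by `(video_id, frame_index)`.
#' @return A data.frame with the 35 columns of [feature_names()], attributes
#'   `missing_mask` (n x 3 logical matrix) and `meta` (video_id, frame_index).
#' @export
extract_features <- function(frames) {
  ord <- order(frames$video_id, frames$frame_index)
  frames <- frames[ord, , drop = FALSE]
  sp <- .spatial_block(frames)
  hu <- .human_block(frames)
  eq <- .equine_block(frames)
  # within-video speed from consecutive body centers
  bcx <- hu$body_center_x; bcy <- hu$body_center_y
  disp <- sqrt(diff(bcx)^2 + diff(bcy)^2)
  speed <- c(0, disp)
  new_video <- c(TRUE, frames$video_id[-1] != frames$video_id[-nrow(frames)])
  speed[new_video] <- 0
  speed[is.na(speed) & !is.na(bcx)] <- 0   # unobserved previous center
  speed[is.na(bcx)] <- NA_real_
  hu$speed <- speed

  out <- cbind(sp, hu, eq)
  stopifnot(identical(names(out), feature_names()))
  hn <- human_landmark_names()
  lm_x <- sapply(hn, function(l) .col(frames, paste0("human_", l, "_x")))
  if (nrow(frames) == 1) lm_x <- rbind(lm_x)
  mask <- cbind(
    spatial = is.na(frames$human_xmin) | is.na(frames$horse_xmin),
    human_pose = rowSums(!is.na(lm_x)) == 0,
    equine_pose = eq$visible_fraction == 0
  )
  out$head_centroid_y[mask[, "equine_pose"]] <- NA_real_
  out$mean_kp_confidence[mask[, "equine_pose"]] <- NA_real_
  out$visible_fraction[mask[, "equine_pose"]] <- NA_real_
  attr(out, "missing_mask") <- mask
  attr(out, "meta") <- data.frame(video_id = frames$video_id,
                                  frame_index = frames$frame_index,
                                  stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-frame feature helpers
#'
#' Single-observation versions of the three modality blocks, returning named
#' numeric vectors. `obs` is a one-row frame table. For
#' `human_pose_features()`, `prev_body_center` is the previous frame's
#' normalized body center (or `NULL` on the first frame, giving speed 0).
#'
#' @param obs One-row frame data.frame.
#' @param prev_body_center Numeric length-2 vector or `NULL`.
#' @return Named numeric vector (12, 15 or 8 values).
#' @export
spatial_features <- function(obs) {
  stopifnot(nrow(obs) == 1)
  unlist(.spatial_block(obs)[1, ])
}

#' @rdname spatial_features
#' @export
human_pose_features <- function(obs, prev_body_center = NULL) {
  stopifnot(nrow(obs) == 1)
  v <- unlist(.human_block(obs)[1, ])
  bc <- c(v[["body_center_x"]], v[["body_center_y"]])
  v[["speed"]] <- if (is.null(prev_body_center) || anyNA(prev_body_center)) {
    if (anyNA(bc)) NA_real_ else 0
  } else {
    sqrt(sum((bc - prev_body_center)^2))
  }
  v
}

#' @rdname spatial_features
#' @export
equine_pose_features <- function(obs) {
  stopifnot(nrow(obs) == 1)
  unlist(.equine_block(obs)[1, ])
}

#' Ear-angle regime classification helper
#'
#' Thresholds on the ear angle: forward-pricked ears (> +30 degrees) indicate
#' interest, pinned-back ears (< -20 degrees) indicate stress; everything in
#' between is neutral.
#'
#' @param ear_angle Numeric vector of ear angles in degrees.
#' @return Character vector: "forward", "neutral", "pinned" (NA preserved).
#' @export
ear_regime <- function(ear_angle) {
  out <- ifelse(ear_angle > 30, "forward",
                ifelse(ear_angle < -20, "pinned", "neutral"))
  out
}

#' Write a feature matrix to CSV with its canonical header
#'
#' @param features Data.frame from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  meta <- attr(features, "meta")
  out <- if (!is.null(meta)) cbind(meta, features) else features
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
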