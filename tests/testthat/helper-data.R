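# shared fixtures, built in code

quick_cfg <- function(iterations = 60, depth = 5) {
  stage_config(iterations = iterations, depth = depth,
               early_stopping_patience = 0)
}

# perfectly separable 2-feature data with disjoint per-leaf supports: any
# consistent learner must recover the labels exactly
separable_data <- function(n_per = 30, seed = 7) {
  set.seed(seed)
  leaves <- behavior_leaves()
  y <- rep(leaves, each = n_per)
  centers <- seq_along(leaves) * 10
  x <- cbind(f1 = rep(centers, each = n_per) + stats::runif(length(y), -1, 1),
             f2 = -rep(centers, each = n_per) + stats::runif(length(y), -1, 1))
  list(x = x, y = y, parent = leaf_parent(y))
}

# a one-row frame table with everything missing, to be filled per test
blank_frame <- function(W = 1920, H = 1080, video_id = "v1", frame_index = 0L) {
  df <- data.frame(video_id = video_id, frame_index = frame_index,
                   frame_width = W, frame_height = H,
                   human_conf = NA_real_, human_xmin = NA_real_,
                   human_ymin = NA_real_, human_xmax = NA_real_,
                   human_ymax = NA_real_,
                   horse_conf = NA_real_, horse_xmin = NA_real_,
                   horse_ymin = NA_real_, horse_xmax = NA_real_,
                   horse_ymax = NA_real_,
                   stringsAsFactors = FALSE)
  for (l in human_landmark_names()) {
    df[[paste0("human_", l, "_x")]] <- NA_real_
    df[[paste0("human_", l, "_y")]] <- NA_real_
  }
  for (k in horse_keypoint_names()) {
    df[[paste0("horse_", k, "_x")]] <- NA_real_
    df[[paste0("horse_", k, "_y")]] <- NA_real_
    df[[paste0("horse_", k, "_conf")]] <- NA_real_
  }
  df
}

set_box <- function(df, subject, center, size, conf = 0.9) {
  df[[paste0(subject, "_xmin")]] <- center[1] - size[1] / 2
  df[[paste0(subject, "_xmax")]] <- center[1] + size[1] / 2
  df[[paste0(subject, "_ymin")]] <- center[2] - size[2] / 2
  df[[paste0(subject, "_ymax")]] <- center[2] + size[2] / 2
  df[[paste0(subject, "_conf")]] <- conf
  df
}

set_pt <- function(df, prefix, x, y, conf = 0.8) {
  df[[paste0(prefix, "_x")]] <- x
  df[[paste0(prefix, "_y")]] <- y
  cc <- paste0(prefix, "_conf")
  if (cc %in% names(df)) df[[cc]] <- conf
  df
}

# horse head rig: eye/ear-base offsets cancel around centroid C; nose on the
# horizontal through C (elevation 0); ear tips at `ear_deg` from the upward
# perpendicular of the head axis, tilted toward the nose
head_rig <- function(df, C = c(1000, 500), nose = c(1100, 500), ear_deg = 0,
                     ear_len = 40) {
  df <- set_pt(df, "horse_nose", nose[1], nose[2])
  df <- set_pt(df, "horse_left_eye", C[1] + 30, C[2] + 20)
  df <- set_pt(df, "horse_right_eye", C[1] + 30, C[2] - 20)
  f <- (nose - C) / sqrt(sum((nose - C)^2))
  u <- c(f[2], -f[1])
  if (u[2] > 0) u <- -u
  a <- ear_deg * pi / 180
  tipv <- ear_len * (cos(a) * u + sin(a) * f)
  for (side in c("left", "right")) {
    b <- c(C[1] - 30, C[2] + if (side == "left") 20 else -20)
    df <- set_pt(df, paste0("horse_", side, "_ear_base"), b[1], b[2])
    df <- set_pt(df, paste0("horse_", side, "_ear_tip"),
                 b[1] + tipv[1], b[2] + tipv[2])
  }
  df
}
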