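#' Human pose landmark schema
#'
#' The 15 named human landmarks used by the feature extractor (an upper-body
#' oriented subset of a full-body pose schema).
#'
#' @return Character vector of 15 landmark names.
#' @export
human_landmark_names <- function() {
  c("nose", "left_eye", "right_eye",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

#' Equine keypoint schema
#'
#' The 17 named equine keypoints used by the feature extractor: nose, eyes,
#' ear bases and tips, withers, shoulders, hips, hooves and tail base. Ear base
#' and tip points are included so ear orientation is computable from the
#' keypoints alone.
#'
#' @return Character vector of 17 keypoint names.
#' @export
horse_keypoint_names <- function() {
  c("nose", "left_eye", "right_eye",
    "left_ear_base", "left_ear_tip", "right_ear_base", "right_ear_tip",
    "withers", "left_shoulder", "right_shoulder",
    "left_front_hoof", "right_front_hoof",
    "left_hip", "right_hip", "left_back_hoof", "right_back_hoof",
    "tail_base")
}

#' Construct a per-class simulation scenario
#'
#' A scenario fixes the class-conditional distributions the simulator draws
#' from: the normalized inter-subject distance band, the ear-angle regime, the
#' human movement speed, the horse head elevation and the occlusion rate.
#'
#' @param leaf Leaf category name.
#' @param distance_band Numeric `(low, high)`; normalized center-to-center
#'   distance band in frame-diagonal units, `0 <= low < high <= 1.5`.
#' @param ear_angle_mean,ear_angle_sd Ear angle distribution in degrees
#'   (positive = pricked forward, negative = pinned back).
#' @param human_speed_mean Mean frame-to-frame human body-center displacement
#'   in normalized (frame-diagonal) units.
#' @param horse_head_elevation_mean Mean head elevation in degrees (positive =
#'   raised, negative = lowered/grazing).
#' @param occlusion_rate Per-frame probability that a modality (horse
#'   detection, human landmark set, or equine keypoint set) drops out.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(leaf, distance_band, ear_angle_mean, ear_angle_sd = 8,
                          human_speed_mean = 0.002,
                          horse_head_elevation_mean = 0,
                          occlusion_rate = 0.05) {
  if (length(distance_band) != 2 || distance_band[1] < 0 ||
      distance_band[1] >= distance_band[2] || distance_band[2] > 1.5) {
    stop("distance_band must satisfy 0 <= low < high <= 1.5")
  }
  if (occlusion_rate < 0 || occlusion_rate > 1) {
    stop("occlusion_rate must be in [0, 1]")
  }
  stopifnot(ear_angle_sd >= 0, human_speed_mean >= 0)
  leaf <- match.arg(leaf, behavior_leaves())
  structure(list(leaf = leaf, distance_band = as.numeric(distance_band),
                 ear_angle_mean = ear_angle_mean, ear_angle_sd = ear_angle_sd,
                 human_speed_mean = human_speed_mean,
                 horse_head_elevation_mean = horse_head_elevation_mean,
                 occlusion_rate = occlusion_rate),
            class = "scenario_spec")
}

#' Default per-class simulation scenarios
#'
#' Encodes the class-conditional structure the classifier assumes: affiliative
#' interactions at normalized distances below 0.3 with forward-pricked ears
#' (> +30 degrees), neutral behaviors between 0.3 and 0.6, avoidant behaviors
#' beyond 0.6, and pinned ears (< -20 degrees) for horse avoidance. Within each
#' parent, leaves differ in human movement speed (active vs subtle engagement,
#' human retreat) and horse head elevation (grazing vs attentive).
#'
#' With `overlap = TRUE`, distance bands are widened so neighboring parents
#' overlap and angle dispersions are inflated; this is the benchmark condition
#' under which classification is imperfect and ordering properties
#' (hierarchical vs flat, oracle vs cascaded, weighted vs unweighted) are
#' exercised.
#'
#' @param overlap Logical; use the overlapping-band benchmark variant.
#' @return Named list of [scenario_spec()] objects, one per leaf.
#' @export
#' @examples
#' default_scenarios()$affiliative_active$distance_band  # c(0, 0.3)
default_scenarios <- function(overlap = FALSE) {
  bands <- list(affiliative = c(0, 0.3), neutral = c(0.3, 0.6),
                avoidant = c(0.6, 1.0))
  sd_mult <- 1
  if (overlap) {
    bands <- list(affiliative = c(0, 0.45), neutral = c(0.2, 0.75),
                  avoidant = c(0.45, 1.0))
    sd_mult <- 3
  }
  list(
    affiliative_active = scenario_spec("affiliative_active", bands$affiliative,
      ear_angle_mean = 35, ear_angle_sd = 8 * sd_mult,
      human_speed_mean = 0.010, horse_head_elevation_mean = 10),
    affiliative_subtle = scenario_spec("affiliative_subtle", bands$affiliative,
      ear_angle_mean = 32, ear_angle_sd = 8 * sd_mult,
      human_speed_mean = 0.002, horse_head_elevation_mean = 0),
    neutral_horse = scenario_spec("neutral_horse", bands$neutral,
      ear_angle_mean = 0, ear_angle_sd = 10 * sd_mult,
      human_speed_mean = 0.002, horse_head_elevation_mean = -40),
    neutral_human = scenario_spec("neutral_human", bands$neutral,
      ear_angle_mean = 5, ear_angle_sd = 10 * sd_mult,
      human_speed_mean = 0.001, horse_head_elevation_mean = 5),
    avoidant_horse = scenario_spec("avoidant_horse", bands$avoidant,
      ear_angle_mean = -30, ear_angle_sd = 8 * sd_mult,
      human_speed_mean = 0.004, horse_head_elevation_mean = 20,
      occlusion_rate = 0.08),
    avoidant_human = scenario_spec("avoidant_human", bands$avoidant,
      ear_angle_mean = -5, ear_angle_sd = 10 * sd_mult,
      human_speed_mean = 0.015, horse_head_elevation_mean = 15,
      occlusion_rate = 0.08)
  )
}

#' Class counts of the reference behavioral dataset
#'
#' The six-leaf sample counts of the study dataset (50,270 temporal samples),
#' used as the default imbalance structure for simulation and for the printed
#' arithmetic anchors (naive baselines, class weights, imbalance ratios).
#'
#' @return Named integer vector over the six leaves.
#' @export
paper_class_counts <- function() {
  c(affiliative_active = 25993L, affiliative_subtle = 8904L,
    neutral_horse = 8717L, neutral_human = 4746L,
    avoidant_horse = 1754L, avoidant_human = 156L)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# place a human/horse center pair at separation d_px along direction theta,
# keeping both boxes inside the frame; rotates the direction in steps if
# needed, else falls back to a scaled diagonal placement.
.place_pair <- function(hc, d_px, theta, half_h, half_e, W, H) {
  hc <- c(.clamp(hc[1], half_h[1], W - half_h[1]),
          .clamp(hc[2], half_h[2], H - half_h[2]))
  offs <- c(0, 15, -15, 30, -30, 45, -45, 60, -60, 90, -90,
            120, -120, 150, -150, 180) * pi / 180
  for (o in offs) {
    ec <- hc + d_px * c(cos(theta + o), sin(theta + o))
    if (ec[1] >= half_e[1] && ec[1] <= W - half_e[1] &&
        ec[2] >= half_e[2] && ec[2] <= H - half_e[2]) {
      return(list(hc = hc, ec = ec))
    }
  }
  # separation too large for any rotation: put the horse in the corner of its
  # feasible rect farthest from the human, and if still short, push the human
  # away from that corner along the joining ray until the target separation
  # (or the frame edge) is reached
  corners <- rbind(c(half_e[1], half_e[2]), c(W - half_e[1], half_e[2]),
                   c(half_e[1], H - half_e[2]), c(W - half_e[1], H - half_e[2]))
  dc <- sqrt((corners[, 1] - hc[1])^2 + (corners[, 2] - hc[2])^2)
  j <- which.max(dc)
  if (dc[j] >= d_px) {
    p <- hc + d_px * (corners[j, ] - hc) / dc[j]
    ec <- c(.clamp(p[1], half_e[1], W - half_e[1]),
            .clamp(p[2], half_e[2], H - half_e[2]))
  } else {
    ec <- corners[j, ]
    ray <- (hc - ec) / dc[j]
    p <- ec + d_px * ray
    hc <- c(.clamp(p[1], half_h[1], W - half_h[1]),
            .clamp(p[2], half_h[2], H - half_h[2]))
  }
  list(hc = hc, ec = ec)
}

# unit template (u, v in [0,1] of the box, v increasing downward) for the 15
# human landmarks
.human_template <- function() {
  m <- rbind(
    nose = c(0.50, 0.07), left_eye = c(0.45, 0.05), right_eye = c(0.55, 0.05),
    left_shoulder = c(0.35, 0.20), right_shoulder = c(0.65, 0.20),
    left_elbow = c(0.30, 0.35), right_elbow = c(0.70, 0.35),
    left_wrist = c(0.28, 0.50), right_wrist = c(0.72, 0.50),
    left_hip = c(0.40, 0.52), right_hip = c(0.60, 0.52),
    left_knee = c(0.40, 0.75), right_knee = c(0.60, 0.75),
    left_ankle = c(0.40, 0.97), right_ankle = c(0.60, 0.97))
  m[human_landmark_names(), , drop = FALSE]
}

#' Simulate labeled dyadic frame-observation streams
#'
#' Generates per-frame detection records (bounding boxes, confidences, human
#' landmarks, equine keypoints) for a horse-human dyad, with the
#' class-conditional statistical structure given by `scenarios`: per-class
#' frame counts match `class_counts` exactly; the normalized center-to-center
#' distance is drawn from the class distance band (geometry permitting; very
#' large separations are capped by the frame); ear angles and head elevations
#' are Gaussian around the class means; each modality independently drops out
#' with the class occlusion rate (the spatial dropout removes the horse
#' detection, mirroring a horse moving out of frame). Frames are grouped into
#' episodes of geometric mean length `episode_mean_frames`, with an episode-
#' level random effect on distance and angles so frames within an episode are
#' temporally correlated; episodes are dealt round-robin across `n_videos`
#' videos.
#'
#' The same `seed` yields an identical dataset.
#'
#' @param class_counts Named vector of frame counts per leaf category (names
#'   from [behavior_leaves()]); classes may be 0 but the total must be >= 1.
#' @param n_videos Number of videos episodes are dealt across.
#' @param frame_width,frame_height Frame geometry in pixels.
#' @param seed Integer seed.
#' @param scenarios Named list of [scenario_spec()] per leaf.
#' @param episode_mean_frames Mean episode length in frames.
#' @param fps Sampling rate used to convert frame index to `time_s`.
#' @return A list with `frames` (one row per frame: boxes, confidences,
#'   flattened landmark/keypoint coordinates; missing values are `NA`) and
#'   `labels` (`video_id`, `frame_index`, `time_s`, `leaf`, `parent`).
#' @export
#' @examples
#' sim <- simulate_dyads(c(affiliative_active = 30, avoidant_horse = 10),
#'                       n_videos = 2, seed = 1)
#' nrow(sim$frames)  # 40
simulate_dyads <- function(class_counts, n_videos = 4,
                           frame_width = 1920, frame_height = 1080,
                           seed = 1, scenarios = default_scenarios(),
                           episode_mean_frames = 30, fps = 3) {
  stopifnot(n_videos >= 1, frame_width > 0, frame_height > 0)
  class_counts <- class_counts[class_counts > 0]
  if (!length(class_counts) || sum(class_counts) < 1) {
    stop("class_counts must contain at least one positive count")
  }
  if (is.null(names(class_counts)) ||
      !all(names(class_counts) %in% behavior_leaves())) {
    stop("class_counts must be named by leaf categories")
  }
  set.seed(seed)
  W <- frame_width; H <- frame_height
  diag_px <- sqrt(W^2 + H^2)
  hn <- human_landmark_names(); kn <- horse_keypoint_names()
  tpl <- .human_template()

  # carve each class's frames into episodes of geometric length
  epis <- list()
  for (leaf in names(class_counts)) {
    n <- as.integer(class_counts[[leaf]])
    lens <- integer(0)
    while (sum(lens) < n) {
      lens <- c(lens, stats::rgeom(max(8, ceiling(n / episode_mean_frames)),
                                   1 / episode_mean_frames) + 1L)
    }
    lens <- lens[cumsum(lens) - lens < n]
    lens[length(lens)] <- n - sum(lens[-length(lens)])
    for (L in lens) epis[[length(epis) + 1L]] <- list(leaf = leaf, len = L)
  }
  # interleave classes before dealing episodes round-robin to videos
  epis <- epis[sample.int(length(epis))]
  video_of <- (seq_along(epis) - 1L) %% n_videos + 1L

  out <- vector("list", length(epis))
  last_hc <- list()  # last human center per video, for cross-episode continuity
  for (e in seq_along(epis)) {
    leaf <- epis[[e]]$leaf
    L <- epis[[e]]$len
    sc <- scenarios[[leaf]]
    if (is.null(sc)) stop("no scenario for leaf: ", leaf)
    band <- sc$distance_band
    bw <- band[2] - band[1]
    d_epi <- stats::runif(1, band[1] + 0.1 * bw, band[2] - 0.1 * bw)
    d_t <- .clamp(d_epi + stats::runif(L, -0.05 * bw, 0.05 * bw),
                  band[1], band[2])
    theta <- stats::runif(1, 0, 2 * pi)
    # human / horse box sizes (log-normal around typical apparent sizes)
    hw <- stats::rlnorm(1, log(90), 0.15); hh <- 2.4 * hw
    ew <- stats::rlnorm(1, log(300), 0.15); eh <- 0.62 * ew
    half_h <- c(hw, hh) / 2; half_e <- c(ew, eh) / 2
    # per-episode drift of the human and head/ear regime
    drift <- stats::runif(1, 0, 2 * pi)
    # step length in px so the displacement of the (x/W, y/H)-normalized body
    # center equals human_speed_mean
    step_px <- function(phi) {
      sc$human_speed_mean / sqrt((cos(phi) / W)^2 + (sin(phi) / H)^2)
    }
    ear_epi <- stats::rnorm(1, sc$ear_angle_mean, 0.8 * sc$ear_angle_sd)
    elev_epi <- stats::rnorm(1, sc$horse_head_elevation_mean, 5)
    s_dir <- sample(c(-1, 1), 1)

    hc <- matrix(NA_real_, L, 2); ec <- matrix(NA_real_, L, 2)
    vid <- sprintf("video%02d", video_of[e])
    cur <- if (!is.null(last_hc[[vid]])) {
      c(.clamp(last_hc[[vid]][1], half_h[1], W - half_h[1]),
        .clamp(last_hc[[vid]][2], half_h[2], H - half_h[2]))
    } else {
      c(stats::runif(1, half_h[1], W - half_h[1]),
        stats::runif(1, half_h[2], H - half_h[2]))
    }
    for (t in seq_len(L)) {
      if (t > 1) {
        step <- step_px(drift)
        cand <- cur + step * c(cos(drift), sin(drift))
        # reflect the drift direction at frame edges
        if (cand[1] < half_h[1] || cand[1] > W - half_h[1]) {
          drift <- pi - drift
          cand <- cur + step_px(drift) * c(cos(drift), sin(drift))
        }
        if (cand[2] < half_h[2] || cand[2] > H - half_h[2]) {
          drift <- -drift
          cand <- cur + step_px(drift) * c(cos(drift), sin(drift))
        }
        cur <- c(.clamp(cand[1], half_h[1], W - half_h[1]),
                 .clamp(cand[2], half_h[2], H - half_h[2]))
      }
      pp <- .place_pair(cur, d_t[t] * diag_px, theta, half_h, half_e, W, H)
      cur <- pp$hc
      hc[t, ] <- pp$hc; ec[t, ] <- pp$ec
    }
    last_hc[[vid]] <- hc[L, ]

    df <- data.frame(video_id = sprintf("video%02d", video_of[e]),
                     frame_index = NA_integer_,
                     frame_width = W, frame_height = H,
                     stringsAsFactors = FALSE)
    df <- df[rep(1, L), , drop = FALSE]
    df$human_conf <- stats::runif(L, 0.75, 0.98)
    df$human_xmin <- hc[, 1] - half_h[1]; df$human_ymin <- hc[, 2] - half_h[2]
    df$human_xmax <- hc[, 1] + half_h[1]; df$human_ymax <- hc[, 2] + half_h[2]
    df$horse_conf <- stats::runif(L, 0.70, 0.97)
    df$horse_xmin <- ec[, 1] - half_e[1]; df$horse_ymin <- ec[, 2] - half_e[2]
    df$horse_xmax <- ec[, 1] + half_e[1]; df$horse_ymax <- ec[, 2] + half_e[2]

    # human landmarks from the box template with mild jitter
    for (j in seq_along(hn)) {
      df[[paste0("human_", hn[j], "_x")]] <-
        df$human_xmin + tpl[j, 1] * hw + stats::rnorm(L, 0, 0.005 * hw)
      df[[paste0("human_", hn[j], "_y")]] <-
        df$human_ymin + tpl[j, 2] * hh + stats::rnorm(L, 0, 0.005 * hh)
    }

    # equine keypoints: head geometry realizes elevation and ear angles
    elev <- elev_epi + stats::rnorm(L, 0, 3)
    th <- elev * pi / 180
    Hx <- ec[, 1] + s_dir * 0.35 * ew; Hy <- ec[, 2] - 0.20 * eh
    r <- 0.18 * ew
    Nx <- Hx + r * s_dir * cos(th); Ny <- Hy - r * sin(th)
    fx <- (Nx - Hx) / r; fy <- (Ny - Hy) / r
    # up-perpendicular of the head axis (negative image-y component)
    ux <- fy; uy <- -fx
    flip <- uy > 0
    ux[flip] <- -ux[flip]; uy[flip] <- -uy[flip]
    within_sd <- 0.6 * sc$ear_angle_sd
    ear_t <- ear_epi + stats::rnorm(L, 0, within_sd)
    kp <- matrix(NA_real_, L, 2 * length(kn),
                 dimnames = list(NULL, paste0(rep(kn, each = 2),
                                              c("_x", "_y"))))
    setkp <- function(name, x, y) {
      kp[, paste0(name, "_x")] <<- x; kp[, paste0(name, "_y")] <<- y
    }
    # eye / ear-base offsets cancel around the head anchor, so the head
    # centroid recovered from them equals the anchor exactly
    setkp("nose", Nx, Ny)
    setkp("left_eye", Hx + s_dir * 0.03 * ew, Hy + 0.04 * eh - 0.012 * ew)
    setkp("right_eye", Hx + s_dir * 0.03 * ew, Hy + 0.04 * eh + 0.012 * ew)
    ear_len <- 0.06 * ew
    for (side in c("left", "right")) {
      off <- if (side == "left") -0.012 * ew else 0.012 * ew
      bx <- Hx - s_dir * 0.03 * ew; by <- Hy - 0.04 * eh + off
      a <- (ear_t + stats::rnorm(L, 0, 1.5)) * pi / 180
      setkp(paste0(side, "_ear_base"), bx, by)
      setkp(paste0(side, "_ear_tip"),
            bx + ear_len * (cos(a) * ux + sin(a) * fx),
            by + ear_len * (cos(a) * uy + sin(a) * fy))
    }
    setkp("withers", ec[, 1] + s_dir * 0.15 * ew, ec[, 2] - 0.30 * eh)
    setkp("left_shoulder", ec[, 1] + s_dir * 0.22 * ew, ec[, 2] - 0.08 * eh)
    setkp("right_shoulder", ec[, 1] + s_dir * 0.20 * ew, ec[, 2] - 0.02 * eh)
    setkp("left_hip", ec[, 1] - s_dir * 0.28 * ew, ec[, 2] - 0.10 * eh)
    setkp("right_hip", ec[, 1] - s_dir * 0.26 * ew, ec[, 2] - 0.04 * eh)
    setkp("left_front_hoof", ec[, 1] + s_dir * 0.22 * ew, ec[, 2] + 0.46 * eh)
    setkp("right_front_hoof", ec[, 1] + s_dir * 0.18 * ew, ec[, 2] + 0.46 * eh)
    setkp("left_back_hoof", ec[, 1] - s_dir * 0.28 * ew, ec[, 2] + 0.46 * eh)
    setkp("right_back_hoof", ec[, 1] - s_dir * 0.24 * ew, ec[, 2] + 0.46 * eh)
    setkp("tail_base", ec[, 1] - s_dir * 0.45 * ew, ec[, 2] - 0.15 * eh)
    body_jit <- grep("(withers|shoulder|hip|hoof|tail)", colnames(kp))
    kp[, body_jit] <- kp[, body_jit] + stats::rnorm(length(kp[, body_jit]), 0, 1.5)
    kp[, seq(1, ncol(kp), 2)] <- .clamp(kp[, seq(1, ncol(kp), 2)], 0, W)
    kp[, seq(2, ncol(kp), 2)] <- .clamp(kp[, seq(2, ncol(kp), 2)], 0, H)
    for (cn in colnames(kp)) df[[paste0("horse_", cn)]] <- kp[, cn]
    for (name in kn) {
      df[[paste0("horse_", name, "_conf")]] <- stats::runif(L, 0.55, 0.95)
    }

    # per-frame Bernoulli dropout of whole modalities
    occ_box <- stats::runif(L) < sc$occlusion_rate
    occ_lm <- stats::runif(L) < sc$occlusion_rate
    occ_kp <- stats::runif(L) < sc$occlusion_rate
    if (any(occ_box)) {
      df[occ_box, c("horse_conf", "horse_xmin", "horse_ymin",
                    "horse_xmax", "horse_ymax")] <- NA_real_
    }
    if (any(occ_lm)) {
      df[occ_lm, paste0("human_", rep(hn, each = 2), c("_x", "_y"))] <- NA_real_
    }
    if (any(occ_kp)) {
      df[occ_kp, paste0("horse_", rep(kn, each = 3),
                        c("_x", "_y", "_conf"))] <- NA_real_
    }
    df$.leaf <- leaf
    out[[e]] <- df
  }

  frames <- do.call(rbind, out)
  # consecutive frame indices within each video, in episode-deal order
  ord <- order(match(frames$video_id, sort(unique(frames$video_id))))
  frames <- frames[ord, , drop = FALSE]
  frames$frame_index <- stats::ave(seq_len(nrow(frames)), frames$video_id,
                                   FUN = seq_along) - 1L
  labels <- data.frame(video_id = frames$video_id,
                       frame_index = frames$frame_index,
                       time_s = frames$frame_index / fps,
                       leaf = frames$.leaf,
                       parent = leaf_parent(frames$.leaf),
                       stringsAsFactors = FALSE)
  frames$.leaf <- NULL
  rownames(frames) <- rownames(labels) <- NULL
  list(frames = frames, labels = labels)
}

#' Write / read a frame-observation table
#'
#' Plain-CSV round trip for the simulator's frame table (one row per frame,
#' flattened landmark columns, `NA` for missing detections).
#'
#' @param frames Frame data.frame from [simulate_dyads()].
#' @param path File path.
#' @return `path` (writer, invisibly) or the frame data.frame (reader).
#' @export
write_frame_table <- function(frames, path) {
  utils::write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_table
#' @export
read_frame_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
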