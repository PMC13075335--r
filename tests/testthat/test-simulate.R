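test_that("default scenarios encode the class-conditional structure", {
  sc <- default_scenarios()
  expect_equal(sc$affiliative_active$distance_band, c(0, 0.3))
  expect_equal(sc$affiliative_subtle$distance_band, c(0, 0.3))
  expect_equal(sc$neutral_horse$distance_band, c(0.3, 0.6))
  expect_equal(sc$avoidant_horse$distance_band, c(0.6, 1.0))
  expect_lt(sc$avoidant_horse$ear_angle_mean, -20)
  expect_gt(sc$affiliative_active$ear_angle_mean, 30)
  expect_gt(sc$affiliative_subtle$ear_angle_mean, 30)
  # overlapping benchmark variant: adjacent parent bands intersect
  ov <- default_scenarios(overlap = TRUE)
  expect_gt(ov$affiliative_active$distance_band[2],
            ov$neutral_horse$distance_band[1])
  expect_gt(ov$neutral_horse$distance_band[2],
            ov$avoidant_horse$distance_band[1])
})

test_that("scenario invariants are enforced", {
  expect_error(scenario_spec("neutral_horse", c(0.5, 0.4), 0), "low < high")
  expect_error(scenario_spec("neutral_horse", c(0, 2), 0))
  expect_error(scenario_spec("neutral_horse", c(0, 0.5), 0, occlusion_rate = 1.5))
  expect_error(scenario_spec("nope", c(0, 0.5), 0))
})

test_that("simulation is deterministic and matches requested counts exactly", {
  counts <- c(affiliative_active = 40, neutral_horse = 25, avoidant_horse = 12)
  s1 <- simulate_dyads(counts, n_videos = 3, seed = 5)
  s2 <- simulate_dyads(counts, n_videos = 3, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_dyads(counts, n_videos = 3, seed = 6)
  expect_false(identical(s1$frames, s3$frames))

  expect_equal(unclass(table(s1$labels$leaf))[names(counts)],
               counts, ignore_attr = TRUE)
  expect_equal(nrow(s1$frames), sum(counts))
  expect_identical(s1$frames$video_id, s1$labels$video_id)
  expect_identical(s1$frames$frame_index, s1$labels$frame_index)
  expect_lte(length(unique(s1$frames$video_id)), 3L)

  # degenerate specs
  expect_error(simulate_dyads(c(affiliative_active = 0), seed = 1), "positive")
  one <- simulate_dyads(c(neutral_human = 10), n_videos = 1, seed = 1)
  expect_identical(nrow(one$frames), 10L)
  expect_identical(unique(one$labels$leaf), "neutral_human")
})

test_that("boxes stay inside the frame and distances recover the class bands", {
  counts <- c(affiliative_active = 1000, neutral_horse = 400,
              avoidant_horse = 400)
  sim <- simulate_dyads(counts, n_videos = 5, seed = 2)
  fr <- sim$frames
  for (s in c("human", "horse")) {
    expect_true(all(fr[[paste0(s, "_xmin")]] >= 0, na.rm = TRUE))
    expect_true(all(fr[[paste0(s, "_xmax")]] <= fr$frame_width, na.rm = TRUE))
    expect_true(all(fr[[paste0(s, "_ymin")]] >= 0, na.rm = TRUE))
    expect_true(all(fr[[paste0(s, "_ymax")]] <= fr$frame_height, na.rm = TRUE))
    expect_true(all(fr[[paste0(s, "_xmax")]] - fr[[paste0(s, "_xmin")]] > 0,
                    na.rm = TRUE))
  }
  # distance recomputed directly from the emitted boxes (independent of the
  # feature extractor)
  d <- sqrt(((fr$human_xmin + fr$human_xmax) / 2 -
             (fr$horse_xmin + fr$horse_xmax) / 2)^2 +
            ((fr$human_ymin + fr$human_ymax) / 2 -
             (fr$horse_ymin + fr$horse_ymax) / 2)^2) /
    sqrt(fr$frame_width^2 + fr$frame_height^2)
  sc <- default_scenarios()
  for (lf in names(counts)) {
    band <- sc[[lf]]$distance_band
    di <- stats::na.omit(d[sim$labels$leaf == lf])
    expect_gt(mean(di), band[1])
    expect_lt(mean(di), band[2])
    expect_true(all(di <= band[2] + 1e-9))
  }
})

test_that("disjoint bands and ear regimes make parents separable by a tiny tree", {
  counts <- stats::setNames(rep(400, 6), behavior_leaves())
  sim <- simulate_dyads(counts, n_videos = 6, seed = 3)
  fe <- extract_features(sim$frames)
  d <- data.frame(dist = fe$dist_norm, ear = fe$ear_angle,
                  y = factor(sim$labels$parent))
  d$dist[is.na(d$dist)] <- 0
  d$ear[is.na(d$ear)] <- 0
  tree <- rpart::rpart(y ~ dist + ear, d,
                       control = rpart::rpart.control(maxdepth = 2))
  ba <- balanced_accuracy(confusion_matrix(d$y, predict(tree, type = "class")))
  expect_gt(ba, 0.9)
})

test_that("feature extraction recovers the scenario parameters", {
  counts <- c(affiliative_active = 800, neutral_horse = 600,
              avoidant_horse = 400, avoidant_human = 300)
  sim <- simulate_dyads(counts, n_videos = 6, seed = 4)
  fe <- extract_features(sim$frames)
  sc <- default_scenarios()
  for (lf in names(counts)) {
    i <- sim$labels$leaf == lf
    band <- sc[[lf]]$distance_band
    m <- mean(fe$dist_norm[i], na.rm = TRUE)
    expect_gt(m, band[1]); expect_lt(m, band[2])
    expect_lt(abs(mean(fe$ear_angle[i], na.rm = TRUE) - sc[[lf]]$ear_angle_mean),
              6)
    expect_lt(abs(mean(fe$head_elevation[i], na.rm = TRUE) -
                  sc[[lf]]$horse_head_elevation_mean), 6)
  }
  # ear regimes land in their behavioral classes
  expect_identical(names(which.max(table(
    ear_regime(fe$ear_angle[sim$labels$leaf == "affiliative_active"])))),
    "forward")
  expect_identical(names(which.max(table(
    ear_regime(fe$ear_angle[sim$labels$leaf == "avoidant_horse"])))),
    "pinned")
  # faster movers have larger recovered speed
  sp_act <- mean(fe$speed[sim$labels$leaf == "affiliative_active"], na.rm = TRUE)
  sp_neu <- mean(fe$speed[sim$labels$leaf == "neutral_horse"], na.rm = TRUE)
  expect_gt(sp_act, sp_neu)
})

test_that("frames are grouped into contiguous episodes within videos", {
  counts <- c(affiliative_active = 300, avoidant_horse = 300)
  sim <- simulate_dyads(counts, n_videos = 4, seed = 9,
                        episode_mean_frames = 20)
  for (v in unique(sim$labels$video_id)) {
    lv <- sim$labels$leaf[sim$labels$video_id == v]
    runs <- rle(lv)$lengths
    expect_gt(mean(runs), 5)  # episodes, not frame-wise shuffling
  }
  # occlusion produces whole-modality dropouts at roughly the configured rate
  sim2 <- simulate_dyads(c(avoidant_horse = 2000), n_videos = 2, seed = 10)
  box_missing <- mean(is.na(sim2$frames$horse_xmin))
  expect_gt(box_missing, 0.04); expect_lt(box_missing, 0.13)
  kp_gone <- is.na(sim2$frames$horse_nose_x)
  all_kp_na <- rowSums(!is.na(sim2$frames[, paste0(
    "horse_", horse_keypoint_names(), "_x")])) == 0
  expect_identical(unname(kp_gone), unname(all_kp_na))
})

test_that("frame tables round-trip through CSV", {
  sim <- simulate_dyads(c(neutral_horse = 20), n_videos = 2, seed = 1)
  path <- file.path(tempdir(), "frames.csv")
  write_frame_table(sim$frames, path)
  back <- read_frame_table(path)
  expect_equal(back$horse_nose_x, sim$frames$horse_nose_x, tolerance = 1e-8)
  expect_identical(nrow(back), nrow(sim$frames))
})
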