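test_that("feature vector structure is 12 + 15 + 8 = 35", {
  expect_length(feature_names(), 35)
  blocks <- feature_blocks()
  expect_equal(lengths(blocks), c(spatial = 12, human_pose = 15,
                                  equine_pose = 8))
  expect_identical(sort(unname(unlist(blocks))), 1:35)
  sim <- simulate_dyads(c(neutral_horse = 5), n_videos = 1, seed = 1)
  fe <- extract_features(sim$frames)
  expect_identical(names(fe), feature_names())
  expect_identical(dim(attr(fe, "missing_mask")), c(5L, 3L))
})

test_that("normalized center distance matches direct arithmetic", {
  fr <- blank_frame()
  fr <- set_box(fr, "human", c(960, 540), c(100, 200))
  fr <- set_box(fr, "horse", c(1160, 540), c(300, 180))
  sp <- spatial_features(fr)
  expect_equal(sp[["dist_norm"]], 200 / sqrt(1920^2 + 1080^2),
               tolerance = 1e-12)
  expect_equal(sp[["delta_x"]], 200 / 1920)
  expect_equal(sp[["delta_y"]], 0)
  expect_equal(sp[["area_human"]], 100 * 200 / (1920 * 1080))
  expect_equal(sp[["both_detected"]], 1)

  # coincident centers
  fr2 <- set_box(fr, "horse", c(960, 540), c(300, 180))
  expect_equal(spatial_features(fr2)[["dist_norm"]], 0)

  # absent horse detection
  fr3 <- blank_frame()
  fr3 <- set_box(fr3, "human", c(960, 540), c(100, 200))
  sp3 <- spatial_features(fr3)
  expect_equal(sp3[["both_detected"]], 0)
  expect_true(is.na(sp3[["dist_norm"]]))
  expect_true(is.na(sp3[["horse_cx"]]))
  expect_false(is.na(sp3[["human_cx"]]))

  # degenerate zero-area box warns
  fr4 <- set_box(fr, "horse", c(1000, 500), c(0, 0))
  expect_warning(spatial_features(fr4), "zero-area")
})

test_that("human pose features follow their definitions", {
  fr <- blank_frame()
  fr <- set_pt(fr, "human_left_shoulder", 0.4 * 1920, 0.3 * 1080)
  fr <- set_pt(fr, "human_right_shoulder", 0.6 * 1920, 0.3 * 1080)
  fr <- set_pt(fr, "human_left_hip", 0.4 * 1920, 0.5 * 1080)
  fr <- set_pt(fr, "human_right_hip", 0.6 * 1920, 0.5 * 1080)
  hp <- human_pose_features(fr)
  expect_equal(hp[["shoulder_width"]], 0.2, tolerance = 1e-12)
  expect_equal(hp[["body_center_x"]], 0.5)
  expect_equal(hp[["body_center_y"]], 0.3)
  expect_equal(hp[["body_height"]], 0.2)
  expect_equal(hp[["speed"]], 0)  # no previous frame

  hp2 <- human_pose_features(fr, prev_body_center = c(0.5, 0.26))
  expect_equal(hp2[["speed"]], 0.04, tolerance = 1e-12)

  # all landmarks absent: the whole block is missing-flagged
  hp3 <- human_pose_features(blank_frame())
  expect_true(all(is.na(hp3)))
  expect_length(hp3, 15)
})

test_that("speed is computed within videos and is 0 for repeated frames", {
  fr <- blank_frame()
  fr <- set_pt(fr, "human_left_shoulder", 700, 300)
  fr <- set_pt(fr, "human_right_shoulder", 900, 300)
  two <- rbind(fr, fr)
  two$frame_index <- 0:1
  fe <- extract_features(two)
  expect_equal(fe$speed, c(0, 0))

  moved <- fr
  moved$human_left_shoulder_x <- 700 + 192
  moved$human_right_shoulder_x <- 900 + 192
  three <- rbind(fr, moved, fr)
  three$frame_index <- 0:2
  three$video_id <- c("a", "a", "b")
  fe3 <- extract_features(three)
  expect_equal(fe3$speed, c(0, 0.1, 0))  # video boundary resets speed
})

test_that("equine head geometry yields exact angles on a constructed rig", {
  # horizontal head axis, neutral upright ears: elevation 0, ear 0, alertness 0.5
  fr <- head_rig(blank_frame(), ear_deg = 0)
  eq <- equine_pose_features(fr)
  expect_equal(eq[["head_elevation"]], 0, tolerance = 1e-9)
  expect_equal(eq[["ear_angle"]], 0, tolerance = 1e-9)
  expect_equal(eq[["alertness"]], 0.5, tolerance = 1e-9)
  expect_equal(eq[["head_centroid_y"]], 500 / 1080, tolerance = 1e-9)

  # forward-pricked and pinned regimes
  expect_equal(equine_pose_features(head_rig(blank_frame(),
                                             ear_deg = 35))[["ear_angle"]],
               35, tolerance = 1e-9)
  expect_identical(ear_regime(35), "forward")
  expect_equal(equine_pose_features(head_rig(blank_frame(),
                                             ear_deg = -25))[["ear_angle"]],
               -25, tolerance = 1e-9)
  expect_identical(ear_regime(-25), "pinned")
  expect_identical(ear_regime(10), "neutral")

  # raised nose gives positive elevation
  fr_up <- head_rig(blank_frame(), C = c(1000, 500),
                    nose = c(1000 + 100 * cos(pi / 6), 500 - 100 * sin(pi / 6)))
  expect_equal(equine_pose_features(fr_up)[["head_elevation"]], 30,
               tolerance = 1e-9)

  # fewer than two visible head keypoints: head features missing
  fr_sparse <- set_pt(blank_frame(), "horse_left_eye", 1000, 500)
  eq_sp <- equine_pose_features(fr_sparse)
  expect_true(is.na(eq_sp[["head_elevation"]]))
  expect_true(is.na(eq_sp[["ear_angle"]]))
  expect_equal(eq_sp[["visible_fraction"]], 1 / 17)
})

test_that("fully occluded frames are missing-flagged with both_detected 0", {
  fe <- extract_features(blank_frame())
  expect_equal(fe$both_detected, 0)
  expect_true(all(is.na(unlist(fe[, setdiff(feature_names(),
                                            "both_detected")]))))
  expect_true(all(attr(fe, "missing_mask")))
})

test_that("normalized features are invariant to uniform frame rescaling", {
  sim <- simulate_dyads(c(affiliative_active = 40, avoidant_horse = 40),
                        n_videos = 2, seed = 8)
  fr <- sim$frames
  s <- 2.7
  sc <- fr
  geo <- c(grep("_(x|y|xmin|xmax|ymin|ymax)$", names(fr), value = TRUE),
           "frame_width", "frame_height")
  for (col in geo) sc[[col]] <- fr[[col]] * s
  f1 <- extract_features(fr)
  f2 <- extract_features(sc)
  expect_equal(as.matrix(f1), as.matrix(f2), tolerance = 1e-9)
})

test_that("relational features are invariant to rigid translation", {
  fr <- head_rig(blank_frame(), ear_deg = 20)
  fr <- set_box(fr, "human", c(500, 600), c(100, 200))
  fr <- set_box(fr, "horse", c(900, 600), c(300, 180))
  fr <- set_pt(fr, "human_left_shoulder", 470, 560)
  fr <- set_pt(fr, "human_right_shoulder", 530, 560)
  tr <- fr
  for (col in grep("_(x|xmin|xmax)$", names(fr), value = TRUE)) {
    tr[[col]] <- fr[[col]] + 40
  }
  for (col in grep("_(y|ymin|ymax)$", names(fr), value = TRUE)) {
    tr[[col]] <- fr[[col]] - 25
  }
  for (feat in c("dist_norm", "shoulder_width", "ear_angle")) {
    expect_equal(extract_features(tr)[[feat]], extract_features(fr)[[feat]],
                 tolerance = 1e-9)
  }
  # positions do move
  expect_false(isTRUE(all.equal(extract_features(tr)$human_cx,
                                extract_features(fr)$human_cx)))
})
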