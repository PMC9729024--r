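test_that("moving distances are trunk-normalised Euclidean steps", {
  # one keypoint moves 3 px between the only two frames, t = 10
  sh <- rbind(c(0, 0), c(0, 0)); hp <- rbind(c(0, 10), c(0, 10))
  still <- rbind(c(5, 5), c(5, 5))
  elbow <- rbind(c(0, 0), c(3, 0))
  task <- make_task(sh, hp, elbow, still, still + 1, still + 2)
  md <- moving_distances(task)
  expect_equal(unname(md$d[1, "elbow"]), 0.3)
  expect_equal(sum(md$d[1, c("wrist", "knee", "ankle")]), 0)
  expect_equal(md$D, 0.3)

  # unit diagonal steps with t = 1
  hp1 <- rbind(c(0, 1), c(0, 1), c(0, 1))
  sh1 <- rbind(c(0, 0), c(0, 0), c(0, 0))
  wrist <- rbind(c(0, 0), c(1, 0), c(1, 1))
  task2 <- make_task(sh1, hp1, sh1, wrist, sh1, sh1)
  expect_equal(moving_distances(task2)$d[, "wrist"], c(1, 1))
})

test_that("SPB indices reduce correctly on constructed postures", {
  task <- make_ideal_task(n = 8)
  md <- moving_distances(task)
  expect_equal(spb1(md), 0)
  expect_equal(spb2(md), 0)
  expect_equal(spb3(task), 0)

  # each keypoint moving 0.1 t per frame: SPB1 = 0.1, SPB2 = 0.4
  n <- 6; t_len <- 100
  sh <- matrix(rep(c(0, 0), each = n), ncol = 2)
  hp <- matrix(rep(c(t_len, 0), each = n), ncol = 2)
  line <- cbind(seq(0, by = 0.1 * t_len, length.out = n), 0)
  task3 <- make_task(sh, hp, line, line + 500, line + 1000, line + 1500)
  md3 <- moving_distances(task3)
  expect_equal(spb1(md3), 0.1)
  expect_equal(spb2(md3), 0.4)
})

test_that("SPB3 equals the square geometry closed form", {
  # each keypoint visits the 4 corners of a t-side square over n = 4 frames
  n <- 4; t_len <- 50
  sh <- matrix(rep(c(0, 0), each = n), ncol = 2)
  hp <- matrix(rep(c(t_len, 0), each = n), ncol = 2)
  sq <- rbind(c(0, 0), c(t_len, 0), c(t_len, t_len), c(0, t_len))
  task <- make_task(sh, hp, sq, sq + 200, sq + 400, sq + 600)
  expect_equal(spb3(task), 1)
  # collinear motion contributes zero area
  lin <- cbind(1:4, 2 * (1:4))
  task2 <- make_task(sh, hp, lin, lin + 10, lin + 20, lin + 30)
  expect_equal(spb3(task2), 0)
  # alternative normalisations
  expect_equal(spb3(task, "none"), 4 * t_len^2 / n)
  expect_equal(spb3(task, "t"), 4 * t_len / n)
})

test_that("AG1 angles follow the unsigned horizontal-deviation definition", {
  expect_equal(ag1(make_ideal_task()), 0)
  # forced 45-degree droop of the arm midline
  task <- make_posture_task(droop = 45)
  th <- ag1_angles(task)
  expect_equal(th$theta1, rep(45, 10), tolerance = 1e-12)
  # raising the arm above horizontal also counts positive (AG1's flaw)
  up <- make_posture_task(droop = -30)
  expect_equal(ag1_angles(up)$theta1, rep(30, 10), tolerance = 1e-12)
  # theta1 ~ 10, theta2 ~ 10 summed and averaged
  expect_equal(ag1(make_posture_task(droop = 10)), 20, tolerance = 1e-12)
})

test_that("AG2/AG3 angles are trunk-referenced and clamped above the joint", {
  # fully extended ideal posture: all four angles zero
  ph <- ag23_angles(make_ideal_task())
  expect_true(all(abs(as.matrix(ph)) < 1e-12))

  # droop 30 with a further 40-degree forearm bend
  task <- make_posture_task(droop = 30, bend = 40)
  ph2 <- ag23_angles(task)
  expect_equal(ph2$phi1, rep(30, 10), tolerance = 1e-12)
  expect_equal(ph2$phi3, rep(40, 10), tolerance = 1e-12)

  # elbow strictly above the shoulder: phi1 clamped to zero
  up <- make_posture_task(droop = -20, bend = 10)
  expect_equal(ag23_angles(up)$phi1, rep(0, 10))
  expect_gt(ag23_angles(up)$phi3[1], 1)
})

test_that("AG2 is the mean and AG3 the max of the summed angles", {
  # droop alternating 10 / 20 degrees: Phi alternates 20 / 40
  a <- make_posture_task(droop = 10, n = 1)
  b <- make_posture_task(droop = 20, n = 1)
  task <- make_task(rbind(a$shoulder, b$shoulder, a$shoulder, b$shoulder),
                    rbind(a$hip, b$hip, a$hip, b$hip),
                    rbind(a$elbow, b$elbow, a$elbow, b$elbow),
                    rbind(a$wrist, b$wrist, a$wrist, b$wrist),
                    rbind(a$knee, b$knee, a$knee, b$knee),
                    rbind(a$ankle, b$ankle, a$ankle, b$ankle))
  expect_equal(ag2(task), 30, tolerance = 1e-12)
  expect_equal(ag3(task), 40, tolerance = 1e-12)
})

test_that("degenerate geometry yields warnings and the unreliable flag", {
  task <- make_posture_task(droop = 10, n = 8)
  # collapse elbow+wrist onto the shoulder in 2 of 8 frames (> 10%)
  task$elbow[1:2, ] <- task$shoulder[1:2, ]
  task$wrist[1:2, ] <- task$shoulder[1:2, ]
  expect_warning(v <- ag1(task), "excluded")
  expect_equal(v, 20, tolerance = 1e-12)
  rep_ <- suppressWarnings(compute_index_report(task))
  expect_true(rep_$unreliable)
})

test_that("index report composes the zero case", {
  trial <- simulate_trial(simulation_params(
    sway_amplitude = 0, droop_deg = 0, bend_deg = 0, dropout_prob = 0,
    outlier_prob = 0, duration_s = 60, seed = 1))
  rep_ <- score_trial(trial$trajectory, "left_arm_right_leg")
  for (f in c("spb1", "spb2", "spb3", "ag1", "ag2", "ag3"))
    expect_equal(rep_[[f]], 0)
  expect_equal(rep_$duration_s, 60)
})

test_that("indices match the brute-force oracles on simulated trials", {
  for (seed in 1:6) {
    trial <- simulate_trial(simulation_params(
      duration_s = runif(1, 2, 6), sway_amplitude = runif(1, 0.002, 0.03),
      droop_deg = runif(1, 0, 35), bend_deg = runif(1, 0, 25),
      dropout_prob = 0, outlier_prob = 0, seed = seed))
    task <- resolve_task_keypoints(trial$trajectory, "left_arm_right_leg")
    md <- moving_distances(task)
    expect_equal(spb1(md), oracle_spb1(task), tolerance = 1e-9)
    expect_equal(spb2(md), oracle_spb2(task), tolerance = 1e-9)
    expect_equal(spb3(task), oracle_spb3(task), tolerance = 1e-9)
    expect_equal(ag1(task), oracle_ag1(task), tolerance = 1e-9)
    o23 <- oracle_ag23(task)
    expect_equal(ag2(task), unname(o23["ag2"]), tolerance = 1e-9)
    expect_equal(ag3(task), unname(o23["ag3"]), tolerance = 1e-9)
  }
})

test_that("indices obey the documented invariances", {
  trial <- simulate_trial(simulation_params(
    duration_s = 3, droop_deg = 18, bend_deg = 10, dropout_prob = 0,
    outlier_prob = 0, seed = 23))
  traj <- trial$trajectory
  base <- compute_index_report(resolve_task_keypoints(traj, "left_arm_right_leg"))
  keys <- c("spb1", "spb2", "spb3", "ag1", "ag2", "ag3")

  shifted <- compute_index_report(resolve_task_keypoints(
    transform_traj(traj, diag(2), c(-321, 87)), "left_arm_right_leg"))
  for (k in keys) expect_equal(shifted[[k]], base[[k]], tolerance = 1e-9)

  scaled <- compute_index_report(resolve_task_keypoints(
    transform_traj(traj, 3.2 * diag(2)), "left_arm_right_leg"))
  for (k in keys) expect_equal(scaled[[k]], base[[k]], tolerance = 1e-9)

  rotated <- compute_index_report(resolve_task_keypoints(
    rotate_traj(traj, 11, c(350, 200)), "left_arm_right_leg"))
  for (k in c("spb1", "spb2", "spb3", "ag2", "ag3"))
    expect_equal(rotated[[k]], base[[k]], tolerance = 1e-9)

  # AG1 references the image horizontal.  For symmetric arm/leg droop the
  # per-limb angle shifts of a rotation cancel in the sum, so the
  # dependence shows when a rotation carries one limb across the
  # horizontal: an upward-bent forearm puts the arm midline just below
  # level, and an 8-degree rotation flips its unsigned angle.
  asym <- simulate_trial(simulation_params(
    duration_s = 2, droop_deg = 12, bend_deg = -30, sway_amplitude = 0.001,
    dropout_prob = 0, outlier_prob = 0, seed = 5))$trajectory
  a_base <- compute_index_report(resolve_task_keypoints(asym, "left_arm_right_leg"))
  a_rot <- compute_index_report(resolve_task_keypoints(
    rotate_traj(asym, 8, c(350, 200)), "left_arm_right_leg"))
  expect_gt(abs(a_rot$ag1 - a_base$ag1), 1)
  expect_equal(a_rot$ag2, a_base$ag2, tolerance = 1e-9)
})

test_that("SPB2 >= 4 SPB1 and AG3 >= AG2 on random trials", {
  for (seed in 1:10) {
    trial <- simulate_trial(simulation_params(
      duration_s = 2, sway_amplitude = runif(1, 0.005, 0.05),
      droop_deg = runif(1, 0, 30), seed = 100 + seed))
    task <- resolve_task_keypoints(trial$trajectory, "left_arm_right_leg")
    md <- moving_distances(task)
    expect_gte(spb2(md), 4 * spb1(md) - 1e-12)
    expect_gte(suppressWarnings(ag3(task)),
               suppressWarnings(ag2(task)) - 1e-12)
  }
})

test_that("index reports serialise to JSON and CSV", {
  trial <- simulate_trial(simulation_params(duration_s = 2, seed = 4))
  rep_ <- score_trial(trial$trajectory, "left_arm_right_leg")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_index_report(rep_, jp)
  write_index_report(rep_, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$spb1, rep_$spb1, tolerance = 1e-9)
  csv <- read.csv(cp)
  expect_equal(csv$ag2, rep_$ag2, tolerance = 1e-9)
  expect_equal(names(csv)[1:8],
               c("side", "spb1", "spb2", "spb3", "ag1", "ag2", "ag3",
                 "duration_s"))
})
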