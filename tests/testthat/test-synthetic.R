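test_that("default flexion waveform has the documented stance/swing shape", {
  grid <- seq(0, 100, length.out = 101)
  flex <- gen_flexion_angle(grid = grid)
  i <- which.max(flex)
  expect_gte(max(flex), 55)
  expect_lte(max(flex), 65)
  expect_gte(grid[i], 65)
  expect_lte(grid[i], 80)
  expect_true(all(flex >= 0 & flex <= 90))

  zero <- waveform_params(baseline = 0)
  expect_equal(gen_flexion_angle(zero, grid), rep(0, 101))
})

test_that("default loads show the two-peak compressive pattern", {
  trial <- cached_trial()
  comp <- -trial$loads$Ry  # compressive (inferior) magnitude
  stance <- which(trial$frame_pct <= 62)
  interior <- stance[-c(1, length(stance))]
  peaks <- interior[vapply(interior, function(i) {
    comp[i] > comp[i - 1] && comp[i] > comp[i + 1]
  }, logical(1))]
  expect_identical(length(peaks), 2L)
  swing <- trial$frame_pct >= 70 & trial$frame_pct <= 90
  expect_lt(max(abs(trial$loads$Ry[swing])), 0.25 * max(comp[stance]))
  # frontal and transverse components are an order smaller than compression
  expect_lt(max(abs(trial$loads$Rz)), 0.2 * max(comp))
  # the sagittal moment is biphasic: both signs occur in stance
  mz <- trial$loads$Mz[stance]
  expect_gt(max(mz), 5)
  expect_lt(min(mz), -5)
})

test_that("load generation is deterministic and noise is seed-driven", {
  W <- 56.4 * 9.81
  grid <- seq(0, 100, length.out = 51)
  quiet <- default_load_params(W)
  expect_identical(gen_resultant_loads(quiet, grid, seed = 1),
                   gen_resultant_loads(quiet, grid, seed = 2))
  noisy <- default_load_params(W, noise_sd = 5)
  a <- gen_resultant_loads(noisy, grid, seed = 1)
  b <- gen_resultant_loads(noisy, grid, seed = 1)
  c <- gen_resultant_loads(noisy, grid, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  zero <- lapply(quiet, function(p) {
    p$bumps$amp <- 0; p$baseline <- 0; p
  })
  z <- gen_resultant_loads(zero, grid)
  expect_true(all(as.matrix(z[, -1]) == 0))
})

test_that("generated geometry is valid and has the right moment-arm signs", {
  trial <- cached_trial()
  for (f in unique(trial$geometry$frame_pct)[c(1, 26, 51, 76, 101)]) {
    g <- trial$geometry[trial$geometry$frame_pct == f, ]
    expect_identical(nrow(validate_frame_geometry(g)), 0L)
    norms <- sqrt(g$lx^2 + g$ly^2 + g$lz^2)
    expect_true(all(abs(norms - 1) <= 1e-9))
  }
  stance <- trial$frame_pct <= 62
  quads <- c("rectus_femoris", "vastus_intermedius", "vastus_medialis",
             "vastus_lateralis")
  hams <- c("semitendinosus", "semimembranosus", "biceps_femoris_long",
            "biceps_femoris_short")
  for (f in trial$frame_pct[stance][c(1, 20, 40, 60)]) {
    g <- trial$geometry[trial$geometry$frame_pct == f, ]
    for (i in seq_len(nrow(g))) {
      mz <- moment_contribution(line_of_action(
        as.numeric(g[i, c("lx", "ly", "lz")]),
        as.numeric(g[i, c("dx", "dy", "dz")])))[3]
      if (g$structure[i] %in% quads) expect_gt(mz, 0)
      if (g$structure[i] %in% hams) expect_lt(mz, 0)
    }
  }
})

test_that("the template at zero flexion matches an independent evaluation", {
  g <- geometry_template(0)
  # rectus femoris: patellar tendon 15 degrees anterior of +y, no z
  phi <- 15 * pi / 180
  expect_equal(as.numeric(g[g$structure == "rectus_femoris",
                            c("lx", "ly", "lz")]),
               c(sin(phi), cos(phi), 0), tolerance = 1e-12)
  expect_equal(as.numeric(g[g$structure == "rectus_femoris",
                            c("dx", "dy", "dz")]),
               c(0.035, -0.030, 0), tolerance = 1e-12)
  # ACL: posterior-superior line through the joint center
  aphi <- -50 * pi / 180
  acl <- c(sin(aphi), cos(aphi), 0.10)
  acl <- acl / sqrt(sum(acl^2))
  expect_equal(as.numeric(g[g$structure == "ACL", c("lx", "ly", "lz")]),
               acl, tolerance = 1e-12)
  expect_equal(as.numeric(g[g$structure == "ACL", c("dx", "dy", "dz")]),
               -0.015 * acl, tolerance = 1e-12)
  expect_equal(
    moment_contribution(line_of_action(acl, -0.015 * acl)), c(0, 0, 0),
    tolerance = 1e-15)
  # medial contact: femur pushing straight down at the medial plateau
  expect_equal(as.numeric(g[g$structure == "contact_medial",
                            c("lx", "ly", "lz")]),
               c(0, -1, 0), tolerance = 1e-12)
  expect_error(geometry_template(120), "0-90")
  expect_error(geometry_template(-5), "0-90")
})

test_that("trials are pure functions of parameters and seed", {
  t1 <- gen_trial(n_frames = 31, seed = 7)
  t2 <- gen_trial(n_frames = 31, seed = 7)
  expect_identical(t1, t2)
  expect_equal(t1$body_weight, 56.4 * 9.81)
  expect_equal(range(t1$frame_pct), c(0, 100))
})

test_that("a written trial round-trips through the package's readers", {
  dir <- withr::local_tempdir()
  trial <- gen_trial(n_frames = 21)
  write_trial(trial, dir)
  back <- read_trial(dir)
  expect_equal(back$loads, trial$loads, tolerance = 1e-12)
  expect_equal(back$flexion_deg, trial$flexion_deg, tolerance = 1e-12)
  expect_equal(back$body_weight, trial$body_weight)
  gb <- back$geometry[order(back$geometry$frame_pct,
                            back$geometry$structure), ]
  gt <- trial$geometry[order(trial$geometry$frame_pct,
                             trial$geometry$structure), ]
  rownames(gb) <- rownames(gt) <- NULL
  expect_equal(gb, gt, tolerance = 1e-12)
})

test_that("the default trial is solvable on at least 95% of frames", {
  cyc <- cached_solutions()[["RFML"]][["J2"]]
  expect_gte(mean(cyc$statuses == "optimal"), 0.95)
})
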