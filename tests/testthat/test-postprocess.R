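fake_solution <- function(forces, formulation = "RM") {
  structure(list(forces = forces, formulation = formulation),
            class = "frame_solution")
}

one_muscle_geometry <- function(l, d) {
  data.frame(structure = "rectus_femoris", kind = "muscle",
             lx = l[1], ly = l[2], lz = l[3],
             dx = d[1], dy = d[2], dz = d[3], stringsAsFactors = FALSE)
}

test_that("unbalanced force is the force-equipollence residual", {
  g <- one_muscle_geometry(c(0, 1, 0), c(0.05, 0, 0))
  sol <- fake_solution(c(rectus_femoris = 100))
  expect_equal(unbalanced_force(sol, g, resultant_load(c(0, 100, 0), rep(0, 3))),
               c(0, 0, 0))
  expect_equal(unbalanced_force(sol, g, resultant_load(c(10, 100, 0), rep(0, 3))),
               c(-10, 0, 0))
})

test_that("unbalanced force equals the assembled force-row residual", {
  set.seed(3)
  props <- muscle_properties()
  for (th in c(5, 25, 55)) {
    g <- geometry_template(th)
    gf <- cbind(frame_pct = 0, g)
    load <- resultant_load(runif(3, -100, 100), runif(3, -10, 10))
    sys <- assemble_equipollence(g, load, formulation("RFML"), props)
    x <- runif(18, 0, 300)
    sol <- fake_solution(stats::setNames(x, sys$labels), "RFML")
    e <- unbalanced_force(sol, g, load)
    resid <- as.numeric(sys$A[sys$force_rows, ] %*% x) - load$force
    expect_equal(e, resid, tolerance = 1e-10)
  }
})

test_that("total ligament force sums the ligament contributions", {
  g <- geometry_template(20)
  forces <- stats::setNames(rep(0, 18), knee_structures()$structure)
  expect_equal(total_ligament_force(fake_solution(forces, "RFML"), g),
               c(0, 0, 0))
  forces["ACL"] <- 50
  l_acl <- as.numeric(g[g$structure == "ACL", c("lx", "ly", "lz")])
  expect_equal(total_ligament_force(fake_solution(forces, "RFML"), g),
               50 * l_acl, tolerance = 1e-12)
  # loop oracle with all four ligaments active
  forces[ligament_names()] <- c(50, 80, 20, 40)
  L <- c(0, 0, 0)
  for (nm in ligament_names()) {
    L <- L + forces[[nm]] * as.numeric(g[g$structure == nm,
                                         c("lx", "ly", "lz")])
  }
  expect_equal(total_ligament_force(fake_solution(forces, "RFML"), g), L,
               tolerance = 1e-12)
  # opposite z-components cancel in z
  g2 <- g
  g2[g2$structure == "MCL", c("lx", "ly", "lz")] <-
    c(0, 1, 0.3) / sqrt(1.09)
  g2[g2$structure == "LCL", c("lx", "ly", "lz")] <-
    c(0, 1, -0.3) / sqrt(1.09)
  f2 <- stats::setNames(rep(0, 18), knee_structures()$structure)
  f2[c("MCL", "LCL")] <- 70
  expect_equal(total_ligament_force(fake_solution(f2, "RFML"), g2)[3], 0,
               tolerance = 1e-12)
  # undefined without ligament variables
  frm <- stats::setNames(rep(0, 14), formulation("RM")$variables)
  expect_error(total_ligament_force(fake_solution(frm, "RM"), g),
               "undefined|ligament")
})

test_that("rms_over_cycle behaves as a per-axis root mean square", {
  expect_equal(rms_over_cycle(cbind(rep(2, 7), 0, 0)), c(2, 0, 0))
  expect_equal(rms_over_cycle(rep(c(1, -1), 10)), 1)
  expect_equal(unname(rms_over_cycle(cbind(x = c(3, 4)))), sqrt(12.5))
  s <- matrix(rnorm(30), 10, 3)
  expect_equal(rms_over_cycle(s), rms_over_cycle(s[sample(10), ]))
  expect_true(all(rms_over_cycle(s) >= 0))
  expect_error(rms_over_cycle(matrix(numeric(), 0, 3)), "at least one")
})

test_that("BW normalization divides by body weight", {
  bw <- 56.4 * 9.81
  expect_equal(to_bw(1107.2, bw), 1107.2 / bw)
  expect_equal(to_bw(1107.2, bw), 2.0, tolerance = 0.01)
  expect_equal(to_bw(0, bw), 0)
  expect_equal(to_bw(bw, bw), 1)
  expect_error(to_bw(1, 0), "positive")
  expect_error(to_bw(1, -5), "positive")
})

test_that("contact peaks are window maxima with locations", {
  grid <- seq(0, 100, by = 1)
  series <- 0.2 + 3.2 * exp(-0.5 * ((grid - 10) / 3)^2) +
    3.5 * exp(-0.5 * ((grid - 40) / 3)^2)
  pk <- extract_contact_peaks(series, grid)
  expect_equal(pk$first_peak_pct, 10)
  expect_equal(pk$second_peak_pct, 40)
  expect_equal(pk$first_peak, max(series[grid <= 30]))
  expect_equal(pk$swing_max, max(series[grid >= 62]))
  expect_lt(pk$swing_max, 0.25)

  const <- rep(1.7, 101)
  pc <- extract_contact_peaks(const, grid)
  expect_equal(c(pc$first_peak, pc$second_peak, pc$swing_max),
               rep(1.7, 3))

  mono <- seq(0, 5, length.out = 101)
  pm <- extract_contact_peaks(mono, grid)
  # exhaustive-scan oracle: maxima sit at the right window edges
  win <- peak_windows()
  for (pair in list(c(pm$first_peak, "first"), c(pm$second_peak, "second"),
                    c(pm$swing_max, "swing"))) {
    rng <- win[[pair[2]]]
    expect_equal(as.numeric(pair[1]),
                 max(mono[grid >= rng[1] & grid <= rng[2]]))
  }
  expect_equal(pm$first_peak_pct, 30)

  expect_error(peak_windows(first = c(-5, 30)), "0-100")
  expect_error(peak_windows(swing = c(80, 70)), "increasing")
})

test_that("the RMS summary table has no empty cells on the default trial", {
  tab <- rms_summary_table(cached_solutions(), cached_trial())
  expect_equal(nrow(tab), 9L)  # 3 quantities x 3 axes
  expect_setequal(unique(tab$quantity),
                  c("e_RM", "e_RML", "L_RML_minus_L_RFML"))
  vals <- as.matrix(tab[, objective_ids()])
  expect_true(all(is.finite(vals)))
  # moment-only formulations leave real force errors on this trial
  expect_gt(max(vals[tab$quantity == "e_RML", ]), 0.1)
})

test_that("contact peak table covers every formulation x criterion", {
  tab <- contact_peak_table(cached_solutions(), cached_trial())
  expect_equal(nrow(tab), 24L)
  expect_true(all(is.finite(tab$first_peak_bw)))
  expect_true(all(tab$n_not_optimal == 0))
})
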