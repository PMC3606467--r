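test_that("moment_contribution computes lever x direction", {
  expect_equal(moment_contribution(line_of_action(c(0, 1, 0), c(0.05, 0, 0))),
               c(0, 0, 0.05))
  expect_equal(moment_contribution(line_of_action(c(1, 0, 0), c(0, 0, 0))),
               c(0, 0, 0))
  l <- c(0.1, 0.9899495, 0.1)
  l <- l / sqrt(sum(l^2))
  d <- c(0.03, -0.02, 0.01)
  expect_equal(moment_contribution(line_of_action(l, d)),
               as.numeric(pracma::cross(d, l)), tolerance = 1e-12)
})

test_that("moment_contribution agrees with an independent cross product", {
  set.seed(42)
  for (k in 1:25) {
    l <- rnorm(3); l <- l / sqrt(sum(l^2))
    d <- runif(3, -0.1, 0.1)
    expect_equal(moment_contribution(line_of_action(l, d)),
                 as.numeric(pracma::cross(d, l)), tolerance = 1e-12)
  }
})

test_that("line_of_action enforces its invariants", {
  expect_error(line_of_action(c(0, 2, 0), c(0, 0, 0)), "unit norm")
  expect_error(line_of_action(c(0, 1, 0), c(1, 0, 0)), "0.5 m")
  expect_error(line_of_action(c(0, 1, NA), c(0, 0, 0)), "finite")
  ok <- line_of_action(c(0, 1, 0), c(0.05, 0, 0))
  expect_s3_class(ok, "line_of_action")
})

test_that("validate_frame_geometry reports exactly the violations", {
  g <- geometry_template(10)
  expect_identical(nrow(validate_frame_geometry(g)), 0L)
  g$ly[g$structure == "ACL"] <- 2          # non-unit direction
  g$dx[g$structure == "MCL"] <- 1          # lever arm out of bounds
  rep <- validate_frame_geometry(g)
  expect_setequal(rep$structure, c("ACL", "MCL"))
  expect_true(any(grepl("unit norm", rep$problem)))
  expect_true(any(grepl("sanity", rep$problem)))
})

test_that("formulations define the study's variable and constraint counts", {
  expect_equal(formulation("RM")$n_vars, 14L)
  expect_equal(formulation("RM")$n_constraints, 3L)
  expect_equal(formulation("RML")$n_vars, 18L)
  expect_equal(formulation("RML")$n_constraints, 3L)
  expect_equal(formulation("RFML")$n_vars, 18L)
  expect_equal(formulation("RFML")$n_constraints, 6L)
  expect_length(muscle_names(), 12L)
  expect_length(ligament_names(), 4L)
  expect_length(contact_names(), 2L)
})

test_that("assembled systems have the documented shape, rhs and bounds", {
  g <- geometry_template(15)
  load <- resultant_load(c(10, -500, 5), c(-20, 1, 18))
  props <- muscle_properties()

  sys <- assemble_equipollence(g, load, formulation("RFML"), props)
  expect_equal(dim(sys$A), c(6L, 18L))
  expect_equal(sys$b, c(load$force, load$moment))
  expect_equal(sys$lower, rep(0, 18))
  expect_equal(unname(sys$upper[sys$kinds != "contact"]), rep(5000, 16))
  expect_equal(unname(sys$upper[sys$kinds == "contact"]), rep(10000, 2))

  sys_rm <- assemble_equipollence(g, load, formulation("RM"), props)
  expect_equal(dim(sys_rm$A), c(3L, 14L))
  expect_equal(sys_rm$b, load$moment)
  expect_false("ACL" %in% sys_rm$labels)

  sys_rml <- assemble_equipollence(g, load, formulation("RML"), props)
  expect_equal(dim(sys_rml$A), c(3L, 18L))
})

test_that("a column stacks the direction over its moment contribution", {
  g <- geometry_template(0)
  i <- which(g$structure == "rectus_femoris")
  g[i, c("lx", "ly", "lz")] <- c(0, 1, 0)
  g[i, c("dx", "dy", "dz")] <- c(0.05, 0, 0)
  sys <- assemble_equipollence(g, resultant_load(rep(0, 3), rep(0, 3)),
                               formulation("RFML"), muscle_properties())
  expect_equal(unname(sys$A[, "rectus_femoris"]), c(0, 1, 0, 0, 0, 0.05))
})

test_that("A x reproduces the per-structure force and moment sums", {
  set.seed(7)
  g <- geometry_template(35)
  load <- resultant_load(c(5, -300, 2), c(-15, 0.5, 10))
  sys <- assemble_equipollence(g, load, formulation("RFML"),
                               muscle_properties())
  x <- runif(18, 0, 200)
  # loop oracle: explicit summation over structures
  fsum <- c(0, 0, 0); msum <- c(0, 0, 0)
  for (j in seq_len(18)) {
    i <- which(g$structure == sys$labels[j])
    l <- as.numeric(g[i, c("lx", "ly", "lz")])
    d <- as.numeric(g[i, c("dx", "dy", "dz")])
    fsum <- fsum + x[j] * l
    msum <- msum + x[j] * as.numeric(pracma::cross(d, l))
  }
  Ax <- as.numeric(sys$A %*% x)
  expect_equal(Ax[sys$force_rows], fsum, tolerance = 1e-12)
  expect_equal(Ax[sys$moment_rows], msum, tolerance = 1e-12)
})

test_that("column order is canonical and RFML nests RML's rows", {
  props <- muscle_properties()
  load <- resultant_load(c(0, -100, 0), c(-5, 0, 5))
  canon <- knee_structures()$structure
  for (th in c(0, 20, 60)) {
    g <- geometry_template(th)
    s_rfml <- assemble_equipollence(g, load, formulation("RFML"), props)
    s_rml <- assemble_equipollence(g, load, formulation("RML"), props)
    s_rm <- assemble_equipollence(g, load, formulation("RM"), props)
    expect_identical(s_rfml$labels, canon)
    expect_identical(s_rml$labels, canon)
    expect_identical(s_rm$labels, canon[knee_structures()$kind != "ligament"])
    # RFML's bottom three rows are RML's moment rows on the same columns
    expect_equal(s_rfml$A[4:6, ], s_rml$A, tolerance = 1e-15)
  }
})

test_that("missing geometry and bad inputs raise informative errors", {
  g <- geometry_template(10)
  g <- g[g$structure != "LCL", ]
  expect_error(
    assemble_equipollence(g, resultant_load(rep(0, 3), rep(0, 3)),
                          formulation("RFML"), muscle_properties()),
    "LCL")
  expect_error(resultant_load(c(1, 2), c(0, 0, 0)), "length-3")
  expect_error(resultant_load(c(1, 2, Inf), c(0, 0, 0)), "finite")
  expect_error(muscle_properties(pcsa = c(rectus_femoris = 10)), "missing")
  expect_error(muscle_properties(force_upper_bound = -1), "force_upper_bound")
})
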