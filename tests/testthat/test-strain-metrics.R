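test_that("index extraction matches the analytic piecewise-linear cases", {
  # plain fall: 0% at t=0 to -20% at 0.30 s, constant to 0.50 s
  tr <- pwTrace(c(0, 0.30, 0.50), c(0, -20, -20), t_pvc = 0.35, T = 0.50)
  ix <- extractIndices(tr, "RV_mid")
  expect_equal(ix$t50, 0.15, tolerance = 1e-9)
  expect_equal(ix$t10, 0.03, tolerance = 1e-9)
  expect_equal(ix$t90, 0.27, tolerance = 1e-9)
  expect_equal(ix$peak_strain, -20)
  expect_equal(ix$systolic_strain, -20)
  expect_equal(ix$post_systolic_strain, 0)
  expect_equal(ix$prestretch, 0)
  expect_false(ix$degenerate)

  # initial bump to +2% at 0.05 s before the fall
  tr2 <- pwTrace(c(0, 0.05, 0.30, 0.50), c(0, 2, -20, -20),
                 t_pvc = 0.35, T = 0.50)
  ix2 <- extractIndices(tr2, "IVS")
  expect_equal(ix2$prestretch, 2, tolerance = 1e-9)
  # span = 22; t10 crosses 2 - 2.2 = -0.2% on the fall of slope -88 %/s
  expect_equal(ix2$t10, 0.05 + 2.2 / 88, tolerance = 1e-6)

  # flat curve is degenerate, not an error
  tr3 <- pwTrace(c(0, 0.5), c(0, 0), t_pvc = 0.3, T = 0.5)
  ix3 <- extractIndices(tr3, "LVfw")
  expect_true(ix3$degenerate)
  expect_equal(ix3$prestretch, 0)
  expect_equal(ix3$peak_strain, 0)
  expect_equal(ix3$t50, 0)

  # unknown segment errors
  expect_error(extractIndices(tr, "RV_all"), "segment")
})

test_that("fit window runs from QRS onset to 50% relaxation of global RV strain", {
  # triangle: 0 -> -20% at 0.35 s -> 0 at 0.70 s
  tr <- pwTrace(c(0, 0.35, 0.70), c(0, -20, 0), t_pvc = 0.40, T = 0.70)
  w <- fitWindow(tr)
  expect_equal(w$t_start, 0)
  expect_equal(w$t_end, 0.525, tolerance = 1e-9)
  # identical segments: global equals each segment, same window
  expect_equal(rowMeans(tr$strain[, 1:3]), tr$strain[, "RV_apex"])
  # monotone non-recovering curve falls back to t_end = T
  tr2 <- pwTrace(c(0, 0.70), c(0, -20), t_pvc = 0.40, T = 0.70)
  expect_warning(w2 <- fitWindow(tr2), "relax")
  expect_equal(w2$t_end, 0.70)
})

test_that("area error obeys its closed forms and quadratic scaling", {
  t <- seq(0, 1, by = 0.001)
  y <- -15 * sin(pi * t)^2
  w <- list(t_start = 0, t_end = 0.4)
  expect_equal(segmentAreaError(t, y, t, y, w), 0)
  # constant 1% offset over a 0.4 s window integrates to 0.4
  expect_equal(segmentAreaError(t, y + 1, t, y, w), 0.4, tolerance = 1e-9)
  # halving the offset quarters the error
  expect_equal(segmentAreaError(t, y + 0.5, t, y, w), 0.1, tolerance = 1e-9)
  # empty or unsupported windows are errors
  expect_error(segmentAreaError(t, y, t, y, list(t_start = 0.5, t_end = 0.2)),
               "empty")
  expect_error(segmentAreaError(t, y, t, y, list(t_start = 2, t_end = 3)),
               "support")
})

test_that("total error sums segment areas plus the cycle-time penalty", {
  tr <- pwTrace(c(0, 0.35, 0.70), c(0, -20, 0), t_pvc = 0.40, T = 0.70)
  expect_equal(totalError(tr, tr), 0)
  # identical strain, cycle time differing by 1 s: E_SS = beta = 0.1
  trLong <- pwTrace(c(0, 0.35, 0.70, 1.70), c(0, -20, 0, 0),
                    t_pvc = 0.40, T = 1.70)
  expect_equal(totalError(trLong, tr), 0.1, tolerance = 1e-6)
  # crashed forward model evaluates to infinite error
  crashed <- structure(list(status = "crashed", trace = NULL),
                       class = "model_result")
  expect_identical(totalError(crashed, tr), Inf)
  # refining the sampling changes the result by less than 0.1%
  sp <- defaultRegistry()
  x <- referencePoint(sp); x["SfAct_RV_base"] <- 0.25
  mod <- evaluateModel(x, sp)$trace
  e1 <- totalError(mod, tr)
  trFine <- pwTrace(c(0, 0.35, 0.70), c(0, -20, 0), t_pvc = 0.40, T = 0.70,
                    dt = 0.0002)
  e2 <- totalError(mod, trFine)
  expect_lt(abs(e2 - e1) / e1, 1e-3)
})

test_that("index extraction is invariant to the absolute time origin convention", {
  # indices are reported relative to QRS onset; a trace sampled on a
  # finer grid with the same morphology yields the same indices
  tr <- pwTrace(c(0, 0.05, 0.30, 0.50), c(0, 2, -20, -20),
                t_pvc = 0.35, T = 0.50, dt = 0.001)
  trF <- pwTrace(c(0, 0.05, 0.30, 0.50), c(0, 2, -20, -20),
                 t_pvc = 0.35, T = 0.50, dt = 0.00025)
  ia <- extractIndices(tr, "RV_apex"); ib <- extractIndices(trF, "RV_apex")
  for (f in c("t10", "t50", "t90", "prestretch", "peak_strain",
              "systolic_strain", "post_systolic_strain"))
    expect_equal(ia[[f]], ib[[f]], tolerance = 1e-6)
})
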