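test_that("identical RV parameters give identical RV traces and the mean follows the global drive", {
  sp <- defaultRegistry()
  res <- evaluateModel(referencePoint(sp), sp)
  expect_identical(res$status, "ok")
  tr <- res$trace
  # at the reference point all three RV segments share parameters
  expect_equal(tr$strain[, "RV_mid"], tr$strain[, "RV_apex"], tolerance = 1e-12)
  expect_equal(tr$strain[, "RV_base"], tr$strain[, "RV_apex"], tolerance = 1e-12)
  # the RV mean is pinned to the global waveform: perturbing tissue
  # parameters redistributes strain between segments without moving it
  g0 <- rowMeans(tr$strain[, c("RV_apex", "RV_mid", "RV_base")])
  x <- referencePoint(sp)
  x["SfAct_RV_base"] <- 0.2
  x["dT_RV_mid"] <- 0.8
  x["kLin_RV_apex"] <- 0.7
  tr2 <- evaluateModel(x, sp)$trace
  g2 <- rowMeans(tr2$strain[, c("RV_apex", "RV_mid", "RV_base")])
  expect_lt(max(abs(g2 - g0)), 1e-9)
})

test_that("a late-activated segment is stretched early and peaks later", {
  sp <- defaultRegistry()
  x <- referencePoint(sp)
  # dT = 60 ms for RV_base, 0 for the others (wide range -0.05..0.12 s)
  x["dT_RV_base"] <- (0.06 - (-0.05)) / (0.12 - (-0.05))
  x["dT_RV_mid"] <- (0 - (-0.05)) / (0.12 - (-0.05))
  tr <- evaluateModel(x, sp)$trace
  # independent closed-form oracle for three equal-k, equal-c segments:
  # u_delayed - G = (c/3k) (a1 + a2 + a3) - (c/k) a_delayed, so while the
  # delayed segment is inactive its strain is G + (2c/3k) a_active > 0
  # as soon as the activation term outgrows the drive
  avd <- 0.02
  early <- tr$t > avd + 0.005 & tr$t < avd + 0.055
  expect_true(any(tr$strain[early, "RV_base"] > 0.1))
  # others are not stretched then
  expect_true(all(tr$strain[early, "RV_apex"] <= 1e-9))
  # delayed peak shortening
  tPeak <- function(seg) tr$t[which.min(tr$strain[, seg])]
  expect_gt(tPeak("RV_base"), tPeak("RV_apex"))
  expect_gt(tPeak("RV_base"), tPeak("RV_mid"))
})

test_that("contractility responses match the disease phenomenology", {
  sp <- defaultRegistry()
  # increasing a segment's contractility never weakens its peak strain
  peaks <- sapply(seq(0.2, 0.8, by = 0.15), function(v) {
    x <- referencePoint(sp)
    x["SfAct_RV_base"] <- v
    min(evaluateModel(x, sp)$trace$strain[, "RV_base"])
  })
  expect_true(all(diff(peaks) <= 1e-9))
  # a weakened segment shows the pre-stretch phenotype
  x <- referencePoint(sp)
  x["SfAct_RV_base"] <- normalizeParams(sp, {
    p <- denormalizeParams(sp, referencePoint(sp)); p["SfAct_RV_base"] <- 60; p
  })[["SfAct_RV_base"]]
  tr <- evaluateModel(x, sp)$trace
  ix <- extractIndices(tr, "RV_base")
  expect_gt(ix$prestretch, 1)
  # and a reduced magnitude of peak strain versus its neighbours
  expect_gt(ix$peak_strain, min(tr$strain[, "RV_apex"]))
})

test_that("evaluation is pure and placeholders are no-ops", {
  sp <- defaultRegistry()
  x <- referencePoint(sp)
  r1 <- evaluateModel(x, sp)
  r2 <- evaluateModel(x, sp)
  expect_identical(r1$trace$strain, r2$trace$strain)
  y <- x
  y["res1_RV_base"] <- 0.93
  y["res2_IVS"] <- 0.11
  y["glob07"] <- 0.99
  r3 <- evaluateModel(y, sp)
  expect_identical(r3$trace$strain, r1$trace$strain)
})

test_that("crash predicate fires only in the weak-stiff over-driven corner", {
  sp <- defaultRegistry()
  x <- referencePoint(sp)
  x["kLin_RV_base"] <- 0.0
  x["SfAct_RV_base"] <- 0.95
  res <- evaluateModel(x, sp)
  expect_identical(res$status, "crashed")
  expect_null(res$trace)
  # one condition alone does not crash
  x2 <- referencePoint(sp); x2["kLin_RV_base"] <- 0.0
  expect_identical(evaluateModel(x2, sp)$status, "ok")
  # out-of-bounds is an error, not a crash
  x3 <- referencePoint(sp); x3[1] <- 1.2
  expect_error(evaluateModel(x3, sp), "outside")
  # crash region occupies a few percent of the hypercube
  set.seed(5)
  cfg <- toyModelConfig()
  hits <- mean(replicate(4000, {
    strainreduce:::crashPredicate(
      stats::setNames(runif(sp$D), paramNames(sp)), cfg)
  }))
  expect_gt(hits, 0.01)
  expect_lt(hits, 0.06)
})

test_that("event times follow their definitions", {
  sp <- defaultRegistry()
  x <- referencePoint(sp)
  ev <- eventTimes(x, sp)
  phys <- denormalizeParams(sp, x)
  expect_equal(ev$t_qrs, 0)
  expect_equal(ev$t_pvc - ev$t_qrs - phys[["AVdelay"]],
               phys[["relSysDur"]] * ev$T)
  # doubling the cycle time at fixed relative systole doubles T_sys
  xLo <- x; xLo["cycleTime"] <- 0   # maps to the 0.6 s bound
  xHi <- x; xHi["cycleTime"] <- 1   # maps to the 1.2 s bound
  evLo <- eventTimes(xLo, sp); evHi <- eventTimes(xHi, sp)
  expect_equal(evLo$T, 0.6)
  expect_equal(evHi$T, 1.2)
  expect_equal(evHi$t_pvc - phys[["AVdelay"]],
               2 * (evLo$t_pvc - phys[["AVdelay"]]))
})
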