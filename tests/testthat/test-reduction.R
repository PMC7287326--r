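test_that("diaphony ranking is ascending in the subject maximum with stable ties", {
  dia <- matrix(c(0.1, 0.0, 0.9, 0.2, 1.0, 0.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("pA", "pB", "pC"), NULL))
  r <- rankParameters(dia)
  # pC is ranked by its maximum (1.0) despite a zero entry
  expect_identical(r$name, c("pA", "pB", "pC"))
  expect_equal(r$max_diaphony, c(0.1, 0.9, 1.0))
  # ties keep registry (row) order
  diaT <- matrix(0.5, 2, 2, dimnames = list(c("q1", "q2"), NULL))
  expect_identical(rankParameters(diaT)$name, c("q1", "q2"))
  expect_error(rankParameters(matrix(c(0.1, NA), 1)), "missing")
})

test_that("reduction proposals omit the lowest-ranked parameters reversibly", {
  sp <- compactRegistry()
  mask <- subsetMask(sp, paramNames(sp))
  ranked <- data.frame(name = paramNames(sp),
                       max_diaphony = seq(0, 1, length.out = sp$D))
  expect_error(proposeReduction(sp, mask, ranked, 0), "kOmit")
  expect_error(proposeReduction(sp, mask, ranked, sp$D), "kOmit")
  m2 <- proposeReduction(sp, mask, ranked, 3)
  expect_length(m2$active, sp$D - 3L)
  expect_false(any(ranked$name[1:3] %in% m2$active))
  # restoring the omitted parameters recovers the original subset
  m3 <- subsetMask(sp, union(m2$active, ranked$name[1:3]))
  expect_setequal(m3$active, mask$active)
})

test_that("validation accepts harmless omissions and rejects losing a disease parameter", {
  sp <- compactRegistry()
  model <- makeToyModel(sp)
  # two noiseless subjects that differ only in basal contractility
  mkSubject <- function(sfact) {
    x <- referencePoint(sp)
    x["SfAct_RV_base"] <- sfact
    model(x)$trace
  }
  subjects <- list(mkSubject(0.15), mkSubject(0.30))
  active <- c("SfAct_RV_base", "dT_RV_base", "glob01")
  mask <- subsetMask(sp, active)
  pts <- sobolPoints(512, 3)
  colnames(pts) <- mask$active
  q <- evaluateCohort(pts, model, subjects, sp, mask, Nb = 40)
  psoCfg <- psoConfig(maxIter = 60)
  # identity reduction: ratio is 1, accepted
  same <- validateReduction(sp, mask, mask, subjects, model, q,
                            psoCfg = psoCfg, seedRoot = 5)
  expect_true(same$accepted)
  expect_equal(same$ratio, 1, tolerance = 1e-9)
  # dropping the placeholder leaves the fit intact
  mNoop <- subsetMask(sp, setdiff(active, "glob01"))
  vNoop <- validateReduction(sp, mask, mNoop, subjects, model, q,
                             psoCfg = psoCfg, seedRoot = 5,
                             beforeFit = same$before)
  expect_true(vNoop$accepted)
  # dropping the contractility parameter that separates the subjects
  # degrades the cohort fit beyond the tolerance
  mBad <- subsetMask(sp, setdiff(active, "SfAct_RV_base"))
  vBad <- validateReduction(sp, mask, mBad, subjects, model, q,
                            psoCfg = psoCfg, seedRoot = 5,
                            beforeFit = same$before)
  expect_false(vBad$accepted)
  expect_gt(vBad$ratio, 1.5)
})

test_that("the reduction loop respects the floor and keeps its audit trail consistent", {
  sp <- compactRegistry()
  model <- makeToyModel(sp)
  cohort <- makeCohort(sp, n = 3,
                       stageMix = c(concealed = 1, electrical = 1,
                                    structural = 1),
                       seed = 300)
  mask0 <- subsetMask(sp, paramNames(sp))
  # floor at the full size: no rounds at all
  recNull <- runReduction(sp, mask0, cohort, model,
                          config = reductionConfig(nQmc = 256, floor = sp$D),
                          seed = 4)
  expect_length(recNull$rounds, 0L)
  expect_identical(recNull$final_mask$active, mask0$active)
  # a short desk-scale run: accepted rounds shrink monotonically and
  # never degrade the mean error beyond the tolerance
  cfg <- reductionConfig(nQmc = 2048, Nb = 40, floor = 10, maxRounds = 3,
                         pso = psoConfig(maxIter = 60))
  rec <- runReduction(sp, mask0, cohort, model, config = cfg, seed = 4)
  expect_gt(length(rec$rounds), 0L)
  sizes <- length(mask0$active)
  for (r in rec$rounds) {
    expect_true(all(r$subset_after %in% r$subset_before))
    if (r$accepted) {
      expect_lt(length(r$subset_after), length(r$subset_before))
      expect_lte(mean(r$pso_after),
                 (1 + cfg$tol) * mean(r$pso_before) + 1e-12)
    }
  }
  accepted <- Filter(function(r) r$accepted, rec$rounds)
  accSizes <- vapply(accepted, function(r) length(r$subset_after), 1L)
  expect_true(all(diff(c(sp$D, accSizes)) < 0))
  expect_identical(rec$final_mask$active,
                   accepted[[length(accepted)]]$subset_after)
})
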