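test_that("the noiseless limit reproduces the model trace exactly", {
  sp <- compactRegistry()
  noise0 <- cohortNoiseConfig(frameRate = 500, noiseSd = 0, driftMax = 0)
  cohort <- makeCohort(sp, n = 2,
                       stageMix = c(concealed = 1, structural = 1),
                       noise = noise0, seed = 8)
  for (s in cohort) {
    tr <- evaluateModel(s$truth, sp)$trace
    # frame interval 1/500 s equals the model step: grids coincide
    expect_equal(s$trace$t, tr$t, tolerance = 1e-12)
    expect_equal(s$trace$strain, tr$strain, tolerance = 1e-12)
    expect_equal(s$trace$T, tr$T)
  }
})

test_that("cohorts are reproducible and stage archetypes shape the truth", {
  sp <- compactRegistry()
  c1 <- makeCohort(sp, n = 6,
                   stageMix = c(concealed = 2, electrical = 2,
                                structural = 2), seed = 15)
  c2 <- makeCohort(sp, n = 6,
                   stageMix = c(concealed = 2, electrical = 2,
                                structural = 2), seed = 15)
  expect_identical(lapply(c1, `[[`, "truth"), lapply(c2, `[[`, "truth"))
  expect_identical(c1[[1]]$trace$strain, c2[[1]]$trace$strain)
  stages <- vapply(c1, `[[`, "", "stage")
  expect_identical(sum(stages == "structural"), 2L)
  # electrical: delayed basal activation; structural: weak basal wall
  el <- c1[stages == "electrical"][[1]]
  expect_gt(el$truth[["dT_RV_base"]], 0.7)
  st <- c1[stages == "structural"][[1]]
  expect_lt(st$truth[["SfAct_RV_base"]], 0.35)
  expect_gt(st$truth[["kLin_RV_base"]], 0.6)
})

test_that("structural subjects show basal pre-stretch in the measurement", {
  sp <- compactRegistry()
  noise0 <- cohortNoiseConfig(noiseSd = 0, driftMax = 0)
  cohort <- makeCohort(sp, n = 3, stageMix = c(structural = 3),
                       noise = noise0, seed = 23)
  for (s in cohort) {
    ix <- extractIndices(s$trace, "RV_base")
    expect_gt(ix$prestretch, 1)
  }
})

test_that("measurement error calibration: less noise, smaller fit error", {
  sp <- compactRegistry()
  mkErr <- function(sd) {
    cohort <- makeCohort(sp, n = 4,
                         stageMix = c(concealed = 2, structural = 2),
                         noise = cohortNoiseConfig(noiseSd = sd,
                                                   driftMax = 0.2),
                         seed = 77)
    mean(vapply(cohort, function(s)
      totalError(evaluateModel(s$truth, sp), s$trace), numeric(1)))
  }
  expect_lt(mkErr(0.1), mkErr(1.0))
})

test_that("strain indices separate structural from concealed subjects", {
  sp <- compactRegistry()
  set.seed(99)
  cohort <- makeCohort(sp, n = 30,
                       stageMix = c(concealed = 15, structural = 15),
                       seed = 99)
  # structural disease affects the mid and basal segments jointly, so
  # the classifier sees pre-stretch and peak strain of both
  feat <- t(vapply(cohort, function(s) {
    ib <- extractIndices(s$trace, "RV_base")
    im <- extractIndices(s$trace, "RV_mid")
    c(psB = ib$prestretch, pkB = ib$peak_strain,
      psM = im$prestretch, pkM = im$peak_strain)
  }, numeric(4)))
  lab <- as.integer(vapply(cohort, `[[`, "", "stage") == "structural")
  df <- data.frame(feat, lab = lab)
  loo <- vapply(seq_along(lab), function(i) {
    f <- suppressWarnings(glm(lab ~ psB + pkB + psM + pkM,
                              family = binomial, data = df[-i, ]))
    p <- suppressWarnings(predict(f, newdata = df[i, , drop = FALSE],
                                  type = "response"))
    (p > 0.5) == lab[i]
  }, logical(1))
  expect_gt(mean(loo), 0.9)
})

test_that("cohort serialization round-trips through the CSV dialect", {
  sp <- compactRegistry()
  cohort <- makeCohort(sp, n = 2,
                       stageMix = c(concealed = 1, electrical = 1),
                       seed = 31)
  dir <- withr::local_tempdir()
  writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "S01.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- readStrainCsv(file.path(dir, "S02.csv"))
  expect_equal(back$strain, cohort[[2]]$trace$strain, tolerance = 1e-9)
  expect_equal(back$T, cohort[[2]]$trace$T)
})
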