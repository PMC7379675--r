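# Dose grids in these tests are scaled to the fixture's nanoscopic mass so
# calibrated primary counts stay well above one (see the methods vignette).
deskDoses <- c(1e5, 2e5, 4e5, 6e5, 8e5)

test_that("P(DSB) statistics follow the SEM definition", {
  st <- estimatePdsb(c(1, 0, 0, 0))
  expect_equal(st$p_dsb, 0.25)
  expect_equal(st$sem, 0.25)   # SD of {1,0,0,0} is 0.5; 0.5/sqrt(4)
  expect_equal(st$n_replicates, 4L)

  allFalse <- estimatePdsb(rep(FALSE, 10))
  expect_equal(allFalse$p_dsb, 0)
  expect_equal(allFalse$sem, 0)

  expect_error(estimatePdsb(TRUE), "2 replicates")

  # closed form sqrt(p(1-p) n/(n-1))/sqrt(n) on random flag lists
  set.seed(4)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    flags <- stats::runif(n) < stats::runif(1)
    st <- estimatePdsb(flags)
    p <- mean(flags)
    expect_equal(st$sem, sqrt(p * (1 - p) * n / (n - 1)) / sqrt(n),
                 tolerance = 1e-12)
  }
})

test_that("replicate estimate recovers a known Bernoulli rate", {
  set.seed(123)
  flags <- stats::rbinom(1000, 1, 0.043)
  st <- estimatePdsb(flags)
  expect_lt(abs(st$p_dsb - 0.043), 3 * sqrt(0.043 * 0.957 / 1000))
})

test_that("quadratic fit recovers exact coefficients and rejects rank deficiency", {
  d <- c(10, 20, 40, 80, 160)
  exact <- data.frame(dose_gy = d, p_dsb = 2e-3 * d)
  fit <- fitDoseResponse(exact)
  cf <- coefficients3(fit)
  expect_equal(unname(cf), c(0, 2e-3, 0), tolerance = 1e-12)

  shuffled <- exact[c(3, 1, 5, 2, 4), ]
  expect_equal(coefficients3(fitDoseResponse(shuffled)), cf, tolerance = 1e-12)

  expect_error(fitDoseResponse(data.frame(dose_gy = c(1, 1, 2),
                                          p_dsb = c(0, 0, 1))),
               "3 distinct doses")
})

test_that("fit on the packaged dosimeter table matches the normal-equations oracle", {
  tab <- loadExperimentalTable()
  X <- cbind(tab$dose_gy^2, tab$dose_gy, 1)
  beta <- solve(t(X) %*% X, t(X) %*% tab$p_dsb)[, 1]
  fit <- fitDoseResponse(tab)
  cf <- coefficients3(fit)
  expect_equal(unname(cf), unname(beta), tolerance = 1e-10)
  expect_equal(signif(cf[["b"]], 2), 1.7e-3)
  expect_equal(predictPdsb(fit, tab$dose_gy), tab$p_dsb - fit@residuals,
               tolerance = 1e-12)
})

test_that("experimental table loads, validates, and round-trips", {
  tab <- loadExperimentalTable()
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$dose_gy, c(25, 50, 100, 150, 200))
  expect_true(all(tab$p_dsb >= 0 & tab$p_dsb <= 1))
  expect_identical(unique(tab$source), "experiment")

  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[, c("dose_gy", "p_dsb", "sem")], f, row.names = FALSE)
  again <- loadExperimentalTable(f)
  expect_equal(again$dose_gy, tab$dose_gy)
  expect_equal(again$p_dsb, tab$p_dsb)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("dose_gy,p_dsb,sem", f2)
  expect_error(loadExperimentalTable(f2), "empty")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dose,p", "1,2"), f3)
  expect_error(loadExperimentalTable(f3), "format")
})

test_that("simulation vs experiment comparison reports per-dose differences", {
  tab <- loadExperimentalTable()
  same <- compareToExperiment(tab, tab)
  expect_equal(same$perDose$abs_diff, rep(0, 5))
  expect_equal(same$maxAbsDiff, 0)

  shifted <- tab
  shifted$p_dsb <- tab$p_dsb + 0.01
  cmp <- compareToExperiment(shifted, tab)
  expect_equal(cmp$perDose$abs_diff, rep(0.01, 5), tolerance = 1e-12)
  expect_equal(cmp$perDose$rel_diff, 0.01 / tab$p_dsb, tolerance = 1e-12)

  # fitted-curve predictions differ from the table by exactly the residuals
  fit <- fitDoseResponse(tab)
  pred <- data.frame(dose_gy = tab$dose_gy, p_dsb = predictPdsb(fit, tab$dose_gy))
  cmpFit <- compareToExperiment(pred, tab)
  expect_equal(cmpFit$perDose$abs_diff, abs(fit@residuals), tolerance = 1e-12)

  expect_error(compareToExperiment(tab[-1, ], tab), "dose mismatch")
})

test_that("dose series is deterministic, monotone within error, and well-formed", {
  g <- buildBdnaFixture(20)
  s <- synthLinacSpectrum()
  p <- defaultPhysicsParams()
  params <- damageParams()
  pts <- runDoseSeries(g, s, p, params, deskDoses, nReplicates = 80,
                       baseSeed = 42, pilotPrimaries = 1500)
  expect_equal(nrow(pts), 5L)
  expect_true(all(pts$p_dsb >= 0 & pts$p_dsb <= 1))
  expect_true(all(pts$sem >= 0))
  expect_true(all(pts$n_primaries >= 1))
  expect_identical(pts$n_primaries, sort(pts$n_primaries))

  # monotone non-decreasing in dose within 3 combined SEM
  for (i in seq_len(nrow(pts) - 1)) {
    slack <- 3 * sqrt(pts$sem[i]^2 + pts$sem[i + 1]^2)
    expect_gte(pts$p_dsb[i + 1] - pts$p_dsb[i], -slack)
  }

  again <- runDoseSeries(g, s, p, params, deskDoses, nReplicates = 80,
                         baseSeed = 42, pilotPrimaries = 1500)
  expect_identical(pts, again)
})

test_that("a 1x1x1 threshold scan reduces to the dose-series estimate", {
  g <- buildBdnaFixture(20)
  s <- synthLinacSpectrum()
  p <- defaultPhysicsParams()
  scan <- scanThresholds(g, s, p, etValues = 19, bptValues = 10,
                         doses = deskDoses[3], nReplicates = 40,
                         baseSeed = 7, pilotPrimaries = 1500)
  pts <- runDoseSeries(g, s, p, damageParams(19, 10), deskDoses[3],
                       nReplicates = 40, baseSeed = 7, pilotPrimaries = 1500)
  expect_equal(scan@pDsb[1, 1, 1], pts$p_dsb)
  expect_equal(scan@sem[1, 1, 1], pts$sem)
  expect_error(scanThresholds(g, s, p, numeric(0), 10, 100,
                              nReplicates = 2), "non-empty")
})

test_that("threshold scans are exactly monotone on shared event streams", {
  g <- buildBdnaFixture(20)
  scan <- scanThresholds(g, synthLinacSpectrum(), defaultPhysicsParams(),
                         etValues = c(10, 19), bptValues = c(6, 14),
                         doses = deskDoses[c(3, 5)], nReplicates = 40,
                         baseSeed = 3, pilotPrimaries = 1500)
  # non-increasing in ET, non-decreasing in BPT, for every (BPT, dose) cell
  expect_true(all(scan@pDsb[1, , ] >= scan@pDsb[2, , ]))
  expect_true(all(scan@pDsb[, 2, ] >= scan@pDsb[, 1, ]))
})

test_that("the full pipeline writes byte-identical outputs under one seed", {
  g <- buildBdnaFixture(20)
  s <- synthLinacSpectrum()
  p <- defaultPhysicsParams()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- runPipeline(g, s, p, damageParams(), deskDoses[c(1, 3, 5)],
                    nReplicates = 30, baseSeed = 11, pilotPrimaries = 1500,
                    outDir = d1)
  r2 <- runPipeline(g, s, p, damageParams(), deskDoses[c(1, 3, 5)],
                    nReplicates = 30, baseSeed = 11, pilotPrimaries = 1500,
                    outDir = d2)
  b1 <- readBin(file.path(d1, "points.csv"), "raw",
                file.size(file.path(d1, "points.csv")))
  b2 <- readBin(file.path(d2, "points.csv"), "raw",
                file.size(file.path(d2, "points.csv")))
  expect_identical(b1, b2)
  expect_identical(r1$points, r2$points)
  expect_true(file.exists(file.path(d1, "fit.json")))
  expect_true(file.exists(file.path(d1, "run_log.txt")))
})
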