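#' P(DSB) statistics from replicate outcomes
#'
#' The break probability is the fraction of replicate molecules destroyed;
#' its uncertainty is the standard error of the mean, SEM = SD / sqrt(N),
#' with SD the sample standard deviation (N - 1 denominator) of the 0/1
#' outcomes.
#'
#' @param brokenFlags logical (or 0/1) vector, one entry per replicate
#'   molecule; at least 2 replicates (SD is undefined otherwise).
#' @return data.frame with \code{p_dsb}, \code{sem}, \code{n_replicates}.
#' @examples
#' estimatePdsb(c(TRUE, FALSE, FALSE, FALSE))   # p = 0.25, sem = 0.25
#' @export
estimatePdsb <- function(brokenFlags) {
  x <- as.numeric(brokenFlags)
  n <- length(x)
  if (n < 2L) stop("at least 2 replicates required (SD undefined)")
  data.frame(p_dsb = mean(x), sem = stats::sd(x) / sqrt(n), n_replicates = n)
}

#' Seed-replicated dose series
#'
#' For each requested dose: the primary count is calibrated from a pilot
#' exposure ([calibratePrimaries()]), then \code{nReplicates} independent
#' exposures are run with seeds \code{baseSeed + 1, ..., baseSeed +
#' nReplicates} (the pilot uses \code{baseSeed} itself), each scored by
#' [scoreMolecule()], and the broken fractions summarized by
#' [estimatePdsb()].
#'
#' @param geometry a \linkS4class{DnaGeometry}.
#' @param spec a \linkS4class{SpectrumHistogram}.
#' @param phys a \linkS4class{PhysicsParams}.
#' @param params a \linkS4class{DamageParams}.
#' @param doses absorbed doses, Gy.
#' @param nReplicates replicate molecules per dose (>= 2).
#' @param baseSeed integer base seed.
#' @param pilotPrimaries primaries for the calibration pilot.
#' @param massMode dose denominator, see [scoringMass()].
#' @return data.frame with one row per dose: \code{dose_gy}, \code{p_dsb},
#'   \code{sem}, \code{n_replicates}, \code{n_primaries}, \code{source}.
#' @export
runDoseSeries <- function(geometry, spec, phys, params, doses,
                          nReplicates = 1000, baseSeed = 1,
                          pilotPrimaries = 2000, massMode = "box-water") {
  pilot <- runExposure(geometry, spec, phys, pilotPrimaries, seed = baseSeed,
                       massMode = massMode)
  rows <- lapply(doses, function(d) {
    nPrim <- calibratePrimaries(d, pilot)
    flags <- vapply(seq_len(nReplicates), function(i) {
      ex <- runExposure(geometry, spec, phys, nPrim, seed = baseSeed + i,
                        massMode = massMode)
      isBroken(scoreMolecule(ex@events, geometry, params))
    }, logical(1))
    cbind(data.frame(dose_gy = d), estimatePdsb(flags),
          data.frame(n_primaries = nPrim, source = "simulation"))
  })
  do.call(rbind, rows)
}

#' Full-factorial ET x BPT x dose threshold scan
#'
#' Event streams are generated once per (dose, replicate) pair and re-scored
#' for every (ET, BPT) combination: scoring is deterministic given events, so
#' monotone orderings across thresholds (P(DSB) non-increasing in ET,
#' non-decreasing in BPT) hold exactly, not just statistically. Replicate
#' seeds are shared across doses (\code{baseSeed + i}); this is recorded in
#' the returned object.
#'
#' @inheritParams runDoseSeries
#' @param etValues energy thresholds to scan, eV.
#' @param bptValues base-pair thresholds to scan, bp.
#' @return a \linkS4class{ThresholdScan}.
#' @export
scanThresholds <- function(geometry, spec, phys, etValues, bptValues, doses,
                           nReplicates = 1000, baseSeed = 1,
                           captureRadiusNm = 0.35, pilotPrimaries = 2000,
                           massMode = "box-water") {
  if (!length(etValues) || !length(bptValues) || !length(doses))
    stop("etValues, bptValues and doses must be non-empty")
  pilot <- runExposure(geometry, spec, phys, pilotPrimaries, seed = baseSeed,
                       massMode = massMode)
  nE <- length(etValues); nB <- length(bptValues); nD <- length(doses)
  broken <- array(FALSE, c(nE, nB, nD, nReplicates))
  for (di in seq_len(nD)) {
    nPrim <- calibratePrimaries(doses[di], pilot)
    for (i in seq_len(nReplicates)) {
      ex <- runExposure(geometry, spec, phys, nPrim, seed = baseSeed + i,
                        massMode = massMode)
      tally <- assignDeposits(ex@events, geometry, captureRadiusNm)
      for (ei in seq_len(nE)) {
        brks <- scoreSsb(tally, etValues[ei])
        for (bi in seq_len(nB))
          broken[ei, bi, di, i] <- pairDsb(brks, bptValues[bi]) >= 1L
      }
    }
  }
  p <- apply(broken, 1:3, mean)
  sem <- apply(broken, 1:3, function(f) stats::sd(f) / sqrt(length(f)))
  new("ThresholdScan", etValues = as.numeric(etValues),
      bptValues = as.numeric(bptValues), doses = as.numeric(doses),
      pDsb = p, sem = sem, baseSeed = as.integer(baseSeed),
      nReplicates = as.integer(nReplicates))
}

#' Quadratic dose-response fit
#'
#' Unweighted least squares of P(DSB) on (dose^2, dose, 1):
#' p = a D^2 + b D + c.
#'
#' @param points data.frame with \code{dose_gy} and \code{p_dsb}; at least
#'   3 distinct doses.
#' @return a \linkS4class{QuadraticFit}.
#' @examples
#' tab <- loadExperimentalTable()
#' fit <- fitDoseResponse(tab)
#' coefficients3(fit)   # (a, b, c); b is about 1.7e-3 per Gy
#' @export
fitDoseResponse <- function(points) {
  d <- points$dose_gy
  p <- points$p_dsb
  if (length(unique(d)) < 3L)
    stop("at least 3 distinct doses required for a quadratic fit")
  fit <- stats::lm(p ~ I(d^2) + d)
  cf <- stats::coef(fit)
  new("QuadraticFit", a = unname(cf["I(d^2)"]), b = unname(cf["d"]),
      c = unname(cf["(Intercept)"]),
      residuals = unname(stats::residuals(fit)), doses = d)
}

#' @rdname QuadraticFit-class
#' @param x a \linkS4class{QuadraticFit}.
#' @return \code{coefficients3}: named vector (a, b, c).
#' @export
setMethod("coefficients3", "QuadraticFit", function(x)
  c(a = x@a, b = x@b, c = x@c))

#' @rdname predictPdsb
#' @export
setMethod("predictPdsb", "QuadraticFit", function(x, dose)
  x@a * dose^2 + x@b * dose + x@c)

setMethod("show", "QuadraticFit", function(object) {
  cat(sprintf("QuadraticFit: p = %.4g D^2 + %.4g D + %.4g  (max |resid| %.3g)\n",
              object@a, object@b, object@c,
              if (length(object@residuals)) max(abs(object@residuals)) else NA))
})

#' Compare simulated and experimental dose-response points
#'
#' @param sim,exp data.frames with \code{dose_gy} and \code{p_dsb}; the dose
#'   lists must match after sorting.
#' @return list with \code{perDose} (data.frame: dose_gy, p_sim, p_exp,
#'   abs_diff, rel_diff), and summary elements \code{maxAbsDiff},
#'   \code{minRelDiff}, \code{maxRelDiff}.
#' @export
compareToExperiment <- function(sim, exp) {
  sim <- sim[order(sim$dose_gy), ]
  exp <- exp[order(exp$dose_gy), ]
  if (nrow(sim) != nrow(exp) ||
      !isTRUE(all.equal(sim$dose_gy, exp$dose_gy)))
    stop("dose mismatch between simulated and experimental points")
  absd <- abs(sim$p_dsb - exp$p_dsb)
  reld <- absd / exp$p_dsb
  perDose <- data.frame(dose_gy = sim$dose_gy, p_sim = sim$p_dsb,
                        p_exp = exp$p_dsb, abs_diff = absd, rel_diff = reld)
  list(perDose = perDose, maxAbsDiff = max(absd),
       minRelDiff = min(reld), maxRelDiff = max(reld))
}

#' Load an experimental dose-response table
#'
#' CSV with columns \code{dose_gy}, \code{p_dsb}, \code{sem}. The default is
#' the packaged table of fluorescence-dosimeter measurements of DNA
#' double-strand-break probability under 6 MV photon irradiation at 25-200
#' Gy.
#'
#' @param path CSV path; \code{NULL} loads the packaged table.
#' @return data.frame with \code{dose_gy}, \code{p_dsb}, \code{sem},
#'   \code{source = "experiment"}.
#' @export
loadExperimentalTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dna_dosimeter_pdsb.csv",
                        package = "dsbkit", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("dose_gy", "p_dsb", "sem")
  if (!all(need %in% names(tab)))
    stop("experimental table format error: need columns ",
         paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("experimental table is empty")
  tab$source <- "experiment"
  tab
}

#' Run the full dose-response pipeline and write its outputs
#'
#' Calibrates, simulates and scores a dose series, fits the quadratic
#' dose-response, compares against an experimental table when the doses
#' match, and writes \code{points.csv}, \code{fit.json} and
#' \code{compare.csv} plus a run log into \code{outDir}. Given one base seed
#' the outputs are byte-identical across runs.
#'
#' @inheritParams runDoseSeries
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param experimental optional experimental table for the comparison;
#'   defaults to the packaged one when the dose lists match.
#' @return list with \code{points}, \code{fit}, \code{comparison} (or NULL).
#' @export
runPipeline <- function(geometry, spec, phys, params, doses,
                        nReplicates = 1000, baseSeed = 1,
                        pilotPrimaries = 2000, outDir = NULL,
                        experimental = NULL) {
  points <- runDoseSeries(geometry, spec, phys, params, doses,
                          nReplicates = nReplicates, baseSeed = baseSeed,
                          pilotPrimaries = pilotPrimaries)
  points$et_ev <- params@etEv
  points$bpt_bp <- params@bptBp
  fit <- if (length(unique(doses)) >= 3L) fitDoseResponse(points) else NULL
  if (is.null(experimental)) {
    expTab <- loadExperimentalTable()
    experimental <- if (setequal(expTab$dose_gy, doses)) expTab else NULL
  }
  comparison <- if (!is.null(experimental))
    compareToExperiment(points, experimental) else NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(points, file.path(outDir, "points.csv"), row.names = FALSE)
    if (!is.null(fit) && requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(
        list(a = fit@a, b = fit@b, c = fit@c, residuals = fit@residuals),
        file.path(outDir, "fit.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(comparison))
      utils::write.csv(comparison$perDose, file.path(outDir, "compare.csv"),
                       row.names = FALSE)
    writeLines(c(
      sprintf("base_seed: %d", baseSeed),
      sprintf("n_replicates: %d", nReplicates),
      sprintf("pilot_primaries: %d", pilotPrimaries),
      sprintf("et_ev: %g", params@etEv),
      sprintf("bpt_bp: %d", params@bptBp),
      sprintf("capture_radius_nm: %g", params@captureRadiusNm),
      sprintf("doses_gy: %s", paste(doses, collapse = " ")),
      sprintf("geometry: %s (%d bp)", geometry@sourceLabel, nBp(geometry))
    ), file.path(outDir, "run_log.txt"))
  }
  list(points = points, fit = fit, comparison = comparison)
}

setMethod("show", "ThresholdScan", function(object) {
  cat(sprintf(
    "ThresholdScan: %d ET x %d BPT x %d doses, %d replicates (base seed %d)\n",
    length(object@etValues), length(object@bptValues), length(object@doses),
    object@nReplicates, object@baseSeed))
  cat("  P(DSB) range:", sprintf("%.3f-%.3f", min(object@pDsb), max(object@pDsb)), "\n")
})
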