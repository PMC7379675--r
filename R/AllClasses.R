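#' @import methods
NULL

#' DnaGeometry: strand/base-pair indexed DNA structure
#'
#' Atomic model of a double-stranded DNA molecule (optionally embedded in a
#' protein context such as a nucleosome) with every nucleic-acid residue
#' assigned to a strand (1 or 2) and a 0-based base-pair index along the
#' duplex. All coordinates are in nanometres; Angstroms from PDB files are
#' converted on read.
#'
#' @slot atoms data.frame with one row per atom: \code{name} (PDB atom name),
#'   \code{element}, \code{x}, \code{y}, \code{z} (nm), \code{resno},
#'   \code{chain}, \code{nucleic} (residue is a DNA nucleotide),
#'   \code{backbone} (atom belongs to the sugar-phosphate group),
#'   \code{scorable} (backbone atom of a nucleic residue: energy deposited
#'   nearest to it is tallied for strand-break calling), \code{strand},
#'   \code{bpIndex}, \code{base}. Non-nucleic atoms (protein, water, ions)
#'   carry \code{NA} strand/bpIndex and act only as inert absorbers in
#'   nearest-atom queries.
#' @slot nucleotides data.frame with one row per nucleotide: \code{chain},
#'   \code{resno}, \code{strand}, \code{bpIndex}, \code{base}, \code{paired}.
#' @slot nBp integer, number of base-pair positions along the duplex.
#' @slot boundingBox 3 x 2 matrix (rows x,y,z; columns min,max), nm.
#' @slot sourceLabel character, file path or \code{"fixture"}.
#'
#' @seealso [parsePdb()], [buildBdnaFixture()], [scoringMass()]
#' @export
setClass("DnaGeometry",
  representation(
    atoms = "data.frame",
    nucleotides = "data.frame",
    nBp = "integer",
    boundingBox = "matrix",
    sourceLabel = "character"
  )
)

setValidity("DnaGeometry", function(object) {
  msg <- character()
  need <- c("name", "element", "x", "y", "z", "resno", "chain",
            "nucleic", "backbone", "scorable", "strand", "bpIndex", "base")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "atom positions must be finite")
  ok_elem <- c("H", "C", "N", "O", "P", "S", "")
  if (length(msg) == 0L && !all(object@atoms$element %in% ok_elem))
    msg <- c(msg, "unsupported element symbol in atoms")
  if (object@nBp < 1L)
    msg <- c(msg, "nBp must be >= 1")
  if (!identical(dim(object@boundingBox), c(3L, 2L)))
    msg <- c(msg, "boundingBox must be a 3 x 2 matrix")
  else {
    ext <- object@boundingBox[, 2] - object@boundingBox[, 1]
    if (any(ext <= 0)) msg <- c(msg, "boundingBox extents must be > 0")
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    tol <- 1e-9
    inside <- xyz >= matrix(object@boundingBox[, 1] - tol, nrow(xyz), 3, byrow = TRUE) &
      xyz <= matrix(object@boundingBox[, 2] + tol, nrow(xyz), 3, byrow = TRUE)
    if (!all(inside)) msg <- c(msg, "all atoms must lie inside boundingBox")
  }
  nt <- object@nucleotides
  if (nrow(nt) > 0) {
    if (!all(nt$strand %in% c(1L, 2L)))
      msg <- c(msg, "strand must be 1 or 2")
    for (s in 1:2) {
      bpi <- nt$bpIndex[nt$strand == s]
      bpi <- bpi[!is.na(bpi)]   # NA = not yet assigned by pairing
      if (anyDuplicated(bpi))
        msg <- c(msg, sprintf("bpIndex not unique within strand %d", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpectrumHistogram: binned electron energy distribution
#'
#' A normalized histogram of electron kinetic energies (MeV) used as the
#' radiation source: the per-bin probabilities sum to one and energies are
#' sampled uniformly within a multinomially selected bin.
#'
#' @slot binEdges ascending numeric vector of bin edges, MeV, length K+1.
#' @slot probabilities numeric vector of bin probabilities, length K,
#'   non-negative, summing to 1 within 1e-12.
#'
#' @seealso [loadSpectrum()], [synthLinacSpectrum()], [sampleEnergies()]
#' @export
setClass("SpectrumHistogram",
  representation(binEdges = "numeric", probabilities = "numeric")
)

setValidity("SpectrumHistogram", function(object) {
  msg <- character()
  k <- length(object@probabilities)
  if (k < 1L) msg <- c(msg, "at least one bin required")
  if (length(object@binEdges) != k + 1L)
    msg <- c(msg, "binEdges must have length(probabilities) + 1")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@probabilities < 0))
    msg <- c(msg, "probabilities must be non-negative")
  if (k >= 1L && abs(sum(object@probabilities) - 1) > 1e-12)
    msg <- c(msg, "probabilities must sum to 1 within 1e-12")
  if (length(msg)) msg else TRUE
})

#' PhysicsParams: parametric electron-interaction model
#'
#' Declared parametric stand-in for detailed track-structure physics: an
#' electron of energy E traverses the scoring volume on a straight chord and
#' leaves discrete energy deposits as a Poisson process with linear density
#' LET(E) / meanDepositEv, each deposit drawn from a truncated exponential.
#' The stopping table is piecewise log-linear in (energy, LET) and ships as
#' an editable CSV of illustrative values; no claim of agreement with any
#' condensed-history or track-structure code is made.
#'
#' @slot stoppingTable data.frame with ascending \code{energy_mev} and
#'   positive \code{let_kev_um}.
#' @slot meanDepositEv mean energy per interaction site, eV.
#' @slot depositMinEv,depositMaxEv truncation bounds for a single deposit, eV.
#'
#' @seealso [defaultPhysicsParams()], [simulatePrimary()]
#' @export
setClass("PhysicsParams",
  representation(
    stoppingTable = "data.frame",
    meanDepositEv = "numeric",
    depositMinEv = "numeric",
    depositMaxEv = "numeric"
  )
)

setValidity("PhysicsParams", function(object) {
  msg <- character()
  st <- object@stoppingTable
  if (!all(c("energy_mev", "let_kev_um") %in% names(st)))
    msg <- c(msg, "stoppingTable needs columns energy_mev, let_kev_um")
  else {
    if (any(diff(st$energy_mev) <= 0))
      msg <- c(msg, "stoppingTable energies must be ascending")
    if (any(st$let_kev_um <= 0))
      msg <- c(msg, "stoppingTable LET values must be > 0")
  }
  if (!(object@depositMinEv > 0 &&
        object@depositMinEv < object@meanDepositEv &&
        object@meanDepositEv < object@depositMaxEv))
    msg <- c(msg, "require 0 < depositMinEv < meanDepositEv < depositMaxEv")
  if (length(msg)) msg else TRUE
})

#' ExposureResult: one seed-replicated irradiation of a molecule
#'
#' @slot events data.frame of deposition events: \code{primary_id},
#'   \code{x_nm}, \code{y_nm}, \code{z_nm}, \code{energy_ev},
#'   \code{within_volume}.
#' @slot nPrimaries number of incident electrons.
#' @slot totalEnergyEv total energy deposited inside the scoring volume, eV.
#' @slot doseGy absorbed dose: in-volume energy (J) / scoring mass (kg).
#' @slot seed integer seed the exposure was generated with.
#'
#' @seealso [runExposure()], [calibratePrimaries()]
#' @export
setClass("ExposureResult",
  representation(
    events = "data.frame",
    nPrimaries = "numeric",
    totalEnergyEv = "numeric",
    doseGy = "numeric",
    seed = "integer"
  )
)

setValidity("ExposureResult", function(object) {
  msg <- character()
  ev <- object@events
  if (nrow(ev) > 0 && any(ev$energy_ev <= 0))
    msg <- c(msg, "event energies must be > 0")
  tot <- sum(ev$energy_ev[ev$within_volume])
  if (!isTRUE(all.equal(tot, object@totalEnergyEv, tolerance = 1e-9, scale = max(1, tot))))
    msg <- c(msg, "totalEnergyEv must equal the sum of in-volume event energies")
  if (object@doseGy < 0) msg <- c(msg, "doseGy must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DamageParams: strand-break and DSB calling thresholds
#'
#' @slot etEv energy threshold for a strand break on the phosphodiester
#'   backbone, eV: a nucleotide whose backbone group accumulates >= etEv
#'   breaks (inclusive comparison).
#' @slot bptBp base-pair threshold, bp: two opposite-strand breaks at most
#'   bptBp base pairs apart (inclusive) form one DSB.
#' @slot captureRadiusNm maximum deposit-to-atom distance for an event to be
#'   assigned to a backbone group, nm.
#'
#' @seealso [damageParams()], [scoreMolecule()]
#' @export
setClass("DamageParams",
  representation(etEv = "numeric", bptBp = "integer", captureRadiusNm = "numeric")
)

setValidity("DamageParams", function(object) {
  msg <- character()
  if (object@etEv <= 0) msg <- c(msg, "etEv must be > 0")
  if (object@bptBp < 0L) msg <- c(msg, "bptBp must be >= 0")
  if (object@captureRadiusNm <= 0) msg <- c(msg, "captureRadiusNm must be > 0")
  if (length(msg)) msg else TRUE
})

#' DamageResult: SSB/DSB calls for one molecule and one event set
#'
#' @slot backboneEnergy 2 x nBp matrix of accumulated backbone energy, eV
#'   (row = strand, column = bpIndex + 1).
#' @slot ssbs data.frame of strand breaks: \code{strand}, \code{bp_index},
#'   \code{accumulated_ev}, sorted by (strand, bp_index).
#' @slot dsbCount number of disjoint opposite-strand break pairs within the
#'   base-pair threshold.
#' @slot broken logical, the binary endpoint: the molecule carries at least
#'   one DSB. Multiple DSBs are counted in \code{dsbCount} but the endpoint
#'   only records whether the molecule is destroyed or not.
#'
#' @seealso [scoreMolecule()]
#' @export
setClass("DamageResult",
  representation(
    backboneEnergy = "matrix",
    ssbs = "data.frame",
    dsbCount = "integer",
    broken = "logical"
  )
)

setValidity("DamageResult", function(object) {
  msg <- character()
  if (object@dsbCount < 0L) msg <- c(msg, "dsbCount must be >= 0")
  if (!identical(object@broken, object@dsbCount >= 1L))
    msg <- c(msg, "broken must equal (dsbCount >= 1)")
  n1 <- sum(object@ssbs$strand == 1L)
  n2 <- sum(object@ssbs$strand == 2L)
  if (object@dsbCount > min(n1, n2))
    msg <- c(msg, "dsbCount cannot exceed the smaller per-strand SSB count")
  if (length(msg)) msg else TRUE
})

#' QuadraticFit: quadratic dose-response model p = a D^2 + b D + c
#'
#' @slot a coefficient of dose squared, 1/Gy^2.
#' @slot b linear coefficient, 1/Gy.
#' @slot c intercept, fraction.
#' @slot residuals per-point residuals of the unweighted least-squares fit.
#' @slot doses doses the fit was computed on, Gy.
#'
#' @seealso [fitDoseResponse()], [predictPdsb()]
#' @export
setClass("QuadraticFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 residuals = "numeric", doses = "numeric")
)

setValidity("QuadraticFit", function(object) {
  d <- object@doses
  p <- object@a * d^2 + object@b * d + object@c
  if (length(d) && (any(p < -0.1) || any(p > 1.1)))
    "fit predicts outside [-0.1, 1.1] over the fitted dose range"
  else TRUE
})

#' ThresholdScan: P(DSB) over an ET x BPT x dose grid
#'
#' Full-factorial threshold scan. Event streams are generated once per
#' (dose, replicate) and re-scored for every (ET, BPT) cell, so monotone
#' orderings across thresholds are exact, not stochastic.
#'
#' @slot etValues energy thresholds scanned, eV.
#' @slot bptValues base-pair thresholds scanned, bp.
#' @slot doses absorbed doses, Gy.
#' @slot pDsb 3-D array [ET, BPT, dose] of P(DSB) estimates.
#' @slot sem 3-D array of standard errors of the mean.
#' @slot baseSeed integer base seed; replicate i used seed baseSeed + i - 1.
#' @slot nReplicates replicate molecules per (dose) cell.
#'
#' @seealso [scanThresholds()]
#' @export
setClass("ThresholdScan",
  representation(
    etValues = "numeric", bptValues = "numeric", doses = "numeric",
    pDsb = "array", sem = "array",
    baseSeed = "integer", nReplicates = "integer"
  )
)

setValidity("ThresholdScan", function(object) {
  msg <- character()
  want <- c(length(object@etValues), length(object@bptValues), length(object@doses))
  if (!identical(dim(object@pDsb), as.integer(want)))
    msg <- c(msg, "pDsb shape inconsistent with axis lengths")
  if (!identical(dim(object@sem), as.integer(want)))
    msg <- c(msg, "sem shape inconsistent with axis lengths")
  if (any(object@pDsb < 0 | object@pDsb > 1))
    msg <- c(msg, "pDsb entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
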