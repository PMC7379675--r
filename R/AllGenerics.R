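#' @rdname DnaGeometry-class
#' @param object,x a \linkS4class{DnaGeometry} (or other dsbkit object).
#' @export
setGeneric("nBp", function(x) standardGeneric("nBp"))

#' @rdname DnaGeometry-class
#' @export
setGeneric("boundingBox", function(x) standardGeneric("boundingBox"))

#' @rdname DnaGeometry-class
#' @export
setGeneric("nucleotides", function(x) standardGeneric("nucleotides"))

#' @rdname DnaGeometry-class
#' @export
setGeneric("dnaAtoms", function(x) standardGeneric("dnaAtoms"))

#' Mass of the scoring volume
#'
#' Denominator of the absorbed dose. Mode \code{"box-water"} treats the
#' bounding box as water (1.0 g/cm^3); mode \code{"atomic"} sums the atomic
#' masses of all atoms. The water-equivalent box is the default because dose
#' is conventionally reported to medium, not to the bare macromolecule; the
#' atomic mode is provided for sensitivity analysis.
#'
#' @param x a \linkS4class{DnaGeometry}.
#' @param mode \code{"box-water"} or \code{"atomic"}.
#' @return mass in kg.
#' @examples
#' g <- buildBdnaFixture(10)
#' scoringMass(g)                    # water-equivalent bounding box
#' scoringMass(g, mode = "atomic")   # sum of atomic masses
#' @export
setGeneric("scoringMass", function(x, mode = c("box-water", "atomic"))
  standardGeneric("scoringMass"))

#' @rdname ExposureResult-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname ExposureResult-class
#' @export
setGeneric("doseGy", function(x) standardGeneric("doseGy"))

#' @rdname DamageResult-class
#' @export
setGeneric("dsbCount", function(x) standardGeneric("dsbCount"))

#' @rdname DamageResult-class
#' @export
setGeneric("isBroken", function(x) standardGeneric("isBroken"))

#' @rdname DamageResult-class
#' @export
setGeneric("ssbs", function(x) standardGeneric("ssbs"))

#' @rdname QuadraticFit-class
#' @export
setGeneric("coefficients3", function(x) standardGeneric("coefficients3"))

#' Predicted P(DSB) at given doses
#' @param x a \linkS4class{QuadraticFit}.
#' @param dose numeric vector of doses, Gy.
#' @return numeric vector of predicted break probabilities.
#' @export
setGeneric("predictPdsb", function(x, dose) standardGeneric("predictPdsb"))
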