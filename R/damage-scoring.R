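#' Damage-calling parameters
#'
#' Defaults follow the values this field most often adopts: ET = 19 eV (the
#' energy accumulated on a nucleotide's sugar-phosphate group that calls a
#' strand break), BPT = 10 bp (the maximum separation of opposite-strand
#' breaks forming one DSB), capture radius 0.35 nm (covalent-bond scale; a
#' tunable of the assignment rule, not a literature constant). Threshold
#' comparisons are inclusive: >= ET and <= BPT.
#'
#' @param etEv energy threshold, eV.
#' @param bptBp base-pair threshold, bp.
#' @param captureRadiusNm deposit-to-atom capture radius, nm.
#' @return a \linkS4class{DamageParams}.
#' @export
damageParams <- function(etEv = 19, bptBp = 10, captureRadiusNm = 0.35) {
  new("DamageParams", etEv = as.numeric(etEv), bptBp = as.integer(bptBp),
      captureRadiusNm = as.numeric(captureRadiusNm))
}

#' Assign deposition events to backbone groups
#'
#' Every in-volume event is attributed to its nearest atom overall (nucleic
#' or not). The event's energy accrues to a nucleotide's backbone tally iff
#' that nearest atom is a scorable backbone atom and lies within the capture
#' radius; deposits nearest to base, protein or solvent atoms never score
#' (they still count toward dose, which is handled upstream). Nearest-atom
#' ties resolve to the lowest (chain, residue number, atom name).
#'
#' @param events data.frame of deposition events (see [simulatePrimary()]).
#' @param geometry a \linkS4class{DnaGeometry}.
#' @param captureRadiusNm capture radius, nm.
#' @param reduce \code{"sum"} accumulates energy per backbone group across
#'   all events before thresholding (default); \code{"max"} keeps only the
#'   largest single deposit, for per-deposit sensitivity analyses.
#' @return numeric matrix, 2 x nBp (row = strand, column = bpIndex + 1), eV.
#' @export
assignDeposits <- function(events, geometry, captureRadiusNm = 0.35,
                           reduce = c("sum", "max")) {
  reduce <- match.arg(reduce)
  at <- geometry@atoms
  at <- at[order(at$chain, at$resno, at$name), ]   # deterministic tie-break
  tally <- matrix(0, nrow = 2, ncol = geometry@nBp)
  ev <- events[events$within_volume, , drop = FALSE]
  if (nrow(ev) == 0L) return(tally)
  A <- as.matrix(at[, c("x", "y", "z")])
  a2 <- rowSums(A^2)
  E <- as.matrix(ev[, c("x_nm", "y_nm", "z_nm")])
  chunk <- 256L
  for (s in seq(1L, nrow(E), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(E))
    Ec <- E[idx, , drop = FALSE]
    # squared distances: |a|^2 - 2 a.e + |e|^2 (last term constant per event)
    d2 <- outer(a2, rowSums(Ec^2), "+") - 2 * (A %*% t(Ec))
    nearest <- max.col(-t(d2), ties.method = "first")
    dist <- sqrt(pmax(0, d2[cbind(nearest, seq_along(idx))]))
    ok <- at$scorable[nearest] & dist <= captureRadiusNm
    if (any(ok)) {
      str <- at$strand[nearest[ok]]
      bpi <- at$bpIndex[nearest[ok]] + 1L
      en <- ev$energy_ev[idx][ok]
      for (k in seq_along(en)) {
        if (reduce == "sum")
          tally[str[k], bpi[k]] <- tally[str[k], bpi[k]] + en[k]
        else
          tally[str[k], bpi[k]] <- max(tally[str[k], bpi[k]], en[k])
      }
    }
  }
  tally
}

#' Call single-strand breaks at an energy threshold
#'
#' @param backboneEnergy 2 x nBp backbone energy matrix from
#'   [assignDeposits()].
#' @param etEv energy threshold, eV (> 0); comparison is inclusive (>= ET).
#' @return data.frame of breaks: \code{strand}, \code{bp_index},
#'   \code{accumulated_ev}, sorted by (strand, bp_index).
#' @export
scoreSsb <- function(backboneEnergy, etEv) {
  if (etEv <= 0) stop("etEv must be > 0")
  hit <- which(backboneEnergy >= etEv, arr.ind = TRUE)
  out <- data.frame(strand = as.integer(hit[, 1]),
                    bp_index = as.integer(hit[, 2]) - 1L,
                    accumulated_ev = backboneEnergy[hit])
  out[order(out$strand, out$bp_index), , drop = FALSE]
}

#' Pair opposite-strand breaks into double-strand breaks
#'
#' Counts disjoint pairs of breaks on opposite strands separated by at most
#' \code{bptBp} base pairs (inclusive), by a greedy sweep: strand-1 breaks
#' are visited in ascending bp order and each is matched to the lowest-index
#' unused strand-2 break within the window. Each break is used at most once.
#' For this interval-window structure the greedy count equals the maximum
#' bipartite matching (property-tested against an exhaustive oracle). Breaks
#' on a single strand never form a DSB.
#'
#' @param ssbs data.frame from [scoreSsb()].
#' @param bptBp base-pair threshold, bp.
#' @return integer DSB count.
#' @examples
#' brk <- data.frame(strand = c(1L, 2L), bp_index = c(5L, 12L),
#'                   accumulated_ev = c(25, 30))
#' pairDsb(brk, 10)   # |5 - 12| = 7 <= 10 -> 1
#' pairDsb(brk, 6)    # 0
#' @export
pairDsb <- function(ssbs, bptBp) {
  if (bptBp < 0) stop("bptBp must be >= 0")
  b1 <- sort(ssbs$bp_index[ssbs$strand == 1L])
  b2 <- sort(ssbs$bp_index[ssbs$strand == 2L])
  if (!length(b1) || !length(b2)) return(0L)
  used <- rep(FALSE, length(b2))
  count <- 0L
  for (x in b1) {
    j <- which(!used & abs(b2 - x) <= bptBp)
    if (length(j)) {
      used[j[1]] <- TRUE
      count <- count + 1L
    }
  }
  count
}

#' Score one molecule: events in, damage out
#'
#' Composition of [assignDeposits()], [scoreSsb()] and [pairDsb()]. The
#' binary endpoint \code{broken} records whether the molecule carries at
#' least one DSB; multiple DSBs are tallied in \code{dsbCount} but the
#' endpoint only distinguishes destroyed from intact, mirroring what a
#' strand-separation readout can observe.
#'
#' @param events deposition event data.frame.
#' @param geometry a \linkS4class{DnaGeometry}.
#' @param params a \linkS4class{DamageParams}.
#' @param reduce backbone accumulation rule, see [assignDeposits()].
#' @return a \linkS4class{DamageResult}.
#' @examples
#' g <- buildBdnaFixture(20)
#' s <- synthLinacSpectrum()
#' p <- defaultPhysicsParams()
#' ex <- runExposure(g, s, p, nPrimaries = 2000, seed = 11)
#' res <- scoreMolecule(events(ex), g, damageParams(etEv = 19, bptBp = 10))
#' dsbCount(res); isBroken(res)
#' @export
scoreMolecule <- function(events, geometry, params, reduce = "sum") {
  tally <- assignDeposits(events, geometry, params@captureRadiusNm, reduce = reduce)
  brks <- scoreSsb(tally, params@etEv)
  n <- pairDsb(brks, params@bptBp)
  new("DamageResult", backboneEnergy = tally, ssbs = brks,
      dsbCount = as.integer(n), broken = n >= 1L)
}

#' @rdname DamageResult-class
#' @param x a \linkS4class{DamageResult}.
#' @export
setMethod("dsbCount", "DamageResult", function(x) x@dsbCount)

#' @rdname DamageResult-class
#' @export
setMethod("isBroken", "DamageResult", function(x) x@broken)

#' @rdname DamageResult-class
#' @export
setMethod("ssbs", "DamageResult", function(x) x@ssbs)

setMethod("show", "DamageResult", function(object) {
  cat(sprintf("DamageResult: %d SSBs, %d DSBs, molecule %s\n",
              nrow(object@ssbs), object@dsbCount,
              if (object@broken) "BROKEN" else "intact"))
})

setMethod("show", "DamageParams", function(object) {
  cat(sprintf("DamageParams: ET = %g eV, BPT = %d bp, capture radius %g nm\n",
              object@etEv, object@bptBp, object@captureRadiusNm))
})
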