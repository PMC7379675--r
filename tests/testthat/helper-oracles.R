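# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain double loops and igraph matching.

# O(N*M) nearest-atom assignment oracle
bruteForceAssign <- function(events, geometry, captureRadiusNm) {
  at <- dnaAtoms(geometry)
  at <- at[order(at$chain, at$resno, at$name), ]
  tally <- matrix(0, 2, nBp(geometry))
  ev <- events[events$within_volume, , drop = FALSE]
  if (nrow(ev) == 0) return(tally)
  for (i in seq_len(nrow(ev))) {
    d <- sqrt((at$x - ev$x_nm[i])^2 + (at$y - ev$y_nm[i])^2 +
                (at$z - ev$z_nm[i])^2)
    j <- which.min(d)
    if (at$scorable[j] && d[j] <= captureRadiusNm) {
      tally[at$strand[j], at$bpIndex[j] + 1L] <-
        tally[at$strand[j], at$bpIndex[j] + 1L] + ev$energy_ev[i]
    }
  }
  tally
}

# exhaustive maximum bipartite matching on the |b1 - b2| <= bpt window graph
maxMatchingOracle <- function(b1, b2, bpt) {
  if (!length(b1) || !length(b2)) return(0L)
  best <- 0L
  recurse <- function(i, used2, count) {
    if (count + (length(b1) - i + 1L) <= best) return()
    if (i > length(b1)) {
      best <<- max(best, count)
      return()
    }
    cand <- which(!used2 & abs(b2 - b1[i]) <= bpt)
    for (j in cand) {
      used2[j] <- TRUE
      recurse(i + 1L, used2, count + 1L)
      used2[j] <- FALSE
    }
    recurse(i + 1L, used2, count)   # leave b1[i] unmatched
  }
  recurse(1L, rep(FALSE, length(b2)), 0L)
  best
}

# brute-force nearest pairing between the two strands' representative
# (Watson-Crick nitrogen) atoms, globally greedy by smallest distance
bruteForcePairing <- function(geometry, cutoff = 1.2) {
  at <- dnaAtoms(geometry)
  rep1 <- at[at$strand == 1 & at$name %in% c("N1", "N3"), ]
  rep2 <- at[at$strand == 2 & at$name %in% c("N1", "N3"), ]
  rep1 <- rep1[order(rep1$resno), ]
  rep2 <- rep2[order(rep2$resno), ]
  d <- outer(seq_len(nrow(rep1)), seq_len(nrow(rep2)), function(i, j) {
    sqrt((rep1$x[i] - rep2$x[j])^2 + (rep1$y[i] - rep2$y[j])^2 +
           (rep1$z[i] - rep2$z[j])^2)
  })
  pairs <- data.frame(resno1 = integer(), resno2 = integer())
  repeat {
    j <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[j[1], j[2]] > cutoff) break
    pairs <- rbind(pairs, data.frame(resno1 = rep1$resno[j[1]],
                                     resno2 = rep2$resno[j[2]]))
    d[j[1], ] <- Inf
    d[, j[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  pairs[order(pairs$resno1), ]
}

# minimal valid DnaGeometry wrapping crafted atoms (non-nucleic box markers)
makeBoxGeometry <- function(corners, elements = rep("C", nrow(corners))) {
  atoms <- data.frame(
    name = elements, element = elements,
    x = corners[, 1], y = corners[, 2], z = corners[, 3],
    resno = seq_len(nrow(corners)), chain = "X",
    nucleic = FALSE, backbone = FALSE, scorable = FALSE,
    strand = NA_integer_, bpIndex = NA_integer_, base = NA_character_,
    stringsAsFactors = FALSE
  )
  nt <- data.frame(chain = character(), resno = integer(), strand = integer(),
                   base = character(), bpIndex = integer(), paired = logical())
  new("DnaGeometry", atoms = atoms, nucleotides = nt, nBp = 1L,
      boundingBox = cbind(min = apply(corners, 2, min),
                          max = apply(corners, 2, max)),
      sourceLabel = "crafted")
}

# events data.frame helper
makeEvents <- function(x, y, z, energy, within = TRUE) {
  data.frame(primary_id = seq_along(x), x_nm = x, y_nm = y, z_nm = z,
             energy_ev = rep(energy, length.out = length(x)),
             within_volume = rep(within, length.out = length(x)))
}
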