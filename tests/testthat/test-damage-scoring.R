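test_that("deposits are assigned to the nearest backbone group within the capture radius", {
  g <- buildBdnaFixture(20)
  at <- dnaAtoms(g)
  pAtom <- at[at$strand == 1 & at$name == "P" & at$bpIndex == 5, ]
  ev <- makeEvents(pAtom$x, pAtom$y, pAtom$z, 20)
  tally <- assignDeposits(ev, g, captureRadiusNm = 0.35)
  expect_equal(tally[1, 6], 20)
  expect_equal(sum(tally), 20)

  # event farther than the capture radius from every atom: no tally
  bb <- boundingBox(g)
  far <- makeEvents(bb[1, 2] + 5, bb[2, 2] + 5, bb[3, 2] + 5, 50)
  far$within_volume <- TRUE   # force it through the in-volume filter
  expect_equal(sum(assignDeposits(far, g, 0.35)), 0)

  # out-of-volume events never tally
  out <- makeEvents(pAtom$x, pAtom$y, pAtom$z, 20, within = FALSE)
  expect_equal(sum(assignDeposits(out, g, 0.35)), 0)
})

test_that("vectorized assignment equals the brute-force all-pairs oracle", {
  g <- buildBdnaFixture(20)
  bb <- boundingBox(g)
  set.seed(21)
  n <- 1000
  ev <- makeEvents(stats::runif(n, bb[1, 1], bb[1, 2]),
                   stats::runif(n, bb[2, 1], bb[2, 2]),
                   stats::runif(n, bb[3, 1], bb[3, 2]),
                   stats::runif(n, 5, 500))
  expect_equal(assignDeposits(ev, g, 0.35),
               bruteForceAssign(ev, g, 0.35), ignore_attr = TRUE)
  # energy bookkeeping: backbone tallies never exceed deposited energy
  expect_lte(sum(assignDeposits(ev, g, 0.35)), sum(ev$energy_ev))
})

test_that("per-deposit (max) accumulation is available and bounded by the sum", {
  g <- buildBdnaFixture(10)
  at <- dnaAtoms(g)
  pAtom <- at[at$strand == 1 & at$name == "P" & at$bpIndex == 2, ]
  ev <- makeEvents(rep(pAtom$x, 3), rep(pAtom$y, 3), rep(pAtom$z, 3), c(10, 15, 12))
  expect_equal(assignDeposits(ev, g, 0.35)[1, 3], 37)
  expect_equal(assignDeposits(ev, g, 0.35, reduce = "max")[1, 3], 15)
})

test_that("strand breaks are called at an inclusive energy threshold", {
  tally <- matrix(0, 2, 10)
  tally[1, 6] <- 19.0
  b <- scoreSsb(tally, 19)
  expect_equal(nrow(b), 1L)
  expect_equal(b$strand, 1L)
  expect_equal(b$bp_index, 5L)

  tally[1, 6] <- 18.9
  expect_equal(nrow(scoreSsb(tally, 19)), 0L)

  tally[1, 6] <- 19
  tally[2, 3] <- 0.01
  expect_equal(nrow(scoreSsb(tally, 1e-12)), 2L)   # ET -> 0+: every tallied site
  expect_error(scoreSsb(tally, 0), "etEv")
})

test_that("DSB pairing follows the opposite-strand window rule", {
  brk <- function(s, bp) data.frame(strand = s, bp_index = bp,
                                    accumulated_ev = rep(99, length(s)))
  expect_equal(pairDsb(brk(c(1, 2), c(5, 12)), 10), 1L)
  expect_equal(pairDsb(brk(c(1, 2), c(5, 12)), 6), 0L)
  expect_equal(pairDsb(brk(c(1, 1), c(5, 12)), 10), 0L)   # same strand only
  expect_equal(pairDsb(brk(c(1, 1, 2, 2), c(10, 11, 15, 20)), 10), 2L)
  expect_equal(pairDsb(brk(integer(0), integer(0)), 10), 0L)
  expect_equal(pairDsb(brk(c(1, 2), c(4, 4)), 0), 1L)     # bpt = 0: same index
})

test_that("greedy pairing equals exhaustive maximum matching on random break sets", {
  set.seed(77)
  for (trial in 1:500) {
    n1 <- sample(0:4, 1); n2 <- sample(0:4, 1)
    b1 <- sort(sample(0:30, n1))
    b2 <- sort(sample(0:30, n2))
    bpt <- sample(0:12, 1)
    ssb <- data.frame(strand = c(rep(1L, n1), rep(2L, n2)),
                      bp_index = c(b1, b2),
                      accumulated_ev = rep(99, n1 + n2))
    expect_equal(pairDsb(ssb, bpt), maxMatchingOracle(b1, b2, bpt),
                 label = sprintf("trial %d", trial))
  }
})

test_that("damage is monotone in ET and BPT on shared tallies", {
  set.seed(31)
  for (trial in 1:100) {
    tally <- matrix(stats::rexp(2 * 30, 1 / 15), 2, 30)
    ets <- c(10, 12.5, 15, 17.5, 19, 22.5)
    sets <- lapply(ets, function(et) scoreSsb(tally, et))
    for (k in seq_along(ets)[-1]) {
      lo <- sets[[k]]; hi <- sets[[k - 1]]
      # SSB set at a higher threshold is a subset of the lower-threshold set
      expect_true(all(paste(lo$strand, lo$bp_index) %in%
                        paste(hi$strand, hi$bp_index)))
      expect_lte(pairDsb(lo, 10), pairDsb(hi, 10))
    }
    brks <- sets[[2]]
    dsb <- vapply(c(6, 8, 10, 12, 14), function(b) pairDsb(brks, b), integer(1))
    expect_true(all(diff(dsb) >= 0))
  }
})

test_that("molecule scoring composes the stages and sets the binary endpoint", {
  g <- buildBdnaFixture(20)
  params <- damageParams(etEv = 19, bptBp = 10)

  empty <- makeEvents(numeric(0), numeric(0), numeric(0), numeric(0))
  r0 <- scoreMolecule(empty, g, params)
  expect_equal(dsbCount(r0), 0L)
  expect_false(isBroken(r0))
  expect_equal(nrow(ssbs(r0)), 0L)

  at <- dnaAtoms(g)
  p1 <- at[at$strand == 1 & at$name == "P" & at$bpIndex == 3, ]
  p2 <- at[at$strand == 2 & at$name == "P" & at$bpIndex == 8, ]
  ev <- makeEvents(c(p1$x, p2$x), c(p1$y, p2$y), c(p1$z, p2$z), c(25, 30))
  r <- scoreMolecule(ev, g, params)
  expect_equal(dsbCount(r), 1L)
  expect_true(isBroken(r))

  # broken is invariant to event ordering
  perm <- ev[2:1, ]
  expect_identical(isBroken(scoreMolecule(perm, g, params)), isBroken(r))

  # saturating threshold dominates: dsb at 8.22 eV >= dsb at 19 eV
  set.seed(12)
  ex <- runExposure(g, synthLinacSpectrum(), defaultPhysicsParams(), 3000, seed = 12)
  rLow <- scoreMolecule(events(ex), g, damageParams(etEv = 8.22, bptBp = 10))
  rHigh <- scoreMolecule(events(ex), g, damageParams(etEv = 19, bptBp = 10))
  expect_gte(dsbCount(rLow), dsbCount(rHigh))
})
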