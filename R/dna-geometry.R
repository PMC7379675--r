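# Sugar-phosphate backbone atom names (PDB4DNA lineage). Old-style PDB files
# use '*' instead of "'"; names are normalized on read.
BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'", "C4'",
                    "O4'", "C3'", "O3'", "C2'", "C1'")

NUCLEIC_RESIDUES <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                      A = "A", C = "C", G = "G", T = "T")

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# atomic masses, unified atomic mass units
ATOMIC_MASS_U <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.973761998, S = 32.06)
U_TO_KG <- 1.66053906660e-27
EV_TO_J <- 1.602176634e-19

normalizeAtomName <- function(name) gsub("*", "'", trimws(name), fixed = TRUE)

elementFromName <- function(name) {
  # strip digits/primes, first remaining letter is the element for organic PDB names
  first <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  toupper(first)
}

boundingBoxOf <- function(xyz) {
  bb <- cbind(min = apply(xyz, 2, min), max = apply(xyz, 2, max))
  rownames(bb) <- c("x", "y", "z")
  bb
}

# Watson-Crick hydrogen-bond nitrogen (N1 purine / N3 pyrimidine), used as the
# pairing representative: across a pair it sits ~0.28 nm from its partner,
# far below any neighbouring-nucleotide distance, which makes nearest-distance
# pairing unambiguous. Falls back to C1', then to the backbone centroid.
pairingRep <- function(atoms, ntKey) {
  reps <- matrix(NA_real_, length(ntKey), 3,
                 dimnames = list(ntKey, c("x", "y", "z")))
  akey <- paste(atoms$chain, atoms$resno, sep = "\r")
  for (i in seq_along(ntKey)) {
    sel <- akey == ntKey[i]
    nm <- atoms$name[sel]
    base <- atoms$base[sel][1]
    want <- if (!is.na(base) && base %in% c("A", "G")) "N1" else "N3"
    j <- which(nm == want)
    if (!length(j)) j <- which(nm == "C1'")
    if (length(j)) {
      reps[i, ] <- as.numeric(atoms[sel, c("x", "y", "z")][j[1], ])
    } else {
      reps[i, ] <- colMeans(atoms[sel, c("x", "y", "z")])
    }
  }
  reps
}

newDnaGeometry <- function(atoms, nucleotides, sourceLabel) {
  bpi <- nucleotides$bpIndex
  nbp <- if (any(!is.na(bpi))) max(bpi, na.rm = TRUE) + 1L else 1L
  new("DnaGeometry",
      atoms = atoms,
      nucleotides = nucleotides,
      nBp = as.integer(nbp),
      boundingBox = boundingBoxOf(as.matrix(atoms[, c("x", "y", "z")])),
      sourceLabel = sourceLabel)
}

#' Read a DNA structure from a PDB file
#'
#' Parses ATOM/HETATM records, keeps one nucleotide per nucleic-acid residue
#' (residue names DA/DC/DG/DT or A/C/G/T), assigns strands by chain grouping
#' and base-pair indices by spatial pairing (see [pairStrands()]). Coordinates
#' are converted from Angstrom to nanometres. Non-nucleic residues (protein,
#' water, ions) are retained as inert absorbers for nearest-atom queries and
#' flagged non-scorable, unless \code{includeNonNucleic = FALSE}.
#'
#' @param path PDB file.
#' @param includeNonNucleic keep protein/solvent atoms as non-scorable
#'   absorbers (default) or drop them entirely.
#' @param pairingCutoffNm maximum representative-atom distance for two
#'   nucleotides to be called a base pair, nm.
#' @return a \linkS4class{DnaGeometry}.
#' @examples
#' g <- buildBdnaFixture(10)
#' f <- tempfile(fileext = ".pdb")
#' writeFixturePdb(g, f)
#' g2 <- parsePdb(f)
#' nBp(g2)
#' @export
parsePdb <- function(path, includeNonNucleic = TRUE, pairingCutoffNm = 1.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  for (i in which(isAtom)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords))
      stop(sprintf("unparseable ATOM record at line %d of %s", i, path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  name <- normalizeAtomName(at$elety)
  element <- toupper(trimws(ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                                   elementFromName(name), at$elesy)))
  resid <- trimws(at$resid)
  nucleic <- resid %in% names(NUCLEIC_RESIDUES)
  if (!any(nucleic))
    stop("not a DNA structure: no nucleic-acid residues (DA/DC/DG/DT or A/C/G/T) in ", path)
  atoms <- data.frame(
    name = name,
    element = element,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,   # Angstrom -> nm
    resno = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    nucleic = nucleic,
    backbone = nucleic & name %in% BACKBONE_ATOMS,
    scorable = FALSE,
    strand = NA_integer_,
    bpIndex = NA_integer_,
    base = ifelse(nucleic, unname(NUCLEIC_RESIDUES[resid]), NA_character_),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z), ]
  if (!includeNonNucleic) atoms <- atoms[atoms$nucleic, ]

  # strand = order of first appearance among chains holding nucleic residues,
  # folded onto {1, 2}
  nchains <- unique(atoms$chain[atoms$nucleic])
  strandOf <- setNames(((seq_along(nchains) - 1L) %% 2L) + 1L, nchains)
  atoms$strand[atoms$nucleic] <- strandOf[atoms$chain[atoms$nucleic]]
  atoms$scorable <- atoms$backbone

  nt <- unique(atoms[atoms$nucleic, c("chain", "resno", "strand", "base")])
  nt <- nt[order(nt$chain, nt$resno), ]
  rownames(nt) <- NULL
  nt$bpIndex <- NA_integer_
  nt$paired <- FALSE

  geom <- newDnaGeometry(atoms, nt, sourceLabel = path)
  if (length(nchains) >= 2L) {
    geom <- pairStrands(geom, pairingCutoffNm = pairingCutoffNm)
  } else {
    # single strand: index along the chain, nothing to pair
    ord <- order(geom@nucleotides$resno)
    geom@nucleotides$bpIndex[ord] <- seq_along(ord) - 1L
    geom <- syncAtomIndices(geom)
  }
  validObject(geom)
  geom
}

# push nucleotide-level strand/bpIndex assignments down to the atom table and
# refresh nBp
syncAtomIndices <- function(geom) {
  nt <- geom@nucleotides
  key <- paste(nt$chain, nt$resno, sep = "\r")
  akey <- paste(geom@atoms$chain, geom@atoms$resno, sep = "\r")
  idx <- match(akey, key)
  geom@atoms$bpIndex <- nt$bpIndex[idx]
  geom@atoms$strand <- ifelse(geom@atoms$nucleic, nt$strand[idx], NA_integer_)
  geom@nBp <- as.integer(max(nt$bpIndex, na.rm = TRUE) + 1L)
  geom
}

#' Assign base-pair indices by spatial strand pairing
#'
#' Each strand-1 nucleotide, taken in residue order, receives bpIndex
#' 0, 1, 2, ... and is matched to the closest not-yet-used strand-2
#' nucleotide within \code{pairingCutoffNm} (representative atoms: the
#' Watson-Crick hydrogen-bond nitrogen N1/N3 when present, else C1', else the
#' residue centroid; ties broken by lowest residue number). Matched strand-2
#' nucleotides inherit the partner's bpIndex; unmatched nucleotides keep a
#' unique bpIndex but are flagged unpaired.
#'
#' @param geometry a \linkS4class{DnaGeometry} with two strands.
#' @param pairingCutoffNm pairing distance cutoff, nm.
#' @return the geometry with bpIndex and pairing flags reassigned.
#' @export
pairStrands <- function(geometry, pairingCutoffNm = 1.2) {
  nt <- geometry@nucleotides
  if (length(unique(nt$strand)) < 2L)
    stop("fewer than 2 strands: cannot pair")
  nt <- nt[order(nt$strand, nt$chain, nt$resno), ]
  rownames(nt) <- NULL
  key <- paste(nt$chain, nt$resno, sep = "\r")
  reps <- pairingRep(geometry@atoms, key)
  i1 <- which(nt$strand == 1L)
  i2 <- which(nt$strand == 2L)
  nt$bpIndex[i1] <- seq_along(i1) - 1L
  nt$paired <- FALSE
  used2 <- rep(FALSE, length(i2))
  partner <- rep(NA_integer_, length(i1))
  for (k in seq_along(i1)) {
    d <- sqrt(colSums((t(reps[i2, , drop = FALSE]) - reps[i1[k], ])^2))
    d[used2] <- Inf
    j <- which.min(d)        # ties resolve to lowest residue order
    if (length(j) && is.finite(d[j]) && d[j] <= pairingCutoffNm) {
      partner[k] <- j
      used2[j] <- TRUE
    }
  }
  nt$paired[i1] <- !is.na(partner)
  matched <- !is.na(partner)
  nt$bpIndex[i2[partner[matched]]] <- nt$bpIndex[i1[matched]]
  nt$paired[i2[partner[matched]]] <- TRUE
  # unmatched strand-2 nucleotides: unique indices past the strand-1 range
  un2 <- i2[!used2]
  if (length(un2))
    nt$bpIndex[un2] <- length(i1) + seq_along(un2) - 1L
  geometry@nucleotides <- nt
  geometry <- syncAtomIndices(geometry)
  validObject(geometry)
  geometry
}

#' Generate an ideal B-DNA duplex fixture
#'
#' Places coarse per-nucleotide pseudo-atoms (P, C4', O3', C1' on the
#' sugar-phosphate backbone plus the Watson-Crick nitrogen N1/N3 on the base)
#' on two antiparallel helical strands with the canonical B-form rise and
#' twist. Strand 2 residue numbers run antiparallel: residue j of chain B
#' pairs with base-pair index nBp - j. Intended as a download-free stand-in
#' for real PDB duplexes in tests and examples.
#'
#' @param nBp number of base pairs (>= 1).
#' @param sequence optional strand-1 base string (A/C/G/T) of length nBp;
#'   default cycles ACGT. Strand 2 takes the complement.
#' @param riseNm axial rise per base pair, nm.
#' @param twistDeg helical twist per base pair, degrees.
#' @return a \linkS4class{DnaGeometry} with \code{sourceLabel = "fixture"}.
#' @examples
#' g <- buildBdnaFixture(10)
#' nBp(g)
#' boundingBox(g)
#' @export
buildBdnaFixture <- function(nBp, sequence = NULL, riseNm = 0.34, twistDeg = 36.0) {
  if (nBp < 1) stop("nBp must be >= 1")
  nBp <- as.integer(nBp)
  if (is.null(sequence)) {
    seq1 <- rep_len(c("A", "C", "G", "T"), nBp)
  } else {
    seq1 <- strsplit(toupper(sequence), "")[[1]]
    if (length(seq1) != nBp) stop("sequence length must equal nBp")
    if (!all(seq1 %in% names(COMPLEMENT))) stop("sequence may only contain A, C, G, T")
  }
  seq2 <- unname(COMPLEMENT[seq1])

  twist <- twistDeg * pi / 180
  delta <- 125.8 * pi / 180   # glycosidic-attachment separation across a pair
  # backbone pseudo-atom layout: radius (nm), angular offset (rad), z offset (nm)
  layout <- data.frame(
    name = c("C1'", "C4'", "P", "O3'"),
    element = c("C", "C", "P", "O"),
    r = c(0.59, 0.785, 0.94, 0.88),
    ang = c(0, 18, 40, 55) * pi / 180,
    dz = c(0.0, 0.03, 0.08, 0.12)
  )

  rows <- vector("list", 2L * nBp)
  for (i in seq_len(nBp) - 1L) {
    z <- i * riseNm
    a1 <- i * twist
    a2 <- a1 + delta
    c1a <- c(0.59 * cos(a1), 0.59 * sin(a1), z)
    c1b <- c(0.59 * cos(a2), 0.59 * sin(a2), z)
    for (s in 1:2) {
      ang0 <- if (s == 1L) a1 else a2
      sgn <- if (s == 1L) 1 else -1
      bb <- data.frame(
        name = layout$name,
        element = layout$element,
        x = layout$r * cos(ang0 + sgn * layout$ang),
        y = layout$r * sin(ang0 + sgn * layout$ang),
        z = z + layout$dz,
        stringsAsFactors = FALSE
      )
      base <- if (s == 1L) seq1[i + 1L] else seq2[i + 1L]
      # WC nitrogen on the C1'-C1' chord, 0.28 nm apart across the pair
      tfrac <- if (s == 1L) 0.3667 else 0.6333
      wc <- c1a + tfrac * (c1b - c1a)
      bb <- rbind(bb, data.frame(
        name = if (base %in% c("A", "G")) "N1" else "N3",
        element = "N", x = wc[1], y = wc[2], z = wc[3]
      ))
      bb$resno <- if (s == 1L) i + 1L else nBp - i
      bb$chain <- if (s == 1L) "A" else "B"
      bb$nucleic <- TRUE
      bb$backbone <- bb$name %in% BACKBONE_ATOMS
      bb$scorable <- bb$backbone
      bb$strand <- s
      bb$bpIndex <- i
      bb$base <- base
      rows[[2L * i + s]] <- bb
    }
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$name), ]
  rownames(atoms) <- NULL
  nt <- unique(atoms[, c("chain", "resno", "strand", "base", "bpIndex")])
  nt <- nt[order(nt$chain, nt$resno), ]
  rownames(nt) <- NULL
  nt$paired <- TRUE
  geom <- newDnaGeometry(atoms, nt, sourceLabel = "fixture")
  validObject(geom)
  geom
}

#' Write a geometry as a standard PDB file
#'
#' Emits fixed-column ATOM records (residue names DA/DC/DG/DT, chain IDs,
#' nm converted back to Angstrom) such that
#' \code{parsePdb(writeFixturePdb(g))} reproduces the strand and base-pair
#' structure exactly and atom positions at PDB column precision (3 decimals
#' in Angstrom).
#'
#' @param geometry a \linkS4class{DnaGeometry} with at least one nucleotide.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFixturePdb <- function(geometry, path) {
  at <- geometry@atoms
  if (nrow(at) == 0L) stop("empty geometry: nothing to write")
  resid <- ifelse(at$nucleic, paste0("D", at$base), "UNK")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))) * 10,
    type = rep("ATOM", nrow(at)),
    resno = at$resno,
    resid = resid,
    eleno = seq_len(nrow(at)),
    elety = at$name,
    chain = at$chain,
    elesy = at$element
  )
  invisible(path)
}

#' @describeIn scoringMass water-equivalent bounding box or atomic-mass sum.
setMethod("scoringMass", "DnaGeometry", function(x, mode = c("box-water", "atomic")) {
  mode <- match.arg(mode)
  if (mode == "box-water") {
    ext <- x@boundingBox[, 2] - x@boundingBox[, 1]
    vol_nm3 <- prod(ext)
    vol_nm3 * 1e-24          # 1 nm^3 of water (1 g/cm^3) = 1e-24 kg
  } else {
    masses <- ATOMIC_MASS_U[x@atoms$element]
    if (anyNA(masses)) stop("unknown element in atomic mass table")
    sum(masses) * U_TO_KG
  }
})

#' @rdname DnaGeometry-class
#' @export
setMethod("nBp", "DnaGeometry", function(x) x@nBp)

#' @rdname DnaGeometry-class
#' @export
setMethod("boundingBox", "DnaGeometry", function(x) x@boundingBox)

#' @rdname DnaGeometry-class
#' @export
setMethod("nucleotides", "DnaGeometry", function(x) x@nucleotides)

#' @rdname DnaGeometry-class
#' @export
setMethod("dnaAtoms", "DnaGeometry", function(x) x@atoms)

setMethod("show", "DnaGeometry", function(object) {
  ext <- object@boundingBox[, 2] - object@boundingBox[, 1]
  cat("DnaGeometry:", object@sourceLabel, "\n",
      sprintf("  %d base pairs, %d nucleotides, %d atoms (%d non-nucleic)\n",
              object@nBp, nrow(object@nucleotides), nrow(object@atoms),
              sum(!object@atoms$nucleic)),
      sprintf("  bounding box %.2f x %.2f x %.2f nm\n", ext[1], ext[2], ext[3]),
      sprintf("  scoring mass %.3e kg (box-water), %.3e kg (atomic)\n",
              scoringMass(object, "box-water"), scoringMass(object, "atomic")))
})
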