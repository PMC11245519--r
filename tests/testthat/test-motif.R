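# Motif definition, derivation, linear and aligned scanning.

plant_default <- function(variant = "YRWFN", gaps = c(7, 10, 26, 1),
                          len = 160L, start = 20L, companion = "F",
                          background = AA20) {
  chars <- sample(background, len, replace = TRUE)
  pos <- start + cumsum(c(0, gaps + 1))
  chars[pos] <- strsplit(variant, "")[[1L]]
  chars[pos[3L] + 1L] <- companion
  list(seq = paste0(chars, collapse = ""), positions = as.integer(pos))
}

test_that("the default motif encodes the reference site geometry", {
  m <- purineMotif()
  expect_identical(m@positionNames, paste0("P", 1:5))
  expect_equal(motifSpacings(m)$center, c(7, 10, 26, 1))
  expect_equal(motifSpacings(m)$max - motifSpacings(m)$min, c(8, 8, 8, 2))
  expect_identical(m@companion$offset, 1L)
})

test_that("linear scan finds planted motifs and reports deviations", {
  set.seed(41)
  pl <- plant_default()
  m <- scanLinear(pl$seq, id = "planted")
  expect_true(m@matched)
  expect_identical(variant(m), "YRWFN")
  expect_identical(m@positions, pl$positions)
  expect_identical(m@deviations, rep(0, 4))
  # breaking P2 breaks the match
  broken <- pl$seq
  substr(broken, pl$positions[2L], pl$positions[2L]) <- "A"
  expect_false(scanLinear(broken)@matched)
  # jittered spacings are reported as signed deviations (background
  # restricted so no competing tuple shares the planted total deviation)
  pl2 <- plant_default(gaps = c(9, 8, 24, 2),
                       background = c("G", "A", "S", "T", "L", "V"))
  m2 <- scanLinear(pl2$seq)
  expect_identical(m2@deviations, c(2, -2, -2, 1))
})

test_that("the companion aromatic is required only on demand", {
  set.seed(42)
  pl <- plant_default(companion = "A", background = setdiff(AA20, "F"))
  strict <- scanLinear(pl$seq)
  relaxed <- scanLinear(pl$seq, requireCompanion = FALSE)
  expect_false(strict@matched)
  expect_match(strict@reason, "companion")
  expect_true(relaxed@matched)
  expect_false(relaxed@companionOk)
})

test_that("linear match decisions equal an independent regex oracle", {
  set.seed(43)
  rx <- motif_regex()
  hits <- 0L
  for (i in 1:300) {
    # half pure background, half with planted fragments at random offsets
    s <- if (i %% 2 == 0) random_protein(150L) else
      plant_default(gaps = c(sample(3:11, 1), sample(6:14, 1),
                             sample(22:30, 1), sample(0:2, 1)),
                    companion = sample(c("F", "A"), 1))$seq
    got <- scanLinear(s)@matched
    want <- grepl(rx, s, perl = TRUE)
    expect_identical(got, want, info = s)
    hits <- hits + got
  }
  expect_gt(hits, 50L)   # the case mix exercises both outcomes
})

test_that("zero tolerance and singleton sets reduce to literal matching", {
  m <- motifDefinition(
    allowed = list(P1 = "Y", P2 = "R", P3 = "W", P4 = "F", P5 = "N"),
    spacings = data.frame(min = c(2, 0, 3, 0), center = c(2, 0, 3, 0),
                          max = c(2, 0, 3, 0)))
  lit <- "YxxRWyyzFN"
  s <- paste0("AAAA", gsub("[xyz]", "G", lit), "AAAA")
  got <- scanLinear(s, m)
  expect_true(got@matched)
  expect_identical(got@positions[1L], 5L)
  expect_false(scanLinear("YGGRWGGGFD", m)@matched)
})

test_that("widening residue sets or windows never unmatches a sequence", {
  set.seed(44)
  wide <- purineMotif(tolerance = 6L, adjacentTolerance = 2L)
  wide@allowed <- lapply(wide@allowed, function(s) union(s, "G"))
  for (i in 1:50) {
    pl <- plant_default(gaps = c(sample(3:11, 1), sample(6:14, 1),
                                 sample(22:30, 1), sample(0:2, 1)))
    if (scanLinear(pl$seq)@matched)
      expect_true(scanLinear(pl$seq, wide)@matched)
  }
})

test_that("ties in total deviation resolve to the leftmost positions", {
  # two identical planted instances: the left one wins
  set.seed(45)
  gaps <- c(7, 10, 26, 1)
  chars <- rep("G", 130L)
  for (st in c(3L, 60L)) {
    pos <- st + cumsum(c(0, gaps + 1))
    chars[pos] <- c("Y", "R", "W", "F", "N")
    chars[pos[3L] + 1L] <- "F"
  }
  m <- scanLinear(paste0(chars, collapse = ""))
  expect_identical(m@positions[1L], 3L)
})

test_that("aligned scanning classifies the reference and variants", {
  anchor <- mcphReference()
  aln <- alignToReference(anchor@sequence, anchor)
  cmap <- mapPositions(aln, anchor, queryId = "self")
  m <- scanAligned(cmap)[[1L]]
  expect_true(m@matched)
  expect_identical(variant(m), "YRWFD")
  expect_identical(m@positions, c(121L, 129L, 140L, 167L, 169L))
  expect_identical(m@deviations, rep(0, 4))
  # a D169N-like homolog scans as the N variant
  s <- anchor@sequence
  substr(s, 169, 169) <- "N"
  cm2 <- mapPositions(alignToReference(s, anchor), anchor, queryId = "R1")
  expect_identical(variant(scanAligned(cm2)[[1L]]), "YRWFN")
  # disallowed residue at P5 unmatches with a reason
  s2 <- anchor@sequence
  substr(s2, 169, 169) <- "A"
  cm3 <- mapPositions(alignToReference(s2, anchor), anchor, queryId = "x")
  bad <- scanAligned(cm3)[[1L]]
  expect_false(bad@matched)
  expect_match(bad@reason, "P5")
})

test_that("a deleted reference position yields an explicit unmatched reason", {
  anchor <- mcphReference()
  s <- anchor@sequence
  gapped <- paste0(substr(s, 1, 168), "-", substr(s, 170, nchar(s)))
  blk <- alignedBlock(c(setNames(chartr("-", "A", gapped), "other"),
                        setNames(gapped, anchor@id)))
  # reference row content must equal the anchor sequence
  expect_error(mapPositions(blk, anchor), "does not match")
})

test_that("variant tables cover matched and unmatched sequences", {
  set.seed(46)
  ms <- c(lapply(1:3, function(i)
    scanLinear(plant_default()$seq, id = paste0("m", i))),
    list(scanLinear(random_protein(60L), id = "bg")))
  vt <- variantTable(ms)
  expect_identical(nrow(vt), 4L)
  expect_identical(sum(vt$variant == "-"), 1L)
  expect_identical(nrow(variantTable(list())), 0L)
})

test_that("motif derivation recovers a planted definition from a cohort", {
  set.seed(47)
  anchor <- mcphReference()
  blk <- make_aligned_cohort(anchor, nRows = 80L)
  contacts <- c(121L, 129L, 140L, 154L, 156L, 159L, 167L, 169L, 185L, 200L)
  m <- deriveMotif(blk, anchor, contacts)
  want <- purineMotif()
  expect_identical(length(m@positionNames), 5L)
  expect_equal(m@spacings, want@spacings)
  for (i in 1:5)
    expect_setequal(m@allowed[[i]], want@allowed[[i]])
  expect_identical(m@companion$anchor, "P3")
  expect_identical(m@companion$offset, 1L)
  expect_setequal(m@companion$allowed, c("F", "Y", "W"))
})

test_that("derivation fails cleanly when no contact column is conserved", {
  set.seed(48)
  anchor <- mcphReference()
  len <- nchar(anchor@sequence)
  rows <- vapply(1:30, function(i) random_protein(len), character(1))
  names(rows) <- paste0("r", 1:30)
  blk <- alignedBlock(c(setNames(anchor@sequence, anchor@id), rows))
  expect_error(deriveMotif(blk, anchor, c(121L, 140L)), "no motif derivable")
})
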