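# Anchoring alignments, position tracking, conservation, trimming.

test_that("self-alignment is the identity with no gaps", {
  anchor <- mcphReference()
  aln <- alignToReference(anchor@sequence, anchor)
  expect_identical(aln@refGapped, anchor@sequence)
  expect_identical(aln@queryGapped, anchor@sequence)
})

test_that("a single deletion produces exactly one query-row gap", {
  anchor <- mcphReference()
  q <- paste0(substr(anchor@sequence, 1, 99),
              substr(anchor@sequence, 101, nchar(anchor@sequence)))
  aln <- alignToReference(q, anchor, mode = "global")
  gaps <- gregexpr("-", aln@queryGapped)[[1L]]
  expect_identical(length(gaps), 1L)
  expect_identical(unname(gregexpr("-", aln@refGapped)[[1L]][1L]), -1L)
})

test_that("alignment scores equal the affine-gap dynamic-programming oracle", {
  set.seed(21)
  for (i in 1:40) {
    r <- random_protein(sample(2:8, 1))
    q <- random_protein(sample(2:8, 1))
    for (mode in c("semiglobal", "global")) {
      got <- alignToReference(q, r, mode = mode)@score
      want <- gotoh_score(r, q, freeRefEnds = mode == "semiglobal")
      expect_equal(got, want, info = paste(mode, r, q))
    }
  }
})

test_that("sequences outside the amino-acid alphabet are rejected", {
  expect_error(alignToReference("MKZ1", mcphReference()), "alphabet")
})

test_that("tracked positions survive insertions and report gaps", {
  anchor <- mcphReference()
  s <- anchor@sequence
  # insertion before position 129 shifts downstream columns
  q <- paste0(substr(s, 1, 124), "GGG", substr(s, 125, nchar(s)))
  cmap <- mapPositions(alignToReference(q, anchor), anchor)
  expect_identical(unname(cmap@residues[1L, c("P1", "P2")]), c("Y", "R"))
  expect_identical(unname(cmap@queryPositions[1L, "P2"]), 132L)
  # deletion covering position 169 reports a gap for P5
  q2 <- paste0(substr(s, 1, 167), substr(s, 171, nchar(s)))
  cmap2 <- mapPositions(alignToReference(q2, anchor, mode = "global"),
                        anchor)
  expect_identical(unname(cmap2@residues[1L, "P5"]), "-")
})

test_that("tracking through an MSA is stable under added unrelated rows", {
  anchor <- mcphReference()
  s <- anchor@sequence
  rows <- c(setNames(s, anchor@id), q1 = chartr("Y", "F", s))
  cm1 <- mapPositions(alignedBlock(rows), anchor)
  set.seed(31)
  rows2 <- c(rows, junk = random_protein(nchar(s)))
  cm2 <- mapPositions(alignedBlock(rows2), anchor)
  expect_identical(cm1@columns, cm2@columns)
  expect_identical(cm1@residues["q1", ], cm2@residues["q1", ])
  expect_error(mapPositions(alignedBlock(rows), anchor,
                            positions = 9999L), "beyond")
})

test_that("conservation frequencies match direct counting", {
  set.seed(32)
  n <- 100L; w <- 12L
  rows <- vapply(seq_len(n), function(i)
    paste0(sample(c(AA20, "-"), w, replace = TRUE), collapse = ""),
    character(1))
  names(rows) <- paste0("s", seq_len(n))
  blk <- alignedBlock(rows)
  prof <- conservationProfile(blk)
  m <- as.matrix(blk)
  for (col in c(1L, 5L, 12L)) {
    counts <- table(factor(m[, col], levels = rownames(prof@freqs)))
    expect_equal(unname(prof@freqs[, col]), as.numeric(counts) / n)
  }
  expect_equal(colSums(prof@freqs), rep(1, w), tolerance = 1e-9)
})

test_that("conserved-column flags respect the residue set and level", {
  blk <- alignedBlock(c(a = "YY", b = "YY", c = "YF", d = "YF"))
  prof <- conservationProfile(blk)
  expect_true(conservedColumns(prof, "Y", tau = 0.9)[1L])
  expect_false(conservedColumns(prof, "Y", tau = 0.9)[2L])
  expect_true(conservedColumns(prof, c("Y", "F"), tau = 0.9)[2L])
})

test_that("trimming removes gappy columns and honours the keep floor", {
  set.seed(33)
  # 10 columns: 2 with 50% gaps, 8 gapless -> keep the 8
  rows <- replicate(10, paste0(sample(AA20, 10, replace = TRUE),
                               collapse = ""))
  m <- do.call(rbind, strsplit(rows, ""))
  m[1:5, c(3L, 7L)] <- "-"
  blk <- alignedBlock(setNames(apply(m, 1, paste0, collapse = ""),
                               paste0("r", 1:10)))
  tr <- trimAlignment(blk)
  expect_identical(keptColumns(tr), setdiff(1:10, c(3L, 7L)))
  expect_identical(columnCount(tr@block), 8L)
  # all columns gappy -> keep the ceiling(0.6*10) = 6 least gapped
  m2 <- m
  for (j in 1:10) m2[seq_len(j), j] <- "-"   # gap fraction j/10
  blk2 <- alignedBlock(setNames(apply(m2, 1, paste0, collapse = ""),
                                paste0("r", 1:10)))
  expect_identical(keptColumns(trimAlignment(blk2)), 1:6)
  # gapless alignment is untouched
  blk3 <- alignedBlock(setNames(rows, paste0("r", 1:10)))
  expect_identical(keptColumns(trimAlignment(blk3)), 1:10)
})

test_that("trimming is monotone in the gap threshold and bounded below", {
  set.seed(34)
  for (i in 1:25) {
    nr <- sample(4:12, 1); nc <- sample(5:30, 1)
    m <- matrix(sample(c(AA20, "-"), nr * nc, replace = TRUE,
                       prob = c(rep(0.045, 20), 0.10)), nr, nc)
    blk <- alignedBlock(setNames(apply(m, 1, paste0, collapse = ""),
                                 paste0("r", seq_len(nr))))
    k10 <- keptColumns(trimAlignment(blk, 0.10))
    k05 <- keptColumns(trimAlignment(blk, 0.05))
    expect_true(all(k05 %in% k10))
    expect_gte(length(k10), ceiling(0.6 * nc))
  }
})
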