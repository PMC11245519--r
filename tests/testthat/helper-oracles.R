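# Independent oracles and fixture builders used across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

random_protein <- function(len, letters = AA20) {
  paste0(sample(letters, len, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Three-state (Gotoh) affine-gap dynamic program, written independently
# of the package's alignment path.  A gap of length L costs
# open + L * ext.  With freeRefEnds, terminal gaps in the query row
# (reference overhangs) are free.
gotoh_score <- function(ref, query, sub = blosum62, open = 11, ext = 1,
                        freeRefEnds = TRUE) {
  r <- strsplit(ref, "")[[1L]]
  q <- strsplit(query, "")[[1L]]
  n <- length(r); m <- length(q)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in query row (consumes ref)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in ref row (consumes query)
  M[1L, 1L] <- 0
  for (i in seq_len(n))
    X[i + 1L, 1L] <- if (freeRefEnds) 0 else -(open + i * ext)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- sub[r[i - 1L], q[j - 1L]]
      M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(max(M[i - 1L, j], Y[i - 1L, j]) - open - ext,
                     X[i - 1L, j] - ext)
      Y[i, j] <- max(max(M[i, j - 1L], X[i, j - 1L]) - open - ext,
                     Y[i, j - 1L] - ext)
    }
  }
  if (freeRefEnds) {
    max(vapply(seq_len(n + 1L), function(i)
      max(M[i, m + 1L], X[i, m + 1L], Y[i, m + 1L]), numeric(1)))
  } else {
    max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  }
}

# Literal restatement of the trimming rule, for randomized cross-checks.
trim_oracle <- function(mat, gapThreshold = 0.10, keepFraction = 0.60) {
  gf <- colMeans(mat == "-")
  keep <- which(gf < gapThreshold)
  need <- ceiling(keepFraction * ncol(mat))
  if (length(keep) < need)
    keep <- sort(order(gf, seq_along(gf))[seq_len(need)])
  keep
}

# Regular-expression oracle for the linear-scan match decision of the
# default purine motif (companion as a lookahead after P3).
motif_regex <- function(motif = purineMotif(), companion = TRUE) {
  sets <- vapply(motif@allowed, function(s)
    paste0("[", paste(s, collapse = ""), "]"), character(1))
  sp <- motif@spacings
  gaps <- sprintf(".{%d,%d}", sp$min, sp$max)
  comp <- if (companion && length(motif@companion))
    paste0("(?=", "[", paste(motif@companion$allowed, collapse = ""), "])")
    else ""
  # companion offset +1 from P3 sits inside the P3->P4 gap
  paste0(sets[1L], gaps[1L], sets[2L], gaps[2L], sets[3L], comp,
         gaps[3L], sets[4L], gaps[4L], sets[5L])
}

# Fixed-column PDB ATOM/HETATM line builder.
pdb_line <- function(record, serial, name, resn, chain, resno, x, y, z,
                     element) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resn, chain, resno, x, y, z, 1, 0, element)
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Naive all-pairs contact oracle: unique protein residues with any
# heavy-atom pair within cutoff of the ligand.
contact_oracle <- function(atoms, hetResidue, cutoff = 3.5) {
  prot <- atoms[!atoms$het & !atoms$element %in% c("H", "D"), ]
  lig <- atoms[atoms$het & atoms$residue_name == hetResidue &
                 !atoms$element %in% c("H", "D"), ]
  hits <- integer()
  for (i in seq_len(nrow(prot))) for (j in seq_len(nrow(lig))) {
    d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                (prot$z[i] - lig$z[j])^2)
    if (d <= cutoff) hits <- c(hits, prot$residue_seq[i])
  }
  sort(unique(hits))
}

# Aligned (gap-free) cohort sharing the reference coordinate system:
# every row carries a motif variant at the reference anchor columns and
# background everywhere else.  Returns an AlignedBlock including the
# reference row.
make_aligned_cohort <- function(anchor, nRows = 60L,
                                variants = c("YRWFN", "YKWYN", "YRWFD",
                                             "FRFYN", "YKWFN", "YHWFN")) {
  len <- nchar(anchor@sequence)
  rows <- vapply(seq_len(nRows), function(i) {
    chars <- sample(AA20, len, replace = TRUE)
    v <- strsplit(sample(variants, 1L), "")[[1L]]
    chars[anchor@anchorPositions - anchor@offset] <- v
    chars[anchor@companionPosition - anchor@offset] <-
      sample(c("F", "Y", "W"), 1L)
    paste0(chars, collapse = "")
  }, character(1))
  names(rows) <- sprintf("SEQ%03d", seq_len(nRows))
  alignedBlock(c(setNames(anchor@sequence, anchor@id), rows))
}
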