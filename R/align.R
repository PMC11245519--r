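# Anchoring query sequences to the reference domain, tracking reference
# positions through alignments, per-column conservation, and the
# gap-fraction column trimming rule.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

check_alphabet <- function(chr, what = "sequence") {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", chr)
  if (!all(ok))
    stop(what, " contains characters outside the amino-acid alphabet + X")
  invisible(chr)
}

#' Construct a reference anchor
#'
#' @param id Reference identifier.
#' @param sequence Ungapped amino-acid string.
#' @param anchorPositions Full-length residue indices of the motif
#'   positions, strictly increasing.
#' @param companionPosition Full-length index of the structural aromatic
#'   companion (0 to disable).
#' @param offset Difference between full-length numbering and sequence
#'   index (full-length position = index + offset).
#' @return A [ReferenceAnchor].
#' @export
referenceAnchor <- function(id, sequence,
                            anchorPositions = c(121L, 129L, 140L, 167L, 169L),
                            companionPosition = 141L, offset = 0L) {
  sequence <- toupper(as.character(sequence))
  check_alphabet(sequence, "reference")
  new("ReferenceAnchor", id = as.character(id), sequence = sequence,
      offset = as.integer(offset),
      anchorPositions = as.integer(anchorPositions),
      companionPosition = as.integer(companionPosition))
}

#' The bundled McpH dCache_1 reference anchor
#'
#' Loads the packaged reference sequence for the *Pseudomonas putida*
#' McpH ligand-binding domain with the purine-binding site residues
#' Y121, R129, W140, F167 and D169 and the structural aromatic F141 at
#' their published full-length positions.  The bundled sequence is a
#' synthetic stand-in (see the file header and the package vignette):
#' the binding-site and companion residues, and the residues reported to
#' contact the ligand, sit at their published positions; the remainder
#' of the chain is a fixed background.
#'
#' @return A [ReferenceAnchor].
#' @export
mcphReference <- function() {
  fa <- system.file("extdata", "mcph_dcache1_synthetic.fasta",
                    package = "dCachePU", mustWork = TRUE)
  ss <- readSensorSequences(fa)
  referenceAnchor(names(ss)[1L], as.character(ss[[1L]]))
}

#' Align a query to the reference domain
#'
#' Optimal pairwise alignment with affine gap penalties via
#' [Biostrings::pairwiseAlignment()].  In the default semi-global mode
#' terminal gaps in the query row (reference overhangs) are free, which
#' anchors a domain-sized query inside the reference without penalty;
#' `mode = "global"` penalizes all terminal gaps.
#'
#' @param query An `AAString`/`AAStringSet` element or character string.
#' @param anchor A [ReferenceAnchor] (or plain character reference).
#' @param mode `"semiglobal"` or `"global"`.
#' @param substitutionMatrix Name of, or an actual, substitution matrix
#'   (default BLOSUM62).
#' @param gapOpening,gapExtension Affine gap penalties; a gap of length L
#'   costs `gapOpening + L * gapExtension`.
#' @return An [AnchorAlignment] whose gapped rows cover the full
#'   reference (free overhangs included).
#' @export
alignToReference <- function(query, anchor, mode = c("semiglobal", "global"),
                             substitutionMatrix = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1) {
  mode <- match.arg(mode)
  qchr <- toupper(as.character(query))
  rchr <- if (is(anchor, "ReferenceAnchor")) anchor@sequence
          else toupper(as.character(anchor))
  if (!nzchar(qchr) || !nzchar(rchr)) stop("empty sequence")
  check_alphabet(qchr, "query")
  check_alphabet(rchr, "reference")
  if (is.character(substitutionMatrix) && length(substitutionMatrix) == 1L) {
    e <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
    substitutionMatrix <- get(substitutionMatrix, envir = e)
  }
  type <- if (mode == "semiglobal") "global-local" else "global"
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(qchr), subject = Biostrings::AAString(rchr),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension, type = type)
  qg <- as.character(Biostrings::pattern(aln))
  rg <- as.character(Biostrings::subject(aln))
  if (mode == "semiglobal") {
    # reinstate free reference overhangs as terminal query gaps
    s <- Biostrings::start(Biostrings::subject(aln))
    e <- Biostrings::end(Biostrings::subject(aln))
    pre <- substr(rchr, 1L, s - 1L)
    post <- substr(rchr, e + 1L, nchar(rchr))
    rg <- paste0(pre, rg, post)
    qg <- paste0(strrep("-", nchar(pre)), qg, strrep("-", nchar(post)))
  }
  new("AnchorAlignment", refGapped = rg, queryGapped = qg,
      score = Biostrings::score(aln), mode = mode)
}

#' @importFrom Biostrings start end
NULL

# column index of each ungapped position of a gapped row
ungapped_to_column <- function(gapped) {
  chars <- strsplit(gapped, "")[[1L]]
  which(chars != "-")
}

#' @describeIn mapPositions Track positions through a pairwise anchoring
#'   alignment.  `anchor` supplies the tracked positions (motif anchors
#'   plus companion); pass `positions` to track an arbitrary set instead.
#' @param positions Optional integer vector (full-length numbering)
#'   overriding the anchor's tracked positions.
#' @param queryId Identifier used for the query row.
#' @export
setMethod("mapPositions", signature("AnchorAlignment", "ReferenceAnchor"),
  function(alignment, anchor, positions = NULL, queryId = "query") {
    pos <- tracked_positions(anchor, positions)
    refcols <- ungapped_to_column(alignment@refGapped)
    idx <- pos - anchor@offset
    if (any(idx < 1L | idx > length(refcols)))
      stop("tracked position beyond the reference ungapped length")
    cols <- refcols[idx]
    build_column_map(anchor@id, pos, cols,
                     setNames(alignment@queryGapped, queryId))
  })

#' @describeIn mapPositions Track positions through a multiple alignment
#'   containing the reference as row `referenceId`.
#' @param referenceId Name of the reference row in the block.
#' @export
setMethod("mapPositions", signature("AlignedBlock", "ReferenceAnchor"),
  function(alignment, anchor, referenceId = anchor@id, positions = NULL) {
    rows <- as.character(alignment@rows)
    if (!referenceId %in% names(rows))
      stop("reference row '", referenceId, "' absent from the alignment")
    pos <- tracked_positions(anchor, positions)
    if (gsub("-", "", rows[[referenceId]]) != anchor@sequence)
      stop("reference row '", referenceId,
           "' does not match the anchor sequence")
    refcols <- ungapped_to_column(rows[[referenceId]])
    idx <- pos - anchor@offset
    if (any(idx < 1L | idx > length(refcols)))
      stop("tracked position beyond the reference ungapped length")
    cols <- refcols[idx]
    build_column_map(referenceId, pos, cols,
                     rows[names(rows) != referenceId])
  })

tracked_positions <- function(anchor, positions) {
  if (!is.null(positions)) {
    pos <- as.integer(positions)
    if (is.null(names(pos))) names(pos) <- paste0("pos", pos)
    return(pos)
  }
  pos <- anchor@anchorPositions
  names(pos) <- paste0("P", seq_along(pos))
  if (anchor@companionPosition != 0L)
    pos <- sort(c(pos, companion = anchor@companionPosition))
  pos
}

build_column_map <- function(referenceId, pos, cols, gappedRows) {
  n <- length(gappedRows)
  res <- matrix("-", nrow = n, ncol = length(pos),
                dimnames = list(names(gappedRows), names(pos)))
  qpos <- matrix(NA_integer_, nrow = n, ncol = length(pos),
                 dimnames = dimnames(res))
  for (i in seq_len(n)) {
    chars <- strsplit(gappedRows[[i]], "")[[1L]]
    ungapped <- cumsum(chars != "-")
    ok <- !is.na(cols)
    res[i, ok] <- chars[cols[ok]]
    hit <- ok & res[i, ] != "-"
    qpos[i, hit] <- ungapped[cols[hit]]
  }
  new("ColumnMap", referenceId = referenceId, positions = pos,
      columns = setNames(as.integer(cols), names(pos)),
      residues = res, queryPositions = qpos)
}

#' Per-column conservation of an alignment
#'
#' Computes per-column relative residue frequencies (over all rows, so
#' frequencies plus the gap fraction sum to one) from which conservation
#' of a residue set can be assessed with [conservedColumns()].
#'
#' @param block An [AlignedBlock] with at least two rows.
#' @return A [ConservationProfile].
#' @export
conservationProfile <- function(block) {
  stopifnot(is(block, "AlignedBlock"))
  if (length(block@rows) < 2L)
    stop("conservation needs at least two alignment rows")
  cm <- Biostrings::consensusMatrix(block@rows)
  freqs <- sweep(cm, 2L, colSums(cm), "/")
  gap <- if ("-" %in% rownames(freqs)) freqs["-", ] else
    numeric(ncol(freqs))
  new("ConservationProfile", freqs = freqs, gapFraction = unname(gap),
      nRows = length(block@rows))
}

#' Flag columns conserved for a residue set
#'
#' A column is conserved for set `set` at level `tau` when the summed
#' frequency of `set` among non-gap rows is at least `tau`.
#'
#' @param profile A [ConservationProfile].
#' @param set Character vector of residue letters.
#' @param tau Conservation level in (0, 1], default 0.9.
#' @param maxGap Columns with gap fraction above this are never conserved
#'   (default 0.5).
#' @return Logical vector, one element per column.
#' @export
conservedColumns <- function(profile, set, tau = 0.9, maxGap = 0.5) {
  inset <- intersect(set, rownames(profile@freqs))
  f <- if (length(inset)) colSums(profile@freqs[inset, , drop = FALSE])
       else numeric(ncol(profile@freqs))
  nongap <- 1 - profile@gapFraction
  ok <- nongap > 0 & profile@gapFraction <= maxGap
  out <- rep(FALSE, ncol(profile@freqs))
  out[ok] <- (f[ok] / nongap[ok]) >= tau
  out
}

#' Trim alignment columns by gap fraction
#'
#' Removes columns whose gap fraction is at or above `gapThreshold`,
#' unless that would leave fewer than `keepFraction` of the columns; in
#' that case the `ceiling(keepFraction * ncol)` columns with the smallest
#' gap fractions are kept (ties broken by the lower column index).
#'
#' @param block An [AlignedBlock].
#' @param gapThreshold Gap-fraction removal threshold, closed at the
#'   bottom (default 0.10: columns with 10% or more gaps go).
#' @param keepFraction Minimum fraction of columns retained (default
#'   0.60).
#' @return A [TrimResult].
#' @export
trimAlignment <- function(block, gapThreshold = 0.10, keepFraction = 0.60) {
  stopifnot(is(block, "AlignedBlock"))
  m <- do.call(rbind, strsplit(as.character(block@rows), ""))
  gf <- colMeans(m == "-")
  nc <- length(gf)
  kept <- which(gf < gapThreshold)
  minKeep <- ceiling(keepFraction * nc)
  if (length(kept) < minKeep)
    kept <- sort(order(gf, seq_len(nc))[seq_len(minKeep)])
  chr <- apply(m[, kept, drop = FALSE], 1L, paste0, collapse = "")
  names(chr) <- names(block@rows)
  new("TrimResult", keptColumns = as.integer(kept),
      block = alignedBlock(chr), gapFraction = unname(gf))
}
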