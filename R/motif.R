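# The purine-binding motif: definition, derivation from conservation +
# structural contacts, and scanning in alignment-anchored or linear
# (spacing-window) mode.

#' Construct a motif definition
#'
#' @param allowed Named list of allowed residue sets, one per motif
#'   position, in order (most frequent residue first).
#' @param spacings Data frame with columns `min`, `center`, `max`: the
#'   number of residues strictly between consecutive motif positions.
#' @param companion `NULL`, or a list with `anchor` (motif position
#'   name), `offset` (signed residue offset from the anchor) and
#'   `allowed` (residue set).
#' @return A [MotifDefinition].
#' @export
motifDefinition <- function(allowed, spacings, companion = NULL) {
  nm <- names(allowed)
  if (is.null(nm)) nm <- paste0("P", seq_along(allowed))
  spacings <- as.data.frame(spacings)
  if (!"center" %in% names(spacings))
    spacings$center <- (spacings$min + spacings$max) / 2
  new("MotifDefinition", positionNames = nm,
      allowed = lapply(allowed, function(s) toupper(as.character(s))),
      spacings = spacings[c("min", "center", "max")],
      companion = if (is.null(companion)) list() else companion)
}

#' The default purine-binding motif
#'
#' Five positions with the allowed residue sets observed across
#' experimentally characterized purine sensors -- P1 \{Y,F\}, P2 \{R,K,H\},
#' P3 \{W,F\}, P4 \{F,Y\}, P5 \{N,D\} -- separated by 7, 10, 26 and 1
#' residues in the McpH reference (positions Y121, R129, W140, F167,
#' D169), with a spacing tolerance that absorbs indels between motif
#' positions, plus the structural aromatic companion immediately after
#' P3 (F141 in McpH).
#'
#' @param tolerance Spacing tolerance applied to the three long gaps
#'   (default 4 residues either way).
#' @param adjacentTolerance Tolerance for the short P4-P5 gap (default 1).
#' @param companion Set `FALSE` to drop the companion position.
#' @return A [MotifDefinition].
#' @examples
#' purineMotif()
#' @export
purineMotif <- function(tolerance = 4L, adjacentTolerance = 1L,
                        companion = TRUE) {
  centers <- c(7L, 10L, 26L, 1L)
  tol <- c(tolerance, tolerance, tolerance, adjacentTolerance)
  motifDefinition(
    allowed = list(P1 = c("Y", "F"), P2 = c("R", "K", "H"),
                   P3 = c("W", "F"), P4 = c("F", "Y"), P5 = c("N", "D")),
    spacings = data.frame(min = pmax(centers - tol, 0L), center = centers,
                          max = centers + tol),
    companion = if (isTRUE(companion))
      list(anchor = "P3", offset = 1L, allowed = c("F", "Y", "W"))
      else NULL)
}

#' @rdname MotifDefinition-class
#' @export
setMethod("motifPositions", "MotifDefinition", function(object)
  setNames(object@allowed, object@positionNames))

#' @rdname MotifDefinition-class
#' @export
setMethod("motifSpacings", "MotifDefinition", function(object)
  object@spacings)

#' Derive a motif from conservation and structural contacts
#'
#' Keeps the ligand-contacting reference positions whose alignment
#' columns are consistently conserved, reads each kept position's allowed
#' residue set off the column composition, and sets spacing windows from
#' the reference gaps.  A contact column counts as conserved when the
#' residues individually reaching frequency `tauRes` among non-gap rows
#' together cover at least `tau` of the non-gap rows and number at most
#' `maxSetSize` (a position admitting many alternatives is not a motif
#' position).
#'
#' @param block An [AlignedBlock] containing the reference row.
#' @param anchor A [ReferenceAnchor]; its sequence must be the reference
#'   row content ungapped.
#' @param contactPositions Ligand-contacting reference positions
#'   (full-length numbering), e.g. from [proposeBindingPositions()].
#' @param referenceId Reference row name (default `anchor@id`).
#' @param tau Conservation level (default 0.9).
#' @param tauRes Minimum residue frequency for membership in an allowed
#'   set (default 0.05).
#' @param maxSetSize Largest admissible allowed set (default 4).
#' @param tolerance,adjacentTolerance Spacing tolerances as in
#'   [purineMotif()]; gaps of 2 residues or fewer get
#'   `adjacentTolerance`.
#' @param companionPosition Optional conserved structural position
#'   (full-length numbering) recorded as the companion; default taken
#'   from the anchor.
#' @return A [MotifDefinition].
#' @export
deriveMotif <- function(block, anchor, contactPositions,
                        referenceId = anchor@id, tau = 0.9, tauRes = 0.05,
                        maxSetSize = 4L, tolerance = 4L,
                        adjacentTolerance = 1L,
                        companionPosition = anchor@companionPosition) {
  contactPositions <- sort(unique(as.integer(contactPositions)))
  if (length(contactPositions) == 0L) stop("no contact positions supplied")
  cmap <- mapPositions(block, anchor, referenceId = referenceId,
                       positions = contactPositions)
  prof <- conservationProfile(block)
  pick <- function(col) {
    if (is.na(col)) return(NULL)
    nongap <- 1 - prof@gapFraction[col]
    if (nongap <= 0.5) return(NULL)
    f <- prof@freqs[setdiff(rownames(prof@freqs), "-"), col] / nongap
    set <- names(sort(f[f >= tauRes], decreasing = TRUE))
    if (length(set) == 0L || length(set) > maxSetSize) return(NULL)
    if (sum(f[set]) < tau) return(NULL)
    set
  }
  sets <- lapply(cmap@columns, pick)
  keep <- !vapply(sets, is.null, logical(1))
  if (!any(keep)) stop("no motif derivable: no conserved contact positions")
  pos <- contactPositions[keep]
  sets <- sets[keep]
  names(sets) <- paste0("P", seq_along(sets))
  centers <- diff(pos) - 1L
  tol <- ifelse(centers <= 2L, adjacentTolerance, tolerance)
  companion <- NULL
  if (!is.null(companionPosition) && length(companionPosition) &&
      companionPosition != 0L && !companionPosition %in% pos) {
    near <- which.min(abs(pos - companionPosition))
    ccol <- mapPositions(block, anchor, referenceId = referenceId,
                         positions = companionPosition)@columns
    cset <- pick(ccol)
    if (!is.null(cset))
      companion <- list(anchor = paste0("P", near),
                        offset = as.integer(companionPosition - pos[near]),
                        allowed = cset)
  }
  motifDefinition(sets,
                  data.frame(min = pmax(centers - tol, 0L), center = centers,
                             max = centers + tol),
                  companion)
}

no_match <- function(id, reason, companion = NA) {
  new("MotifMatch", id = id, matched = FALSE, variant = "-",
      positions = integer(), deviations = numeric(),
      companionOk = as.logical(companion), reason = reason)
}

#' Scan a sequence for the motif by residue spacings
#'
#' Enumerates all position tuples whose residues lie in the allowed sets
#' with inter-position spacings inside the motif windows (and, when the
#' motif defines one and `requireCompanion` is `TRUE`, an allowed
#' companion residue at its offset).  Of all satisfying tuples the one
#' with minimal total absolute spacing deviation is reported, ties
#' resolved towards the leftmost positions.  Unknown residues (`X`)
#' never match.
#'
#' @param seq An `AAString`, single `AAStringSet` element or character
#'   string.
#' @param motif A [MotifDefinition] (default [purineMotif()]).
#' @param requireCompanion Whether a defined companion must match
#'   (default `TRUE`).
#' @param id Identifier stored in the result.
#' @param allCandidates If `TRUE`, attach all satisfying tuples (up to
#'   `maxCandidates`) as a data.frame in attribute `"candidates"`.
#' @param maxCandidates Cap for `allCandidates` (default 10).
#' @return A [MotifMatch].
#' @export
scanLinear <- function(seq, motif = purineMotif(), requireCompanion = TRUE,
                       id = "query", allCandidates = FALSE,
                       maxCandidates = 10L) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1L]]
  if (length(chars) == 0L) stop("empty sequence")
  k <- length(motif@positionNames)
  sp <- motif@spacings
  cand <- lapply(motif@allowed, function(set) which(chars %in% set))
  if (any(vapply(cand, length, integer(1)) == 0L))
    return(no_match(id, "missing allowed residue for some motif position"))
  comp <- motif@companion
  useComp <- requireCompanion && length(comp) > 0L
  compIdx <- if (length(comp)) match(comp$anchor, motif@positionNames) else NA
  tuples <- list(matrix(cand[[1L]], ncol = 1L))
  for (j in seq_len(k - 1L)) {
    prev <- tuples[[j]]
    if (nrow(prev) == 0L) break
    nxt <- lapply(seq_len(nrow(prev)), function(r) {
      p <- prev[r, j]
      ok <- cand[[j + 1L]][cand[[j + 1L]] - p - 1L >= sp$min[j] &
                           cand[[j + 1L]] - p - 1L <= sp$max[j]]
      if (length(ok) == 0L) return(NULL)
      cbind(matrix(prev[r, ], nrow = length(ok), ncol = j, byrow = TRUE), ok)
    })
    grown <- do.call(rbind, nxt)
    if (is.null(grown)) grown <- matrix(0L, 0L, j + 1L)
    tuples[[j + 1L]] <- grown
  }
  tup <- tuples[[min(length(tuples), k)]]
  if (ncol(tup) < k || nrow(tup) == 0L)
    return(no_match(id, "no position tuple satisfies the spacing windows"))
  compOk <- rep(NA, nrow(tup))
  if (length(comp)) {
    cpos <- tup[, compIdx] + comp$offset
    inside <- cpos >= 1L & cpos <= length(chars)
    compOk <- inside & chars[pmax(pmin(cpos, length(chars)), 1L)] %in%
      comp$allowed
  }
  if (useComp) {
    tup <- tup[compOk, , drop = FALSE]
    compOk <- compOk[compOk]
    if (nrow(tup) == 0L)
      return(no_match(id, "companion aromatic absent", companion = FALSE))
  }
  gaps <- tup[, -1L, drop = FALSE] - tup[, -k, drop = FALSE] - 1L
  dev <- sweep(gaps, 2L, sp$center)
  total <- rowSums(abs(dev))
  ord <- do.call(order, c(list(total), lapply(seq_len(k), function(j)
    tup[, j])))
  best <- ord[1L]
  m <- new("MotifMatch", id = id, matched = TRUE,
           variant = paste0(chars[tup[best, ]], collapse = ""),
           positions = as.integer(tup[best, ]),
           deviations = as.numeric(dev[best, ]),
           companionOk = as.logical(compOk[best]), reason = "")
  if (allCandidates) {
    sel <- ord[seq_len(min(length(ord), maxCandidates))]
    attr(m, "candidates") <- data.frame(
      tup[sel, , drop = FALSE] |>
        `colnames<-`(motif@positionNames),
      total_deviation = total[sel],
      variant = apply(tup[sel, , drop = FALSE], 1L, function(p)
        paste0(chars[p], collapse = "")))
  }
  m
}

#' Scan aligned sequences at the motif's reference columns
#'
#' Classifies every sequence of a [ColumnMap] built against the motif's
#' reference: a sequence matches when each motif position carries a
#' non-gap residue from the allowed set at the tracked column (and, when
#' required, the companion column holds an allowed residue).
#'
#' @param columnMap A [ColumnMap] whose tracked positions `P1..Pk`
#'   (plus optionally `companion`) come from the same reference as the
#'   motif.
#' @param motif A [MotifDefinition].
#' @param requireCompanion Whether a defined companion must match.
#' @return A list of [MotifMatch], one per mapped sequence.
#' @export
scanAligned <- function(columnMap, motif = purineMotif(),
                        requireCompanion = TRUE) {
  k <- length(motif@positionNames)
  pn <- intersect(colnames(columnMap@residues), motif@positionNames)
  if (length(pn) != k)
    stop("column map does not track all motif positions")
  comp <- motif@companion
  useComp <- requireCompanion && length(comp) > 0L
  hasCompCol <- "companion" %in% colnames(columnMap@residues)
  ids <- rownames(columnMap@residues)
  lapply(seq_along(ids), function(i) {
    id <- ids[i]
    if (anyNA(columnMap@columns[pn]))
      return(no_match(id, "reference position deleted from the alignment"))
    res <- columnMap@residues[i, pn]
    ok <- mapply(function(r, set) r %in% set, res, motif@allowed)
    compOk <- NA
    if (length(comp) && hasCompCol) {
      cc <- columnMap@columns[["companion"]]
      compOk <- !is.na(cc) &&
        columnMap@residues[i, "companion"] %in% comp$allowed
    }
    if (!all(ok))
      return(no_match(id, paste0("disallowed residue at ",
                                 paste(pn[!ok], collapse = ",")),
                      companion = compOk))
    if (useComp && !isTRUE(compOk))
      return(no_match(id, "companion aromatic absent", companion = FALSE))
    pos <- columnMap@queryPositions[i, pn]
    gaps <- diff(pos) - 1L
    new("MotifMatch", id = id, matched = TRUE,
        variant = paste0(res, collapse = ""), positions = as.integer(pos),
        deviations = as.numeric(gaps - motif@spacings$center),
        companionOk = as.logical(compOk), reason = "")
  })
}

#' Tabulate motif-scan results
#'
#' @param matches A list of [MotifMatch] (or a single one).
#' @return A data.frame with columns `id`, `variant`, `matched`;
#'   unmatched sequences carry variant `"-"`.
#' @export
variantTable <- function(matches) {
  if (is(matches, "MotifMatch")) matches <- list(matches)
  if (length(matches) == 0L)
    return(data.frame(id = character(), variant = character(),
                      matched = logical()))
  data.frame(
    id = vapply(matches, function(m) m@id, character(1)),
    variant = vapply(matches, function(m) m@variant, character(1)),
    matched = vapply(matches, function(m) m@matched, logical(1)),
    stringsAsFactors = FALSE)
}

#' Read / write a motif definition as YAML
#'
#' The schema mirrors the [MotifDefinition] slots: a `positions` list of
#' `{name, residues}`, a `spacings` list of `{min, center, max}`, and an
#' optional `companion` of `{anchor, offset, residues}`.
#'
#' @param path YAML file path.
#' @return `readMotifYaml`: a [MotifDefinition].
#' @export
readMotifYaml <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setNames(lapply(y$positions, function(p)
    as.character(p$residues)),
    vapply(y$positions, function(p) p$name, character(1)))
  sp <- do.call(rbind, lapply(y$spacings, function(s)
    data.frame(min = s$min,
               center = if (is.null(s$center)) (s$min + s$max) / 2
                        else s$center,
               max = s$max)))
  comp <- if (!is.null(y$companion))
    list(anchor = y$companion$anchor, offset = y$companion$offset,
         allowed = as.character(y$companion$residues))
  motifDefinition(allowed, sp, comp)
}

#' @rdname readMotifYaml
#' @param motif A [MotifDefinition].
#' @export
writeMotifYaml <- function(motif, path) {
  y <- list(
    positions = lapply(seq_along(motif@positionNames), function(i)
      list(name = motif@positionNames[i], residues = motif@allowed[[i]])),
    spacings = lapply(seq_len(nrow(motif@spacings)), function(i)
      as.list(motif@spacings[i, ])))
  if (length(motif@companion))
    y$companion <- list(anchor = motif@companion$anchor,
                        offset = motif@companion$offset,
                        residues = motif@companion$allowed)
  yaml::write_yaml(y, path)
  invisible(path)
}
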