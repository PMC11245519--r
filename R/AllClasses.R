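#' @import methods
#' @importFrom Biostrings AAStringSet width readAAStringSet writeXStringSet
#'   pairwiseAlignment consensusMatrix pattern subject score AAString
#' @importFrom stats median rnorm runif setNames filter approx
#' @importFrom utils read.table write.table head tail
NULL

# Central S4 containers.  Sequence collections are plain Biostrings
# AAStringSet objects throughout; the classes below hold everything the
# pipeline derives from them.

#' Gapped multiple sequence alignment block
#'
#' A light container for a multiple sequence alignment: a set of
#' equal-length gapped amino-acid strings (gap character `-`).
#'
#' @slot rows An [Biostrings::AAStringSet] of gapped rows, all the same width.
#' @export
setClass("AlignedBlock", representation(rows = "AAStringSet"))

setValidity("AlignedBlock", function(object) {
  w <- Biostrings::width(object@rows)
  if (length(w) == 0L) return("alignment has no rows")
  if (length(unique(w)) != 1L)
    return(sprintf("rows have unequal widths (%s)",
                   paste(unique(w), collapse = ", ")))
  ids <- names(object@rows)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all rows must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate row identifiers: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' Reference anchor for position tracking
#'
#' Binds a reference sensor-domain sequence to the residue positions that
#' define the purine-binding site, in the reference's own (full-length
#' protein) numbering.
#'
#' @slot id Reference sequence identifier.
#' @slot sequence Ungapped amino-acid string of the reference.
#' @slot offset Integer; full-length position = sequence index + offset.
#' @slot anchorPositions Strictly increasing full-length residue indices of
#'   the motif positions.
#' @slot companionPosition Full-length index of the structural aromatic
#'   companion position (0 if unused).
#' @export
setClass("ReferenceAnchor", representation(
  id = "character", sequence = "character", offset = "integer",
  anchorPositions = "integer", companionPosition = "integer"))

setValidity("ReferenceAnchor", function(object) {
  if (nchar(object@sequence) == 0L) return("empty reference sequence")
  ap <- object@anchorPositions
  if (length(ap) == 0L || any(diff(ap) <= 0L))
    return("anchor positions must be strictly increasing")
  idx <- ap - object@offset
  if (any(idx < 1L) || any(idx > nchar(object@sequence)))
    return("anchor positions outside the reference sequence")
  cp <- object@companionPosition
  if (cp != 0L && (cp - object@offset < 1L ||
                   cp - object@offset > nchar(object@sequence)))
    return("companion position outside the reference sequence")
  TRUE
})

#' Pairwise anchoring alignment
#'
#' Result of aligning a query sequence against the reference domain:
#' two equal-length gapped strings and the alignment score.
#'
#' @slot refGapped,queryGapped Equal-length gapped strings.
#' @slot score Alignment score.
#' @slot mode `"semiglobal"` (terminal gaps in the query row free) or
#'   `"global"`.
#' @export
setClass("AnchorAlignment", representation(
  refGapped = "character", queryGapped = "character",
  score = "numeric", mode = "character"))

setValidity("AnchorAlignment", function(object) {
  if (nchar(object@refGapped) != nchar(object@queryGapped))
    return("gapped rows differ in length")
  TRUE
})

#' Map from reference anchor positions to alignment columns
#'
#' For each tracked reference position: the alignment column holding that
#' reference residue (NA if the residue is deleted from the alignment),
#' and, per aligned sequence, the residue letter (or `-`) and its ungapped
#' position in that sequence.
#'
#' @slot referenceId Identifier of the reference row.
#' @slot positions Tracked reference positions (full-length numbering);
#'   names label the positions (e.g. `P1`..`P5`, `companion`).
#' @slot columns Alignment column per tracked position (NA if deleted).
#' @slot residues Character matrix, sequences x positions.
#' @slot queryPositions Integer matrix of ungapped indices (NA at gaps).
#' @export
setClass("ColumnMap", representation(
  referenceId = "character", positions = "integer", columns = "integer",
  residues = "matrix", queryPositions = "matrix"))

setValidity("ColumnMap", function(object) {
  cc <- object@columns[!is.na(object@columns)]
  if (length(cc) > 1L && any(diff(cc) <= 0L))
    return("mapped columns must be strictly increasing")
  if (length(object@positions) != length(object@columns))
    return("positions and columns differ in length")
  TRUE
})

#' Per-column conservation profile of an alignment
#'
#' @slot freqs Numeric matrix (residue letters + `-` by columns): per-column
#'   relative frequencies over all rows; each column sums to 1.
#' @slot gapFraction Per-column gap fraction (the `-` row of `freqs`).
#' @slot nRows Number of alignment rows.
#' @export
setClass("ConservationProfile", representation(
  freqs = "matrix", gapFraction = "numeric", nRows = "integer"))

#' Result of gap-fraction alignment trimming
#'
#' @slot keptColumns Strictly increasing original column indices retained.
#' @slot block The trimmed [AlignedBlock].
#' @slot gapFraction Gap fraction of every original column.
#' @export
setClass("TrimResult", representation(
  keptColumns = "integer", block = "AlignedBlock", gapFraction = "numeric"))

#' Purine-binding motif definition
#'
#' An ordered set of motif positions with allowed residue sets, spacing
#' windows between consecutive positions (counting residues strictly
#' between them), and an optional structural aromatic companion position
#' at a fixed offset from one of the motif positions.
#'
#' @slot positionNames Names of the motif positions (e.g. `P1`..`P5`).
#' @slot allowed List of allowed residue sets, one per position, ordered
#'   by preference (most frequent first).
#' @slot spacings Data frame with columns `min`, `center`, `max`: the
#'   spacing window and its center for each consecutive pair.
#' @slot companion List with elements `anchor` (position name), `offset`
#'   (signed residue offset) and `allowed` (residue set), or empty list.
#' @export
setClass("MotifDefinition", representation(
  positionNames = "character", allowed = "list",
  spacings = "data.frame", companion = "list"))

setValidity("MotifDefinition", function(object) {
  k <- length(object@positionNames)
  if (k < 2L) return("a motif needs at least two positions")
  if (length(object@allowed) != k)
    return("one allowed residue set per position required")
  if (nrow(object@spacings) != k - 1L)
    return("spacings must have exactly one row per consecutive pair")
  if (any(object@spacings$min > object@spacings$max))
    return("spacing min must not exceed max")
  if (any(object@spacings$min < 0))
    return("spacings are residue counts and must be non-negative")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- vapply(object@allowed, function(s)
    length(s) == 0L || !all(s %in% aa), logical(1))
  if (any(bad))
    return("allowed sets must be non-empty subsets of the 20 amino acids")
  if (length(object@companion)) {
    if (!all(c("anchor", "offset", "allowed") %in% names(object@companion)))
      return("companion needs anchor, offset and allowed")
    if (!object@companion$anchor %in% object@positionNames)
      return("companion anchor is not a motif position")
  }
  TRUE
})

#' Result of scanning one sequence for the motif
#'
#' @slot id Sequence identifier.
#' @slot matched Whether the motif was found.
#' @slot variant Concatenated residues at the motif positions (`"-"` when
#'   unmatched).
#' @slot positions 1-based residue indices of the matched positions.
#' @slot deviations Signed offsets of each realized spacing from its
#'   window center.
#' @slot companionOk Whether the companion position held an allowed residue
#'   (NA when no companion is defined).
#' @slot reason Why the sequence failed to match (empty when matched).
#' @export
setClass("MotifMatch", representation(
  id = "character", matched = "logical", variant = "character",
  positions = "integer", deviations = "numeric", companionOk = "logical",
  reason = "character"))

#' Cohort summary of motif variants by receptor class and taxonomy
#'
#' @slot counts Data frame with columns `variant`, `receptor_class`,
#'   `taxon`, `count`.
#' @slot nMatched Number of matched proteins summarized.
#' @slot rank Taxonomic rank used for the `taxon` margin.
#' @export
setClass("SummaryReport", representation(
  counts = "data.frame", nMatched = "integer", rank = "character"))

#' Isothermal titration calorimetry injection series
#'
#' Raw per-injection heats of a titration together with the cell and
#' syringe concentrations and the injection schedule.
#'
#' @slot cellVolume Active cell volume V0 in litres.
#' @slot cellConc Protein concentration in the cell, mol/L.
#' @slot syringeConc Ligand concentration in the syringe, mol/L.
#' @slot injectionVolumes Injection volumes in litres.
#' @slot rawHeats Measured heats per injection, microcalories.
#' @slot dilutionHeats Ligand-into-buffer dilution heats, microcalories:
#'   either one value per injection, a single mean value, or empty
#'   (no correction available).
#' @export
setClass("TitrationSeries", representation(
  cellVolume = "numeric", cellConc = "numeric", syringeConc = "numeric",
  injectionVolumes = "numeric", rawHeats = "numeric",
  dilutionHeats = "numeric"))

setValidity("TitrationSeries", function(object) {
  if (object@cellVolume <= 0) return("cell volume must be positive")
  if (object@cellConc <= 0 || object@syringeConc <= 0)
    return("concentrations must be positive")
  if (any(object@injectionVolumes <= 0))
    return("injection volumes must be positive")
  if (length(object@rawHeats) != length(object@injectionVolumes))
    return("one raw heat per injection required")
  nd <- length(object@dilutionHeats)
  if (!nd %in% c(0L, 1L, length(object@rawHeats)))
    return("dilution heats must be empty, scalar, or one per injection")
  TRUE
})

#' One-binding-site fit of an ITC titration
#'
#' @slot kd Dissociation constant, mol/L; `kdSE` its asymptotic standard
#'   error.
#' @slot dh Binding enthalpy, kcal/mol; `dhSE` its standard error.
#' @slot n Stoichiometry (sites per protein); `nSE` its standard error.
#' @slot residualNorm Root-mean-square residual of the fit, kcal/mol.
#' @slot converged Whether the optimizer converged to a binding model.
#' @slot status `"ok"`, `"no-binding"` or `"not-converged"`.
#' @slot normalizedHeats Dilution-corrected heats per mole of injectant
#'   (kcal/mol), first injection included.
#' @slot fitted Model heats (kcal/mol) for the fitted injections.
#' @slot usedInjections Indices of injections entering the fit.
#' @export
setClass("OneSiteFit", representation(
  kd = "numeric", kdSE = "numeric", dh = "numeric", dhSE = "numeric",
  n = "numeric", nSE = "numeric", residualNorm = "numeric",
  converged = "logical", status = "character",
  normalizedHeats = "numeric", fitted = "numeric",
  usedInjections = "integer"))

#' Thermal-shift assay melt curve
#'
#' @slot temperatures Strictly increasing temperatures, degrees C.
#' @slot fluorescence Fluorescence readings, arbitrary units.
#' @export
setClass("MeltCurve", representation(
  temperatures = "numeric", fluorescence = "numeric"))

setValidity("MeltCurve", function(object) {
  if (length(object@temperatures) < 10L)
    return("a melt curve needs at least 10 points")
  if (length(object@temperatures) != length(object@fluorescence))
    return("temperatures and fluorescence differ in length")
  if (any(diff(object@temperatures) <= 0))
    return("temperatures must be strictly increasing")
  TRUE
})

#' Melting-temperature call from a melt curve
#'
#' @slot tm Melting temperature (degrees C; NA when no transition).
#' @slot peakHeight Height of the first-derivative peak.
#' @slot noiseFloor Noise floor the peak was compared against.
#' @slot transition Whether a transition was detected.
#' @export
setClass("TmCall", representation(
  tm = "numeric", peakHeight = "numeric", noiseFloor = "numeric",
  transition = "logical"))

#' Fold change between two dissociation constants
#'
#' @slot ratio Mutant/reference KD ratio.
#' @slot rounded Ratio rounded to the nearest integer (half away from
#'   zero).
#' @export
setClass("FoldChange", representation(
  ratio = "numeric", rounded = "integer"))
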