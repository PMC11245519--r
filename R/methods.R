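# Accessors and show methods.

#' @rdname AlignedBlock-class
#' @export
setMethod("columnCount", "AlignedBlock", function(object)
  unname(Biostrings::width(object@rows)[1L]))

#' @rdname AlignedBlock-class
#' @export
setMethod("alignmentIds", "AlignedBlock", function(object)
  names(object@rows))

#' @rdname AlignedBlock-class
#' @param x An `AlignedBlock`.
#' @param ... Unused.
#' @export
setMethod("as.matrix", "AlignedBlock", function(x, ...)
  do.call(rbind, strsplit(as.character(x@rows), "")))

setMethod("show", "AlignedBlock", function(object) {
  cat("AlignedBlock:", length(object@rows), "rows x",
      columnCount(object), "columns\n")
})

setMethod("show", "ReferenceAnchor", function(object) {
  idx <- object@anchorPositions - object@offset
  res <- substring(object@sequence, idx, idx)
  cat("ReferenceAnchor '", object@id, "' (", nchar(object@sequence),
      " aa)\n  anchors: ",
      paste0(res, object@anchorPositions, collapse = " "), "\n", sep = "")
  if (object@companionPosition != 0L) {
    ci <- object@companionPosition - object@offset
    cat("  companion: ", substring(object@sequence, ci, ci),
        object@companionPosition, "\n", sep = "")
  }
})

setMethod("show", "AnchorAlignment", function(object) {
  cat("AnchorAlignment (", object@mode, "), score ", object@score,
      "\n", sep = "")
  w <- nchar(object@refGapped)
  cat("  ref:   ", substr(object@refGapped, 1L, min(w, 60L)),
      if (w > 60L) "..." else "", "\n", sep = "")
  cat("  query: ", substr(object@queryGapped, 1L, min(w, 60L)),
      if (w > 60L) "..." else "", "\n", sep = "")
})

setMethod("show", "ColumnMap", function(object) {
  cat("ColumnMap against '", object@referenceId, "': ",
      nrow(object@residues), " sequence(s)\n", sep = "")
  print(data.frame(position = object@positions, column = object@columns))
})

setMethod("show", "MotifDefinition", function(object) {
  k <- length(object@positionNames)
  cat("MotifDefinition with", k, "positions\n")
  for (i in seq_len(k)) {
    cat("  ", object@positionNames[i], " [",
        paste(object@allowed[[i]], collapse = ""), "]", sep = "")
    if (i < k)
      cat(" --{", object@spacings$min[i], "-", object@spacings$max[i],
          "}--", sep = "")
  }
  cat("\n")
  if (length(object@companion))
    cat("  companion: ", object@companion$anchor,
        sprintf("%+d", object@companion$offset), " [",
        paste(object@companion$allowed, collapse = ""), "]\n", sep = "")
})

#' @rdname MotifMatch-class
#' @export
setMethod("variant", "MotifMatch", function(object) object@variant)

setMethod("show", "MotifMatch", function(object) {
  if (object@matched) {
    cat("MotifMatch '", object@id, "': ", object@variant, " at ",
        paste(object@positions, collapse = "/"), "\n", sep = "")
    cat("  spacing deviations:",
        paste(sprintf("%+g", object@deviations), collapse = " "), "\n")
  } else {
    cat("MotifMatch '", object@id, "': no match (", object@reason, ")\n",
        sep = "")
  }
})

setMethod("show", "SummaryReport", function(object) {
  cat("SummaryReport:", object@nMatched, "matched proteins at rank",
      object@rank, "\n")
  print(object@counts)
})

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries:", length(object@rawHeats), "injections;",
      "cell", object@cellConc * 1e6, "uM,", "syringe",
      object@syringeConc * 1e6, "uM\n")
})

#' @rdname OneSiteFit-class
#' @export
setMethod("kd", "OneSiteFit", function(object) object@kd)

#' @rdname OneSiteFit-class
#' @export
setMethod("deltaH", "OneSiteFit", function(object) object@dh)

#' @rdname OneSiteFit-class
#' @export
setMethod("stoichiometry", "OneSiteFit", function(object) object@n)

#' @rdname OneSiteFit-class
#' @export
setMethod("isConverged", "OneSiteFit", function(object) object@converged)

setMethod("show", "OneSiteFit", function(object) {
  if (object@status == "ok") {
    cat(sprintf(
      "OneSiteFit: KD = %.3g M (SE %.2g), dH = %.3g kcal/mol, n = %.3g\n",
      object@kd, object@kdSE, object@dh, object@n))
  } else {
    cat("OneSiteFit:", object@status, "\n")
  }
})

setMethod("show", "MeltCurve", function(object) {
  cat(sprintf("MeltCurve: %d points, %.1f-%.1f degC\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures)))
})

#' @rdname TmCall-class
#' @export
setMethod("tmValue", "TmCall", function(object) object@tm)

setMethod("show", "TmCall", function(object) {
  if (object@transition)
    cat(sprintf("TmCall: Tm = %.2f degC (peak %.3g, floor %.3g)\n",
                object@tm, object@peakHeight, object@noiseFloor))
  else cat("TmCall: no transition\n")
})

setMethod("show", "FoldChange", function(object) {
  cat(sprintf("FoldChange: %.3g (rounded %d)\n", object@ratio,
              object@rounded))
})

#' @rdname TrimResult-class
#' @export
setMethod("keptColumns", "TrimResult", function(object) object@keptColumns)

setMethod("show", "TrimResult", function(object) {
  cat("TrimResult:", length(object@keptColumns), "of",
      length(object@gapFraction), "columns kept\n")
})
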