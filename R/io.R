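# Readers and writers for every external representation the pipeline
# touches: FASTA sequences, aligned FASTA / Stockholm alignments, HMMER
# per-domain hit tables, PDB coordinate subsets, annotation tables, and
# TSV/JSON reports.

#' Read sensor-domain protein sequences from FASTA
#'
#' Reads a FASTA file into an upper-cased, stop-stripped
#' [Biostrings::AAStringSet].  Identifiers are the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet`, one entry per FASTA record, in file order.
#'   Full headers are kept in the `description` metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a toy", "MKV"), fa)
#' readSensorSequences(fa)
#' @export
readSensorSequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in '", path, "'")
  desc <- names(ss)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chr <- toupper(gsub("\\*", "", as.character(ss)))
  if (any(nchar(chr) == 0L))
    stop("empty sequence record(s): ",
         paste(ids[nchar(chr) == 0L], collapse = ", "))
  if (any(grepl("-|\\.", chr)))
    stop("gap characters found; use readAlignment() for aligned input")
  out <- Biostrings::AAStringSet(chr)
  names(out) <- ids
  S4Vectors::metadata(out)$description <- desc
  out
}

#' Construct an AlignedBlock from gapped strings
#'
#' @param gapped Named character vector (or gapped `AAStringSet`) of
#'   equal-length rows; `.` gaps are normalized to `-`.
#' @return An [AlignedBlock].
#' @export
alignedBlock <- function(gapped) {
  nm <- names(gapped)
  chr <- setNames(toupper(chartr(".", "-", as.character(gapped))), nm)
  len <- nchar(chr)
  if (length(unique(len)) > 1L) {
    bad <- names(chr)[len != len[1L]][1L]
    stop("alignment rows have unequal lengths; first offending row: '",
         bad, "'")
  }
  rows <- Biostrings::AAStringSet(chr)
  names(rows) <- names(chr)
  new("AlignedBlock", rows = rows)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Stockholm; `.` gap characters are
#' normalized to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`; `"auto"` sniffs the first
#'   line.
#' @return An [AlignedBlock].
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) == 0L) stop("no alignment rows in '", path, "'")
    chr <- as.character(ss)
    names(chr) <- sub("\\s.*$", "", names(ss))
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                     nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no alignment rows in '", path, "'")
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad))
      stop("unparsable Stockholm row at line: ", lines[bad][1L])
    ids <- vapply(parts, `[`, character(1), 1L)
    seqs <- vapply(parts, `[`, character(1), 2L)
    # interleaved blocks: concatenate rows sharing an identifier
    chr <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                  paste0, character(1), collapse = "")
  }
  if (anyDuplicated(names(chr)))
    stop("duplicate alignment row identifiers: ",
         paste(unique(names(chr)[duplicated(names(chr))]), collapse = ", "))
  alignedBlock(chr)
}

#' Write an alignment as aligned FASTA
#'
#' @param block An [AlignedBlock].
#' @param path Output path.
#' @export
writeAlignment <- function(block, path) {
  Biostrings::writeXStringSet(block@rows, path)
  invisible(path)
}

#' Read a per-domain hit table
#'
#' Parses either HMMER3 `domtblout` per-domain tables (whitespace
#' delimited, `#` comments, envelope coordinates in columns 20-21) or a
#' simple 5-column TSV (`protein_id domain_name env_start env_end
#' e_value`).  Rows are returned unfiltered; apply [filterDomainHits()]
#' separately.
#'
#' @param path Path to the hit table.
#' @param dialect `"tsv"` or `"domtblout"`.
#' @return A data.frame with columns `protein_id`, `domain_name`,
#'   `env_start`, `env_end`, `e_value`.
#' @export
readDomainHits <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no domain hit rows in '", path, "'")
  parse_row <- function(ln, i) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (dialect == "tsv") {
      if (length(f) < 5L)
        stop("unparsable domain hit row at line ", i, ": '", ln, "'")
      out <- list(protein_id = f[1L], domain_name = f[2L],
                  env_start = f[3L], env_end = f[4L], e_value = f[5L])
    } else {
      # domtblout: target(1) qname(4) i-Evalue(13) env from(20) env to(21)
      if (length(f) < 22L)
        stop("unparsable domtblout row at line ", i, ": '", ln, "'")
      out <- list(protein_id = f[1L], domain_name = f[4L],
                  env_start = f[20L], env_end = f[21L], e_value = f[13L])
    }
    es <- suppressWarnings(as.integer(out$env_start))
    ee <- suppressWarnings(as.integer(out$env_end))
    ev <- suppressWarnings(as.numeric(out$e_value))
    if (anyNA(c(es, ee, ev)))
      stop("unparsable domain hit row at line ", i, ": '", ln, "'")
    if (es < 1L || es > ee)
      stop("invalid envelope coordinates at line ", i,
           ": env_start ", es, ", env_end ", ee)
    if (ev < 0) stop("negative E-value at line ", i)
    data.frame(protein_id = out$protein_id, domain_name = out$domain_name,
               env_start = es, env_end = ee, e_value = ev,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, Map(parse_row, lines[idx], idx, USE.NAMES = FALSE))
}

#' Filter domain hits by E-value
#'
#' @param hits Data frame from [readDomainHits()].
#' @param threshold Maximum per-domain E-value retained (default 0.01).
#' @param domain Optional domain name to restrict to (e.g. `"dCache_1"`).
#' @return The filtered data.frame.
#' @export
filterDomainHits <- function(hits, threshold = 0.01, domain = NULL) {
  keep <- hits$e_value <= threshold
  if (!is.null(domain)) keep <- keep & hits$domain_name == domain
  hits[keep, , drop = FALSE]
}

#' Extract domain regions from full-length sequences
#'
#' Cuts the envelope span of each hit out of its protein sequence.
#'
#' @param sequences An `AAStringSet` of full-length proteins.
#' @param hits Filtered hit table ([filterDomainHits()]).
#' @return An `AAStringSet` of domain regions named
#'   `<protein_id>/<env_start>-<env_end>`.
#' @export
extractDomainRegions <- function(sequences, hits) {
  miss <- setdiff(hits$protein_id, names(sequences))
  if (length(miss))
    stop("hits reference sequences not provided: ",
         paste(miss, collapse = ", "))
  lens <- nchar(as.character(sequences))[hits$protein_id]
  if (any(hits$env_end > lens))
    stop("envelope end beyond sequence length for: ",
         paste(hits$protein_id[hits$env_end > lens], collapse = ", "))
  out <- Biostrings::AAStringSet(substr(
    as.character(sequences)[hits$protein_id], hits$env_start, hits$env_end))
  names(out) <- sprintf("%s/%d-%d", hits$protein_id,
                        hits$env_start, hits$env_end)
  out
}

#' Read a PDB coordinate subset
#'
#' Interprets only ATOM/HETATM records of a PDB file, via
#' [bio3d::read.pdb()].  Elements missing from columns 77-78 are
#' inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @return A data.frame of atoms in file order with columns `serial`,
#'   `atom_name`, `element`, `residue_name`, `chain_id`, `residue_seq`,
#'   `x`, `y`, `z`, `het`.
#' @export
readStructure <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  a <- pdb$atom
  if (!any(a$type == "ATOM")) stop("no ATOM records in '", path, "'")
  elem <- toupper(trimws(a$elesy))
  fallback <- toupper(substr(gsub("[0-9']", "", trimws(a$elety)), 1L, 1L))
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  out <- data.frame(
    serial = a$eleno, atom_name = trimws(a$elety), element = elem,
    residue_name = trimws(a$resid), chain_id = a$chain,
    residue_seq = a$resno, x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM", stringsAsFactors = FALSE)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z)))
    stop("non-finite coordinates in '", path, "'")
  out
}

#' Read a protein annotation table
#'
#' A TSV with columns `protein_id`, `lineage` (semicolon-separated ranks,
#' domain first) and `architecture` (`|`-separated domain names).
#'
#' @param path Path to the TSV.
#' @return A data.frame with those three character columns.
#' @export
readAnnotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("protein_id", "lineage", "architecture")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$protein_id))
    stop("duplicate protein_id in annotations: ",
         paste(unique(tab$protein_id[duplicated(tab$protein_id)]),
               collapse = ", "))
  if (any(!nzchar(tab$lineage)))
    stop("empty lineage for: ",
         paste(tab$protein_id[!nzchar(tab$lineage)], collapse = ", "))
  tab[need]
}

# ---- reports ---------------------------------------------------------------

report_as_list <- function(report) {
  if (is(report, "OneSiteFit"))
    return(list(kd = report@kd, kd_se = report@kdSE, dh = report@dh,
                dh_se = report@dhSE, n = report@n, n_se = report@nSE,
                residual_norm = report@residualNorm,
                converged = report@converged, status = report@status))
  if (is(report, "TmCall"))
    return(list(tm = report@tm, peak_height = report@peakHeight,
                noise_floor = report@noiseFloor,
                transition = report@transition))
  if (is(report, "SummaryReport")) return(report@counts)
  if (is.data.frame(report)) return(report)
  stop("unsupported report type: ", class(report)[1L])
}

#' Write a report as TSV or JSON
#'
#' Numeric values are written at full double precision so that
#' [readReport()] round-trips them exactly.
#'
#' @param report A data.frame, [SummaryReport], [OneSiteFit] or [TmCall].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- report_as_list(report)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows", na = "null")
  } else {
    df <- if (is.data.frame(x)) x else
      data.frame(field = names(x),
                 value = vapply(x, function(v)
                   if (is.numeric(v)) formatC(v, digits = 17, format = "g")
                   else as.character(v), character(1)),
                 stringsAsFactors = FALSE)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], formatC, digits = 17, format = "g")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a report written by [writeReport()]
#'
#' @param path Path to the report.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame (TSV / JSON data frames) or named list
#'   (JSON objects).
#' @export
readReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
}

#' @importFrom S4Vectors metadata
NULL
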