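# Receptor-class assignment from domain architecture, and the roll-up of
# motif variants by receptor class and taxonomy.

#' Default receptor classification rules
#'
#' Ordered by priority: the signalling module decides the receptor
#' class.  `MCPsignal` marks a chemoreceptor; GGDEF/EAL a diguanylate
#' cyclase / phosphodiesterase; HisKA-family + HATPase_c a sensor
#' histidine kinase; SpoIIE/PP2C a Ser/Thr phosphatase.  Hybrid
#' architectures take the highest-priority matching class.
#'
#' @return A data.frame with columns `class_name`, `trigger_domains`
#'   (list column) and `priority`.
#' @export
receptorRules <- function() {
  data.frame(
    class_name = c("chemoreceptor",
                   "diguanylate cyclase/phosphodiesterase",
                   "histidine kinase", "Ser/Thr phosphatase"),
    trigger_domains = I(list(
      "MCPsignal", c("GGDEF", "EAL"),
      c("HisKA", "HisKA_3", "HATPase_c"), c("SpoIIE", "PP2C"))),
    priority = 1:4, stringsAsFactors = FALSE)
}

#' Classify receptor type from a domain architecture
#'
#' @param architecture Character vector of domain names (or a single
#'   `|`-separated string).
#' @param rules Rules table as from [receptorRules()].
#' @return The class name of the highest-priority rule whose trigger set
#'   intersects the architecture, or `"other"`.
#' @examples
#' classifyReceptor(c("dCache_1", "MCPsignal"))
#' classifyReceptor("dCache_1|GGDEF|EAL")
#' @export
classifyReceptor <- function(architecture, rules = receptorRules()) {
  if (length(architecture) == 1L && grepl("\\|", architecture))
    architecture <- strsplit(architecture, "\\|")[[1L]]
  if (length(architecture) == 0L || all(!nzchar(architecture)))
    return("other")
  rules <- rules[order(rules$priority), , drop = FALSE]
  for (i in seq_len(nrow(rules)))
    if (length(intersect(rules$trigger_domains[[i]], architecture)))
      return(rules$class_name[i])
  "other"
}

lineage_rank <- function(lineage, rank) {
  ranks <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
             family = 5L, genus = 6L, species = 7L)
  idx <- if (is.character(rank) && rank %in% names(ranks)) ranks[[rank]]
         else as.integer(rank)
  vapply(strsplit(lineage, ";"), function(p) {
    p <- trimws(p)
    if (idx <= length(p) && nzchar(p[idx])) p[idx] else "unassigned"
  }, character(1))
}

#' Summarize a scanned cohort by variant, receptor class and taxonomy
#'
#' Counts matched proteins per (motif variant, receptor class, taxon at
#' `rank`).  Proteins without a lineage entry at the requested rank fall
#' into `"unassigned"`.  The result is independent of input row order.
#'
#' @param variants Variant table from [variantTable()].
#' @param annotations Annotation table ([readAnnotations()] layout):
#'   `protein_id`, `lineage`, `architecture`.
#' @param rank Taxonomic rank (name among domain/phylum/class/order/
#'   family/genus/species, or a 1-based lineage index); default
#'   `"phylum"`.
#' @param rules Receptor classification rules.
#' @return A [SummaryReport].
#' @export
summarizeCohort <- function(variants, annotations, rank = "phylum",
                            rules = receptorRules()) {
  if (anyDuplicated(variants$id))
    stop("duplicate protein ids in the variant table: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (anyDuplicated(annotations$protein_id))
    stop("duplicate protein ids in the annotations")
  matched <- variants[variants$matched, , drop = FALSE]
  if (nrow(matched) == 0L)
    return(new("SummaryReport",
               counts = data.frame(variant = character(),
                                   receptor_class = character(),
                                   taxon = character(), count = integer()),
               nMatched = 0L, rank = as.character(rank)))
  miss <- setdiff(matched$id, annotations$protein_id)
  if (length(miss))
    stop("matched proteins lack annotation rows: ",
         paste(miss, collapse = ", "))
  ann <- annotations[match(matched$id, annotations$protein_id), ,
                     drop = FALSE]
  cls <- vapply(ann$architecture, classifyReceptor, character(1),
                rules = rules, USE.NAMES = FALSE)
  tax <- lineage_rank(ann$lineage, rank)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(matched))),
    by = list(variant = matched$variant, receptor_class = cls, taxon = tax),
    FUN = sum)
  agg <- agg[order(agg$variant, agg$receptor_class, agg$taxon), ,
             drop = FALSE]
  rownames(agg) <- NULL
  new("SummaryReport", counts = agg, nMatched = nrow(matched),
      rank = as.character(rank))
}
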