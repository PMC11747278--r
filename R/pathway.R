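#' @name pathway_catalog
#' @title Anthraquinone-pathway cataloguing of KO-annotated transcripts
#'
#' @description
#' Anthraquinones in Rubia species derive from the shikimate /
#' o-succinylbenzoate route, whose precursors are fed by the shikimate
#' pathway, the TCA cycle, and the MVA and MEP isoprenoid pathways.  The
#' package ships a reference scheme table mapping each enzyme of these four
#' pathways to its KEGG Orthology (KO) id, together with the unigene counts
#' reported for a cultivated Rubia cordifolia full-length transcriptome;
#' KO-annotated transcript sets are catalogued against this scheme.
NULL

#' Load the packaged anthraquinone-pathway reference scheme
#'
#' @return A `data.frame`: `pathway` (MVA, MEP, TCA, shikimate), `ec`,
#'   `ko_id` (K followed by 5 digits), `gene_name`, `symbol`,
#'   `unigene_count`.
#' @export
load_reference_scheme <- function() {
  path <- system.file("extdata", "anthraquinone_scheme.tsv",
                      package = "fltrx", mustWork = TRUE)
  sch <- read_tsv_table(path, c(pathway = "character", ec = "character",
                                ko_id = "character",
                                gene_name = "character",
                                symbol = "character",
                                unigene_count = "integer"))
  if (!nrow(sch)) stop("packaged scheme table is corrupt: no rows")
  if (any(!grepl("^K[0-9]{5}$", sch$ko_id))) {
    stop("packaged scheme table is corrupt: malformed KO id")
  }
  if (any(sch$unigene_count < 0L)) {
    stop("packaged scheme table is corrupt: negative count")
  }
  if (!all(sch$pathway %in% c("MVA", "MEP", "TCA", "shikimate"))) {
    stop("packaged scheme table is corrupt: unknown pathway label")
  }
  sch
}

#' Read a KO annotation table (transcript_id, ko_id)
#'
#' @param path TSV path with columns transcript_id and ko_id.
#' @return A `data.frame` with those two character columns.
#' @export
read_ko_annotations <- function(path) {
  ann <- read_tsv_table(path, c(transcript_id = "character",
                                ko_id = "character"))
  bad <- !grepl("^K[0-9]{5}$", ann$ko_id)
  if (any(bad)) stop("malformed KO id: ", ann$ko_id[bad][[1L]])
  ann
}

#' Catalogue KO-annotated transcripts against the pathway scheme
#'
#' Duplicate (transcript, KO) pairs are deduplicated with a message; each
#' transcript counts at most once per scheme row.  Annotations whose KO id
#' is not part of the scheme are summarized under `unclassified`.
#'
#' @param annotations `data.frame` with columns `transcript_id`, `ko_id`.
#' @param scheme scheme table from [load_reference_scheme()].
#' @return A list: `per_enzyme` (the scheme plus an `observed_count`
#'   column), `pathway_subtotals` (named vector over the four pathways),
#'   `grand_total` (distinct transcripts matching any scheme row),
#'   `unclassified` (`data.frame` of KO id / transcript count for KO ids
#'   outside the scheme).
#' @export
catalog_transcripts <- function(annotations, scheme = load_reference_scheme()) {
  stopifnot(all(c("transcript_id", "ko_id") %in% names(annotations)))
  ndup <- sum(duplicated(annotations[, c("transcript_id", "ko_id")]))
  if (ndup > 0L) {
    message(sprintf("deduplicated %d repeated (transcript, KO) pairs", ndup))
    annotations <- annotations[!duplicated(
      annotations[, c("transcript_id", "ko_id")]), , drop = FALSE]
  }
  counts <- vapply(scheme$ko_id, function(k) {
    length(unique(annotations$transcript_id[annotations$ko_id == k]))
  }, 0L)
  per_enzyme <- cbind(scheme, observed_count = unname(counts))
  sub <- tapply(per_enzyme$observed_count, per_enzyme$pathway, sum)
  sub <- sub[c("MVA", "MEP", "TCA", "shikimate")]
  sub[is.na(sub)] <- 0L
  sub <- stats::setNames(as.integer(sub),
                         c("MVA", "MEP", "TCA", "shikimate"))
  matched <- annotations$ko_id %in% scheme$ko_id
  uncl <- annotations[!matched, , drop = FALSE]
  uncl_tab <- if (nrow(uncl)) {
    agg <- tapply(uncl$transcript_id, uncl$ko_id,
                  function(x) length(unique(x)))
    data.frame(ko_id = names(agg), n_transcripts = as.integer(agg),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(ko_id = character(), n_transcripts = integer(),
               stringsAsFactors = FALSE)
  }
  list(per_enzyme = per_enzyme,
       pathway_subtotals = sub,
       grand_total = length(unique(annotations$transcript_id[matched])),
       unclassified = uncl_tab)
}

#' Pathway subtotals of the printed scheme counts
#'
#' @param scheme scheme table from [load_reference_scheme()].
#' @return A list: `per_pathway` (named sums of the printed unigene counts)
#'   and `overall`.
#' @export
pathway_totals <- function(scheme = load_reference_scheme()) {
  per <- tapply(scheme$unigene_count, scheme$pathway, sum)
  per <- per[c("MVA", "MEP", "TCA", "shikimate")]
  list(per_pathway = stats::setNames(as.integer(per),
                                     c("MVA", "MEP", "TCA", "shikimate")),
       overall = sum(scheme$unigene_count))
}
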