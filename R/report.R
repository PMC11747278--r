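#' @name report
#' @title Summary accounting and pipeline orchestration
#'
#' @description
#' Aggregates per-stage outputs into the summary accounting used for
#' full-length transcriptome reports: raw counts with derived percentages.
#' Percentages are always recomputed from their two counts at render time
#' (never stored) and rounded half-up at the printed precision.
NULL

#' Percentage with half-up rounding
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @param decimals decimal places (default 2).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
pct <- function(numerator, denominator, decimals = 2L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Format a count with its percentage
#'
#' @inheritParams pct
#' @return A string like `"208,689 (83.72%)"`.
#' @export
pct_format <- function(numerator, denominator, decimals = 2L) {
  sprintf("%s (%s%%)", format(numerator, big.mark = ",", trim = TRUE),
          formatC(pct(numerator, denominator, decimals),
                  format = "f", digits = decimals))
}

# percentage pairs derivable from the assembled counts:
# name, numerator key, denominator key, decimals
.report_pct_spec <- list(
  list("flnc_of_ccs", "flnc_reads", "ccs_reads", 2L),
  list("hq_of_consensus", "hq_isoforms", "consensus_isoforms", 2L),
  list("annotated_of_nonredundant", "annotated_transcripts",
       "nonredundant_transcripts", 2L),
  list("busco_single", "busco_single", "busco_total", 1L),
  list("busco_duplicated", "busco_duplicated", "busco_total", 1L),
  list("busco_fragmented", "busco_fragmented", "busco_total", 1L),
  list("busco_missing", "busco_missing", "busco_total", 1L),
  list("orf_complete_of_total", "orf_complete", "orf_total", 2L))

#' Assemble a summary report from stage outputs
#'
#' Counts are harvested from the supplied stage results and merged with
#' externally produced counts (e.g. read-processing or BUSCO class counts,
#' which this package consumes but never computes).  A key supplied by two
#' sources with different values is an error.
#'
#' @param stage_outputs named list; recognized entries are `collapse`
#'   (result of [collapse()]), `as_summary` ([summarize_as()]), `ssr_stats`
#'   ([classify_ssr_types()]), `orfs` (a [find_orfs_set()] table), `lncrna`
#'   ([consensus_lncrna()]) and `catalog` ([catalog_transcripts()]).
#' @param external_counts named list of integer counts (e.g. `ccs_reads`,
#'   `flnc_reads`, `consensus_isoforms`, `hq_isoforms`, `busco_single`,
#'   `busco_duplicated`, `busco_fragmented`, `busco_missing`, `busco_total`,
#'   `annotated_transcripts`).
#' @return An object of class `fltrx_report`: list with `counts` (named
#'   integer vector), `sources` (named provenance), and `percentages`
#'   (recomputed at build time from `counts`).
#' @export
build_report <- function(stage_outputs = list(), external_counts = list()) {
  if (!length(stage_outputs) && !length(external_counts)) {
    stop("at least one stage output or external count is required")
  }
  counts <- list()
  sources <- list()
  add <- function(key, value, src) {
    value <- as.integer(value)
    if (!is.null(counts[[key]]) && counts[[key]] != value) {
      stop(sprintf("conflicting counts for '%s': %d (%s) vs %d (%s)",
                   key, counts[[key]], sources[[key]], value, src))
    }
    counts[[key]] <<- value
    sources[[key]] <<- src
  }
  so <- stage_outputs
  if (!is.null(so$collapse)) {
    add("nonredundant_transcripts", length(so$collapse$nonredundant),
        "collapse")
    add("input_transcripts", nrow(so$collapse$clusters), "collapse")
  }
  if (!is.null(so$as_summary)) {
    add("as_event_total", so$as_summary$total_events, "as_summary")
    add("as_unigenes", so$as_summary$n_unigenes, "as_summary")
  }
  if (!is.null(so$ssr_stats)) {
    for (cl in names(so$ssr_stats$counts)) {
      add(paste0("ssr_", cl), so$ssr_stats$counts[[cl]], "ssr_stats")
    }
    add("ssr_total", so$ssr_stats$total, "ssr_stats")
    add("ssr_transcripts", so$ssr_stats$transcripts_with_ssr, "ssr_stats")
  }
  if (!is.null(so$orfs)) {
    add("orf_total", nrow(so$orfs), "orfs")
    add("orf_complete", sum(so$orfs$completeness == "complete"), "orfs")
  }
  if (!is.null(so$lncrna)) {
    add("lncrna_count", so$lncrna$venn$intersection, "lncrna")
    add("lncrna_candidates", so$lncrna$venn$n_candidates, "lncrna")
  }
  if (!is.null(so$catalog)) {
    add("pathway_unigenes", so$catalog$grand_total, "catalog")
  }
  for (key in names(external_counts)) {
    add(key, external_counts[[key]], "external")
  }
  if (all(c("busco_single", "busco_duplicated", "busco_fragmented",
            "busco_missing") %in% names(counts)) &&
      is.null(counts$busco_total)) {
    add("busco_total", counts$busco_single + counts$busco_duplicated +
          counts$busco_fragmented + counts$busco_missing, "derived")
  }
  cv <- unlist(counts)
  percentages <- list()
  for (sp in .report_pct_spec) {
    if (all(c(sp[[2L]], sp[[3L]]) %in% names(cv)) && cv[[sp[[3L]]]] > 0) {
      percentages[[sp[[1L]]]] <- pct(cv[[sp[[2L]]]], cv[[sp[[3L]]]], sp[[4L]])
    }
  }
  if (!is.null(counts$ssr_total) && counts$ssr_total > 0) {
    for (cl in c(paste0("p", 1:6), "compound")) {
      k <- paste0("ssr_", cl)
      if (k %in% names(cv)) {
        percentages[[paste0(k, "_share")]] <- pct(cv[[k]], cv[["ssr_total"]])
      }
    }
  }
  structure(list(counts = cv, sources = unlist(sources),
                 percentages = unlist(percentages)),
            class = "fltrx_report")
}

#' @export
print.fltrx_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a report as an aligned text block
#'
#' @param report an `fltrx_report` from [build_report()].
#' @return Character vector of lines.
#' @export
render_report <- function(report) {
  cv <- report$counts
  line <- function(label, key, denkey = NULL, dec = 2L) {
    if (!(key %in% names(cv))) return(NULL)
    val <- if (!is.null(denkey) && denkey %in% names(cv) && cv[[denkey]] > 0) {
      pct_format(cv[[key]], cv[[denkey]], dec)
    } else {
      format(cv[[key]], big.mark = ",", trim = TRUE)
    }
    sprintf("%-38s %s", label, val)
  }
  out <- c(
    "Full-length transcriptome summary",
    "---------------------------------",
    line("CCS reads", "ccs_reads"),
    line("Full-length non-chimeric reads", "flnc_reads", "ccs_reads"),
    line("Consensus isoforms", "consensus_isoforms"),
    line("High-quality isoforms", "hq_isoforms", "consensus_isoforms"),
    line("Input transcripts", "input_transcripts"),
    line("Non-redundant transcripts", "nonredundant_transcripts"),
    line("Annotated transcripts", "annotated_transcripts",
         "nonredundant_transcripts"),
    line("Complete single-copy BUSCOs", "busco_single", "busco_total", 1L),
    line("Complete duplicated BUSCOs", "busco_duplicated", "busco_total", 1L),
    line("Fragmented BUSCOs", "busco_fragmented", "busco_total", 1L),
    line("Missing BUSCOs", "busco_missing", "busco_total", 1L),
    line("AS events", "as_event_total"),
    line("AS unigenes", "as_unigenes"),
    line("SSR loci", "ssr_total"),
    line("SSR-bearing transcripts", "ssr_transcripts"),
    line("ORFs", "orf_total"),
    line("Complete ORFs", "orf_complete", "orf_total"),
    line("lncRNA candidates (length filter)", "lncrna_candidates"),
    line("Consensus lncRNAs", "lncrna_count"),
    line("Pathway-catalogued unigenes", "pathway_unigenes"))
  unlist(out)
}

#' Run the full pipeline over one transcript set
#'
#' Executes collapse, all-vs-all alignment + AS detection, SSR scanning,
#' ORF discovery, consensus lncRNA calling, optional KO cataloguing and
#' report assembly, writing per-stage tables plus a JSON report and a run
#' log into `outdir`.  Stages listed in `skip` are omitted.  With identical
#' inputs and seed the report JSON is byte-identical between runs.
#'
#' @param config a named list: either `fasta` (input path) or `simulate`
#'   (argument list for [simulate_transcriptome()]); `outdir` (required);
#'   optional `annotations` (KO TSV path), `external_counts`,
#'   `skip` (character vector among collapse, as, ssr, orf, lncrna,
#'   catalog), `seed`, and per-stage parameter lists `collapse_args`,
#'   `align_args`, `as_args`, `ssr_args`, `orf_args`, `lncrna_args`.
#' @return The `fltrx_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  skip <- config$skip %||% character(0)
  logf <- file.path(outdir, "run_log.jsonl")
  unlink(logf)
  t0_all <- Sys.time()
  log_stage <- function(stage, note = "", secs = NA) {
    line <- jsonlite::toJSON(
      list(stage = stage, note = note,
           seconds = if (is.na(secs)) NULL else round(secs, 3)),
      auto_unbox = TRUE)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    message(sprintf("[fltrx] %s %s", stage, note))
  }
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log_stage(stage, "done", as.numeric(Sys.time() - t0, units = "secs"))
    r
  }

  manifest <- NULL
  if (!is.null(config$simulate)) {
    sim <- timed("simulate",
                 do.call(simulate_transcriptome, config$simulate))
    set <- sim$set
    manifest <- sim$manifest
    write_fasta(set, file.path(outdir, "transcripts.fasta"))
    write_manifest(manifest, file.path(outdir, "manifest.json"))
  } else if (!is.null(config$fasta)) {
    set <- timed("read", read_fasta(config$fasta))
  } else {
    stop("config must name an input: either 'fasta' or 'simulate'")
  }

  stage_outputs <- list()
  clusters <- NULL
  if (!("collapse" %in% skip)) {
    col <- timed("collapse", do.call(collapse,
      c(list(set = set), config$collapse_args %||% list())))
    write_tsv_table(col$clusters, file.path(outdir, "clusters.tsv"))
    write_fasta(col$nonredundant, file.path(outdir, "nonredundant.fasta"))
    stage_outputs$collapse <- col
    clusters <- col$clusters
  }
  if (!("as" %in% skip)) {
    hsps <- timed("align", do.call(align_all_vs_all,
      c(list(set = set), config$align_args %||% list())))
    write_alignment_tabular(hsps, file.path(outdir, "hsps.tsv"))
    events <- timed("as_detect", do.call(detect_as_events,
      c(list(hsps = hsps, lengths = transcript_lengths(set)),
        config$as_args %||% list())))
    write_tsv_table(events, file.path(outdir, "as_events.tsv"))
    smry <- summarize_as(events, clusters)
    jsonlite::write_json(smry, file.path(outdir, "as_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_outputs$as_summary <- smry
  }
  if (!("ssr" %in% skip)) {
    loci <- timed("ssr", do.call(scan_ssrs,
      c(list(set = set), config$ssr_args %||% list())))
    write_tsv_table(loci, file.path(outdir, "ssr_loci.tsv"))
    stats_ <- classify_ssr_types(loci)
    jsonlite::write_json(stats_, file.path(outdir, "ssr_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_outputs$ssr_stats <- stats_
  }
  orfs <- NULL
  if (!("orf" %in% skip)) {
    orfs <- timed("orf", do.call(find_orfs_set,
      c(list(set = set), config$orf_args %||% list())))
    write_tsv_table(orfs[, setdiff(names(orfs), "protein")],
                    file.path(outdir, "orfs.tsv"))
    stage_outputs$orfs <- orfs
  }
  if (!("lncrna" %in% skip)) {
    lnc <- timed("lncrna", do.call(consensus_lncrna,
      c(list(set = set), config$lncrna_args %||% list())))
    write_tsv_table(lnc$calls, file.path(outdir, "lncrna_calls.tsv"))
    jsonlite::write_json(lnc$venn, file.path(outdir, "lncrna_venn.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_outputs$lncrna <- lnc
  }
  if (!is.null(config$annotations) && !("catalog" %in% skip)) {
    ann <- read_ko_annotations(config$annotations)
    cat_ <- timed("catalog", catalog_transcripts(ann))
    write_tsv_table(cat_$per_enzyme, file.path(outdir, "catalog.tsv"))
    stage_outputs$catalog <- cat_
  }
  report <- timed("report", build_report(
    stage_outputs, config$external_counts %||% list()))
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         percentages = as.list(report$percentages)),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(render_report(report), file.path(outdir, "report.txt"))
  log_stage("pipeline", "complete",
            as.numeric(Sys.time() - t0_all, units = "secs"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
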