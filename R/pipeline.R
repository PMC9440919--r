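#' @title End-to-end orchestration and DE-table intersection
#'
#' @description
#' `run_pipeline()` executes the stages in order — exon quantification,
#' breakpoint calling, promoter-evidence classification (optional), ORF
#' scanning and proteomic validation (optional) — and aggregates a single
#' report with provenance (input checksums, configuration hash, seed,
#' package version). `rank_and_intersect()` is the companion utility that
#' intersects the top-N most strongly upregulated genes across
#' differential-expression tables.
#'
#' @name pipeline
NULL

#' Intersect top-N upregulated genes across DE tables
#'
#' Per table: keep genes with `padj < padj_max` and `log2FC > lfc_min`,
#' rank by descending log2FC (ties by ascending padj, then lexicographic
#' id), take the top N, and intersect across tables.
#'
#' @param tables Named list (>= 2) of data.frames with columns `gene_id`
#'   (or `gene`/`id`), `log2FC`, `padj`.
#' @param N Top-list size (default 25).
#' @param lfc_min Minimum log2 fold change (default 1).
#' @param padj_max Maximum adjusted p-value (default 0.05).
#' @return Character vector of shared gene ids (sorted).
#' @export
rank_and_intersect <- function(tables, N = 25L, lfc_min = 1, padj_max = 0.05) {
  stopifnot(N >= 1, is.list(tables), length(tables) >= 2)
  tops <- lapply(tables, function(d) {
    idcol <- intersect(c("gene_id", "gene", "id"), names(d))[1]
    if (is.na(idcol) || !all(c("log2FC", "padj") %in% names(d)))
      stop("DE table needs columns gene_id (or gene/id), log2FC, padj")
    if (anyDuplicated(d[[idcol]])) stop("DE table has duplicated gene ids")
    d <- d[!is.na(d$padj) & d$padj < padj_max & d$log2FC > lfc_min, , drop = FALSE]
    d <- d[order(-d$log2FC, d$padj, d[[idcol]]), , drop = FALSE]
    utils::head(d[[idcol]], N)
  })
  sort(Reduce(intersect, tops))
}

.known_config_keys <- c("seed", "inputs", "groups", "boundary", "promoter",
                        "orf", "proteomics", "output_dir")

#' Validate a pipeline configuration
#'
#' @param config Pipeline configuration list (see [run_pipeline()]).
#' @return The config with defaults filled in; errors name the offending
#'   key.
#' @export
validate_config <- function(config) {
  bad <- setdiff(names(config), .known_config_keys)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$inputs)) stop("config$inputs is required")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$boundary <- utils::modifyList(
    list(tau_on = 1, tau_off = 0.1, delta = 1), config$boundary %||% list())
  config$promoter <- utils::modifyList(
    list(window = 2000, rho_act = 3, rho_rep = 3), config$promoter %||% list())
  config$proteomics <- utils::modifyList(
    list(m_min = 2L, control = "control", treated = "treated"),
    config$proteomics %||% list())
  config$orf <- utils::modifyList(list(), config$orf %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full inference pipeline
#'
#' Stages run in order: exon quantification, per-sample breakpoint calls +
#' per-group consensus, promoter-evidence classification (skipped with an
#' explicit report entry when no ChIP tracks are given), ORF scan
#' (skipped without genome sequence or CDS), peptide validation and
#' quantification (skipped without a peptide table). Missing *optional*
#' inputs skip their stage; missing required inputs are errors.
#'
#' `config` is a list with elements:
#' \describe{
#'   \item{inputs}{list: `annotation` (GTF path) or `transcript`
#'     (a `transcript_model`); `transcript_id` (when the annotation holds
#'     several); `counts` + `library_sizes`, or `bed` (named vector of BED
#'     paths); `genome` (FASTA path or DNAStringSet); `chip` (named list of
#'     bedGraph paths or GRanges tracks); `domains` (TSV path or
#'     data.frame); `peptides` (TSV path or data.frame);
#'     `unique_peptides` (character, optional — derived from the predicted
#'     short ORF when absent).}
#'   \item{groups}{named character vector mapping samples to conditions.}
#'   \item{boundary/promoter/proteomics}{threshold overrides (see
#'     [detect_breakpoint()], [classify_alternative_promoter()],
#'     [quantify_peptides()]).}
#'   \item{output_dir}{optional directory for per-stage TSV/JSON output.}
#' }
#'
#' @param config Pipeline configuration list.
#' @return A `pipeline_report`: list with `calls`, `consensus`,
#'   `promoter`, `orf`, `coverage`, `quant`, `isoform_support`,
#'   `skipped`, `provenance`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  inp <- config$inputs
  skipped <- character(0)

  # --- transcript model ------------------------------------------------
  t <- if (!is.null(inp$transcript)) inp$transcript else {
    if (is.null(inp$annotation)) stop("inputs$annotation or inputs$transcript required")
    models <- read_annotation(inp$annotation, inp$transcript_id %||% NULL)
    if (length(models) == 0) stop("no transcripts parsed from annotation")
    if (length(models) > 1 && is.null(inp$transcript_id))
      stop("several transcripts in annotation; set inputs$transcript_id")
    models[[1]]
  }

  # --- quantification --------------------------------------------------
  m <- if (!is.null(inp$counts)) {
    exon_expression_matrix(inp$counts,
                           GenomicRanges::width(t$exons),
                           inp$library_sizes)
  } else if (!is.null(inp$bed)) {
    quantify_samples(inp$bed, t, library_sizes = inp$library_sizes)
  } else stop("inputs$counts (+ library_sizes) or inputs$bed required")

  # --- boundary --------------------------------------------------------
  b <- config$boundary
  calls <- lapply(colnames(m$rpkm), function(s)
    detect_breakpoint(exon_profile(m, s),
                      tau_on = b$tau_on, tau_off = b$tau_off, delta = b$delta))
  names(calls) <- colnames(m$rpkm)
  groups <- config$groups %||%
    stats::setNames(rep("all", length(calls)), names(calls))
  consensus <- consensus_call(calls, groups[names(calls)])
  # consensus breakpoint used downstream: prefer a short-calling group
  kk <- unlist(lapply(consensus, function(c)
    if (c$class == "short_3prime") c$breakpoint_k else NULL))
  k_used <- if (length(kk) > 0) as.integer(kk[1]) else NA_integer_

  # --- promoter evidence ----------------------------------------------
  promoter <- NULL
  if (is.null(inp$chip)) {
    skipped <- c(skipped, "promoter: no ChIP tracks supplied")
  } else if (is.na(k_used)) {
    skipped <- c(skipped, "promoter: no short_3prime consensus breakpoint")
  } else {
    tracks <- lapply(inp$chip, function(x)
      if (is.character(x)) read_signal_track(x) else x)
    pr <- config$promoter
    promoter <- classify_alternative_promoter(
      tracks, t, k_used, window = pr$window,
      rho_act = pr$rho_act, rho_rep = pr$rho_rep)
  }

  # --- ORF scan --------------------------------------------------------
  orf <- NULL; seq <- NULL; domains <- NULL
  if (is.null(inp$genome)) {
    skipped <- c(skipped, "orfscan: no genome sequence supplied")
  } else if (is.na(t$cds_start)) {
    skipped <- c(skipped, "orfscan: transcript lacks a canonical CDS")
  } else {
    seq <- spliced_sequence(t, inp$genome)
    if (!is.null(inp$domains))
      domains <- if (is.character(inp$domains)) read_domains(inp$domains)
                 else inp$domains
    orf <- orf_candidates(t, seq,
                          first_exon = if (!is.na(k_used)) k_used else NULL,
                          domains = domains)
  }

  # --- proteomics ------------------------------------------------------
  coverage <- NULL; quant <- NULL; isoform_support <- NULL
  if (is.null(inp$peptides)) {
    skipped <- c(skipped, "proteomics: no peptide table supplied")
  } else if (is.null(orf) || length(orf) == 0) {
    skipped <- c(skipped, "proteomics: no predicted short ORF to validate")
  } else {
    obs <- if (is.character(inp$peptides)) read_peptide_observations(inp$peptides)
           else inp$peptides
    short <- orf[[1]]                       # longest candidate (smallest start)
    canonical_protein <- translate_orf(
      substr(as.character(seq), t$cds_start, t$cds_stop - 1))
    coverage <- map_peptides(unique(obs$sequence), short$protein)
    canon_map <- map_peptides(unique(obs$sequence), canonical_protein)
    isoform_support <- infer_isoform_support(canon_map$matches, short$delta,
                                             m_min = config$proteomics$m_min)
    uniq <- inp$unique_peptides %||%
      select_unique_peptides(canonical_protein, short$delta)
    uniq <- intersect(uniq, obs$sequence)
    if (length(uniq) == 0) {
      skipped <- c(skipped, "quantification: no unique peptides observed")
    } else {
      quant <- quantify_peptides(obs, uniq,
                                 control = config$proteomics$control,
                                 treated = config$proteomics$treated)
    }
  }

  report <- structure(list(
    calls = calls_table(calls),
    consensus = consensus,
    breakpoint_k = k_used,
    promoter = promoter,
    orf = orf,
    coverage = coverage,
    quant = quant,
    isoform_support = isoform_support,
    skipped = skipped,
    provenance = .provenance(config)), class = "pipeline_report")
  if (!is.null(config$output_dir)) .write_report(report, m, config$output_dir)
  report
}

.provenance <- function(config) {
  inp <- config$inputs
  files <- Filter(function(x) is.character(x) && all(file.exists(x)),
                  inp[names(inp) != "chip"])
  chip_files <- if (!is.null(inp$chip))
    Filter(is.character, as.list(inp$chip)) else list()
  all_files <- unlist(c(files, chip_files), use.names = TRUE)
  checksums <- if (length(all_files) > 0)
    stats::setNames(as.character(tools::md5sum(all_files)), names(all_files))
  else character(0)
  cfg_flat <- config
  cfg_flat$output_dir <- NULL   # the hash describes the analysis, not where it lands
  cfg_flat$inputs <- lapply(cfg_flat$inputs, function(x)
    if (is.character(x)) x else class(x)[1])
  list(config_hash = .hash_object(cfg_flat),
       input_checksums = as.list(checksums),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("shortiso")))
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version-pinned serialization keeps the hash stable across sessions
  saveRDS(x, f, version = 2, compress = FALSE)
  as.character(tools::md5sum(f))
}

.write_report <- function(report, m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(m, file.path(dir, "expression.tsv"))
  utils::write.table(report$calls, file.path(dir, "isoform_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$promoter))
    utils::write.table(promoter_evidence_table(report$promoter),
                       file.path(dir, "promoter_evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$orf))
    utils::write.table(orf_table(report$orf), file.path(dir, "orf_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serializable form of a pipeline report
#'
#' Plain-list rendering of a `pipeline_report` (no GRanges, no
#' timestamps), suitable for `jsonlite::write_json()`; identical inputs
#' and seed give byte-identical JSON.
#'
#' @param report A `pipeline_report`.
#' @return Nested list.
#' @export
report_json <- function(report) {
  list(
    calls = report$calls,
    consensus = report$consensus,
    breakpoint_k = report$breakpoint_k,
    promoter = if (!is.null(report$promoter))
      promoter_evidence_table(report$promoter),
    orf = if (!is.null(report$orf)) orf_table(report$orf),
    coverage = if (!is.null(report$coverage)) list(
      protein_length = report$coverage$protein_length,
      coverage_pct = report$coverage$coverage_pct,
      n_peptides_mapped = report$coverage$n_peptides_mapped),
    quant = if (!is.null(report$quant)) list(
      group_means = as.list(report$quant$group_means),
      fold_change = report$quant$fold_change,
      t_statistic = report$quant$t_statistic,
      p_value = report$quant$p_value),
    isoform_support = report$isoform_support,
    skipped = report$skipped,
    provenance = report$provenance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  samples: %d; consensus breakpoint k = %s\n",
              nrow(x$calls), format(x$breakpoint_k)))
  for (g in names(x$consensus))
    cat(sprintf("  group %s: %s%s\n", g, x$consensus[[g]]$class,
                if (!is.na(x$consensus[[g]]$breakpoint_k))
                  sprintf(" (k = %d)", x$consensus[[g]]$breakpoint_k) else ""))
  if (!is.null(x$promoter)) cat(sprintf("  promoter: %s\n", x$promoter$verdict))
  if (!is.null(x$orf)) cat(sprintf("  ORF candidates: %d\n", length(x$orf)))
  if (!is.null(x$coverage))
    cat(sprintf("  coverage: %.1f%%\n", x$coverage$coverage_pct))
  if (!is.null(x$quant))
    cat(sprintf("  fold change: %.2f (p = %.3g)\n",
                x$quant$fold_change, x$quant$p_value))
  if (!is.null(x$isoform_support))
    cat(sprintf("  isoform support: %s\n", x$isoform_support))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
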