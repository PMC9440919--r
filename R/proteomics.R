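#' @title Proteogenomic peptide evidence: digestion, mapping, support and
#'   label-free quantification
#'
#' @description
#' Turns peptide-level mass-spectrometry evidence into isoform validation:
#' in-silico tryptic digestion predicts observable peptides; observed
#' peptides are mapped exactly onto a protein to compute sequence coverage;
#' the position of mapped peptides relative to the short isoform's
#' N-terminal offset decides whether the data support the short or the
#' full-length protein; and summed XIC areas of isoform-unique peptides are
#' averaged per sample and compared between conditions (Welch t-test on
#' log2 sample averages).
#'
#' @name proteomics
NULL

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P; emits
#' all products with at most `missed_cleavages` internal uncut sites,
#' filtered by length. With 0 missed cleavages and no length filter the
#' peptides concatenate back to the protein.
#'
#' @param protein Amino-acid string.
#' @param missed_cleavages Maximum internal missed cleavage sites
#'   (default 0).
#' @param min_len,max_len Length filter in residues.
#' @return data.frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive), `missed`.
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L,
                           min_len = 1L, max_len = Inf) {
  protein <- as.character(protein)
  if (min_len > max_len) stop("min_len must not exceed max_len")
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  n <- nchar(protein)
  if (n == 0) stop("empty protein")
  aa <- strsplit(protein, "")[[1]]
  # cut after position i when aa[i] in {K,R} and aa[i+1] != P
  cuts <- which(aa %in% c("K", "R") & c(aa[-1], "") != "P")
  cuts <- cuts[cuts < n]
  bounds <- c(0L, cuts, n)          # fragment i spans bounds[i]+1 .. bounds[i+1]
  nf <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nf)) {
    for (m in 0:min(missed_cleavages, nf - i)) {
      s <- bounds[i] + 1L; e <- bounds[i + m + 1L]
      len <- e - s + 1L
      if (len >= min_len && len <= max_len)
        out[[length(out) + 1L]] <- list(
          peptide = substr(protein, s, e), start = s, end = e, missed = m)
    }
  }
  if (length(out) == 0)
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  data.frame(peptide = vapply(out, `[[`, character(1), "peptide"),
             start = vapply(out, `[[`, integer(1), "start"),
             end = vapply(out, `[[`, integer(1), "end"),
             missed = vapply(out, `[[`, integer(1), "missed"),
             stringsAsFactors = FALSE)
}

#' Map observed peptides onto a protein and compute coverage
#'
#' Each peptide is matched at every exact occurrence; the covered residue
#' set is the union of matched spans. Unmatched peptides are reported, not
#' an error.
#'
#' @param observed Character vector of peptide sequences.
#' @param protein Amino-acid string.
#' @param il_equivalent Treat I and L as indistinguishable (default FALSE).
#' @return A `coverage_report`: list with `protein_length`, `covered`
#'   (sorted residue positions), `coverage_pct`, `n_peptides_mapped`,
#'   `unmatched` and a `matches` data.frame (peptide, start, end).
#' @export
map_peptides <- function(observed, protein, il_equivalent = FALSE) {
  protein <- as.character(protein)
  n <- nchar(protein)
  key <- function(x) if (il_equivalent) gsub("I", "L", x) else x
  prot_k <- key(protein)
  covered <- logical(n)
  matches <- list()
  unmatched <- character(0)
  for (pep in unique(as.character(observed))) {
    if (nchar(pep) == 0) next
    hits <- gregexpr(key(pep), prot_k, fixed = TRUE)[[1]]
    if (hits[1] == -1) { unmatched <- c(unmatched, pep); next }
    for (s in hits) {
      e <- s + nchar(pep) - 1L
      covered[s:e] <- TRUE
      matches[[length(matches) + 1L]] <- list(peptide = pep, start = s, end = e)
    }
  }
  mt <- if (length(matches))
    data.frame(peptide = vapply(matches, `[[`, character(1), "peptide"),
               start = vapply(matches, `[[`, integer(1), "start"),
               end = vapply(matches, `[[`, integer(1), "end"),
               stringsAsFactors = FALSE)
  else data.frame(peptide = character(0), start = integer(0), end = integer(0))
  structure(list(
    protein_length = n,
    covered = which(covered),
    coverage_pct = 100 * sum(covered) / n,
    n_peptides_mapped = length(unique(mt$peptide)),
    unmatched = unmatched,
    matches = mt), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %.1f%% of %d aa covered by %d peptide(s)%s\n",
              x$coverage_pct, x$protein_length, x$n_peptides_mapped,
              if (length(x$unmatched)) sprintf(" (%d unmatched)", length(x$unmatched)) else ""))
  invisible(x)
}

#' Infer isoform support from peptides mapped on the canonical protein
#'
#' A mapped peptide is N-exclusive when it requires canonical N-terminal
#' sequence absent from the short isoform: its end at or before the offset
#' `delta`, or straddling it. Any N-exclusive peptide supports the
#' full-length protein; with none, at least `m_min` shared peptides
#' support the short isoform; anything else is ambiguous.
#'
#' @param matches data.frame of mapped peptides with columns `start`,
#'   `end` on the canonical protein (e.g. `map_peptides(...)$matches`).
#' @param delta N-terminal offset of the short isoform (canonical length
#'   minus short length).
#' @param m_min Minimum shared peptides for short-isoform support
#'   (default 2).
#' @return One of `"short_supported"`, `"full_length_supported"`,
#'   `"ambiguous"`.
#' @export
infer_isoform_support <- function(matches, delta, m_min = 2L) {
  if (delta < 0) stop("delta must be >= 0")
  if (nrow(matches) == 0) return("ambiguous")
  # straddling peptides need N-terminal residues, so they count N-exclusive
  n_excl <- matches$start <= delta
  if (any(n_excl)) return("full_length_supported")
  shared <- unique(matches$peptide[!n_excl])
  if (length(shared) >= m_min) "short_supported" else "ambiguous"
}

#' Read a peptide-evidence table
#'
#' TSV with columns `sequence`, `sample`, `condition`, `auc`; repeated rows
#' per fragment ion are allowed and are summed per peptide and sample by
#' [quantify_peptides()].
#'
#' @param path TSV file.
#' @return data.frame of peptide observations.
#' @export
read_peptide_observations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "sample", "condition", "auc")
  if (!all(need %in% names(d)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  if (any(d$auc < 0)) stop("XIC areas must be non-negative")
  d
}

#' Label-free quantification of isoform-unique peptides
#'
#' Per peptide and sample, fragment-ion XIC areas are summed; per sample,
#' the summed areas are averaged over the unique peptides (peptides missing
#' in a sample are excluded from that sample's mean and flagged). Group
#' means and the treated/control fold change are computed on the natural
#' scale; the test is a Welch unpaired two-sided t-test on log2 sample
#' averages (intensities are multiplicative).
#'
#' @param observations data.frame with columns `sequence`, `sample`,
#'   `condition`, `auc` (see [read_peptide_observations()]).
#' @param unique_peptides Character vector of isoform-unique peptide
#'   sequences to quantify.
#' @param control,treated Condition labels; fold change is
#'   `treated / control`.
#' @return A `quant_result`: list with `sample_means` (data.frame sample,
#'   condition, mean_auc, n_peptides), `group_means`, `fold_change`,
#'   `t_statistic`, `p_value`, `missing` (peptide x sample gaps).
#' @export
quantify_peptides <- function(observations, unique_peptides,
                              control = "control", treated = "treated") {
  obs <- observations[observations$sequence %in% unique_peptides, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations of the unique peptides")
  if (!all(c(control, treated) %in% obs$condition))
    stop("both condition labels must be present in the observations")
  # per peptide per sample: sum fragment-ion areas
  per_pep <- stats::aggregate(auc ~ sequence + sample + condition, data = obs, FUN = sum)
  # per sample: average over unique peptides actually observed there
  per_sample <- stats::aggregate(auc ~ sample + condition, data = per_pep, FUN = mean)
  npep <- stats::aggregate(sequence ~ sample, data = per_pep,
                           FUN = function(x) length(unique(x)))
  per_sample$n_peptides <- npep$sequence[match(per_sample$sample, npep$sample)]
  names(per_sample)[names(per_sample) == "auc"] <- "mean_auc"
  missing <- expand.grid(sequence = unique_peptides,
                         sample = unique(obs$sample), stringsAsFactors = FALSE)
  seen <- paste(per_pep$sequence, per_pep$sample)
  missing <- missing[!paste(missing$sequence, missing$sample) %in% seen, , drop = FALSE]
  if (nrow(missing) > 0)
    warning(nrow(missing), " peptide/sample combination(s) unobserved; ",
            "excluded from the affected sample means")

  g_ctrl <- per_sample$mean_auc[per_sample$condition == control]
  g_trt <- per_sample$mean_auc[per_sample$condition == treated]
  group_means <- c(stats::setNames(mean(g_ctrl), control),
                   stats::setNames(mean(g_trt), treated))
  fold_change <- if (group_means[[control]] > 0)
    group_means[[treated]] / group_means[[control]] else NA_real_

  t_statistic <- p_value <- NA_real_
  if (length(g_ctrl) < 2 || length(g_trt) < 2) {
    warning("fewer than 2 samples in a group; test skipped")
  } else if (any(c(g_ctrl, g_trt) <= 0)) {
    warning("non-positive sample average; log-scale test skipped")
  } else if (stats::sd(log2(g_ctrl)) == 0 && stats::sd(log2(g_trt)) == 0) {
    # degenerate: identical within groups
    t_statistic <- 0; p_value <- 1
  } else {
    tt <- stats::t.test(log2(g_trt), log2(g_ctrl), var.equal = FALSE)
    t_statistic <- unname(tt$statistic); p_value <- tt$p.value
  }
  structure(list(sample_means = per_sample, group_means = group_means,
                 fold_change = unname(fold_change),
                 t_statistic = t_statistic, p_value = p_value,
                 missing = missing), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result: fold change %.3f (%s); t = %s, p = %s\n",
              x$fold_change,
              paste(sprintf("%s %.3g", names(x$group_means), x$group_means),
                    collapse = " vs "),
              format(x$t_statistic, digits = 3), format(x$p_value, digits = 3)))
  invisible(x)
}

#' Select peptides unique to the shared C-terminal region
#'
#' Default operationalization of "isoform-unique": tryptic peptides of the
#' canonical protein lying entirely 3' of the offset `delta` (inside the
#' short isoform) and, when a background proteome is given, occurring
#' nowhere in it.
#'
#' @param protein Canonical protein sequence.
#' @param delta N-terminal offset of the short isoform.
#' @param background Optional [Biostrings::AAStringSet] (or FASTA path) of
#'   background proteins.
#' @param min_len,max_len Peptide length filter (default 7..25, the usual
#'   detectable range).
#' @return Character vector of unique peptide sequences.
#' @export
select_unique_peptides <- function(protein, delta, background = NULL,
                                   min_len = 7L, max_len = 25L) {
  dig <- tryptic_digest(protein, 0L, min_len, max_len)
  pep <- dig$peptide[dig$start > delta]
  if (!is.null(background)) {
    if (is.character(background) && length(background) == 1 && file.exists(background))
      background <- Biostrings::readAAStringSet(background)
    bg <- paste(as.character(background), collapse = "\n")
    pep <- pep[!vapply(pep, function(p) grepl(p, bg, fixed = TRUE), logical(1))]
  }
  unique(pep)
}
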