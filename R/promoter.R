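#' @title Chromatin evidence for an internal alternative promoter
#'
#' @description
#' Scores histone-mark and RNA Pol II signal tracks for the chromatin
#' signature of an internal alternative promoter at a truncation
#' breakpoint: a silent canonical promoter, a Polycomb-repressed
#' (H3K27me3) 5' gene body, and a local gain of active marks (H3K27ac,
#' H3K4me3, Pol II) immediately 5' of the expressed 3' block.
#'
#' Evidence is expressed as fold enrichment rather than peak calls. Active
#' marks are scored against the locus-wide mean of their own track, which
#' makes scores invariant to rescaling any one track (library size).
#' The repressive score contrasts the 5' body against the expressed
#' 3' region of the same mark: the repressed body typically covers most of
#' the locus, so a locus-wide mean would itself be inflated by the signal
#' being tested.
#'
#' @name promoter_evidence
NULL

#' Read a signal track from bedGraph
#'
#' @param path bedGraph file (0-based half-open on disk; returned as a
#'   1-based closed [GenomicRanges::GRanges] with a `score` column).
#' @return GRanges with non-negative `score`, sorted, non-overlapping bins.
#' @export
read_signal_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- GenomicRanges::sort(gr)
  if (any(S4Vectors::mcols(gr)$score < 0))
    stop("signal track '", path, "' contains negative values")
  gr
}

#' Length-weighted mean signal over a window
#'
#' Bins partially overlapping the window contribute proportionally to the
#' overlapped length.
#'
#' @param track GRanges with `score` (see [read_signal_track()]).
#' @param w A [GenomicRanges::GRanges] of length 1 (the window).
#' @return Mean signal (numeric scalar).
#' @export
window_signal <- function(track, w) {
  stopifnot(methods::is(track, "GRanges"), methods::is(w, "GRanges"),
            length(w) == 1)
  GenomicRanges::strand(w) <- "*"
  hits <- GenomicRanges::findOverlaps(track, w, ignore.strand = TRUE)
  if (length(hits) == 0)
    stop("window does not overlap the signal track")
  tb <- track[S4Vectors::queryHits(hits)]
  ov_w <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(tb), rep(GenomicRanges::granges(w), length(tb))))
  sum(S4Vectors::mcols(tb)$score * ov_w) / sum(ov_w)
}

#' Classify alternative-promoter evidence at a breakpoint
#'
#' Windows (all on the genome, strand-aware):
#' * candidate: `+/- window` bp around the 5' genomic end of exon `k`;
#' * canonical: `+/- window` bp around the transcript start;
#' * 5' body: genomic span of exons `1..k-1`;
#' * 3' region: genomic span of exons `k..E` (reference for the repressive
#'   score).
#'
#' `alt_active_score` is the mean over available active marks (H3K27ac,
#' H3K4me3, PolII) of the candidate-window signal divided by that mark's
#' locus-wide mean; the candidate promoter is called active when this score
#' reaches `rho_act` while the canonical window's analogous score stays
#' below it. `body_repressive_score` is mean H3K27me3 over the 5' body
#' divided by its mean over the 3' region; the body is called repressed
#' when it reaches `rho_rep` (vacuously true, flagged, when no H3K27me3
#' track is supplied). The verdict is `alternative_promoter` iff both hold;
#' `canonical_only` when the canonical promoter alone is active;
#' otherwise `no_evidence`.
#'
#' @param tracks Named list of signal tracks (GRanges with `score`); names
#'   among `H3K27ac`, `H3K4me3`, `PolII`, `H3K27me3`. `H3K27ac` is
#'   required.
#' @param t A `transcript_model`.
#' @param k Breakpoint exon index (>= 2).
#' @param window Half-width of the promoter windows in bp (default 2000).
#' @param rho_act Fold-enrichment threshold for active marks (default 3).
#' @param rho_rep Fold-enrichment threshold for the repressive body
#'   (default 3).
#' @return A `promoter_evidence` object: list with scores, the two boolean
#'   calls, `h3k27me3_available`, and `verdict`.
#' @export
classify_alternative_promoter <- function(tracks, t, k, window = 2000,
                                          rho_act = 3, rho_rep = 3) {
  stopifnot(is.list(tracks))
  if (!"H3K27ac" %in% names(tracks))
    stop("an H3K27ac track is required")
  if (k < 2 || k > n_exons(t))
    stop("breakpoint k must be in 2..n_exons(t) (empty 5' body otherwise)")
  chrom <- as.character(GenomicRanges::seqnames(t$exons)[1])
  gwin <- function(center, half) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(max(1, center - half), center + half))
  span <- function(idx) {
    s <- GenomicRanges::start(t$exons)[idx]; e <- GenomicRanges::end(t$exons)[idx]
    GenomicRanges::GRanges(chrom, IRanges::IRanges(min(s), max(e)))
  }
  # strand-aware anchors
  exk <- t$exons[k]
  anchor_alt <- if (t$strand == "+") GenomicRanges::start(exk)
                else GenomicRanges::end(exk)
  anchor_can <- if (t$strand == "+") min(GenomicRanges::start(t$exons))
                else max(GenomicRanges::end(t$exons))
  w_alt <- gwin(anchor_alt, window)
  w_can <- gwin(anchor_can, window)
  w_body <- span(seq_len(k - 1))
  w_3p <- span(k:n_exons(t))
  locus <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    min(GenomicRanges::start(t$exons)), max(GenomicRanges::end(t$exons))))

  bin_w <- vapply(tracks, function(tr) stats::median(GenomicRanges::width(tr)),
                  numeric(1))
  if (any(2 * window + 1 < bin_w))
    warning("promoter window narrower than the track bin width; ",
            "scores are based on partial bins")

  active_marks <- intersect(c("H3K27ac", "H3K4me3", "PolII"), names(tracks))
  alt_scores <- can_scores <- numeric(0)
  for (m in active_marks) {
    bg <- window_signal(tracks[[m]], locus)
    if (bg <= 0) stop("mark ", m, ": zero locus-wide background")
    alt_scores[m] <- window_signal(tracks[[m]], w_alt) / bg
    can_scores[m] <- window_signal(tracks[[m]], w_can) / bg
  }
  alt_active_score <- mean(alt_scores)
  canonical_active_score <- mean(can_scores)
  active_alt <- alt_active_score >= rho_act && canonical_active_score < rho_act

  h3k27me3_available <- "H3K27me3" %in% names(tracks)
  if (h3k27me3_available) {
    ref <- window_signal(tracks[["H3K27me3"]], w_3p)
    if (ref <= 0) ref <- .Machine$double.eps
    body_repressive_score <- window_signal(tracks[["H3K27me3"]], w_body) / ref
    repressed_5prime <- body_repressive_score >= rho_rep
  } else {
    body_repressive_score <- NA_real_
    repressed_5prime <- TRUE   # vacuous, flagged via h3k27me3_available
  }

  verdict <-
    if (active_alt && repressed_5prime) "alternative_promoter"
    else if (!active_alt && canonical_active_score >= rho_act) "canonical_only"
    else "no_evidence"
  structure(list(
    verdict = verdict,
    active_alt = active_alt,
    repressed_5prime = repressed_5prime,
    alt_active_score = alt_active_score,
    canonical_active_score = canonical_active_score,
    body_repressive_score = body_repressive_score,
    background_score = 1.0,
    h3k27me3_available = h3k27me3_available,
    per_mark_alt_scores = alt_scores,
    windows = list(candidate = w_alt, canonical = w_can,
                   body_5prime = w_body, region_3prime = w_3p)),
    class = "promoter_evidence")
}

#' @export
print.promoter_evidence <- function(x, ...) {
  cat(sprintf(paste0("promoter_evidence: %s\n",
                     "  alt active %.2fx (canonical %.2fx); 5' body H3K27me3 %sx%s\n"),
              x$verdict, x$alt_active_score, x$canonical_active_score,
              ifelse(is.na(x$body_repressive_score), "NA",
                     sprintf("%.2f", x$body_repressive_score)),
              if (!x$h3k27me3_available) " [no H3K27me3 track]" else ""))
  invisible(x)
}

#' Flatten promoter evidence to a one-row data.frame
#' @param ev A `promoter_evidence` object.
#' @return data.frame suitable for TSV export.
#' @export
promoter_evidence_table <- function(ev) {
  data.frame(verdict = ev$verdict, active_alt = ev$active_alt,
             repressed_5prime = ev$repressed_5prime,
             alt_active_score = ev$alt_active_score,
             canonical_active_score = ev$canonical_active_score,
             body_repressive_score = ev$body_repressive_score,
             h3k27me3_available = ev$h3k27me3_available,
             stringsAsFactors = FALSE)
}
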