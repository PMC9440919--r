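#' @title Per-exon read counting and RPKM profiles
#'
#' @description
#' Quantifies expression of a transcript exon by exon: aligned reads (BED 3
#' or BED 12 with split blocks) are counted against each exon, and counts
#' are converted to RPKM (reads per kilobase of exon per million mapped
#' reads), the unit behind per-exon expression heatmaps. A read overlapping
#' several exons increments each of them once; reads are never fractionally
#' assigned.
#'
#' @name exonquant
NULL

#' Read aligned-read intervals from BED
#'
#' BED 12 records are split into their blocks (spliced alignments); BED 3/6
#' records are treated as ungapped.
#'
#' @param path BED file.
#' @return A [GenomicRanges::GRangesList], one element per read (each
#'   element holds the read's aligned blocks).
#' @export
read_bed_reads <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("invalid BED file '", path, "': ",
                                          conditionMessage(e)))
  if (length(gr) == 0)
    return(GenomicRanges::GRangesList())
  if ("blocks" %in% names(S4Vectors::mcols(gr))) {
    rtracklayer::blocks(gr)
  } else {
    methods::as(GenomicRanges::granges(gr), "GRangesList")
  }
}

#' Count reads per exon
#'
#' A read increments an exon's count when the genomic overlap between any
#' of its aligned blocks and the exon is at least `min_overlap` bp. A read
#' spanning several exons increments each overlapped exon once.
#'
#' @param reads A [GenomicRanges::GRangesList] (one element per read, as
#'   from [read_bed_reads()]) or a plain [GenomicRanges::GRanges] of
#'   ungapped reads.
#' @param t A `transcript_model`.
#' @param min_overlap Minimum genomic overlap in bp (default 1).
#' @return Integer vector of length `n_exons(t)`, ordered by exon index.
#' @export
count_reads_per_exon <- function(reads, t, min_overlap = 1L) {
  if (methods::is(reads, "GRanges"))
    reads <- methods::as(reads, "GRangesList")
  stopifnot(methods::is(reads, "GRangesList"))
  ex <- GenomicRanges::granges(t$exons)
  # strand-blind counting: unstranded RNA-seq convention
  GenomicRanges::strand(ex) <- "*"
  n <- GenomicRanges::countOverlaps(ex, reads, minoverlap = min_overlap,
                                    ignore.strand = TRUE)
  # countOverlaps on GRangesList counts a read once per list element even if
  # several of its blocks hit the same exon
  as.integer(n)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((exon_length/1000) * (library_size/1e6))`.
#'
#' @param count Read count(s), non-negative.
#' @param exon_length Feature length(s) in bp, positive.
#' @param library_size Total mapped reads in the sample, positive.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, exon_length, library_size) {
  if (any(exon_length <= 0)) stop("exon_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / ((exon_length / 1000) * (library_size / 1e6))
}

#' Per-exon expression matrix for one transcript
#'
#' @param counts Integer matrix, exons in rows (transcript order) and
#'   samples in columns.
#' @param exon_lengths Exon lengths in bp, one per row.
#' @param library_sizes Total mapped reads per sample, one per column.
#' @return An `exon_expression_matrix` holding counts, RPKM, lengths and
#'   library sizes.
#' @export
exon_expression_matrix <- function(counts, exon_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  stopifnot(nrow(counts) == length(exon_lengths),
            ncol(counts) == length(library_sizes))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(library_sizes <= 0)) stop("all library sizes must be positive")
  library_sizes <- stats::setNames(as.numeric(library_sizes),
                                   names(library_sizes) %||% colnames(counts))
  rp <- sweep(sweep(counts, 1, exon_lengths / 1000, "/"),
              2, library_sizes / 1e6, "/")
  rownames(counts) <- rownames(rp) <- seq_len(nrow(counts))
  structure(list(counts = counts, rpkm = rp,
                 exon_lengths = as.numeric(exon_lengths),
                 library_sizes = library_sizes),
            class = "exon_expression_matrix")
}

#' @export
print.exon_expression_matrix <- function(x, ...) {
  cat(sprintf("exon_expression_matrix: %d exons x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Build an expression matrix from per-sample BED files
#'
#' Library size defaults to the total read count of each sample's BED input
#' (quantification against total mapped reads) unless given explicitly.
#'
#' @param bed_paths Named character vector of BED files, one per sample.
#' @param t A `transcript_model`.
#' @param library_sizes Optional named numeric vector overriding per-sample
#'   library sizes.
#' @param min_overlap Passed to [count_reads_per_exon()].
#' @return An `exon_expression_matrix`.
#' @export
quantify_samples <- function(bed_paths, t, library_sizes = NULL,
                             min_overlap = 1L) {
  if (is.null(names(bed_paths)))
    names(bed_paths) <- paste0("sample", seq_along(bed_paths))
  cnts <- sapply(bed_paths, function(p) {
    reads <- read_bed_reads(p)
    count_reads_per_exon(reads, t, min_overlap = min_overlap)
  })
  cnts <- matrix(as.integer(cnts), nrow = n_exons(t),
                 dimnames = list(NULL, names(bed_paths)))
  if (is.null(library_sizes)) {
    library_sizes <- vapply(bed_paths,
                            function(p) length(read_bed_reads(p)), numeric(1))
    if (any(library_sizes == 0))
      stop("sample with empty BED input needs an explicit library size")
  }
  exon_expression_matrix(cnts, GenomicRanges::width(t$exons),
                         library_sizes[names(bed_paths)])
}

#' Per-exon RPKM profile of one sample
#'
#' @param m An `exon_expression_matrix`.
#' @param sample Sample identifier (column name).
#' @return Numeric RPKM vector ordered exon 1..E.
#' @export
exon_profile <- function(m, sample) {
  stopifnot(inherits(m, "exon_expression_matrix"))
  if (!sample %in% colnames(m$rpkm))
    stop("unknown sample '", sample, "'")
  as.numeric(m$rpkm[, sample])
}

#' Per-exon counts from a bedGraph coverage track
#'
#' For inputs where only per-base coverage is available: the estimated exon
#' count is `round(mean_coverage * exon_length / read_length)`.
#'
#' @param track A bedGraph-derived [GenomicRanges::GRanges] with a `score`
#'   column (see [read_signal_track()]) or a bedGraph path.
#' @param t A `transcript_model`.
#' @param read_length Read length in bp used to convert coverage to counts.
#' @return Integer vector of per-exon estimated counts.
#' @export
counts_from_coverage <- function(track, t, read_length) {
  stopifnot(read_length > 0)
  if (is.character(track)) track <- read_signal_track(track)
  ex <- GenomicRanges::granges(t$exons)
  GenomicRanges::strand(ex) <- "*"
  vapply(seq_along(ex), function(i) {
    mc <- tryCatch(window_signal(track, ex[i]), error = function(e) 0)
    as.integer(round(mc * GenomicRanges::width(ex)[i] / read_length))
  }, integer(1))
}

#' Write counts and RPKM to TSV
#'
#' @param m An `exon_expression_matrix`.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  d <- data.frame(exon_index = seq_len(nrow(m$counts)),
                  exon_length = m$exon_lengths)
  for (s in colnames(m$counts)) {
    d[[paste0("count_", s)]] <- m$counts[, s]
    d[[paste0("rpkm_", s)]] <- m$rpkm[, s]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
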