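#' @title Transcript models: annotation I/O and coordinate conversion
#'
#' @description
#' A `transcript_model` is the package's central gene-structure object: an
#' ordered set of exons (strand-aware, numbered 1..E from the transcript 5'
#' end, as in "exon 23 to exon 28"), plus the canonical CDS expressed in
#' spliced-transcript coordinates. Exons are held as a
#' [GenomicRanges::GRanges] (1-based, closed intervals); GTF/GFF3, BED and
#' bedGraph conventions are converted at the I/O boundary by rtracklayer.
#'
#' Transcript coordinates used throughout the package are 1-based:
#' `cds_start` is the position of the A of the canonical ATG and `cds_stop`
#' the first nucleotide of the canonical stop codon on the spliced
#' transcript.
#'
#' @name genemodel
NULL

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param exons A [GenomicRanges::GRanges] of exon intervals on one
#'   chromosome and one strand (`+` or `-`). Exons must not overlap.
#' @param cds_start,cds_stop Canonical CDS in 1-based spliced-transcript
#'   coordinates: first nt of the start codon and first nt of the stop
#'   codon. `NA` for non-coding transcripts (disables ORF analysis).
#'
#' @return An object of class `transcript_model` with exons sorted in
#'   transcript (5' to 3') order and an `exon_index` metadata column.
#' @export
transcript_model <- function(transcript_id, gene_id, exons,
                             cds_start = NA_integer_, cds_stop = NA_integer_) {
  stopifnot(methods::is(exons, "GRanges"), length(exons) >= 1)
  str <- unique(as.character(GenomicRanges::strand(exons)))
  if (length(str) != 1 || !str %in% c("+", "-"))
    stop("exons must lie on a single strand, '+' or '-'")
  if (length(unique(as.character(GenomicRanges::seqnames(exons)))) != 1)
    stop("exons must lie on a single chromosome")
  exons <- GenomicRanges::sort(exons, decreasing = (str == "-"))
  if (length(exons) > 1) {
    hits <- GenomicRanges::findOverlaps(exons, drop.self = TRUE)
    if (length(hits) > 0) stop("exons of one transcript must not overlap")
  }
  S4Vectors::mcols(exons)$exon_index <- seq_along(exons)
  tlen <- sum(GenomicRanges::width(exons))
  if (!is.na(cds_start) && !is.na(cds_stop)) {
    cds_start <- as.integer(cds_start); cds_stop <- as.integer(cds_stop)
    if (!(cds_start >= 1 && cds_start < cds_stop))
      stop("cds_start must satisfy 1 <= cds_start < cds_stop")
    if ((cds_stop - cds_start) %% 3 != 0)
      stop("CDS length (cds_stop - cds_start) must be a multiple of 3")
    if (cds_stop + 2 > tlen)
      stop("stop codon extends beyond transcript end")
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         exons = exons, strand = str,
         cds_start = cds_start, cds_stop = cds_stop),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s): %d exons, strand %s, length %d nt\n",
              x$transcript_id, x$gene_id, length(x$exons), x$strand,
              transcript_length(x)))
  if (!is.na(x$cds_start))
    cat(sprintf("  canonical CDS: %d..%d (stop codon at %d), %d aa\n",
                x$cds_start, x$cds_stop + 2L, x$cds_stop,
                (x$cds_stop - x$cds_start) %/% 3))
  invisible(x)
}

#' Spliced transcript length in nucleotides
#' @param t A `transcript_model`.
#' @return Integer length.
#' @export
transcript_length <- function(t) sum(GenomicRanges::width(t$exons))

#' Number of exons
#' @param t A `transcript_model`.
#' @return Integer exon count.
#' @export
n_exons <- function(t) length(t$exons)

#' Read transcript models from GTF/GFF3 annotation
#'
#' Parses an annotation file with rtracklayer (dialect detected from the
#' file), assigns strand-aware exon indices (exon 1 = transcript 5' end)
#' and converts CDS features to spliced-transcript coordinates. A
#' transcript without CDS features is returned with `cds_start = NA`; the
#' ORF stage refuses such models.
#'
#' @param path GTF or GFF3 file.
#' @param transcript_ids Optional character vector restricting which
#'   transcripts are built.
#' @return Named list of `transcript_model` objects (possibly empty, with a
#'   warning, for an annotation containing no exon features).
#' @export
read_annotation <- function(path, transcript_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(grepl("^\\s*(#|$)", lines))) {
    warning("annotation '", path, "' contains no features")
    return(list())
  }
  anno <- tryCatch(rtracklayer::import(path),
                   error = function(e) stop("failed to parse annotation '", path,
                                            "': ", conditionMessage(e)))
  if (length(anno) == 0 || !"type" %in% names(S4Vectors::mcols(anno))) {
    warning("annotation '", path, "' contains no features")
    return(list())
  }
  tx_col <- intersect(c("transcript_id", "Parent", "ID"),
                      names(S4Vectors::mcols(anno)))[1]
  if (is.na(tx_col)) stop("annotation lacks transcript identifiers")
  get_tx <- function(gr) {
    v <- S4Vectors::mcols(gr)[[tx_col]]
    if (methods::is(v, "List") || is.list(v))
      v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
                  character(1))
    as.character(v)
  }
  ex <- anno[S4Vectors::mcols(anno)$type == "exon"]
  cds <- anno[S4Vectors::mcols(anno)$type == "CDS"]
  if (length(ex) == 0) {
    warning("annotation '", path, "' contains no exon features")
    return(list())
  }
  ex_tx <- get_tx(ex)
  cds_tx <- if (length(cds)) get_tx(cds) else character(0)
  ids <- unique(ex_tx)
  if (!is.null(transcript_ids)) ids <- intersect(ids, transcript_ids)
  models <- lapply(ids, function(id) {
    exi <- ex[ex_tx == id]
    gene <- if ("gene_id" %in% names(S4Vectors::mcols(exi)))
      as.character(S4Vectors::mcols(exi)$gene_id[1]) else NA_character_
    t0 <- transcript_model(id, gene, GenomicRanges::granges(exi))
    cdsi <- if (length(cds)) cds[cds_tx == id] else cds
    if (length(cdsi) > 0) {
      cdsi <- GenomicRanges::sort(GenomicRanges::granges(cdsi),
                                  decreasing = (t0$strand == "-"))
      g_first <- if (t0$strand == "+") GenomicRanges::start(cdsi)[1]
                 else GenomicRanges::end(cdsi)[1]
      g_last <- if (t0$strand == "+") GenomicRanges::end(cdsi)[length(cdsi)]
                else GenomicRanges::start(cdsi)[length(cdsi)]
      cs <- genomic_to_transcript(t0, g_first)
      # GTF CDS conventionally excludes the stop codon: first stop nt is the
      # transcript position right after the last CDS base.
      ce <- genomic_to_transcript(t0, g_last) + 1L
      t0 <- transcript_model(id, gene, GenomicRanges::granges(exi),
                             cds_start = cs, cds_stop = ce)
    }
    t0
  })
  names(models) <- ids
  models
}

#' Write transcript models back to GTF
#'
#' Serializes exon and CDS features so that a parse/serialize round trip
#' reproduces the same models.
#'
#' @param models List of `transcript_model`.
#' @param path Output GTF file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  grs <- lapply(models, function(t) {
    ex <- GenomicRanges::granges(t$exons)
    S4Vectors::mcols(ex)$type <- "exon"
    S4Vectors::mcols(ex)$phase <- NA_integer_
    out <- ex
    if (!is.na(t$cds_start)) {
      # CDS excluding the stop codon, mapped back exon by exon
      cds_tx <- seq(t$cds_start, t$cds_stop - 1L)
      g <- vapply(cds_tx, function(p) transcript_to_genomic(t, p), numeric(1))
      cdsr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        GenomicRanges::seqnames(ex)[1],
        IRanges::IRanges(start = g, width = 1), strand = t$strand))
      # transcript order for phase bookkeeping
      cdsr <- GenomicRanges::sort(cdsr, decreasing = (t$strand == "-"))
      w <- GenomicRanges::width(cdsr)
      before <- c(0L, cumsum(utils::head(w, -1)))
      S4Vectors::mcols(cdsr)$type <- "CDS"
      S4Vectors::mcols(cdsr)$phase <- as.integer((3L - before %% 3L) %% 3L)
      out <- c(ex, cdsr)
    }
    S4Vectors::mcols(out)$transcript_id <- t$transcript_id
    S4Vectors::mcols(out)$gene_id <- t$gene_id
    out
  })
  all <- do.call(c, unname(grs))
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Map a genomic position onto the spliced transcript
#'
#' @param t A `transcript_model`.
#' @param g Genomic position (1-based) lying inside an exon of `t`.
#' @return 1-based spliced-transcript position; inverse of
#'   [transcript_to_genomic()].
#' @export
genomic_to_transcript <- function(t, g) {
  ex <- t$exons
  s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
  i <- which(g >= s & g <= e)
  if (length(i) != 1)
    stop("position ", g, " is not exonic in transcript ", t$transcript_id)
  w <- GenomicRanges::width(ex)
  before <- if (i > 1) sum(w[seq_len(i - 1)]) else 0L
  off <- if (t$strand == "+") g - s[i] else e[i] - g
  as.integer(before + off + 1L)
}

#' Map a spliced-transcript position back to the genome
#'
#' @param t A `transcript_model`.
#' @param p 1-based transcript position in `[1, transcript_length(t)]`.
#' @return Genomic position (1-based).
#' @export
transcript_to_genomic <- function(t, p) {
  tlen <- transcript_length(t)
  if (p < 1 || p > tlen)
    stop("transcript position ", p, " outside [1, ", tlen, "]")
  w <- GenomicRanges::width(t$exons)
  cum <- cumsum(w)
  i <- which(p <= cum)[1]
  off <- p - (if (i > 1) cum[i - 1] else 0L) - 1L
  if (t$strand == "+") GenomicRanges::start(t$exons)[i] + off
  else GenomicRanges::end(t$exons)[i] - off
}

#' Exon index containing a transcript position
#'
#' @param t A `transcript_model`.
#' @param p 1-based transcript position.
#' @return 1-based exon index (5' to 3').
#' @export
exon_of_position <- function(t, p) {
  tlen <- transcript_length(t)
  if (p < 1 || p > tlen)
    stop("transcript position ", p, " outside [1, ", tlen, "]")
  cum <- cumsum(GenomicRanges::width(t$exons))
  which(p <= cum)[1]
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences 5' to 3', reverse-complementing for
#' minus-strand transcripts.
#'
#' @param t A `transcript_model`.
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path) holding the
#'   chromosomes.
#' @return A [Biostrings::DNAString] of length `transcript_length(t)`.
#' @export
spliced_sequence <- function(t, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  chrom <- as.character(GenomicRanges::seqnames(t$exons)[1])
  nm <- sub("\\s.*$", "", names(genome))
  j <- match(chrom, nm)
  if (is.na(j)) stop("chromosome '", chrom, "' absent from genome FASTA")
  chr <- genome[[j]]
  if (max(GenomicRanges::end(t$exons)) > length(chr))
    stop("exon interval exceeds length of chromosome '", chrom, "'")
  # genomic order, then flip for minus strand
  ord <- order(GenomicRanges::start(t$exons))
  pieces <- lapply(ord, function(i)
    Biostrings::subseq(chr, GenomicRanges::start(t$exons)[i],
                       GenomicRanges::end(t$exons)[i]))
  seq <- do.call(Biostrings::xscat, pieces)
  if (t$strand == "-") seq <- Biostrings::reverseComplement(seq)
  seq
}

#' Domain annotations on the canonical protein
#'
#' @param name Character vector of domain labels (e.g. "transmembrane").
#' @param aa_start,aa_end 1-based inclusive residue coordinates.
#' @param canonical_length Optional canonical protein length used to
#'   validate coordinates.
#' @return A data.frame with columns `name`, `aa_start`, `aa_end`.
#' @export
domain_annotation <- function(name, aa_start, aa_end, canonical_length = NULL) {
  stopifnot(length(name) == length(aa_start), length(aa_start) == length(aa_end))
  aa_start <- as.integer(aa_start); aa_end <- as.integer(aa_end)
  if (any(aa_start < 1) || any(aa_end < aa_start))
    stop("domains must satisfy 1 <= aa_start <= aa_end")
  if (!is.null(canonical_length) && any(aa_end > canonical_length))
    stop("domain end exceeds canonical protein length")
  data.frame(name = as.character(name), aa_start = aa_start, aa_end = aa_end,
             stringsAsFactors = FALSE)
}

#' Read domain annotations from TSV (columns name, aa_start, aa_end)
#' @param path TSV file.
#' @param canonical_length Optional validation length.
#' @return Domain data.frame as from [domain_annotation()].
#' @export
read_domains <- function(path, canonical_length = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "aa_start", "aa_end")
  if (!all(need %in% names(d)))
    stop("domain TSV must have columns: ", paste(need, collapse = ", "))
  domain_annotation(d$name, d$aa_start, d$aa_end, canonical_length)
}

#' Flatten transcript exons to a data.frame
#'
#' One row per exon with genomic and transcript coordinates; convenient for
#' TSV export.
#'
#' @param t A `transcript_model`.
#' @return data.frame with exon_index, chrom, start, end, strand, width,
#'   tx_start, tx_end (1-based, closed).
#' @export
exon_table <- function(t) {
  w <- GenomicRanges::width(t$exons)
  cum <- cumsum(w)
  data.frame(
    exon_index = seq_along(w),
    chrom = as.character(GenomicRanges::seqnames(t$exons)),
    start = GenomicRanges::start(t$exons),
    end = GenomicRanges::end(t$exons),
    strand = t$strand,
    width = w,
    tx_start = c(1L, utils::head(cum, -1) + 1L),
    tx_end = cum,
    stringsAsFactors = FALSE)
}
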