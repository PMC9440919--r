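#' @title Stop-anchored ORF prediction and domain-loss assessment
#'
#' @description
#' Enumerates candidate open reading frames in a truncated transcript that
#' are in frame with, and terminate at, the canonical stop codon — so that
#' every candidate protein is a C-terminal suffix of the canonical protein.
#' Candidates are translated, their average molecular mass computed (the
#' quantity compared against gel-band sizes), and canonical protein domains
#' classified as lost, retained or truncated relative to the candidate's
#' N-terminal offset.
#'
#' @name orfscan
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Expasy average residue masses (Da); protein mass = sum + one water
.AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MASS <- 18.01528

#' In-frame ATG start sites anchored at the canonical stop codon
#'
#' Returns every ATG position inside `search_window` that is in frame with
#' `cds_stop` and has no stop codon at any in-frame position strictly
#' between it and `cds_stop`.
#'
#' @param seq Transcript nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param cds_stop 1-based position of the first nt of the canonical stop
#'   codon; `seq[cds_stop..cds_stop+2]` must be TAA, TAG or TGA.
#' @param search_window Integer pair `c(from, to)` (1-based, inclusive)
#'   restricting the scan; defaults to the whole region 5' of the stop.
#' @return Ascending integer vector of 1-based start positions (possibly
#'   empty).
#' @export
find_inframe_starts <- function(seq, cds_stop,
                                search_window = c(1L, cds_stop - 1L)) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (cds_stop < 1 || cds_stop + 2 > n)
    stop("cds_stop outside sequence")
  if (!substr(seq, cds_stop, cds_stop + 2) %in% .STOP_CODONS)
    stop("no stop codon (TAA/TAG/TGA) at cds_stop = ", cds_stop)
  from <- max(1L, as.integer(search_window[1]))
  to <- min(as.integer(search_window[2]), cds_stop - 1L)
  if (search_window[1] < 1 || search_window[2] > n)
    stop("search window outside sequence")
  if (from > to) return(integer(0))
  # all in-frame stop positions 5' of cds_stop, for the interior check
  frame_pos <- seq(cds_stop %% 3, cds_stop, by = 3)
  frame_pos <- frame_pos[frame_pos >= 1 & frame_pos + 2 <= n]
  codons <- substring(seq, frame_pos, frame_pos + 2)
  is_stop <- codons %in% .STOP_CODONS
  stops_before <- frame_pos[is_stop & frame_pos < cds_stop]
  starts <- frame_pos[codons == "ATG" & frame_pos >= from &
                        frame_pos + 2 <= to + 2 & frame_pos <= to]
  if (length(stops_before) > 0) {
    ok <- vapply(starts, function(p) !any(stops_before > p), logical(1))
    starts <- starts[ok]
  }
  sort(as.integer(starts))
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code; the initiator codon is rendered as M. The input
#' runs from the ATG up to (not including) the stop codon.
#'
#' @param seq Nucleotide string with length divisible by 3.
#' @return Amino-acid string, one residue per codon.
#' @export
translate_orf <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n == 0 || n %% 3 != 0) stop("coding sequence length must be a positive multiple of 3")
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stop("ambiguous or invalid base '", substr(seq, bad, bad),
         "' at position ", bad)
  starts <- seq(1, n, by = 3)
  codons <- substring(seq, starts, starts + 2)
  internal_stop <- which(codons %in% .STOP_CODONS)
  if (length(internal_stop) > 0)
    stop("internal stop codon at nt position ", starts[internal_stop[1]])
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[1] <- "M"   # initiator rendered as M regardless of codon table quirks
  paste(aa, collapse = "")
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water (18.015 Da). Average (not
#' monoisotopic) masses are used because the result is compared against
#' gel-band sizes.
#'
#' @param protein Amino-acid string of standard residues.
#' @return Mass in Dalton.
#' @export
protein_mass <- function(protein) {
  protein <- as.character(protein)
  if (nchar(protein) == 0) stop("empty protein")
  aa <- strsplit(protein, "")[[1]]
  m <- .AA_AVG_MASS[aa]
  if (any(is.na(m)))
    stop("non-standard residue '", aa[which(is.na(m))[1]], "' in protein")
  sum(m) + .WATER_MASS
}

#' Enumerate ORF candidates of a truncated transcript
#'
#' Combines [find_inframe_starts()], [translate_orf()], [protein_mass()]
#' and [assess_domains()] into a table of candidates, each terminating at
#' the canonical stop codon.
#'
#' @param t A `transcript_model` with a canonical CDS.
#' @param seq Spliced transcript sequence (character or DNAString).
#' @param search_window 1-based `c(from, to)` window for start-site search;
#'   by default the region from the first nt of `first_exon` to the stop.
#' @param first_exon Exon index whose 5' end opens the default search
#'   window (typically the breakpoint k from [detect_breakpoint()]).
#' @param domains Optional domain data.frame (see [domain_annotation()]).
#' @return List of `orf_candidate` objects (fields: `start_nt`,
#'   `start_exon`, `protein`, `length_aa`, `mass_da`, `delta`,
#'   `domains_lost`, `domains_retained`, `domains_truncated`), ordered by
#'   ascending start.
#' @export
orf_candidates <- function(t, seq, search_window = NULL, first_exon = NULL,
                           domains = NULL) {
  if (is.na(t$cds_start))
    stop("transcript ", t$transcript_id,
         " has no canonical CDS; ORF stage disabled for it")
  seq <- toupper(as.character(seq))
  if (is.null(search_window)) {
    from <- if (is.null(first_exon)) 1L else {
      et <- exon_table(t); et$tx_start[first_exon]
    }
    search_window <- c(from, t$cds_stop - 1L)
  }
  canonical_protein <- translate_orf(substr(seq, t$cds_start, t$cds_stop - 1))
  canonical_length <- nchar(canonical_protein)
  starts <- find_inframe_starts(seq, t$cds_stop, search_window)
  lapply(starts, function(p) {
    prot <- translate_orf(substr(seq, p, t$cds_stop - 1))
    cand <- structure(list(
      start_nt = p,
      start_exon = exon_of_position(t, p),
      protein = prot,
      length_aa = nchar(prot),
      mass_da = protein_mass(prot),
      delta = canonical_length - nchar(prot),
      domains_lost = character(0), domains_retained = character(0),
      domains_truncated = character(0)), class = "orf_candidate")
    if (!is.null(domains))
      cand <- assess_domains(cand, domains, canonical_length,
                             canonical_protein = canonical_protein)
    cand
  })
}

#' @export
print.orf_candidate <- function(x, ...) {
  cat(sprintf("orf_candidate: start nt %d (exon %d), %d aa, %.1f kDa, delta %d\n",
              x$start_nt, x$start_exon, x$length_aa, x$mass_da / 1000, x$delta))
  if (length(c(x$domains_lost, x$domains_retained, x$domains_truncated)))
    cat(sprintf("  domains lost: %s | retained: %s | truncated: %s\n",
                paste(x$domains_lost, collapse = ","),
                paste(x$domains_retained, collapse = ","),
                paste(x$domains_truncated, collapse = ",")))
  invisible(x)
}

#' Classify canonical domains as lost, retained or truncated
#'
#' With `delta` the candidate's N-terminal offset (canonical length minus
#' candidate length), a domain is lost when `aa_end <= delta`, retained
#' when `aa_start > delta`, truncated otherwise. Every domain lands in
#' exactly one class. When the canonical protein sequence is supplied the
#' candidate is verified to be its C-terminal suffix.
#'
#' @param cand An `orf_candidate`.
#' @param domains Domain data.frame (see [domain_annotation()]).
#' @param canonical_length Canonical protein length in aa.
#' @param canonical_protein Optional canonical protein sequence for the
#'   suffix check.
#' @return The candidate with the three domain lists filled in.
#' @export
assess_domains <- function(cand, domains, canonical_length,
                           canonical_protein = NULL) {
  delta <- canonical_length - cand$length_aa
  if (delta < 0) stop("candidate longer than canonical protein")
  if (!is.null(canonical_protein)) {
    suffix <- substr(canonical_protein, delta + 1, canonical_length)
    if (!identical(suffix, cand$protein))
      stop("short ORF is not a C-terminal fragment of the canonical protein")
  }
  if (any(domains$aa_end > canonical_length))
    stop("domain end exceeds canonical protein length")
  cand$delta <- delta
  cand$domains_lost <- domains$name[domains$aa_end <= delta]
  cand$domains_retained <- domains$name[domains$aa_start > delta]
  cand$domains_truncated <- domains$name[domains$aa_start <= delta &
                                           domains$aa_end > delta]
  cand
}

#' Tabulate ORF candidates
#' @param cands List of `orf_candidate`.
#' @return data.frame with one row per candidate.
#' @export
orf_table <- function(cands) {
  data.frame(
    start_nt = vapply(cands, function(c) c$start_nt, integer(1)),
    start_exon = vapply(cands, function(c) c$start_exon, integer(1)),
    length_aa = vapply(cands, function(c) c$length_aa, integer(1)),
    mass_kda = round(vapply(cands, function(c) c$mass_da, numeric(1)) / 1000, 1),
    delta = vapply(cands, function(c) c$delta, numeric(1)),
    domains_lost = vapply(cands, function(c) paste(c$domains_lost, collapse = ","), character(1)),
    domains_retained = vapply(cands, function(c) paste(c$domains_retained, collapse = ","), character(1)),
    domains_truncated = vapply(cands, function(c) paste(c$domains_truncated, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Write candidate proteins to FASTA
#' @param cands List of `orf_candidate`.
#' @param path Output FASTA file.
#' @param prefix Sequence-name prefix.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(cands, path, prefix = "orf") {
  seqs <- Biostrings::AAStringSet(vapply(cands, function(c) c$protein, character(1)))
  names(seqs) <- vapply(cands, function(c)
    sprintf("%s_start%d_exon%d", prefix, c$start_nt, c$start_exon), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
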