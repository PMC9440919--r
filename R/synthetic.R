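#' @title Synthetic ground-truth generators
#'
#' @description
#' Generates fixtures with the statistical structure the analysis assumes,
#' so every stage is testable without external downloads: a 28-exon gene
#' whose 5' exons are silent while a 3' block (exons k..E, default 23..28)
#' is expressed; negative-binomial exon counts; chromatin tracks with a
#' repressed 5' body and a local active-mark peak at the truncation point;
#' and condition-dependent peptide intensities confined to the shared
#' C-terminal region. All generators are deterministic given the seed; one
#' global seed fans out to fixed per-generator substreams so adding a
#' generator never perturbs the others.
#'
#' The planted gene model is a synthetic stand-in for the murine locus the
#' study describes, not its real sequence: the short ORF opens at the first
#' nt of exon k and runs 250 codons to the canonical stop, so its product
#' is a ~28 kDa C-terminal fragment; a "transmembrane" domain sits in the
#' lost N-terminal region.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param seed Global seed (integer).
#' @param E Exon count.
#' @param exon_length Exon length in bp.
#' @param intron_length Intron length in bp.
#' @param strand `"+"` or `"-"`.
#' @param k First exon of the expressed 3' block (truncation breakpoint).
#' @param short_orf_aa Length of the planted short ORF in residues.
#' @param depth Expected reads per expressed exon.
#' @param expression_ratio On/off expression ratio (silent-exon mean =
#'   `depth / expression_ratio`; may be `Inf` for fully silent).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param library_background Reads added to the locus total to form the
#'   per-sample library size (total mapped reads).
#' @param n_per_group Samples per condition.
#' @param peak_fold ChIP peak fold over background.
#' @param peak_width ChIP peak full width in bp.
#' @param noise_sd_frac ChIP Gaussian noise sd as a fraction of background.
#' @param bin_width ChIP track bin width in bp.
#' @param peptide_fold True treated/control peptide fold change.
#' @param peptide_cv Lognormal coefficient of variation of intensities.
#' @param detection_prob Per-peptide per-sample detection probability.
#' @param n_unique_peptides Number of isoform-unique peptides reported.
#' @param target_coverage_pct Sequence coverage the unique-peptide set is
#'   chosen to approximate.
#' @param base_auc Baseline summed XIC area per peptide.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, E = 28L, exon_length = 150L,
                       intron_length = 2000L, strand = "+",
                       k = 23L, short_orf_aa = 250L,
                       depth = 100, expression_ratio = 50,
                       nb_dispersion = 0.2, library_background = 3e8,
                       n_per_group = 3L,
                       peak_fold = 5, peak_width = 5000,
                       noise_sd_frac = 0.2, bin_width = 100L,
                       peptide_fold = 2.0, peptide_cv = 0.2,
                       detection_prob = 0.9, n_unique_peptides = 6L,
                       target_coverage_pct = 40, base_auc = 1000,
                       chrom = "chrS") {
  cfg <- list(seed = as.integer(seed), E = as.integer(E),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length), strand = strand,
              k = as.integer(k), short_orf_aa = as.integer(short_orf_aa),
              depth = depth, expression_ratio = expression_ratio,
              nb_dispersion = nb_dispersion,
              library_background = library_background,
              n_per_group = as.integer(n_per_group),
              peak_fold = peak_fold, peak_width = peak_width,
              noise_sd_frac = noise_sd_frac, bin_width = as.integer(bin_width),
              peptide_fold = peptide_fold, peptide_cv = peptide_cv,
              detection_prob = detection_prob,
              n_unique_peptides = as.integer(n_unique_peptides),
              target_coverage_pct = target_coverage_pct, base_auc = base_auc,
              chrom = chrom)
  stopifnot(cfg$E >= 3, cfg$k >= 2, cfg$k <= cfg$E, cfg$exon_length > 0,
            cfg$depth > 0, cfg$nb_dispersion >= 0,
            cfg$detection_prob > 0, cfg$detection_prob <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# fixed substream seeds: adding a generator never perturbs the others
.substream <- function(seed, generator) {
  offs <- c(genemodel = 101L, counts = 211L, chip = 307L, peptides = 401L,
            reads = 503L)
  if (!generator %in% names(offs)) stop("unknown substream ", generator)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[generator]]
}

#' Simulate the gene model, genome and domain annotation
#'
#' Plants a canonical ORF (ATG at the transcript start, stop in the last
#' exon) containing an in-frame ATG at the first nt of exon `k` with no
#' in-frame stop downstream of it, so the short ORF of `short_orf_aa`
#' residues terminates at the canonical stop codon. A "transmembrane"
#' domain is placed entirely inside the lost N-terminal region and a
#' "cytoplasmic_tail" domain inside the retained C-terminal region.
#'
#' @param cfg A [sim_config()].
#' @return List with `transcript` (a `transcript_model`), `genome`
#'   ([Biostrings::DNAStringSet]), `domains` (data.frame),
#'   `canonical_protein`, `short_protein`, `short_start_nt`, `delta`.
#' @export
simulate_gene_model <- function(cfg = sim_config()) {
  set.seed(.substream(cfg$seed, "genemodel"))
  E <- cfg$E; L <- cfg$exon_length
  tlen <- E * L
  s_k <- (cfg$k - 1L) * L + 1L            # transcript pos of exon k's first nt
  if ((s_k - 1L) %% 3L != 0L)
    stop("constraints unsatisfiable: exon ", cfg$k,
         " does not start in frame with a CDS opening at position 1")
  cds_stop <- s_k + 3L * cfg$short_orf_aa
  if (cds_stop + 2L > tlen)
    stop("constraints unsatisfiable: short ORF of ", cfg$short_orf_aa,
         " aa overruns the transcript (exons too short)")
  canonical_aa <- (cds_stop - 1L) %/% 3L
  sense <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)
  codons <- sample(sense, canonical_aa, replace = TRUE)
  codons[1] <- "ATG"
  codons[(s_k - 1L) %/% 3L + 1L] <- "ATG"
  tail_len <- tlen - (cds_stop + 2L)
  txseq <- paste0(paste(codons, collapse = ""), "TAA",
                  if (tail_len > 0)
                    paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE),
                          collapse = "") else "")

  # place exons on the genome
  step <- L + cfg$intron_length
  g_starts <- 1000L + (seq_len(E) - 1L) * step + 1L
  chrom_len <- g_starts[E] + L - 1L + 1000L
  ex <- GenomicRanges::GRanges(cfg$chrom,
                               IRanges::IRanges(g_starts, width = L),
                               strand = cfg$strand)
  # transcript order: index 1 has smallest start on '+', largest on '-'
  tx_order <- if (cfg$strand == "+") seq_len(E) else rev(seq_len(E))
  chr <- rep("N", chrom_len)
  bg <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  chr <- bg
  for (i in seq_len(E)) {
    seg <- substr(txseq, (i - 1L) * L + 1L, i * L)
    if (cfg$strand == "-")
      seg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
    gi <- tx_order[i]   # genomic slot holding transcript exon i
    chr[seq(g_starts[gi], g_starts[gi] + L - 1L)] <- strsplit(seg, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(chr, collapse = ""))
  names(genome) <- cfg$chrom

  t <- transcript_model("synthTX1", "synthG1", ex,
                        cds_start = 1L, cds_stop = cds_stop)
  canonical_protein <- translate_orf(substr(txseq, 1, cds_stop - 1))
  short_protein <- translate_orf(substr(txseq, s_k, cds_stop - 1))
  delta <- nchar(canonical_protein) - nchar(short_protein)
  # transmembrane entirely inside the lost region; tail inside the retained one
  tm_start <- max(1L, min(delta - 40L, round(0.6 * delta)))
  domains <- domain_annotation(
    c("transmembrane", "cytoplasmic_tail"),
    c(tm_start, delta + max(10L, cfg$short_orf_aa %/% 5L)),
    c(tm_start + 20L, delta + max(10L, cfg$short_orf_aa %/% 5L) + 30L),
    canonical_length = nchar(canonical_protein))
  list(transcript = t, genome = genome, domains = domains,
       canonical_protein = canonical_protein, short_protein = short_protein,
       short_start_nt = s_k, delta = delta, config = cfg)
}

#' Simulate per-exon counts
#'
#' Exon means are `depth` where expressed under `state` and
#' `depth / expression_ratio` otherwise; counts are negative binomial with
#' the configured dispersion (Poisson in the dispersion -> 0 limit).
#' Library size is the locus total plus `library_background`.
#'
#' @param cfg A [sim_config()].
#' @param state `"full"` (all exons expressed), `"off"` (none), or
#'   `"short"` (exons `k..E`).
#' @param n_samples Number of samples to draw.
#' @param seed Substream seed override (defaults to the config seed's
#'   counts substream).
#' @return List with `counts` (E x n_samples integer matrix) and
#'   `library_sizes`.
#' @export
simulate_counts <- function(cfg = sim_config(), state = "short",
                            n_samples = 1L, seed = NULL) {
  set.seed(if (is.null(seed)) .substream(cfg$seed, "counts") else seed)
  expressed <- switch(state,
    full = rep(TRUE, cfg$E),
    off = rep(FALSE, cfg$E),
    short = seq_len(cfg$E) >= cfg$k,
    stop("state must be one of 'full', 'off', 'short'"))
  off_mean <- if (is.infinite(cfg$expression_ratio)) 0
              else cfg$depth / cfg$expression_ratio
  mu <- ifelse(expressed, cfg$depth, off_mean)
  draw <- function(m) {
    if (m == 0) return(numeric(n_samples))
    if (cfg$nb_dispersion < 1e-8) as.numeric(stats::rpois(n_samples, m))
    else as.numeric(stats::rnbinom(n_samples, mu = m, size = 1 / cfg$nb_dispersion))
  }
  counts <- t(vapply(mu, draw, numeric(n_samples)))
  counts <- matrix(as.integer(counts), nrow = cfg$E)
  colnames(counts) <- paste0("sample", seq_len(n_samples))
  list(counts = counts,
       library_sizes = colSums(counts) + cfg$library_background)
}

#' Write simulated reads for one sample to BED
#'
#' Expands per-exon counts into ungapped BED3 read intervals inside each
#' exon (uniform start offsets), exercising the BED counting path.
#'
#' @param counts Integer vector of per-exon counts.
#' @param t A `transcript_model`.
#' @param path Output BED file.
#' @param read_length Read length in bp.
#' @param seed Seed for read placement.
#' @return `path`, invisibly.
#' @export
simulate_reads_bed <- function(counts, t, path, read_length = 50L, seed = 1L) {
  set.seed(seed)
  stopifnot(length(counts) == n_exons(t))
  s <- GenomicRanges::start(t$exons); e <- GenomicRanges::end(t$exons)
  rows <- list()
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    max_off <- max(0L, (e[i] - s[i] + 1L) - read_length)
    off <- sample.int(max_off + 1L, counts[i], replace = TRUE) - 1L
    rows[[i]] <- data.frame(chrom = as.character(GenomicRanges::seqnames(t$exons))[i],
                            start = s[i] + off - 1L,     # BED is 0-based
                            end = s[i] + off - 1L + read_length)
  }
  bed <- do.call(rbind, rows)
  if (is.null(bed)) bed <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0))
  utils::write.table(bed[order(bed$start), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate chromatin signal tracks
#'
#' Background 1.0 plus Gaussian noise (sd = `noise_sd_frac` x background,
#' clamped at 0) in `bin_width` bins over the locus plus flanks. Scenario
#' `"alternative_promoter"` adds a `peak_fold` peak of width `peak_width`
#' on the active marks at the 5' end of exon `k` and elevates H3K27me3 by
#' the same fold over the span of exons `1..k-1`; `"canonical_only"` puts
#' the active peak at the canonical TSS instead; `"flat"` adds nothing.
#'
#' @param cfg A [sim_config()].
#' @param t A `transcript_model` (from [simulate_gene_model()]).
#' @param scenario One of `"alternative_promoter"`, `"canonical_only"`,
#'   `"flat"`.
#' @param seed Substream seed override.
#' @return Named list of GRanges tracks: H3K27ac, H3K4me3, PolII, H3K27me3.
#' @export
simulate_chip_tracks <- function(cfg = sim_config(), t, scenario = "alternative_promoter",
                                 seed = NULL) {
  scenario <- match.arg(scenario, c("alternative_promoter", "canonical_only", "flat"))
  set.seed(if (is.null(seed)) .substream(cfg$seed, "chip") else seed)
  chrom <- as.character(GenomicRanges::seqnames(t$exons)[1])
  gmin <- min(GenomicRanges::start(t$exons)); gmax <- max(GenomicRanges::end(t$exons))
  lo <- max(1L, gmin - 5000L); hi <- gmax + 5000L
  starts <- seq(lo, hi, by = cfg$bin_width)
  bins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    starts, pmin(starts + cfg$bin_width - 1L, hi)))
  mids <- (GenomicRanges::start(bins) + GenomicRanges::end(bins)) / 2

  exk <- t$exons[cfg$k]
  anchor_alt <- if (t$strand == "+") GenomicRanges::start(exk) else GenomicRanges::end(exk)
  anchor_can <- if (t$strand == "+") gmin else gmax
  body_idx <- seq_len(cfg$k - 1L)
  body_lo <- min(GenomicRanges::start(t$exons)[body_idx])
  body_hi <- max(GenomicRanges::end(t$exons)[body_idx])

  mk_track <- function(peak_at = NULL, elevated = NULL) {
    v <- 1 + stats::rnorm(length(bins), 0, cfg$noise_sd_frac)
    if (!is.null(peak_at)) {
      in_pk <- abs(mids - peak_at) <= cfg$peak_width / 2
      v[in_pk] <- v[in_pk] + (cfg$peak_fold - 1)
    }
    if (!is.null(elevated)) {
      in_el <- mids >= elevated[1] & mids <= elevated[2]
      v[in_el] <- v[in_el] + (cfg$peak_fold - 1)
    }
    out <- bins
    S4Vectors::mcols(out)$score <- pmax(v, 0)
    out
  }
  if (scenario == "alternative_promoter") {
    list(H3K27ac = mk_track(peak_at = anchor_alt),
         H3K4me3 = mk_track(peak_at = anchor_alt),
         PolII = mk_track(peak_at = anchor_alt),
         H3K27me3 = mk_track(elevated = c(body_lo, body_hi)))
  } else if (scenario == "canonical_only") {
    list(H3K27ac = mk_track(peak_at = anchor_can),
         H3K4me3 = mk_track(peak_at = anchor_can),
         PolII = mk_track(peak_at = anchor_can),
         H3K27me3 = mk_track())
  } else {
    list(H3K27ac = mk_track(), H3K4me3 = mk_track(),
         PolII = mk_track(), H3K27me3 = mk_track())
  }
}

# deterministic subset-sum: n peptides whose total length best approximates
# the target covered length (tryptic 0-missed peptides are disjoint)
.select_coverage_subset <- function(lengths, n, target_len) {
  stopifnot(length(lengths) >= n)
  best <- NULL; best_err <- Inf
  # DP over (count, achievable sum) keeping the lexicographically first subset
  states <- list(`0_0` = integer(0))
  for (i in seq_along(lengths)) {
    new <- states
    for (key in names(states)) {
      parts <- as.integer(strsplit(key, "_")[[1]])
      cnt <- parts[1]; sm <- parts[2]
      if (cnt < n) {
        k2 <- paste0(cnt + 1L, "_", sm + lengths[i])
        if (is.null(new[[k2]])) new[[k2]] <- c(states[[key]], i)
      }
    }
    states <- new
  }
  for (key in names(states)) {
    parts <- as.integer(strsplit(key, "_")[[1]])
    if (parts[1] == n) {
      err <- abs(parts[2] - target_len)
      if (err < best_err) { best_err <- err; best <- states[[key]] }
    }
  }
  best
}

#' Simulate peptide observations
#'
#' Tryptic peptides of the short protein (detectable range 7-25 aa) are
#' the candidate pool; `n_unique_peptides` of them are selected so their
#' combined span is closest to `target_coverage_pct` of the short protein.
#' Per sample, each peptide's summed XIC area is
#' `base_auc x fold(condition) x lognormal(cv)` split over three fragment
#' ions, observed with probability `detection_prob` (at least one peptide
#' is always retained per sample). Under `scenario = "full"` two
#' N-exclusive peptides of the canonical protein are added in both
#' conditions, emulating full-length protein evidence.
#'
#' @param cfg A [sim_config()].
#' @param gm Output of [simulate_gene_model()].
#' @param scenario `"short"` (default) or `"full"`.
#' @param seed Substream seed override.
#' @return List with `observations` (data.frame: sequence, sample,
#'   condition, auc), `unique_peptides`, `true_fold`.
#' @export
simulate_peptides <- function(cfg = sim_config(), gm, scenario = "short",
                              seed = NULL) {
  scenario <- match.arg(scenario, c("short", "full"))
  set.seed(if (is.null(seed)) .substream(cfg$seed, "peptides") else seed)
  prot <- gm$short_protein
  dig <- tryptic_digest(prot, 0L, min_len = 7L, max_len = 25L)
  if (nrow(dig) < cfg$n_unique_peptides)
    stop("short protein yields too few detectable tryptic peptides")
  target_len <- cfg$target_coverage_pct / 100 * nchar(prot)
  sel <- .select_coverage_subset(nchar(dig$peptide), cfg$n_unique_peptides,
                                 round(target_len))
  unique_peptides <- dig$peptide[sel]

  samples <- c(paste0("control", seq_len(cfg$n_per_group)),
               paste0("treated", seq_len(cfg$n_per_group)))
  conditions <- rep(c("control", "treated"), each = cfg$n_per_group)
  sdlog <- sqrt(log(1 + cfg$peptide_cv^2))
  rows <- list()
  for (si in seq_along(samples)) {
    fold <- if (conditions[si] == "treated") cfg$peptide_fold else 1
    detected <- stats::runif(length(unique_peptides)) <= cfg$detection_prob
    if (!any(detected)) detected[1] <- TRUE
    for (pi in which(detected)) {
      total <- cfg$base_auc * fold *
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      frac <- c(0.5, 0.3, 0.2)   # three fragment ions per peptide
      for (f in frac)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = unique_peptides[pi], sample = samples[si],
          condition = conditions[si], auc = total * f,
          stringsAsFactors = FALSE)
    }
  }
  if (scenario == "full") {
    ndig <- tryptic_digest(gm$canonical_protein, 0L, min_len = 7L, max_len = 25L)
    npep <- utils::head(ndig$peptide[ndig$end <= gm$delta], 2)
    for (si in seq_along(samples)) for (p in npep)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = p, sample = samples[si], condition = conditions[si],
        auc = cfg$base_auc *
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog),
        stringsAsFactors = FALSE)
  }
  list(observations = do.call(rbind, rows),
       unique_peptides = unique_peptides,
       true_fold = cfg$peptide_fold)
}

#' Write a complete synthetic fixture directory
#'
#' Emits genome FASTA, GTF annotation, domain TSV, per-sample read BEDs
#' (control = off state, treated = short state), ChIP bedGraphs, the
#' peptide-observation TSV and a JSON copy of the configuration. All files
#' are plain text; file names carry the `synthetic_` prefix.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param scenario ChIP/peptide scenario, as in [simulate_chip_tracks()].
#' @return Named list of written paths plus the generated objects,
#'   invisibly.
#' @export
write_synthetic_fixtures <- function(cfg = sim_config(), dir,
                                     scenario = "alternative_promoter") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulate_gene_model(cfg)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(gm$genome, p("synthetic_genome.fa"))
  write_annotation(list(gm$transcript), p("synthetic_annotation.gtf"))
  utils::write.table(gm$domains, p("synthetic_domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  n <- cfg$n_per_group
  trt <- simulate_counts(cfg, "short", n, seed = .substream(cfg$seed, "counts"))
  ctl <- simulate_counts(cfg, "off", n, seed = .substream(cfg$seed, "counts") + 1L)
  beds <- character(0)
  for (i in seq_len(n)) {
    f1 <- p(sprintf("synthetic_reads_treated%d.bed", i))
    simulate_reads_bed(trt$counts[, i], gm$transcript, f1,
                       seed = .substream(cfg$seed, "reads") + i)
    f2 <- p(sprintf("synthetic_reads_control%d.bed", i))
    simulate_reads_bed(ctl$counts[, i], gm$transcript, f2,
                       seed = .substream(cfg$seed, "reads") + 100L + i)
    beds <- c(beds, stats::setNames(c(f1, f2),
                                    c(paste0("treated", i), paste0("control", i))))
  }
  tracks <- simulate_chip_tracks(cfg, gm$transcript, scenario)
  track_paths <- vapply(names(tracks), function(m) {
    f <- p(sprintf("synthetic_chip_%s.bedGraph", m))
    rtracklayer::export(tracks[[m]], f, format = "bedGraph")
    f
  }, character(1))
  pep <- simulate_peptides(cfg, gm,
                           scenario = if (scenario == "alternative_promoter")
                             "short" else "full")
  utils::write.table(pep$observations, p("synthetic_peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(pep$unique_peptides, p("synthetic_unique_peptides.txt"))
  jsonlite::write_json(unclass(cfg), p("synthetic_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    dir = dir, gene_model = gm,
    counts = list(treated = trt, control = ctl),
    beds = beds, tracks = track_paths, peptides = pep,
    paths = list(genome = p("synthetic_genome.fa"),
                 annotation = p("synthetic_annotation.gtf"),
                 domains = p("synthetic_domains.tsv"),
                 peptide_table = p("synthetic_peptides.tsv"))))
}
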