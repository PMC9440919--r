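test_that("GTF exons are indexed strand-aware and CDS converted to transcript coordinates", {
  gtf <- c(
    'chr1\ttoy\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\tCDS\t150\t200\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\tCDS\t300\t350\t.\t+\t1\tgene_id "g1"; transcript_id "t1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  models <- read_annotation(f)
  expect_length(models, 1)
  t <- models[["t1"]]
  expect_equal(GenomicRanges::start(t$exons), c(100, 300))
  expect_equal(GenomicRanges::end(t$exons), c(200, 400))
  expect_equal(S4Vectors::mcols(t$exons)$exon_index, c(1, 2))
  # CDS 150..200 + 300..350 -> transcript 51..152, stop codon right after
  expect_equal(t$cds_start, 51)
  expect_equal(t$cds_stop, 153)
})

test_that("on the minus strand exon 1 is the interval with the larger start", {
  gtf <- c(
    'chr1\ttoy\texon\t100\t200\t.\t-\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t300\t400\t.\t-\t.\tgene_id "g1"; transcript_id "t1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  t <- read_annotation(f)[["t1"]]
  expect_equal(GenomicRanges::start(t$exons)[1], 300)
  expect_equal(S4Vectors::mcols(t$exons)$exon_index, c(1, 2))
})

test_that("an annotation without features yields an empty set with a warning", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f)
  expect_warning(models <- read_annotation(f), "no features|no exon")
  expect_length(models, 0)
})

test_that("genomic/transcript coordinate conversion matches hand-derived values", {
  t <- toy_transcript("+")
  expect_equal(genomic_to_transcript(t, 100), 1)   # first exonic base
  expect_equal(genomic_to_transcript(t, 300), 102) # exon1 width 101, then first of exon2
  expect_equal(transcript_to_genomic(t, 102), 300)
  expect_error(genomic_to_transcript(t, 250), "not exonic")
  tm <- toy_transcript("-")
  expect_equal(genomic_to_transcript(tm, 400), 1)  # 5' end on minus strand
  expect_equal(genomic_to_transcript(tm, 200), 102)
})

test_that("coordinate round trip holds for every exonic base of random transcripts", {
  set.seed(42)
  for (i in 1:60) {
    t <- random_transcript(sample(2:8, 1))
    g_all <- unlist(lapply(seq_along(t$exons), function(j)
      seq(GenomicRanges::start(t$exons)[j], GenomicRanges::end(t$exons)[j])))
    p <- vapply(g_all, function(g) genomic_to_transcript(t, g), integer(1))
    expect_equal(sort(p), seq_len(transcript_length(t)))
    g_back <- vapply(p, function(pp) transcript_to_genomic(t, pp), numeric(1))
    expect_equal(g_back, as.numeric(g_all))
  }
})

test_that("spliced sequence concatenates exons and reverse-complements minus strand", {
  chr <- Biostrings::DNAStringSet("NNACGNNTTTNN")
  names(chr) <- "chr1"
  exp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3, 8), c(5, 10)),
                                strand = "+")
  tp <- transcript_model("tp", "g", exp)
  expect_equal(as.character(spliced_sequence(tp, chr)), "ACGTTT")
  exm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3, 8), c(5, 10)),
                                strand = "-")
  tm <- transcript_model("tm", "g", exm)
  expect_equal(as.character(spliced_sequence(tm, chr)), "AAACGT")
  # sequence length equals sum of exon lengths
  expect_equal(length(spliced_sequence(tp, chr)), transcript_length(tp))
  # chromosome absent / exon beyond contig end are named errors
  bad <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 3), strand = "+")
  expect_error(spliced_sequence(transcript_model("tb", "g", bad), chr), "chr2")
  over <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 99), strand = "+")
  expect_error(spliced_sequence(transcript_model("to", "g", over), chr),
               "exceeds")
})

test_that("serializing and re-parsing an annotation reproduces the model", {
  cfg <- sim_config(seed = 3)
  gm <- simulate_gene_model(cfg)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(list(gm$transcript), f)
  t2 <- read_annotation(f)[[gm$transcript$transcript_id]]
  expect_equal(GenomicRanges::start(t2$exons),
               GenomicRanges::start(gm$transcript$exons))
  expect_equal(t2$strand, gm$transcript$strand)
  expect_equal(t2$cds_start, gm$transcript$cds_start)
  expect_equal(t2$cds_stop, gm$transcript$cds_stop)
})

test_that("transcript_model enforces its invariants", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50), c(60, 80)),
                               strand = "+")
  expect_error(transcript_model("t", "g", ex), "overlap")
  ok <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 90), strand = "+")
  expect_error(transcript_model("t", "g", ok, cds_start = 10, cds_stop = 12),
               "multiple of 3")
  expect_error(transcript_model("t", "g", ok, cds_start = 10, cds_stop = 89),
               "beyond transcript end|multiple")
})
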