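test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42)
  gm1 <- simulate_gene_model(cfg)
  gm2 <- simulate_gene_model(cfg)
  expect_identical(as.character(gm1$genome), as.character(gm2$genome))
  expect_identical(gm1$short_protein, gm2$short_protein)
  expect_identical(simulate_counts(cfg, "short", 3)$counts,
                   simulate_counts(cfg, "short", 3)$counts)
  t1 <- simulate_chip_tracks(cfg, gm1$transcript)
  t2 <- simulate_chip_tracks(cfg, gm1$transcript)
  expect_identical(S4Vectors::mcols(t1$H3K27ac)$score,
                   S4Vectors::mcols(t2$H3K27ac)$score)
  p1 <- simulate_peptides(cfg, gm1)
  p2 <- simulate_peptides(cfg, gm1)
  expect_identical(p1$observations, p2$observations)
})

test_that("the planted gene model satisfies every downstream precondition", {
  cfg <- sim_config(seed = 5)
  gm <- simulate_gene_model(cfg)
  t <- gm$transcript
  seq <- as.character(spliced_sequence(t, gm$genome))
  # canonical CDS opens with ATG and ends at a stop codon
  expect_equal(substr(seq, t$cds_start, t$cds_start + 2), "ATG")
  expect_true(substr(seq, t$cds_stop, t$cds_stop + 2) %in%
                c("TAA", "TAG", "TGA"))
  # planted in-frame ATG at the first nt of exon k, clean ORF to the stop
  expect_equal(substr(seq, gm$short_start_nt, gm$short_start_nt + 2), "ATG")
  expect_equal(exon_of_position(t, gm$short_start_nt), cfg$k)
  expect_equal(nchar(gm$short_protein), cfg$short_orf_aa)
  # short protein is the C-terminal suffix of the canonical protein
  expect_true(endsWith(gm$canonical_protein, gm$short_protein))
  # transmembrane domain sits entirely in the lost N-terminal region
  tm <- gm$domains[gm$domains$name == "transmembrane", ]
  expect_lte(tm$aa_end, gm$delta)
  # domain coordinates valid on the canonical protein
  expect_true(all(gm$domains$aa_end <= nchar(gm$canonical_protein)))
})

test_that("unsatisfiable gene-model constraints error out", {
  expect_error(simulate_gene_model(sim_config(E = 28, exon_length = 150,
                                              short_orf_aa = 400)),
               "unsatisfiable")
  expect_error(simulate_gene_model(sim_config(exon_length = 100)),
               "unsatisfiable|frame")
})

test_that("minus-strand gene models behave identically through the pipeline core", {
  cfg <- sim_config(seed = 8, strand = "-")
  gm <- simulate_gene_model(cfg)
  expect_equal(gm$transcript$strand, "-")
  # exon 1 is the rightmost interval on the minus strand
  expect_equal(GenomicRanges::start(gm$transcript$exons)[1],
               max(GenomicRanges::start(gm$transcript$exons)))
  seq <- as.character(spliced_sequence(gm$transcript, gm$genome))
  expect_equal(substr(seq, gm$short_start_nt, gm$short_start_nt + 2), "ATG")
  cands <- orf_candidates(gm$transcript, seq, first_exon = cfg$k)
  expect_equal(cands[[1]]$protein, gm$short_protein)
})

test_that("count states produce the intended expression pattern", {
  cfg <- sim_config(seed = 13)
  off0 <- sim_config(seed = 13, expression_ratio = Inf)
  expect_true(all(simulate_counts(off0, "off", 2)$counts == 0))
  sc <- simulate_counts(cfg, "short", 20)
  m5 <- mean(sc$counts[1:(cfg$k - 1), ])
  m3 <- mean(sc$counts[cfg$k:cfg$E, ])
  expect_gt(m3 / max(m5, 1e-9), 10)   # ~50-fold in expectation
  expect_equal(sc$library_sizes,
               colSums(sc$counts) + cfg$library_background)
})

test_that("dispersion -> 0 approaches the Poisson limit", {
  cfg <- sim_config(seed = 14, nb_dispersion = 0)
  x <- as.numeric(simulate_counts(cfg, "full", 1000)$counts[1, ])
  # mean 100: variance within Monte-Carlo error of the mean
  expect_equal(stats::var(x) / mean(x), 1, tolerance = 0.15)
  cfg2 <- sim_config(seed = 14, nb_dispersion = 0.2)
  y <- as.numeric(simulate_counts(cfg2, "full", 1000)$counts[1, ])
  # overdispersed: variance ~ mu + 0.2 mu^2 = 21 mu
  expect_gt(stats::var(y) / mean(y), 5)
})

test_that("simulated BED reads reproduce the generating counts", {
  cfg <- sim_config(seed = 15)
  gm <- simulate_gene_model(cfg)
  counts <- simulate_counts(cfg, "short", 1)$counts[, 1]
  f <- withr::local_tempfile(fileext = ".bed")
  simulate_reads_bed(counts, gm$transcript, f, seed = 99)
  got <- count_reads_per_exon(read_bed_reads(f), gm$transcript)
  # reads are placed fully inside their exon, so counting is exact
  expect_equal(as.integer(got), as.integer(counts))
})

test_that("fixture directories are complete, plain-text and reproducible", {
  cfg <- sim_config(seed = 16, n_per_group = 2)
  d1 <- withr::local_tempdir()
  fx <- write_synthetic_fixtures(cfg, d1)
  expect_true(all(file.exists(unlist(fx$paths))))
  expect_true(all(file.exists(fx$beds)))
  # re-parse the GTF and recover the same transcript
  t2 <- read_annotation(fx$paths$annotation)[[1]]
  expect_equal(t2$cds_stop, fx$gene_model$transcript$cds_stop)
  # same seed, second directory: byte-identical files
  d2 <- withr::local_tempdir()
  write_synthetic_fixtures(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
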