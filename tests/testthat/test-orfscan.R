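test_that("stop-anchored start finding matches hand-worked examples", {
  # "GGATGAAATAA": ATG at 3 (1-based), stop at 9
  expect_equal(find_inframe_starts("GGATGAAATAA", 9), 3L)
  expect_equal(translate_orf(substr("GGATGAAATAA", 3, 8)), "MK")
  # two nested in-frame starts
  expect_equal(find_inframe_starts("ATGGCAATGGCATAA", 13), c(1L, 7L))
  # no ATG at all
  expect_equal(find_inframe_starts("CCCCCCTAA", 7), integer(0))
  # errors: not a stop codon; window outside sequence
  expect_error(find_inframe_starts("ATGAAACCC", 7), "stop codon")
  expect_error(find_inframe_starts("ATGTAA", 4, search_window = c(1, 50)),
               "window")
  # an in-frame internal stop disqualifies upstream starts
  expect_equal(find_inframe_starts("ATGTAAATGTAA", 10), 7L)
})

test_that("find_inframe_starts equals the brute-force oracle on random sequences", {
  set.seed(202)
  for (i in 1:1000) {
    s <- random_stop_anchored_seq(300)
    got <- find_inframe_starts(s$seq, s$cds_stop)
    want <- oracle_inframe_starts(s$seq, s$cds_stop)
    expect_equal(got, as.integer(want))
  }
})

test_that("nested starts give nested proteins (suffix property)", {
  set.seed(203)
  checked <- 0
  for (i in 1:600) {
    s <- random_stop_anchored_seq(300)
    starts <- find_inframe_starts(s$seq, s$cds_stop)
    if (length(starts) < 2) next
    prots <- vapply(starts, function(p)
      translate_orf(substr(s$seq, p, s$cds_stop - 1)), character(1))
    for (j in 2:length(prots))
      expect_true(endsWith(prots[1], prots[j]))
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("translation follows the standard code and rejects bad input", {
  expect_equal(translate_orf("ATGAAA"), "MK")
  expect_equal(translate_orf("ATG"), "M")
  expect_error(translate_orf("ATGTAAAAA"), "internal stop")
  expect_error(translate_orf("ATGANA"), "position 5")
  expect_error(translate_orf("ATGA"), "multiple of 3")
  # initiator rendered as M even for a non-ATG start codon
  expect_equal(substr(translate_orf("TTGAAA"), 1, 1), "M")
})

test_that("protein mass uses average residue masses plus one water", {
  expect_equal(protein_mass("G"), 75.07, tolerance = 0.01)
  expect_equal(protein_mass("MK"), 277.39, tolerance = 0.02)
  expect_error(protein_mass(""), "empty")
  expect_error(protein_mass("AB"), "non-standard")
  # additivity: mass(A+B) = mass(A) + mass(B) - water
  set.seed(9)
  aas <- names(shortiso:::.AA_AVG_MASS)
  for (i in 1:20) {
    a <- paste(sample(aas, 8, TRUE), collapse = "")
    b <- paste(sample(aas, 5, TRUE), collapse = "")
    expect_equal(protein_mass(paste0(a, b)),
                 protein_mass(a) + protein_mass(b) - 18.01528,
                 tolerance = 1e-9)
  }
})

test_that("domains partition into lost/retained/truncated by the offset rule", {
  mk <- function(len) structure(list(protein = strrep("A", len),
                                     length_aa = len), class = "orf_candidate")
  doms <- domain_annotation(c("d_lost", "d_trunc", "d_kept"),
                            c(20, 55, 61), c(41, 70, 80))
  c1 <- assess_domains(mk(40), doms, canonical_length = 100)  # delta 60
  expect_equal(c1$domains_lost, "d_lost")
  expect_equal(c1$domains_truncated, "d_trunc")
  expect_equal(c1$domains_retained, "d_kept")
  # every domain in exactly one class
  expect_setequal(c(c1$domains_lost, c1$domains_retained, c1$domains_truncated),
                  doms$name)
  # delta 0: everything retained
  c2 <- assess_domains(mk(100), doms, canonical_length = 100)
  expect_setequal(c2$domains_retained, doms$name)
  expect_length(c2$domains_lost, 0)
})

test_that("the suffix check rejects candidates that are not C-terminal fragments", {
  cand <- structure(list(protein = "XYZ", length_aa = 3), class = "orf_candidate")
  expect_error(assess_domains(cand, domain_annotation("d", 1, 2), 10,
                              canonical_protein = "AAAAAAAAAA"),
               "not a C-terminal fragment")
})

test_that("orf_candidates on the synthetic transcript finds the planted short ORF", {
  cfg <- sim_config(seed = 31)
  gm <- simulate_gene_model(cfg)
  seq <- spliced_sequence(gm$transcript, gm$genome)
  cands <- orf_candidates(gm$transcript, seq, first_exon = cfg$k,
                          domains = gm$domains)
  expect_gte(length(cands), 1)
  first <- cands[[1]]
  expect_equal(first$start_nt, gm$short_start_nt)
  expect_equal(first$start_exon, cfg$k)
  expect_equal(first$protein, gm$short_protein)
  expect_equal(first$delta, gm$delta)
  expect_true("transmembrane" %in% first$domains_lost)
  expect_true("cytoplasmic_tail" %in% first$domains_retained)
  # every candidate ends at the same canonical stop (protein suffix chain)
  for (c in cands)
    expect_true(endsWith(gm$canonical_protein, c$protein))
  # a transcript without CDS refuses the ORF stage
  t2 <- transcript_model("nc", "g", GenomicRanges::granges(gm$transcript$exons))
  expect_error(orf_candidates(t2, seq), "no canonical CDS")
})
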