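test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("AKRPMK")$peptide, c("AK", "RPMK"))
  expect_equal(tryptic_digest("MK")$peptide, "MK")
  expect_setequal(tryptic_digest("AKGR", missed_cleavages = 1)$peptide,
                  c("AK", "GR", "AKGR"))
  expect_error(tryptic_digest("AK", min_len = 5, max_len = 2), "min_len")
  # reported positions are 1-based inclusive spans
  d <- tryptic_digest("AKRPMK")
  expect_equal(d$start, c(1L, 3L))
  expect_equal(d$end, c(2L, 6L))
})

test_that("0-missed-cleavage digests reconstruct the protein", {
  set.seed(404)
  aas <- names(shortiso:::.AA_AVG_MASS)
  for (i in 1:1000) {
    prot <- paste(sample(aas, sample(5:60, 1), replace = TRUE), collapse = "")
    d <- tryptic_digest(prot)
    expect_equal(paste(d$peptide, collapse = ""), prot)
    # spans tile the protein
    expect_equal(d$start, c(1L, utils::head(d$end, -1) + 1L))
  }
})

test_that("peptide mapping computes exact-match coverage", {
  # residues 1-4 and 3-6 of a length-10 protein -> 60%
  prot <- "ACDEFGHIKL"
  cov <- map_peptides(c(substr(prot, 1, 4), substr(prot, 3, 6)), prot)
  expect_equal(cov$coverage_pct, 60)
  expect_equal(cov$covered, 1:6)
  expect_equal(map_peptides(character(0), prot)$coverage_pct, 0)
  expect_equal(map_peptides(prot, prot)$coverage_pct, 100)
  # unmatched peptides are reported, not errors
  cov2 <- map_peptides(c("WWWW", substr(prot, 1, 4)), prot)
  expect_equal(cov2$unmatched, "WWWW")
  expect_equal(cov2$n_peptides_mapped, 1)
})

test_that("coverage is monotone under peptide addition and order-invariant", {
  set.seed(77)
  prot <- paste(sample(names(shortiso:::.AA_AVG_MASS), 80, TRUE), collapse = "")
  peps <- vapply(1:12, function(i) {
    s <- sample(1:70, 1); substr(prot, s, s + sample(4:9, 1))
  }, character(1))
  covs <- vapply(1:12, function(n)
    map_peptides(peps[1:n], prot)$coverage_pct, numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_equal(map_peptides(sample(peps), prot)$coverage_pct,
               covs[12])
})

test_that("I/L-equivalent matching is an explicit switch", {
  prot <- "AAAILAAAK"
  expect_equal(map_peptides("AALL", prot)$n_peptides_mapped, 0)
  expect_equal(map_peptides("AALL", prot, il_equivalent = TRUE)$n_peptides_mapped, 1)
})

test_that("isoform support follows the N-exclusive peptide rule", {
  mk <- function(starts, ends) data.frame(
    peptide = if (length(starts)) paste0("p", seq_along(starts)) else character(0),
    start = starts, end = ends)
  # delta 5: peptides at 6-9 and 10-12 are shared -> short supported
  expect_equal(infer_isoform_support(mk(c(6, 10), c(9, 12)), delta = 5),
               "short_supported")
  # peptide at 2-4 is N-exclusive -> full-length supported
  expect_equal(infer_isoform_support(mk(2, 4), delta = 5),
               "full_length_supported")
  # straddling the offset also requires N-terminal sequence
  expect_equal(infer_isoform_support(mk(4, 9), delta = 5),
               "full_length_supported")
  # empty evidence -> ambiguous; single shared peptide below m_min too
  expect_equal(infer_isoform_support(mk(integer(0), integer(0)), 5), "ambiguous")
  expect_equal(infer_isoform_support(mk(7, 9), delta = 5), "ambiguous")
  # monotone: adding an N-exclusive peptide moves toward full-length support
  expect_equal(infer_isoform_support(mk(c(6, 10, 2), c(9, 12, 4)), delta = 5),
               "full_length_supported")
})

test_that("quantification averages summed XIC areas and tests on log2 scale", {
  obs <- rbind(
    data.frame(sequence = "PEPK", sample = c("c1", "c2", "t1", "t2"),
               condition = c("control", "control", "treated", "treated"),
               auc = c(140, 160, 290, 310)),
    data.frame(sequence = "TIDER", sample = c("c1", "c2", "t1", "t2"),
               condition = c("control", "control", "treated", "treated"),
               auc = c(140, 160, 290, 310)))
  q <- quantify_peptides(obs, c("PEPK", "TIDER"))
  expect_equal(q$fold_change, 2)
  expect_equal(unname(q$group_means["treated"]), 300)
  # identical groups: fold 1, t = 0
  obs2 <- obs; obs2$auc <- 100
  q2 <- quantify_peptides(obs2, c("PEPK", "TIDER"))
  expect_equal(q2$fold_change, 1)
  expect_equal(q2$t_statistic, 0)
  # fragment-ion rows are summed per peptide before averaging
  frag <- data.frame(sequence = "PEPK",
                     sample = rep(c("c1", "c2", "t1", "t2"), each = 2),
                     condition = rep(c("control", "control", "treated", "treated"),
                                     each = 2),
                     auc = c(70, 70, 80, 80, 145, 145, 155, 155))
  expect_equal(quantify_peptides(frag, "PEPK")$fold_change, 2)
})

test_that("degenerate quantification inputs warn instead of failing", {
  one <- data.frame(sequence = "PEPK", sample = c("c1", "t1"),
                    condition = c("control", "treated"), auc = c(100, 200))
  expect_warning(q <- quantify_peptides(one, "PEPK"), "fewer than 2")
  expect_equal(q$fold_change, 2)
  expect_true(is.na(q$p_value))
  zero <- data.frame(sequence = "PEPK",
                     sample = c("c1", "c2", "t1", "t2"),
                     condition = c("control", "control", "treated", "treated"),
                     auc = c(100, 100, 0, 0))
  expect_warning(qz <- quantify_peptides(zero, "PEPK"), "log-scale test skipped")
  expect_equal(qz$fold_change, 0)
  # a peptide missing from one sample is excluded from that sample's mean
  miss <- rbind(
    data.frame(sequence = "PEPK", sample = c("c1", "c2", "t1", "t2"),
               condition = c("control", "control", "treated", "treated"),
               auc = c(100, 100, 200, 200)),
    data.frame(sequence = "TIDER", sample = c("c1", "c2", "t1"),
               condition = c("control", "control", "treated"),
               auc = c(100, 100, 200)))
  expect_warning(qm <- quantify_peptides(miss, c("PEPK", "TIDER")),
                 "unobserved")
  expect_equal(qm$fold_change, 2)
})

test_that("synthetic peptide tables recover the true fold change", {
  cfg <- sim_config(seed = 600)
  gm <- simulate_gene_model(cfg)
  folds <- vapply(1:200, function(i) {
    pep <- simulate_peptides(cfg, gm, seed = 6000 + i)
    suppressWarnings(
      quantify_peptides(pep$observations, pep$unique_peptides)$fold_change)
  }, numeric(1))
  expect_gte(mean(folds >= 1.6 & folds <= 2.4), 0.90)
})

test_that("unique-peptide selection excludes background-proteome matches", {
  prot <- "AAAKCCCKDDDKEEEK"
  # delta 3: first peptide AAAK straddles/precedes the offset
  u <- select_unique_peptides(prot, delta = 3, min_len = 4, max_len = 10)
  expect_false("AAAK" %in% u)
  expect_true(all(c("CCCK", "DDDK", "EEEK") %in% u))
  bg <- Biostrings::AAStringSet("XXXDDDKXXX")
  u2 <- select_unique_peptides(prot, delta = 3, background = bg,
                               min_len = 4, max_len = 10)
  expect_false("DDDK" %in% u2)
  expect_true("CCCK" %in% u2)
})
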