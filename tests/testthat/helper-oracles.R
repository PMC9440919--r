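# Independent oracles and toy-object builders shared across tests.
# Each oracle is coded from the definition, not from the implementation.

# two-exon "+"-strand toy: exon1 100..200, exon2 300..400 (1-based closed)
toy_transcript <- function(strand = "+") {
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 300), c(200, 400)),
                               strand = strand)
  transcript_model("t1", "g1", ex)
}

# random toy transcript with n exons of random widths/gaps, either strand
random_transcript <- function(n_exons = 5, strand = sample(c("+", "-"), 1)) {
  w <- sample(20:120, n_exons, replace = TRUE)
  gap <- sample(50:500, n_exons, replace = TRUE)
  starts <- cumsum(gap + c(0, utils::head(w, -1)))
  ex <- GenomicRanges::GRanges("chrR", IRanges::IRanges(starts, width = w),
                               strand = strand)
  transcript_model(paste0("rt", sample.int(1e6, 1)), "rg", ex)
}

# breakpoint oracle: literal loop over k plus the midpoint boundary walk,
# means computed independently of the implementation's running sums
oracle_breakpoint <- function(profile, tau_on = 1, tau_off = 0.1) {
  y <- log2(profile + 1)
  E <- length(y)
  best_k <- NA; best_s <- -Inf
  for (k in 2:E) {
    s <- mean(y[k:E]) - mean(y[seq_len(k - 1)])
    if (s > best_s + 1e-12) { best_s <- s; best_k <- k }
  }
  tau_mid <- sqrt(tau_on * tau_off)
  k <- best_k
  repeat {
    if (k > 2 && profile[k - 1] >= tau_mid) { k <- k - 1; next }
    break
  }
  repeat {
    if (k < E && profile[k] < tau_mid) { k <- k + 1; next }
    break
  }
  list(k = k, score = mean(y[k:E]) - mean(y[seq_len(k - 1)]))
}

# ORF-start oracle: enumerate every ATG substring ending at cds_stop, keep
# frame-consistent internal-stop-free ones
oracle_inframe_starts <- function(seq, cds_stop, window = c(1, cds_stop - 1)) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- integer(0)
  for (p in seq(window[1], window[2])) {
    if (p + 2 > nchar(seq)) next
    if (substr(seq, p, p + 2) != "ATG") next
    if ((cds_stop - p) %% 3 != 0) next
    clean <- TRUE
    q <- p + 3
    while (q < cds_stop) {
      if (substr(seq, q, q + 2) %in% stops) { clean <- FALSE; break }
      q <- q + 3
    }
    if (clean) hits <- c(hits, p)
  }
  hits
}

# brute-force interval-overlap counting: all read x exon pairs
oracle_count_overlaps <- function(read_starts, read_ends, exon_starts,
                                  exon_ends, min_overlap = 1) {
  vapply(seq_along(exon_starts), function(i) {
    ov <- pmin(read_ends, exon_ends[i]) - pmax(read_starts, exon_starts[i]) + 1
    sum(ov >= min_overlap)
  }, numeric(1))
}

# random DNA with a guaranteed terminal stop codon for ORF-scan fuzzing
random_stop_anchored_seq <- function(max_len = 300) {
  n <- sample(seq(12, max_len), 1)
  n <- n - (n %% 3)
  body <- paste(sample(c("A", "C", "G", "T"), n - 3, replace = TRUE),
                collapse = "")
  stopc <- sample(c("TAA", "TAG", "TGA"), 1)
  list(seq = paste0(body, stopc), cds_stop = n - 2)
}
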