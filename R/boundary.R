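#' @title Truncation-breakpoint calling from exon profiles
#'
#' @description
#' The computational core of short-isoform detection: given a per-exon RPKM
#' profile in which the 5' exons are silent and a 3' block is expressed
#' (the pattern of a transcript restricted to, e.g., exons 23-28), find the
#' first expressed 3' exon by an exhaustive two-block contrast on
#' log2(RPKM + 1) and classify the profile.
#'
#' For each candidate breakpoint k in 2..E the score is
#' `mean(y[k..E]) - mean(y[1..k-1])` with `y = log2(rpkm + 1)`; the k
#' maximizing the score wins (smallest k on ties, favouring the longest
#' short transcript consistent with the data). The block-mean contrast
#' locates the step but is weakly informed about the boundary exon itself:
#' dropping a below-average expressed exon from the 3' block raises the
#' contrast slightly, so a raw argmax tends to trim weak boundary exons.
#' A boundary refinement therefore reassigns boundary exons against the
#' log-scale midpoint of the two expression thresholds,
#' `sqrt(tau_on * tau_off)`: the breakpoint walks left over expressed
#' neighbours and right over silent ones. The profile is classified
#' `short_3prime` when the best score reaches `delta` and the 5'/3' block
#' mean RPKMs fall below `tau_off` / above `tau_on` respectively;
#' `full_length` when every exon reaches `tau_on`; `not_expressed` when
#' every exon is below `tau_off`; otherwise `ambiguous`.
#'
#' @name boundary
NULL

#' Call the truncation breakpoint of one exon profile
#'
#' @param profile Non-negative per-exon RPKM vector, ordered exon 1..E
#'   (E >= 3).
#' @param tau_on Minimum mean RPKM for an "expressed" block (default 1).
#' @param tau_off Maximum mean RPKM for a "silent" block (default 0.1).
#' @param delta Minimum block contrast in log2 units (default 1).
#' @return An `isoform_call`: list with `class` (one of `short_3prime`,
#'   `full_length`, `not_expressed`, `ambiguous`), `breakpoint_k` (NA for
#'   non-short classes), `mean_5prime`, `mean_3prime` (block means on the
#'   log2 scale at the best k), and `score = mean_3prime - mean_5prime`.
#' @export
detect_breakpoint <- function(profile, tau_on = 1, tau_off = 0.1, delta = 1) {
  profile <- as.numeric(profile)
  E <- length(profile)
  if (E < 3) stop("profile must have at least 3 exons")
  if (any(is.na(profile)) || any(profile < 0))
    stop("profile entries must be non-negative and non-missing")
  y <- log2(profile + 1)
  cs <- cumsum(y)
  ks <- 2:E
  m5 <- cs[ks - 1] / (ks - 1)
  m3 <- (cs[E] - cs[ks - 1]) / (E - ks + 1)
  scores <- m3 - m5
  best <- which.max(scores)   # which.max returns the first (smallest k) on ties
  k <- ks[best]
  # boundary refinement at the log-midpoint of the class thresholds
  tau_mid <- sqrt(tau_on * tau_off)
  while (k > 2 && profile[k - 1] >= tau_mid) k <- k - 1
  while (k < E && profile[k] < tau_mid) k <- k + 1
  mean5 <- mean(y[1:(k - 1)])
  mean3 <- mean(y[k:E])
  score <- mean3 - mean5
  rpkm5 <- mean(profile[1:(k - 1)])
  rpkm3 <- mean(profile[k:E])
  cls <-
    if (score >= delta && rpkm5 <= tau_off && rpkm3 >= tau_on) "short_3prime"
    else if (all(profile >= tau_on)) "full_length"
    else if (all(profile < tau_off)) "not_expressed"
    else "ambiguous"
  structure(list(
    class = cls,
    breakpoint_k = if (cls == "short_3prime") as.integer(k) else NA_integer_,
    mean_5prime = mean5, mean_3prime = mean3,
    score = score), class = "isoform_call")
}

#' @export
print.isoform_call <- function(x, ...) {
  cat(sprintf("isoform_call: %s%s (score %.2f; 5' %.2f, 3' %.2f log2 units)\n",
              x$class,
              if (!is.na(x$breakpoint_k)) sprintf(" at exon %d", x$breakpoint_k) else "",
              x$score, x$mean_5prime, x$mean_3prime))
  invisible(x)
}

#' Consensus isoform call across samples of a group
#'
#' The class is decided by strict majority (ties give `ambiguous`); the
#' consensus breakpoint is the median of the per-sample breakpoints among
#' `short_3prime` calls (lower median for even counts, keeping an integer
#' exon index).
#'
#' @param calls List of `isoform_call` objects.
#' @param groups Character vector of group labels, parallel to `calls`.
#' @return Named list (one per group) of consensus calls: list with
#'   `class`, `breakpoint_k`, `n_samples`.
#' @export
consensus_call <- function(calls, groups) {
  stopifnot(length(calls) == length(groups), length(calls) >= 1)
  out <- lapply(split(seq_along(calls), groups), function(idx) {
    if (length(idx) == 0) stop("empty group")
    cls <- vapply(calls[idx], function(c) c$class, character(1))
    tab <- sort(table(cls), decreasing = TRUE)
    cons_cls <- if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous"
                else names(tab)[1]
    ks <- vapply(calls[idx], function(c)
      if (c$class == "short_3prime") as.numeric(c$breakpoint_k) else NA_real_,
      numeric(1))
    ks <- ks[!is.na(ks)]
    k <- if (cons_cls == "short_3prime" && length(ks) > 0)
      as.integer(sort(ks)[ceiling(length(ks) / 2)]) else NA_integer_
    list(class = cons_cls, breakpoint_k = k, n_samples = length(idx))
  })
  out
}

#' Tabulate per-sample isoform calls
#'
#' @param calls Named list of `isoform_call` (names = samples).
#' @return data.frame with one row per sample.
#' @export
calls_table <- function(calls) {
  if (is.null(names(calls))) names(calls) <- paste0("sample", seq_along(calls))
  data.frame(
    sample = names(calls),
    class = vapply(calls, function(c) c$class, character(1)),
    breakpoint_k = vapply(calls, function(c) as.integer(c$breakpoint_k), integer(1)),
    mean_5prime = vapply(calls, function(c) c$mean_5prime, numeric(1)),
    mean_3prime = vapply(calls, function(c) c$mean_3prime, numeric(1)),
    score = vapply(calls, function(c) c$score, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
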