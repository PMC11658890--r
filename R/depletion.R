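# Depletion statistics: normalized frequencies, log2 fold change,
# non-targeting-derived significance threshold, significant-set call.

#' Depth-normalized PAM frequencies
#'
#' `freq(p) = (count(p) + pseudocount) / (matched_reads + pseudocount * 4^L)`.
#' The pseudocount (default 1) keeps fully depleted PAMs at a finite
#' frequency so their log2 fold change is defined.
#'
#' @param table A [pam_count_table()].
#' @param pseudocount Non-negative value added to every count.
#' @return Named numeric vector summing to 1.
#' @export
normalize_frequencies <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "pam_count_table"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (table$matched_reads == 0L) {
    stop("no PAMs extracted: cannot normalize a sample with 0 matched reads")
  }
  n <- length(table$counts)
  (table$counts + pseudocount) / (table$matched_reads + pseudocount * n)
}

#' Per-PAM log2 fold change versus the untreated library
#'
#' @param sample_freq,untreated_freq Named frequency vectors over the same
#'   PAM set (e.g. from [normalize_frequencies()]).
#' @return Named numeric vector `log2(sample / untreated)`.
#' @export
log2_fold_change <- function(sample_freq, untreated_freq) {
  if (!setequal(names(sample_freq), names(untreated_freq))) {
    stop("frequency maps must cover the same PAM set")
  }
  untreated_freq <- untreated_freq[names(sample_freq)]
  if (any(untreated_freq <= 0)) {
    stop("untreated frequencies must be > 0; use a pseudocount > 0 when ",
         "normalizing")
  }
  log2(sample_freq / untreated_freq)
}

#' Depletion-significance threshold from non-targeting controls
#'
#' Pools the non-targeting log2 fold changes as the null for apparent
#' depletion and returns the one-sided lower bound at the given confidence:
#' `mean - qnorm(confidence) * sd` (Gaussian model, the default), or the
#' minimum observed non-targeting value (`method = "empirical"`). A PAM in
#' a targeting sample is called depleted only if it falls below this bound,
#' i.e. depletes further than the non-targeting control plausibly can.
#'
#' @param non_targeting_log2fc A numeric vector, or a list of per-sample
#'   vectors that is pooled.
#' @param confidence Confidence level in (0.5, 1); default 0.999999, the
#'   99.9999 percent level (z approx. 4.7534).
#' @param method `"gaussian"` or `"empirical"`.
#' @return Threshold (scalar log2 fold change, typically negative).
#' @export
depletion_threshold <- function(non_targeting_log2fc,
                                confidence = 0.999999,
                                method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  x <- unlist(non_targeting_log2fc, use.names = FALSE)
  if (length(x) == 0L) stop("need at least one non-targeting sample")
  if (confidence <= 0.5 || confidence >= 1) {
    stop("confidence must lie in (0.5, 1)")
  }
  if (method == "empirical") return(min(x))
  if (length(x) < 2L) {
    stop("need at least 2 pooled non-targeting values to estimate spread")
  }
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) return(m)
  m - stats::qnorm(confidence) * s
}

#' Call significantly depleted PAMs
#'
#' Strictly below the threshold: a log2 fold change exactly at the
#' threshold is not called (so a degenerate all-zero null yields no calls).
#'
#' @param log2fc Named per-PAM log2 fold changes.
#' @param threshold Scalar from [depletion_threshold()].
#' @return Character vector of significant PAMs, sorted lexicographically.
#' @export
call_significant <- function(log2fc, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  sort(names(log2fc)[log2fc < threshold])
}

#' Assemble the per-PAM depletion table
#'
#' @param sample_freq,untreated_freq Frequency vectors.
#' @param threshold Significance threshold.
#' @param confidence Confidence level used to derive it.
#' @return data.frame of class `depletion_table` (columns pam, freq_sample,
#'   freq_untreated, log2fc, significant) with `threshold` and
#'   `confidence` attributes.
#' @export
depletion_table <- function(sample_freq, untreated_freq, threshold,
                            confidence = 0.999999) {
  lfc <- log2_fold_change(sample_freq, untreated_freq)
  sig <- call_significant(lfc, threshold)
  out <- data.frame(pam = names(lfc),
                    freq_sample = unname(sample_freq[names(lfc)]),
                    freq_untreated = unname(untreated_freq[names(lfc)]),
                    log2fc = unname(lfc),
                    significant = names(lfc) %in% sig,
                    row.names = NULL)
  out <- out[order(out$pam), ]
  rownames(out) <- NULL
  structure(out, class = c("depletion_table", "data.frame"),
            threshold = threshold, confidence = confidence)
}
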