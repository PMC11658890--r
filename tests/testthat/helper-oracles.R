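# Independent oracles used across tests.

# Position-by-position scanner: the reference implementation extract_pams
# is checked against. Scans every offset of the read and its reverse
# complement for upstream_anchor + L bases + downstream_anchor.
brute_force_extract <- function(seqs, library) {
  up <- pamkin:::upstream_anchor(library)
  down <- pamkin:::downstream_anchor(library)
  L <- library$randomized_length
  rc1 <- function(s) chartr("ACGTN", "TGCAN",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  scan_one <- function(s) {
    hits <- character(0)
    for (ori in c(s, rc1(s))) {
      n <- nchar(ori)
      span <- nchar(up) + L + nchar(down)
      if (n < span) next
      for (i in seq_len(n - span + 1L)) {
        if (substr(ori, i, i + nchar(up) - 1L) == up &&
            substr(ori, i + nchar(up) + L,
                   i + span - 1L) == down) {
          hits <- c(hits, substr(ori, i + nchar(up),
                                 i + nchar(up) + L - 1L))
        }
      }
    }
    hits
  }
  pams <- all_pams(L)
  counts <- stats::setNames(integer(length(pams)), pams)
  matched <- 0L
  for (s in toupper(seqs)) {
    h <- scan_one(s)
    if (length(h) == 1L && !grepl("[^ACGT]", h)) {
      counts[h] <- counts[h] + 1L
      matched <- matched + 1L
    }
  }
  list(counts = counts, matched = matched, total = length(seqs))
}

# Grid-search oracle for the exponential fit objective.
grid_rss <- function(t, y, y0 = 0, k_range, ymax_range, n = 200L) {
  ks <- seq(k_range[1], k_range[2], length.out = n)
  ys <- seq(ymax_range[1], ymax_range[2], length.out = n)
  best <- Inf
  for (k in ks) {
    pred_base <- 1 - exp(-k * t)
    for (ym in ys) {
      rss <- sum((y - y0 - ym * pred_base)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Small sample sheet for depletion pipelines.
make_samples <- function(n_ntc = 1L) {
  data.frame(
    sample_id = c("untreated", paste0("ntc", seq_len(n_ntc)), "targeting"),
    role = c("untreated", rep("non_targeting", n_ntc), "targeting"))
}
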