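# PAM extraction from amplicon reads.

#' Per-sample PAM counts over the complete PAM space
#'
#' @param sample_id Sample identifier.
#' @param sample_role `untreated`, `non_targeting` or `targeting`.
#' @param counts Named non-negative integer vector keyed by every PAM in
#'   the `4^L` space (zero-filled; missing keys are filled with 0).
#' @param total_reads Reads seen.
#' @param matched_reads Reads with a unique anchored cassette hit; equals
#'   `sum(counts)`.
#' @return Object of class `pam_count_table`.
#' @export
pam_count_table <- function(sample_id, sample_role, counts, total_reads,
                            matched_reads = sum(counts)) {
  sample_role <- match.arg(sample_role,
                           c("untreated", "non_targeting", "targeting"))
  L <- unique(nchar(names(counts)))
  if (length(L) != 1L) stop("count keys must share one length")
  full <- all_pams(L)
  out <- stats::setNames(integer(length(full)), full)
  unknown <- setdiff(names(counts), full)
  if (length(unknown)) stop("non-ACGT count keys: ",
                            paste(utils::head(unknown), collapse = ", "))
  out[names(counts)] <- as.integer(counts)
  if (any(out < 0L)) stop("counts must be non-negative")
  if (sum(out) != matched_reads) stop("counts must sum to matched_reads")
  if (matched_reads > total_reads) stop("matched_reads exceeds total_reads")
  structure(list(sample_id = sample_id, sample_role = sample_role,
                 counts = out, total_reads = as.integer(total_reads),
                 matched_reads = as.integer(matched_reads)),
            class = "pam_count_table")
}

#' @export
print.pam_count_table <- function(x, ...) {
  cat("PAM counts [", x$sample_id, ", ", x$sample_role, "]: ",
      x$matched_reads, "/", x$total_reads, " reads matched over ",
      length(x$counts), " PAMs\n", sep = "")
  invisible(x)
}

read_sequences <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (file.size(reads) == 0L ||
        (grepl("\\.gz$", reads) &&
         length(readLines(gzfile(reads), n = 1L)) == 0L)) {
      return(character(0))
    }
    return(as.character(Biostrings::readDNAStringSet(reads,
                                                     format = "fastq")))
  }
  as.character(reads)
}

#' Extract randomized PAMs from reads
#'
#' Scans each read and its reverse complement for
#' `upstream_anchor N{L} downstream_anchor` with a regular expression. A
#' read contributes one count when the cassette is found exactly once
#' across both orientations and the captured bases are all A/C/G/T; the
#' recorded PAM is in non-target-strand 5' to 3' orientation. Reads with no
#' hit, multiple hits, or ambiguous bases in the cassette count toward
#' `total_reads` only.
#'
#' @param reads FASTQ path (optionally gzipped), a
#'   [Biostrings::DNAStringSet], or a character vector of read sequences.
#' @param library A `pam_library_spec`.
#' @param sample_id,sample_role Metadata for the returned table.
#' @return A [pam_count_table()] zero-filled over the full PAM space; an
#'   empty input gives an empty table with `total_reads` 0.
#' @export
extract_pams <- function(reads, library, sample_id = "sample",
                         sample_role = "untreated") {
  stopifnot(inherits(library, "pam_library_spec"))
  seqs <- toupper(read_sequences(reads))
  L <- library$randomized_length
  pams <- all_pams(L)
  counts <- stats::setNames(integer(length(pams)), pams)
  if (length(seqs) == 0L) {
    return(pam_count_table(sample_id, sample_role, counts, total_reads = 0L))
  }
  pat <- paste0(upstream_anchor(library),
                "([A-Z]{", L, "})",
                downstream_anchor(library))
  hits_f <- gregexpr(pat, seqs, perl = TRUE)
  hits_r <- gregexpr(pat, revcomp(seqs), perl = TRUE)
  n_hit <- function(h) sum(attr(h, "match.length") > 0L & unlist(h) > 0L)
  nf <- vapply(hits_f, n_hit, integer(1))
  nr <- vapply(hits_r, n_hit, integer(1))
  unique_hit <- (nf + nr) == 1L
  tet <- character(sum(unique_hit))
  idx <- which(unique_hit)
  up_len <- nchar(upstream_anchor(library))
  for (j in seq_along(idx)) {
    i <- idx[j]
    s <- if (nf[i] == 1L) seqs[i] else revcomp(seqs[i])
    pos <- if (nf[i] == 1L) hits_f[[i]][1] else hits_r[[i]][1]
    tet[j] <- substr(s, pos + up_len, pos + up_len + L - 1L)
  }
  keep <- !grepl("[^ACGT]", tet)
  tab <- table(tet[keep])
  counts[names(tab)] <- as.integer(tab)
  pam_count_table(sample_id, sample_role, counts,
                  total_reads = length(seqs))
}
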