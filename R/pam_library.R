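# Geometry of the randomized-PAM amplicon library.

#' Describe a randomized-PAM amplicon library
#'
#' The depletion-assay amplicon is a constant fragment carrying a randomized
#' cassette: a fixed 5' flank (ending in the invariant TTTT of the
#' 5'-TTTTNNNN-3' PAM cassette on the non-target strand), `randomized_length`
#' randomized bases, and a fixed 3' flank. PAM extraction anchors on the
#' constant sequence immediately flanking the randomized bases.
#'
#' @param upstream_flank Constant sequence 5' of the randomized bases
#'   (non-target-strand orientation); its 3' end is the upstream anchor.
#' @param downstream_flank Constant sequence 3' of the randomized bases.
#' @param randomized_length Number of randomized positions (default 4,
#'   giving a 256-member PAM space).
#' @param position_labels Labels assigned 5' to 3' across the randomized
#'   positions; defaults to -5, -6, -7, -8 (numbered in the 5' to 3'
#'   direction, descending), so the first randomized base is position -5.
#' @param anchor_length Number of flank bases used as the extraction anchor
#'   on each side (>= 6).
#' @return An object of class `pam_library_spec`.
#' @examples
#' lib <- default_pam_library()
#' nchar(library_fragment(lib, "CAAA"))
#' @export
pam_library_spec <- function(upstream_flank, downstream_flank,
                             randomized_length = 4L,
                             position_labels = c("-5", "-6", "-7", "-8"),
                             anchor_length = 12L) {
  upstream_flank <- toupper(upstream_flank)
  downstream_flank <- toupper(downstream_flank)
  if (!nzchar(upstream_flank) || !nzchar(downstream_flank)) {
    stop("flanks must be non-empty")
  }
  if (grepl("[^ACGT]", upstream_flank) || grepl("[^ACGT]", downstream_flank)) {
    stop("flanks must use only A, C, G, T")
  }
  randomized_length <- as.integer(randomized_length)
  anchor_length <- as.integer(anchor_length)
  if (anchor_length < 6L) stop("anchor_length must be >= 6")
  if (nchar(upstream_flank) < anchor_length ||
      nchar(downstream_flank) < anchor_length) {
    stop("flanks must be at least anchor_length long")
  }
  if (length(position_labels) != randomized_length) {
    stop("need one position label per randomized base")
  }
  spec <- structure(list(
    upstream_flank = upstream_flank,
    downstream_flank = downstream_flank,
    randomized_length = randomized_length,
    position_labels = as.character(position_labels),
    anchor_length = anchor_length
  ), class = "pam_library_spec")
  validate_anchors(spec)
  spec
}

upstream_anchor <- function(spec) {
  substr(spec$upstream_flank,
         nchar(spec$upstream_flank) - spec$anchor_length + 1L,
         nchar(spec$upstream_flank))
}

downstream_anchor <- function(spec) {
  substr(spec$downstream_flank, 1L, spec$anchor_length)
}

# Anchors must locate the cassette unambiguously in every possible fragment
# (forward and reverse-complement): checked at load time, once.
validate_anchors <- function(spec) {
  probe <- strrep("A", spec$randomized_length)  # any tetramer; flanks constant
  frag <- library_fragment(spec, probe)
  for (anch in c(upstream_anchor(spec), downstream_anchor(spec))) {
    n_fwd <- count_fixed(frag, anch)
    n_rev <- count_fixed(revcomp(frag), anch)
    if (n_fwd + n_rev != 1L) {
      stop("anchor '", anch, "' is not unique within the designed fragment")
    }
  }
  invisible(spec)
}

count_fixed <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  sum(hits > 0L)
}

#' The study's default library: 206-bp fragment, 5'-TTTTNNNN-3' cassette
#'
#' A 206-bp amplicon with four randomized PAM positions (-5 to -8) preceded
#' by the fixed TTTT, 20 bp of constant sequence 3' of the cassette and the
#' remaining constant sequence 5' of it.
#'
#' @return A `pam_library_spec`.
#' @export
default_pam_library <- function() {
  pam_library_spec(
    upstream_flank = paste0(
      "GACACGTCATTTTTCAGTCTACAAAGGTGCTGAACAGCCGCTGGTCGTGCTGACACAAAG",
      "TTTTCCGGACGCCGATGCGTTTATCTCGGCCACAAACAATTACTCCTGGAGCACTACCCC",
      "TGTTTGACATGTTATTTCACACTGCCACGACTGAAAAATGGATAGGTCACCGGGAGAA",
      "TTTT"),
    downstream_flank = "TAGTATAGTGGATCCGCGGA"
  )
}

#' Assemble the full amplicon for a given PAM
#'
#' @param spec A `pam_library_spec`.
#' @param pam Sequence for the randomized positions (length
#'   `randomized_length`).
#' @return The fragment as a single string.
#' @export
library_fragment <- function(spec, pam) {
  stopifnot(inherits(spec, "pam_library_spec"))
  if (any(nchar(pam) != spec$randomized_length)) {
    stop("pam must have length ", spec$randomized_length)
  }
  paste0(spec$upstream_flank, toupper(pam), spec$downstream_flank)
}

#' @export
print.pam_library_spec <- function(x, ...) {
  cat("PAM library: ", nchar(x$upstream_flank), " bp | N{",
      x$randomized_length, "} | ", nchar(x$downstream_flank), " bp (",
      nchar(x$upstream_flank) + x$randomized_length +
        nchar(x$downstream_flank), " bp fragment)\n", sep = "")
  cat("positions (5'->3'):", paste(x$position_labels, collapse = " "), "\n")
  invisible(x)
}
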