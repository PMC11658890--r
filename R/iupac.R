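# IUPAC nucleotide ambiguity codes and matching helpers.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC code to the set of bases it denotes
#'
#' @param code Single IUPAC nucleotide letter.
#' @return Character vector of the bases (subset of A, C, G, T).
#' @examples
#' iupac_bases("W")
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  if (!code %in% names(.IUPAC)) {
    stop("not an IUPAC nucleotide code: ", code)
  }
  .IUPAC[[code]]
}

#' Collapse a set of bases to its IUPAC ambiguity code
#'
#' @param bases Character vector over A, C, G, T (order and duplicates
#'   ignored).
#' @return Single IUPAC letter, e.g. `c("A","T")` gives `"W"`.
#' @examples
#' bases_to_iupac(c("A", "T"))
#' @export
bases_to_iupac <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0L || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a non-empty subset of A, C, G, T")
  }
  key <- paste(bases, collapse = "")
  hit <- vapply(.IUPAC, function(b) paste(sort(b), collapse = "") == key,
                logical(1))
  names(.IUPAC)[hit][1]
}

#' Match fixed-length sequences against an IUPAC pattern
#'
#' Exact, position-by-position matching: sequence i matches iff every base
#' is in the set the pattern's code at that position denotes.
#'
#' @param x Character vector of sequences over A, C, G, T.
#' @param pattern IUPAC pattern of the same length as each element of `x`.
#' @return Logical vector along `x`.
#' @examples
#' iupac_match(c("CAAA", "CTAA", "CGAA"), "CWAA")
#' @export
iupac_match <- function(x, pattern) {
  pattern <- toupper(pattern)
  codes <- strsplit(pattern, "")[[1]]
  if (!all(codes %in% names(.IUPAC))) {
    stop("pattern contains non-IUPAC characters: ", pattern)
  }
  cls <- vapply(codes, function(cd) {
    paste0("[", paste(.IUPAC[[cd]], collapse = ""), "]")
  }, character(1))
  grepl(paste0("^", paste(cls, collapse = ""), "$"), toupper(x))
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all DNA k-mers in lexicographic order
#'
#' @param length k-mer length.
#' @return Character vector of `4^length` sequences, sorted.
#' @export
all_pams <- function(length = 4L) {
  stopifnot(length >= 1L)
  grid <- do.call(expand.grid,
                  c(rep(list(c("A", "C", "G", "T")), length),
                    stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic
  sort(apply(grid, 1L, paste, collapse = ""))
}
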