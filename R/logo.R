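# Sequence logo matrix and IUPAC consensus over a set of significant PAMs.

#' Position-wise base frequencies and information content
#'
#' Each position's base frequencies are the (optionally weighted) share of
#' the summarized PAMs carrying that base; information content is
#' `2 + sum_b f_b log2 f_b` bits (`0 log 0 = 0`), i.e. uncorrected Shannon
#' information against a uniform background.
#'
#' @param pams Character vector of equal-length PAM sequences (typically
#'   the significant set). May be empty: an empty `logo_matrix` with
#'   `n_pams = 0` is returned, not an error.
#' @param position_labels Labels for the columns 5' to 3'; default -5..-8.
#' @param weights Optional non-negative per-PAM weights (e.g. depletion
#'   magnitudes); default unweighted.
#' @return data.frame of class `logo_matrix` with columns
#'   `position_label`, `A`, `C`, `G`, `T`, `bits` and attribute `n_pams`.
#' @export
logo_matrix <- function(pams, position_labels = NULL, weights = NULL) {
  if (length(pams) == 0L) {
    out <- data.frame(position_label = character(0), A = numeric(0),
                      C = numeric(0), G = numeric(0), T = numeric(0),
                      bits = numeric(0))
    return(structure(out, class = c("logo_matrix", "data.frame"),
                     n_pams = 0L))
  }
  L <- unique(nchar(pams))
  if (length(L) != 1L) stop("PAMs must share one length")
  if (is.null(position_labels)) {
    position_labels <- as.character(seq(-5, by = -1, length.out = L))
  }
  if (length(position_labels) != L) {
    stop("need one position label per PAM position")
  }
  if (is.null(weights)) weights <- rep(1, length(pams))
  if (length(weights) != length(pams) || any(weights < 0)) {
    stop("weights must be non-negative, one per PAM")
  }
  if (sum(weights) == 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  mat <- do.call(rbind, strsplit(toupper(pams), ""))
  rows <- lapply(seq_len(L), function(j) {
    f <- vapply(c("A", "C", "G", "T"),
                function(b) sum(w[mat[, j] == b]), numeric(1))
    bits <- 2 + sum(ifelse(f > 0, f * log2(f), 0))
    data.frame(position_label = position_labels[j],
               A = f[["A"]], C = f[["C"]], G = f[["G"]], T = f[["T"]],
               bits = bits)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("logo_matrix", "data.frame"),
            n_pams = length(pams))
}

#' IUPAC consensus from a logo matrix
#'
#' Per position, every base whose frequency reaches `inclusion_fraction`
#' joins the ambiguity set, which is collapsed to its IUPAC code; codes are
#' concatenated 5' to 3'. The default 0.25 admits any base at or above the
#' uniform background share.
#'
#' @param logo A [logo_matrix()] with at least one summarized PAM.
#' @param inclusion_fraction Frequency cutoff in (0, 1].
#' @return IUPAC consensus string, e.g. `"CWAA"`.
#' @export
consensus_call <- function(logo, inclusion_fraction = 0.25) {
  stopifnot(inherits(logo, "logo_matrix"))
  if (inclusion_fraction <= 0 || inclusion_fraction > 1) {
    stop("inclusion_fraction must lie in (0, 1]")
  }
  if (attr(logo, "n_pams") == 0L) stop("logo summarizes no PAMs")
  codes <- vapply(seq_len(nrow(logo)), function(j) {
    f <- unlist(logo[j, c("A", "C", "G", "T")])
    keep <- names(f)[f >= inclusion_fraction]
    if (length(keep) == 0L) keep <- names(f)[which.max(f)]
    bases_to_iupac(keep)
  }, character(1))
  paste(codes, collapse = "")
}
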