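# Cleavage recognition model over the randomized PAM space.
#
# The depletion assay's premise: a PAM the nuclease recognizes is cleaved
# and drops out of the amplified library. The model maps each PAM to a
# cleavage probability via an ordered rule list (first match wins).

#' Define a PAM recognition model
#'
#' @param rules List of `list(pattern =, probability =)` entries (or a
#'   data.frame with those columns). Patterns are IUPAC strings over the
#'   randomized positions; rules are evaluated in order and the first match
#'   wins.
#' @param default_probability Cleavage probability for PAMs matching no
#'   rule.
#' @param randomized_length Expected pattern length (default 4).
#' @return An object of class `recognition_model`.
#' @examples
#' m <- recognition_model(list(list(pattern = "CWAA", probability = 1)))
#' cleavage_probability(m, c("CAAA", "CTAA", "GGGG"))
#' @export
recognition_model <- function(rules = list(), default_probability = 0,
                              randomized_length = 4L) {
  if (is.data.frame(rules)) {
    rules <- lapply(seq_len(nrow(rules)), function(i) {
      list(pattern = rules$pattern[i], probability = rules$probability[i])
    })
  }
  for (r in rules) {
    if (is.null(r$pattern) || is.null(r$probability)) {
      stop("each rule needs a pattern and a probability")
    }
    if (nchar(r$pattern) != randomized_length) {
      stop("rule pattern '", r$pattern, "' must have length ",
           randomized_length)
    }
    if (!all(strsplit(toupper(r$pattern), "")[[1]] %in% names(.IUPAC))) {
      stop("rule pattern '", r$pattern, "' uses non-IUPAC characters")
    }
    if (r$probability < 0 || r$probability > 1) {
      stop("cleavage probabilities must lie in [0, 1]")
    }
  }
  if (default_probability < 0 || default_probability > 1) {
    stop("default_probability must lie in [0, 1]")
  }
  structure(list(rules = rules,
                 default_probability = default_probability,
                 randomized_length = as.integer(randomized_length)),
            class = "recognition_model")
}

#' Cleavage probability of each PAM under a recognition model
#'
#' Ordered-rule semantics: the first rule whose IUPAC pattern matches a PAM
#' assigns its probability; unmatched PAMs get the model default.
#'
#' @param model A `recognition_model`.
#' @param pams Character vector of PAM sequences.
#' @return Numeric vector of probabilities in `[0, 1]`, named by PAM.
#' @export
cleavage_probability <- function(model, pams) {
  stopifnot(inherits(model, "recognition_model"))
  p <- rep(model$default_probability, length(pams))
  assigned <- rep(FALSE, length(pams))
  for (r in model$rules) {
    hit <- !assigned & iupac_match(pams, r$pattern)
    p[hit] <- r$probability
    assigned <- assigned | hit
  }
  names(p) <- pams
  p
}

#' @export
print.recognition_model <- function(x, ...) {
  cat("PAM recognition model:", length(x$rules), "rule(s), default p =",
      x$default_probability, "\n")
  for (r in x$rules) {
    cat("  ", r$pattern, "-> p =", r$probability, "\n")
  }
  invisible(x)
}
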