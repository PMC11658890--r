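# Single-exponential kinetics: cleavage fractions and 2AP fluorescence.
#
# Cleavage model:  Y = Ymax (1 - exp(-k t)),         0 <= Ymax <= 1
# 2AP model:       Y = Y0 + Ymax (1 - exp(-k t)),    Y0 fixed to the blank
# nd rule: the rate is "not determined" when the fitted amplitude falls at
# or below the assay floor (0.05 cleaved fraction; 100 AU fluorescence).

ND_YMAX_CLEAVAGE <- 0.05
ND_YMAX_2AP <- 100

#' Fraction of substrate cleaved from band densities
#'
#' @param cleaved_density,uncleaved_density Non-negative gel densitometry
#'   values for the cleaved and uncleaved target-strand bands.
#' @return `cleaved / (cleaved + uncleaved)`, in `[0, 1]`.
#' @export
fraction_cleaved <- function(cleaved_density, uncleaved_density) {
  if (any(cleaved_density < 0) || any(uncleaved_density < 0)) {
    stop("densities must be non-negative")
  }
  tot <- cleaved_density + uncleaved_density
  if (any(tot == 0)) stop("empty lane: both densities are 0")
  cleaved_density / tot
}

new_exp_fit <- function(model, k_obs, ymax, y0, nd, rss, n_points,
                        converged = TRUE, message = NULL) {
  structure(list(model = model, k_obs = k_obs, ymax = ymax, y0 = y0,
                 nd = nd, rss = rss, n_points = n_points,
                 converged = converged, message = message),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  k <- if (x$nd) "nd" else signif(x$k_obs, 3)
  cat("exponential fit (", x$model, "): k_obs = ", k,
      ", Ymax = ", signif(x$ymax, 4),
      if (!is.null(x$y0)) paste0(", Y0 = ", signif(x$y0, 4)) else "",
      ", rss = ", signif(x$rss, 3), ", n = ", x$n_points, "\n", sep = "")
  invisible(x)
}

# core bounded NLS with multi-start restarts on non-convergence
fit_exponential <- function(t, y, y0 = 0, ymax_upper = Inf) {
  n <- length(t)
  yr <- y - y0
  ymax0 <- min(max(max(yr), 1e-6), ymax_upper)
  # first crossing of half the apparent amplitude sets the rate guess
  half <- which(yr >= ymax0 / 2 & t > 0)
  k0 <- if (length(half)) 1 / t[half[1]] else
    1 / max(stats::median(t[t > 0]), .Machine$double.eps)
  starts <- unique(c(k0, 10^seq(-3, 2, length.out = 5) * k0))
  best <- NULL
  for (ks in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yr ~ ymax * (1 - exp(-k * t)),
        start = list(ymax = ymax0, k = ks),
        lower = c(ymax = 0, k = 1e-9),
        upper = c(ymax = ymax_upper, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(ymax = unname(cf["ymax"]), k = unname(cf["k"]),
                   rss = rss)
    }
    if (!is.null(best) && ks == starts[1]) break  # first start converged
  }
  if (is.null(best)) {
    return(list(ymax = max(yr), k = NA_real_, rss = sum((yr - max(yr))^2),
                converged = FALSE,
                message = "nonlinear least squares did not converge"))
  }
  c(best, converged = TRUE, message = list(NULL))
}

pooled_points <- function(course) {
  obs <- as.data.frame(course)
  obs[order(obs$replicate, obs$time), ]
}

check_course <- function(course, assay) {
  stopifnot(inherits(course, "time_course"))
  if (attr(course, "assay") != assay) {
    stop("expected a ", assay, " time course")
  }
  if (length(unique(course$time)) < 3L) {
    stop("need at least 3 distinct time points to fit")
  }
}

#' Fit the cleavage model Y = Ymax (1 - exp(-k t))
#'
#' Nonlinear least squares with `0 <= Ymax <= 1`, `k > 0`, fitted to all
#' replicate points pooled (default) or per replicate. A fit with
#' `Ymax <= 0.05` is flagged `nd` (rate not determined); non-convergence
#' after multi-start restarts is returned as an `nd` result with a
#' diagnostic, never an error.
#'
#' @param course A `time_course` with assay `cleavage_fraction`.
#' @param mode `"pooled"` (one fit over all replicates) or
#'   `"per_replicate"` (a list of fits, see [aggregate_replicates()]).
#' @return An `exp_fit` (or list of them for `"per_replicate"`).
#' @export
fit_cleavage <- function(course, mode = c("pooled", "per_replicate")) {
  mode <- match.arg(mode)
  check_course(course, "cleavage_fraction")
  if (mode == "per_replicate") {
    reps <- split(as.data.frame(course), course$replicate)
    return(lapply(reps, function(d) {
      fit_cleavage(time_course(d, time_unit = attr(course, "time_unit"),
                               assay = "cleavage_fraction",
                               condition = attr(course, "condition")))
    }))
  }
  obs <- pooled_points(course)
  f <- fit_exponential(obs$time, obs$value, y0 = 0, ymax_upper = 1)
  nd <- !isTRUE(f$converged) || f$ymax <= ND_YMAX_CLEAVAGE
  new_exp_fit("cleavage", k_obs = f$k, ymax = f$ymax, y0 = NULL, nd = nd,
              rss = f$rss, n_points = nrow(obs),
              converged = isTRUE(f$converged), message = f$message)
}

#' Fit the 2AP model Y = Y0 + Ymax (1 - exp(-k t)) with Y0 fixed
#'
#' `Y0` is fixed to the mean of the matched blank trace; `Ymax >= 0` and
#' `k > 0` are fitted per replicate (default, each replicate yielding one
#' rate to average) or pooled. A fit with `Ymax <= 100` AU is flagged `nd`.
#'
#' @param course A `time_course` with assay `fluorescence_AU`.
#' @param blank_mean Baseline (AU); defaults to the course's `blank_mean`
#'   attribute. Required.
#' @param mode `"per_replicate"` (default) or `"pooled"`.
#' @return List of `exp_fit` (or a single `exp_fit` for `"pooled"`).
#' @export
fit_2ap <- function(course, blank_mean = NULL,
                    mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  check_course(course, "fluorescence_AU")
  if (is.null(blank_mean)) blank_mean <- attr(course, "blank_mean")
  if (is.null(blank_mean)) {
    stop("blank_mean is required: supply the matched blank trace average")
  }
  fit_one <- function(obs) {
    f <- fit_exponential(obs$time, obs$value, y0 = blank_mean,
                         ymax_upper = Inf)
    nd <- !isTRUE(f$converged) || f$ymax <= ND_YMAX_2AP
    new_exp_fit("two_ap", k_obs = f$k, ymax = f$ymax, y0 = blank_mean,
                nd = nd, rss = f$rss, n_points = nrow(obs),
                converged = isTRUE(f$converged), message = f$message)
  }
  if (mode == "pooled") return(fit_one(pooled_points(course)))
  lapply(split(as.data.frame(course), course$replicate), fit_one)
}

#' Average replicate rate constants
#'
#' Mean and sample standard deviation (n - 1 denominator) of `k_obs` over
#' the non-nd replicate fits; the reported rate is mean +/- SD. If any
#' replicate is nd the aggregate is annotated; if all are, the aggregate
#' itself is nd.
#'
#' @param fits List of `exp_fit` objects (one per replicate).
#' @return List with `mean_k`, `sd_k`, `n` (replicates used), `nd`,
#'   `any_nd`, of class `k_aggregate`.
#' @export
aggregate_replicates <- function(fits) {
  if (inherits(fits, "exp_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "exp_fit")))
  nd <- vapply(fits, function(f) isTRUE(f$nd), logical(1))
  ks <- vapply(fits[!nd], function(f) f$k_obs, numeric(1))
  if (length(ks) == 0L) {
    return(structure(list(mean_k = NA_real_, sd_k = NA_real_, n = 0L,
                          nd = TRUE, any_nd = TRUE),
                     class = "k_aggregate"))
  }
  structure(list(mean_k = mean(ks),
                 sd_k = if (length(ks) > 1L) stats::sd(ks) else NA_real_,
                 n = length(ks), nd = FALSE, any_nd = any(nd)),
            class = "k_aggregate")
}

#' @export
print.k_aggregate <- function(x, ...) {
  if (x$nd) cat("k_obs: nd (all replicates below the amplitude floor)\n")
  else cat("k_obs =", signif(x$mean_k, 3), "+/-",
           signif(x$sd_k, 3), "(n =", x$n,
           if (x$any_nd) ", some replicates nd)" else ")", "\n")
  invisible(x)
}

#' Fold change between two fitted rate constants
#'
#' @param numerator,denominator `exp_fit`, `k_aggregate`, or a bare rate.
#' @return `k(numerator) / k(denominator)`.
#' @export
fold_change <- function(numerator, denominator) {
  get_k <- function(x) {
    if (inherits(x, "exp_fit")) {
      if (isTRUE(x$nd)) stop("fold change undefined for nd")
      return(x$k_obs)
    }
    if (inherits(x, "k_aggregate")) {
      if (isTRUE(x$nd)) stop("fold change undefined for nd")
      return(x$mean_k)
    }
    if (is.numeric(x) && length(x) == 1L) return(x)
    stop("cannot take a rate from this object")
  }
  get_k(numerator) / get_k(denominator)
}
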