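# Time-course container shared by the cleavage and 2AP assays.

#' Construct a kinetic time course
#'
#' @param observations data.frame with columns `replicate`, `time`, `value`.
#' @param time_unit `"minute"` (cleavage) or `"second"` (2AP).
#' @param assay `"cleavage_fraction"` or `"fluorescence_AU"`.
#' @param condition Free-text metadata (enzyme, substrate/PAM, MgCl2 in mM).
#' @param blank_mean Mean of the matched blank trace (AU); required before
#'   fitting the fluorescence model.
#' @return data.frame of class `time_course` with metadata attributes.
#' @export
time_course <- function(observations, time_unit = c("minute", "second"),
                        assay = c("cleavage_fraction", "fluorescence_AU"),
                        condition = "", blank_mean = NULL) {
  time_unit <- match.arg(time_unit)
  assay <- match.arg(assay)
  obs <- as.data.frame(observations)
  if (!all(c("replicate", "time", "value") %in% names(obs))) {
    stop("observations need columns replicate, time, value")
  }
  if (nrow(obs) == 0L) stop("empty time course")
  if (any(obs$time < 0)) stop("times must be non-negative")
  for (r in unique(obs$replicate)) {
    tt <- obs$time[obs$replicate == r]
    if (any(diff(tt) <= 0)) {
      stop("times must be strictly increasing within replicate ", r)
    }
  }
  if (assay == "cleavage_fraction" &&
      (any(obs$value < 0) || any(obs$value > 1))) {
    stop("cleavage fractions must lie in [0, 1]")
  }
  structure(obs[, c("replicate", "time", "value")],
            class = c("time_course", "data.frame"),
            time_unit = time_unit, assay = assay, condition = condition,
            blank_mean = blank_mean)
}

#' Convert a time course between minutes and seconds
#'
#' Rescales the time axis; a fitted rate constant transforms inversely
#' (minute -> second divides k by 60).
#'
#' @param course A `time_course`.
#' @param to Target unit.
#' @return The converted `time_course`.
#' @export
convert_time_unit <- function(course, to = c("minute", "second")) {
  to <- match.arg(to)
  from <- attr(course, "time_unit")
  if (from == to) return(course)
  f <- if (from == "minute") 60 else 1 / 60
  obs <- as.data.frame(course)
  obs$time <- obs$time * f
  time_course(obs, time_unit = to, assay = attr(course, "assay"),
              condition = attr(course, "condition"),
              blank_mean = attr(course, "blank_mean"))
}

#' Simulate a cleavage-fraction time course
#'
#' Generates `ymax * (1 - exp(-k t))` plus Gaussian noise, clipped to
#' `[0, 1]`; with `noise_sd = 0` the emitted values satisfy the generating
#' equation exactly.
#'
#' @param k Rate constant (per minute), > 0.
#' @param ymax Reaction endpoint (fraction cleaved), in `[0, 1]`.
#' @param times Sampling times in minutes; defaults to the assay schedule
#'   0, 0.5, 1, 2.5, 5, 10, 30, 60, 120 min.
#' @param noise_sd Gaussian noise SD (fraction units), >= 0.
#' @param n_replicates Replicates drawn (default 1).
#' @param seed Optional seed.
#' @param condition Metadata string.
#' @return A `time_course` with assay `cleavage_fraction`.
#' @export
simulate_cleavage_timecourse <- function(k, ymax,
                                         times = c(0, 0.5, 1, 2.5, 5, 10,
                                                   30, 60, 120),
                                         noise_sd = 0, n_replicates = 1L,
                                         seed = NULL, condition = "") {
  if (k <= 0) stop("k must be > 0")
  if (ymax < 0 || ymax > 1) stop("ymax must lie in [0, 1]")
  if (length(times) == 0L) stop("times must be non-empty")
  if (any(times < 0)) stop("times must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    obs <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      y <- ymax * (1 - exp(-k * times))
      if (noise_sd > 0) {
        y <- pmin(pmax(y + stats::rnorm(length(times), 0, noise_sd), 0), 1)
      }
      data.frame(replicate = r, time = times, value = y)
    }))
    time_course(obs, time_unit = "minute", assay = "cleavage_fraction",
                condition = condition)
  })
}

#' Simulate a 2-aminopurine fluorescence trace with its blank
#'
#' Fluorescence `y0 + ymax * (1 - exp(-k t))` plus noise, sampled on a
#' fixed grid (default every 20 s, the assay's recording interval); the
#' matched blank is `y0` plus noise on the same grid.
#'
#' @param k Rate constant (per second), > 0.
#' @param ymax Fitted-endpoint amplitude (AU), >= 0.
#' @param y0 Baseline fluorescence (AU; the blank level).
#' @param interval Sampling interval in seconds (> 0; default 20).
#' @param duration Trace length in seconds (>= interval).
#' @param noise_sd Gaussian noise SD (AU), >= 0.
#' @param n_replicates Replicates drawn (default 1).
#' @param seed Optional seed.
#' @param condition Metadata string.
#' @return List with `trace` (a `time_course`, `blank_mean` attribute set
#'   from the blank) and `blank` (a `time_course` of the blank).
#' @export
simulate_2ap_trace <- function(k, ymax, y0, interval = 20, duration = 300,
                               noise_sd = 0, n_replicates = 1L, seed = NULL,
                               condition = "") {
  if (k <= 0) stop("k must be > 0")
  if (ymax < 0) stop("ymax must be >= 0")
  if (interval <= 0) stop("interval must be > 0")
  if (duration < interval) stop("duration must be >= interval")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  times <- seq(0, duration, by = interval)
  with_seed(seed, {
    sim_rep <- function(base) {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        y <- base(times)
        if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
        data.frame(replicate = r, time = times, value = y)
      }))
    }
    trace_obs <- sim_rep(function(t) y0 + ymax * (1 - exp(-k * t)))
    blank_obs <- sim_rep(function(t) rep(y0, length(t)))
    blank <- time_course(blank_obs, time_unit = "second",
                         assay = "fluorescence_AU",
                         condition = paste(condition, "blank"))
    trace <- time_course(trace_obs, time_unit = "second",
                         assay = "fluorescence_AU", condition = condition,
                         blank_mean = mean(blank_obs$value))
    list(trace = trace, blank = blank)
  })
}
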