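# End-to-end runs: PAM depletion track and kinetics track.
#
# Each run writes its resolved parameters, input checksums and per-stage
# record counts to a log, all tables as TSV, and a machine-readable JSON
# report, so a run directory is self-describing and reproducible.

write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

run_log <- function(path, params, inputs = character(0), lines = character(0)) {
  hdr <- c(paste0("pamkin version: ",
                  as.character(utils::packageVersion("pamkin"))),
           paste0(names(params), " = ",
                  vapply(params, function(p) paste(format(p), collapse = ","),
                         character(1))))
  sums <- if (length(inputs)) {
    paste0("md5 ", names(inputs), " = ", tools::md5sum(unname(inputs)))
  } else character(0)
  writeLines(c(hdr, sums, lines), path)
  path
}

#' Run the full PAM depletion analysis
#'
#' Executes extract -> normalize -> log2 fold change -> non-targeting
#' threshold -> significant set -> logo -> IUPAC consensus for every
#' targeting sample in the manifest, writing per-sample count tables, the
#' depletion table, the logo matrix, a run log and a JSON report.
#'
#' @param manifest data.frame (or TSV path) with columns `sample_id`,
#'   `role` (`untreated` / `non_targeting` / `targeting`) and `path`
#'   (FASTQ). At least one sample of each role is required. Multiple
#'   untreated samples are pooled into one reference.
#' @param output_dir Run directory (created).
#' @param library A `pam_library_spec`.
#' @param confidence Confidence for the depletion threshold (default
#'   0.999999).
#' @param pseudocount Pseudocount for frequency normalization (default 1).
#' @param inclusion_fraction Consensus inclusion cutoff (default 0.25).
#' @param threshold_method `"gaussian"` or `"empirical"` (see
#'   [depletion_threshold()]).
#' @param weight_by_depletion Weight logo frequencies by depletion
#'   magnitude (-log2fc) instead of uniformly.
#' @return The report, invisibly: per targeting sample the significant-PAM
#'   count and consensus, plus the threshold and file paths.
#' @export
run_pam_pipeline <- function(manifest, output_dir,
                             library = default_pam_library(),
                             confidence = 0.999999, pseudocount = 1,
                             inclusion_fraction = 0.25,
                             threshold_method = c("gaussian", "empirical"),
                             weight_by_depletion = FALSE) {
  threshold_method <- match.arg(threshold_method)
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  manifest <- as.data.frame(manifest)
  need <- c("untreated", "non_targeting", "targeting")
  missing_roles <- setdiff(need, manifest$role)
  if (length(missing_roles)) {
    stop("manifest is missing required role(s): ",
         paste(missing_roles, collapse = ", "))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  tabs <- lapply(seq_len(nrow(manifest)), function(i) {
    extract_pams(manifest$path[i], library,
                 sample_id = manifest$sample_id[i],
                 sample_role = manifest$role[i])
  })
  names(tabs) <- manifest$sample_id
  count_files <- vapply(tabs, function(tb) {
    write_tsv(data.frame(pam = names(tb$counts), count = unname(tb$counts)),
              file.path(output_dir, paste0("counts_", tb$sample_id, ".tsv")))
  }, character(1))

  # pooled untreated reference
  untr <- tabs[manifest$role == "untreated"]
  ref_counts <- Reduce(`+`, lapply(untr, `[[`, "counts"))
  ref_tab <- pam_count_table("untreated_pooled", "untreated", ref_counts,
                             total_reads = sum(vapply(untr, `[[`,
                                                      integer(1),
                                                      "total_reads")))
  ref_freq <- normalize_frequencies(ref_tab, pseudocount)

  ntc_lfc <- lapply(tabs[manifest$role == "non_targeting"], function(tb) {
    log2_fold_change(normalize_frequencies(tb, pseudocount), ref_freq)
  })
  threshold <- depletion_threshold(ntc_lfc, confidence = confidence,
                                   method = threshold_method)

  report <- list(parameters = list(confidence = confidence,
                                   pseudocount = pseudocount,
                                   inclusion_fraction = inclusion_fraction,
                                   threshold_method = threshold_method,
                                   weight_by_depletion = weight_by_depletion),
                 threshold = threshold, samples = list(),
                 files = as.list(count_files))
  log_lines <- character(0)
  for (tb in tabs[manifest$role == "targeting"]) {
    freq <- normalize_frequencies(tb, pseudocount)
    dep <- depletion_table(freq, ref_freq, threshold, confidence)
    sig <- dep$pam[dep$significant]
    weights <- if (weight_by_depletion && length(sig)) {
      -dep$log2fc[dep$significant]
    } else NULL
    logo <- logo_matrix(sig, position_labels = library$position_labels,
                        weights = weights)
    consensus <- if (length(sig)) {
      consensus_call(logo, inclusion_fraction)
    } else "no significant PAMs"
    dep_file <- write_tsv(dep, file.path(output_dir,
                                         paste0("depletion_",
                                                tb$sample_id, ".tsv")))
    logo_file <- write_tsv(logo, file.path(output_dir,
                                           paste0("logo_",
                                                  tb$sample_id, ".tsv")))
    report$samples[[tb$sample_id]] <-
      list(n_significant = length(sig), consensus = consensus,
           significant = sig, depletion_file = dep_file,
           logo_file = logo_file)
    log_lines <- c(log_lines,
                   sprintf("%s: %d/%d reads matched, %d significant, %s",
                           tb$sample_id, tb$matched_reads, tb$total_reads,
                           length(sig), consensus))
  }
  report_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  run_log(file.path(output_dir, "run.log"),
          params = report$parameters,
          inputs = stats::setNames(manifest$path, manifest$sample_id),
          lines = c(sprintf("threshold = %.6f", threshold), log_lines))
  invisible(report)
}

#' Run the kinetics analysis over a long-format table
#'
#' Fits the single-exponential model per condition, aggregates replicate
#' rates, evaluates requested fold changes, and writes a TSV summary plus
#' JSON report.
#'
#' @param data data.frame (or TSV path) with columns `condition`,
#'   `replicate`, `time`, `value` and, for the fluorescence model, `blank`
#'   (the per-condition blank mean, constant within a condition).
#' @param output_dir Run directory (created).
#' @param model `"cleavage"` or `"two_ap"`.
#' @param time_unit `"minute"` or `"second"`.
#' @param mode Fit mode passed to the fitter; defaults to pooled for
#'   cleavage and per-replicate for 2AP.
#' @param fold_requests List of `c(numerator_condition,
#'   denominator_condition)` pairs.
#' @return The report, invisibly: per condition `k_obs` (or `"nd"`),
#'   `ymax`, aggregate mean +/- SD, and any fold changes.
#' @export
run_kinetics_pipeline <- function(data, output_dir,
                                  model = c("cleavage", "two_ap"),
                                  time_unit = c("minute", "second"),
                                  mode = NULL, fold_requests = list()) {
  model <- match.arg(model)
  time_unit <- match.arg(time_unit)
  input_path <- NULL
  if (is.character(data) && length(data) == 1L) {
    input_path <- data
    data <- utils::read.delim(data, stringsAsFactors = FALSE)
  }
  data <- as.data.frame(data)
  if (!all(c("condition", "replicate", "time", "value") %in% names(data))) {
    stop("need columns condition, replicate, time, value")
  }
  if (is.null(mode)) {
    mode <- if (model == "cleavage") "pooled" else "per_replicate"
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  assay <- if (model == "cleavage") "cleavage_fraction" else "fluorescence_AU"

  conditions <- unique(data$condition)
  results <- list()
  rows <- list()
  for (cond in conditions) {
    d <- data[data$condition == cond, ]
    blank <- if ("blank" %in% names(d)) unique(d$blank)[1] else NULL
    course <- time_course(d, time_unit = time_unit, assay = assay,
                          condition = cond, blank_mean = blank)
    fits <- if (model == "cleavage") {
      fit_cleavage(course, mode = mode)
    } else {
      fit_2ap(course, mode = mode)
    }
    if (inherits(fits, "exp_fit")) fits <- list(fits)
    agg <- aggregate_replicates(fits)
    results[[cond]] <- list(
      fits = lapply(fits, function(f) {
        list(k_obs = if (f$nd) "nd" else f$k_obs, ymax = f$ymax,
             y0 = f$y0, nd = f$nd, rss = f$rss, n_points = f$n_points)
      }),
      mean_k = if (agg$nd) "nd" else agg$mean_k,
      sd_k = agg$sd_k, n = agg$n, nd = agg$nd, any_nd = agg$any_nd)
    rows[[cond]] <- data.frame(
      condition = cond,
      k_obs = if (agg$nd) NA_real_ else agg$mean_k,
      sd_k = agg$sd_k, n = agg$n, nd = agg$nd,
      ymax = mean(vapply(fits, `[[`, numeric(1), "ymax")))
  }
  report <- list(model = model, time_unit = time_unit, mode = mode,
                 conditions = results)
  if (length(fold_requests)) {
    folds <- list()
    for (fr in fold_requests) {
      if (!all(fr %in% conditions)) {
        stop("unknown condition in fold-change request: ",
             paste(setdiff(fr, conditions), collapse = ", "))
      }
      a <- results[[fr[1]]]; b <- results[[fr[2]]]
      if (identical(a$mean_k, "nd") || identical(b$mean_k, "nd")) {
        stop("fold change undefined for nd")
      }
      folds[[paste(fr[1], "vs", fr[2])]] <- a$mean_k / b$mean_k
    }
    report$fold_changes <- folds
  }
  summary_path <- write_tsv(do.call(rbind, rows),
                            file.path(output_dir, "fit_summary.tsv"))
  report_path <- file.path(output_dir, "fit_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  run_log(file.path(output_dir, "run.log"),
          params = list(model = model, time_unit = time_unit, mode = mode),
          inputs = if (is.null(input_path)) character(0) else
            c(input = input_path),
          lines = sprintf("%s: %d points", conditions,
                          vapply(conditions, function(cc)
                            sum(data$condition == cc), integer(1))))
  invisible(report)
}
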