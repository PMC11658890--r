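# Synthetic randomized-PAM depletion experiment.
#
# Sampling model: the untreated library is uniform over the 4^L PAM space.
# Treatment with a targeting RNP removes each PAM with its cleavage
# probability, so the surviving (amplified, sequenced) pool is multinomial
# with weight 1 - p(cleave) per PAM, renormalized. Untreated and
# non-targeting samples keep weight 1 for every PAM. PCR amplification of
# the survivors is collapsed into this one multinomial draw.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Plan a simulated PAM depletion experiment
#'
#' @param library A `pam_library_spec`.
#' @param model A `recognition_model` applied to targeting samples only.
#' @param reads_per_sample Reads drawn per sample (> 0).
#' @param samples data.frame with columns `sample_id` and `role`; roles are
#'   `untreated`, `non_targeting` or `targeting`.
#' @param seed Integer seed; a fixed seed reproduces byte-identical output.
#' @param revcomp_fraction Fraction of reads emitted reverse-complemented
#'   (exercises orientation handling; default 0).
#' @param error_rate Uniform per-base substitution probability (default 0).
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(library, model, reads_per_sample, samples,
                            seed = 1L, revcomp_fraction = 0,
                            error_rate = 0) {
  stopifnot(inherits(library, "pam_library_spec"),
            inherits(model, "recognition_model"))
  if (model$randomized_length != library$randomized_length) {
    stop("model and library randomized lengths differ")
  }
  reads_per_sample <- as.integer(reads_per_sample)
  if (is.na(reads_per_sample) || reads_per_sample <= 0L) {
    stop("reads_per_sample must be a positive integer")
  }
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "role") %in% names(samples))) {
    stop("samples needs columns sample_id and role")
  }
  bad <- setdiff(samples$role, c("untreated", "non_targeting", "targeting"))
  if (length(bad)) stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (revcomp_fraction < 0 || revcomp_fraction > 1) {
    stop("revcomp_fraction must lie in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  structure(list(library = library, model = model,
                 reads_per_sample = reads_per_sample, samples = samples,
                 seed = as.integer(seed),
                 revcomp_fraction = revcomp_fraction,
                 error_rate = error_rate),
            class = "simulation_plan")
}

# survival weights over the full PAM space for one sample role
survival_weights <- function(plan, role) {
  pams <- all_pams(plan$library$randomized_length)
  if (role == "targeting") {
    w <- 1 - cleavage_probability(plan$model, pams)
  } else {
    w <- stats::setNames(rep(1, length(pams)), pams)
  }
  if (sum(w) <= 0) stop("library fully depleted: all survival weights zero")
  w
}

#' Draw per-sample PAM counts for a simulated depletion experiment
#'
#' The count-level core of the simulator: one multinomial draw per sample
#' over the full PAM space with the role's survival weights. The FASTQ
#' writer [simulate_pam_library_reads()] materializes reads from exactly
#' these counts.
#'
#' @param plan A `simulation_plan`.
#' @return List with `counts` (list of [pam_count_table()] per sample) and
#'   `ground_truth` (data.frame: sample_id, pam, true_weight,
#'   expected_count, count).
#' @export
simulate_pam_library_counts <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  with_seed(plan$seed, {
    pams <- all_pams(plan$library$randomized_length)
    tabs <- list()
    gt <- list()
    for (i in seq_len(nrow(plan$samples))) {
      id <- plan$samples$sample_id[i]
      role <- plan$samples$role[i]
      w <- survival_weights(plan, role)
      prob <- w / sum(w)
      counts <- as.integer(stats::rmultinom(1L, plan$reads_per_sample, prob))
      names(counts) <- pams
      tabs[[id]] <- pam_count_table(id, role, counts,
                                    total_reads = plan$reads_per_sample,
                                    matched_reads = plan$reads_per_sample)
      gt[[id]] <- data.frame(sample_id = id, pam = pams,
                             true_weight = unname(w),
                             expected_count = unname(prob) *
                               plan$reads_per_sample,
                             count = counts, row.names = NULL)
    }
    list(counts = tabs, ground_truth = do.call(rbind, gt))
  })
}

#' Simulate FASTQ reads from a randomized-PAM depletion experiment
#'
#' Writes one single-end FASTQ per sample: each read is the full library
#' fragment with its randomized cassette drawn from the post-cleavage PAM
#' distribution. Quality is constant ('I', Q40). A ground-truth TSV
#' (sample, PAM, survival weight, expected and realized count) is written
#' alongside, plus a plain key-value config recording the plan.
#'
#' @param plan A `simulation_plan`.
#' @param output_dir Directory for FASTQ and ground-truth files.
#' @param gzip Write `.fastq.gz` instead of `.fastq`.
#' @return Invisibly, a list with `files` (named FASTQ paths),
#'   `ground_truth` (data.frame and its TSV path) and `counts`.
#' @export
simulate_pam_library_reads <- function(plan, output_dir, gzip = FALSE) {
  stopifnot(inherits(plan, "simulation_plan"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_pam_library_counts(plan)
  files <- character(0)
  # per-read randomness (orientation, substitution errors) continues the
  # plan's seeded stream deterministically
  with_seed(plan$seed + 1L, {
    for (id in names(sim$counts)) {
      tab <- sim$counts[[id]]
      nz <- tab$counts[tab$counts > 0L]
      seqs <- rep(library_fragment(plan$library, names(nz)), times = nz)
      if (plan$error_rate > 0 && length(seqs)) {
        seqs <- mutate_reads(seqs, plan$error_rate)
      }
      if (plan$revcomp_fraction > 0 && length(seqs)) {
        flip <- stats::runif(length(seqs)) < plan$revcomp_fraction
        seqs[flip] <- revcomp(seqs[flip])
      }
      path <- file.path(output_dir,
                        paste0(id, if (gzip) ".fastq.gz" else ".fastq"))
      write_fastq(seqs, ids = sprintf("%s_read%06d", id, seq_along(seqs)),
                  path = path, gzip = gzip)
      files[[id]] <- path
    }
  })
  gt_path <- file.path(output_dir, "ground_truth.tsv")
  utils::write.table(sim$ground_truth, gt_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- c(paste0("seed=", plan$seed),
           paste0("reads_per_sample=", plan$reads_per_sample),
           paste0("randomized_length=", plan$library$randomized_length),
           paste0("revcomp_fraction=", plan$revcomp_fraction),
           paste0("error_rate=", plan$error_rate),
           paste0("samples=", paste(plan$samples$sample_id, collapse = ",")))
  writeLines(cfg, file.path(output_dir, "simulation_config.txt"))
  invisible(list(files = files, ground_truth = sim$ground_truth,
                 ground_truth_path = gt_path, counts = sim$counts))
}

mutate_reads <- function(seqs, rate) {
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    if (length(hit)) {
      for (j in hit) {
        b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1L)
      }
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# plain 4-line FASTQ writer; constant quality, deterministic record order
write_fastq <- function(seqs, ids, path, gzip = FALSE) {
  qual <- strrep("I", nchar(seqs))
  rec <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}
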