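# Synthetic-data generators: read simulator and kinetic time courses.

lib <- default_pam_library()

test_that("designed fragment is 206 bp with the configured flank geometry", {
  frag <- library_fragment(lib, "CAAA")
  expect_equal(nchar(frag), 206L)
  # 20 bp of constant sequence 3' of the cassette; fixed TTTT just 5' of it
  expect_equal(nchar(lib$downstream_flank), 20L)
  cassette_start <- nchar(lib$upstream_flank) + 1L
  expect_equal(substr(frag, cassette_start - 4L, cassette_start - 1L),
               "TTTT")
  expect_equal(substr(frag, cassette_start, cassette_start + 3L), "CAAA")
})

test_that("recognition model applies ordered IUPAC rules, first match wins", {
  m <- recognition_model(list(list(pattern = "CWAA", probability = 1),
                              list(pattern = "CNNN", probability = 0.5)),
                         default_probability = 0.1)
  p <- cleavage_probability(m, c("CAAA", "CTAA", "CGGG", "GAAA"))
  expect_equal(unname(p), c(1, 1, 0.5, 0.1))
  expect_error(recognition_model(list(list(pattern = "CWAA",
                                           probability = 1.5))),
               "probabilit")
  expect_error(recognition_model(list(list(pattern = "CWA",
                                           probability = 1))), "length")
})

test_that("full CWAA depletion removes exactly the two matching tetramers", {
  # brute-force enumeration over all 256 PAMs
  matches <- all_pams(4)[iupac_match(all_pams(4), "CWAA")]
  expect_equal(matches, c("CAAA", "CTAA"))
  m <- recognition_model(list(list(pattern = "CWAA", probability = 1)))
  plan <- simulation_plan(lib, m, 256L * 200L, make_samples(), seed = 11)
  sim <- simulate_pam_library_counts(plan)
  gt <- sim$ground_truth
  tgt <- gt[gt$sample_id == "targeting", ]
  expect_equal(tgt$true_weight[tgt$pam %in% matches], c(0, 0))
  expect_true(all(tgt$true_weight[!tgt$pam %in% matches] == 1))
  expect_equal(sum(tgt$count[tgt$pam %in% matches]), 0L)
  # untreated / non-targeting samples ignore the model
  untr <- gt[gt$sample_id == "untreated", ]
  expect_true(all(untr$true_weight == 1))
  expect_equal(unname(untr$expected_count), rep(200, 256))
})

test_that("a model cleaving everything is rejected as fully depleted", {
  m <- recognition_model(default_probability = 1)
  plan <- simulation_plan(lib, m, 100L, make_samples(), seed = 1)
  expect_error(simulate_pam_library_counts(plan), "fully depleted")
})

test_that("fixed seed reproduces byte-identical FASTQ output", {
  m <- recognition_model(list(list(pattern = "CWAA", probability = 1)))
  plan <- simulation_plan(lib, m, 500L, make_samples(), seed = 42,
                          revcomp_fraction = 0.3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_pam_library_reads(plan, d1)
  simulate_pam_library_reads(plan, d2)
  for (f in c("untreated.fastq", "ntc1.fastq", "targeting.fastq",
              "ground_truth.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))))
  }
})

test_that("no-depletion counts pass a chi-square test against uniform", {
  # sampling noise only: at alpha = 0.001 nearly every seed should accept
  m <- recognition_model(default_probability = 0)
  rejections <- 0L
  for (seed in 1:40) {
    plan <- simulation_plan(lib, m, 256L * 30L,
                            data.frame(sample_id = "u", role = "untreated"),
                            seed = seed)
    counts <- simulate_pam_library_counts(plan)$counts[["u"]]$counts
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    if (p < 0.001) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("observed counts converge to expected counts with depth", {
  m <- recognition_model(list(list(pattern = "CNNN", probability = 0.8)))
  rel_err <- vapply(c(2e3, 2e4, 2e5), function(n) {
    plan <- simulation_plan(lib, m, as.integer(n),
                            data.frame(sample_id = "t", role = "targeting"),
                            seed = 5)
    sim <- simulate_pam_library_counts(plan)
    gt <- sim$ground_truth
    mean(abs(gt$count - gt$expected_count) / pmax(gt$expected_count, 1))
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 0.05)
})

test_that("noiseless cleavage courses satisfy the generating equation", {
  tc <- simulate_cleavage_timecourse(k = 0.1, ymax = 0.8)
  expect_equal(tc$value, 0.8 * (1 - exp(-0.1 * tc$time)))
  expect_equal(tc$value[tc$time == 0], 0)            # t = 0 forces Y = 0
  expect_equal(tc$value[tc$time == 10], 0.8 * (1 - exp(-1)))  # ~0.5057
  far <- simulate_cleavage_timecourse(k = 0.25, ymax = 0.8,
                                      times = c(0, 1, 100 / 0.25))
  expect_equal(far$value[3], 0.8, tolerance = 1e-10)  # asymptote
  expect_error(simulate_cleavage_timecourse(0.1, 0.8, noise_sd = -1),
               "noise_sd")
  expect_error(simulate_cleavage_timecourse(0.1, 0.8, times = numeric(0)),
               "times")
})

test_that("noisy cleavage values stay clipped to [0, 1] and are seeded", {
  a <- simulate_cleavage_timecourse(0.5, 0.95, noise_sd = 0.3,
                                    n_replicates = 5, seed = 9)
  b <- simulate_cleavage_timecourse(0.5, 0.95, noise_sd = 0.3,
                                    n_replicates = 5, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$value >= 0 & a$value <= 1))
})

test_that("2AP traces sample every 20 s and satisfy the closed form", {
  s <- simulate_2ap_trace(k = 0.03, ymax = 4000, y0 = 500, duration = 300)
  expect_equal(unique(s$trace$time), seq(0, 300, by = 20))
  expect_equal(s$trace$value[s$trace$time == 0], 500)
  expect_equal(s$trace$value[s$trace$time == 100],
               500 + 4000 * (1 - exp(-3)))  # ~4300.85
  expect_equal(s$blank$value, rep(500, length(s$blank$value)))
  expect_equal(attr(s$trace, "blank_mean"), 500)
  expect_error(simulate_2ap_trace(0.03, 4000, 500, interval = 0), "interval")
  expect_error(simulate_2ap_trace(0.03, 4000, 500, duration = 10),
               "duration")
})
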