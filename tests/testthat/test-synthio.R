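test_that("noiseless single-module cohort is exactly rank one", {
  cfg <- simulation_config(n_samples = 30, n_genes = 40,
                           module_sizes = 20, noise_sd = 0,
                           regulator_effect = 1, seed = 3)
  co <- generate_cohort(cfg)
  members <- names(co$truth$module_labels)
  cc <- cor(t(co$expr[members, ]))
  expect_equal(max(abs(abs(cc) - 1)), 0, tolerance = 1e-12)
  expect_equal(unname(co$truth$module_labels), rep(1L, 20))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_samples = 20, n_genes = 100,
                           module_sizes = c(20, 20), seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$activity, b$truth$activity)
  expect_identical(generate_survival(a$truth$activity, cfg),
                   generate_survival(b$truth$activity, cfg))
  expect_identical(generate_cna_profiles(cfg, a$truth),
                   generate_cna_profiles(cfg, b$truth))
  expect_identical(generate_dose_response(cfg), generate_dose_response(cfg))
})

test_that("latent activity has exactly zero mean", {
  co <- generate_cohort(simulation_config(n_samples = 25, n_genes = 60,
                                          module_sizes = 30, seed = 2))
  expect_equal(mean(co$truth$activity), 0, tolerance = 1e-14)
})

test_that("within-module correlation rises monotonically with beta/sigma", {
  mean_abs_cor <- function(beta, sigma) {
    cfg <- simulation_config(n_samples = 40, n_genes = 30, module_sizes = 30,
                             regulator_effect = beta, noise_sd = sigma,
                             seed = 5)
    cc <- cor(t(generate_cohort(cfg)$expr))
    mean(abs(cc[upper.tri(cc)]))
  }
  r <- c(mean_abs_cor(0.25, 1), mean_abs_cor(1, 1), mean_abs_cor(4, 1))
  expect_true(all(diff(r) > 0))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(simulation_config(module_sizes = c(600, 600)), "module_sizes")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(simulation_config(censor_rate = 1), "censor_rate")
  expect_error(simulation_config(cna_segment_means = numeric(0)),
               "cna_segment_means")
  expect_error(simulation_config(drug_params = list(A = list(m = 0, Dm = 1))),
               "drug_params")
})

test_that("zero censor rate yields events only, and survival inputs validate", {
  cfg <- simulation_config(n_samples = 50, n_genes = 20, module_sizes = 10,
                           censor_rate = 0, seed = 4)
  co <- generate_cohort(cfg)
  surv <- generate_survival(co$truth$activity, cfg)
  expect_true(all(surv$event == 1L))
  expect_true(all(surv$time > 0))
  expect_error(generate_survival(co$truth$activity[1:10], cfg), "length")
})

test_that("high activity confers uniformly worse survival when gamma is large", {
  cfg <- simulation_config(n_samples = 100, n_genes = 20, module_sizes = 10,
                           survival_gamma = 2, censor_rate = 0, seed = 7)
  activity <- rep(c(-1, 1), each = 50)
  names(activity) <- sprintf("S%03d", 1:100)
  surv <- generate_survival(activity, cfg)
  lo <- km_curve(surv[activity < 0, ])
  hi <- km_curve(surv[activity > 0, ])
  s_at <- function(km, t) {
    i <- km$time <= t
    if (!any(i)) 1 else km$surv[max(which(i))]
  }
  grid <- sort(unique(surv$time))
  expect_true(all(vapply(grid, function(t) s_at(hi, t) <= s_at(lo, t),
                         logical(1))))
})

test_that("noiseless CNA tracks reproduce the planted segments and calls", {
  cfg <- simulation_config(n_samples = 10, n_genes = 20, module_sizes = 10,
                           cna_segment_means = c(0.5, -0.3),
                           cna_probes_per_segment = 10,
                           cna_amp_segment = 1, cna_noise_sd = 0, seed = 6)
  co <- generate_cohort(cfg)
  prof <- generate_cna_profiles(cfg, co$truth)
  neg <- setdiff(colnames(prof$values), co$truth$amplified_samples)[1]
  track <- data.frame(chrom = prof$probes$chrom, pos = prof$probes$pos,
                      value = prof$values[, neg])
  segs <- segment_profile(track)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$median, c(0.5, -0.3))
  amp <- co$truth$amplified_samples[1]
  segs_amp <- segment_profile(data.frame(chrom = prof$probes$chrom,
                                         pos = prof$probes$pos,
                                         value = prof$values[, amp]))
  expect_identical(amplification_call(segs_amp, prof$locus), "positive")
})

test_that("noisy CNA tracks are labeled per truth in at least 95% of samples", {
  cfg <- simulation_config(n_samples = 50, n_genes = 20, module_sizes = 10,
                           cna_noise_sd = 0.1, seed = 3)
  co <- generate_cohort(cfg)
  prof <- generate_cna_profiles(cfg, co$truth)
  calls <- vapply(colnames(prof$values), function(s) {
    segs <- segment_profile(data.frame(chrom = prof$probes$chrom,
                                       pos = prof$probes$pos,
                                       value = prof$values[, s]))
    amplification_call(segs, prof$locus)
  }, character(1))
  truth <- ifelse(colnames(prof$values) %in% co$truth$amplified_samples,
                  "positive", "negative")
  expect_gte(mean(calls == truth), 0.95)
})

test_that("dose-response tables follow the median-effect model exactly", {
  cfg <- simulation_config(n_samples = 10, n_genes = 20, module_sizes = 10,
                           drug_params = list(A = list(m = 1, Dm = 1),
                                              B = list(m = 2, Dm = 0.5)))
  dr <- generate_dose_response(cfg)
  tab <- dr$single$A
  expect_equal(tab$viability[tab$dose == 1], 0.5)  # D = Dm: half effect
  fa <- 1 - tab$viability
  expect_equal(log(fa / (1 - fa)), 1 * (log(tab$dose) - log(1)),
               tolerance = 1e-12)
  expect_equal(dr$true_ci, 1)
})
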