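#' Simulation configuration for synthetic cohorts
#'
#' Bundles every parameter of the synthetic-data generator: a cohort of
#' tumor samples in which a latent regulator activity drives one planted
#' co-expression module, survival outcomes whose hazard depends on that
#' activity, piecewise-constant copy-number tracks with an activity-linked
#' amplified locus, and median-effect dose-response tables with a known
#' combination index.
#'
#' @param n_samples number of samples in the cohort.
#' @param n_genes total number of genes (planted modules plus background).
#' @param module_sizes integer vector of planted module sizes; the first
#'   module is the regulator-driven one recorded in the ground truth.
#' @param regulator_effect loading `beta` of the latent activity on the
#'   driven-module genes.
#' @param noise_sd standard deviation of the i.i.d. Gaussian residuals on
#'   module genes (background genes are standard normal noise).
#' @param survival_gamma log-hazard coefficient on the latent activity.
#' @param baseline_hazard baseline exponential event rate (> 0).
#' @param censor_rate fraction of records independently censored, in [0, 1).
#' @param cna_segment_means per-segment log2-ratio means of the baseline
#'   copy-number track shared by all samples.
#' @param cna_probes_per_segment probes per copy-number segment.
#' @param cna_amp_segment index of the segment that is amplified in
#'   high-activity samples (the designated locus).
#' @param cna_amp_mean log2-ratio mean of the amplified segment in
#'   amplification-positive samples (> 0).
#' @param cna_noise_sd probe-level Gaussian noise sd on log2 ratios.
#' @param drug_params named list of single agents, each a list with slope
#'   `m` (> 0) and median-effect dose `Dm` (> 0). The first two agents are
#'   used for combination designs.
#' @param combo_ci true combination index of the generated combo points:
#'   1 reproduces Loewe additivity, values < 1 a configured synergy.
#' @param dose_noise_sd Gaussian noise sd added to generated viabilities.
#' @param seed global seed; per-stage substreams are derived from it so each
#'   generator can be rerun independently.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_samples = 20, n_genes = 100,
#'                          module_sizes = c(20, 20))
#' cohort <- generate_cohort(cfg)
#' dim(cohort$expr)
#' @export
simulation_config <- function(n_samples = 60,
                              n_genes = 1000,
                              module_sizes = c(50, 50, 50),
                              regulator_effect = 1,
                              noise_sd = 0.5,
                              survival_gamma = 1,
                              baseline_hazard = 0.1,
                              censor_rate = 0.2,
                              cna_segment_means = c(0, -0.3, 0),
                              cna_probes_per_segment = 20,
                              cna_amp_segment = 2,
                              cna_amp_mean = 0.8,
                              cna_noise_sd = 0.1,
                              drug_params = list(
                                A = list(m = 1.5, Dm = 1),
                                B = list(m = 2,   Dm = 0.5)),
                              combo_ci = 1,
                              dose_noise_sd = 0,
                              seed = 1) {
  .check_count(n_samples, "n_samples")
  .check_count(n_genes, "n_genes")
  if (length(module_sizes) < 1L || any(module_sizes < 1) ||
      any(module_sizes != round(module_sizes)))
    .stopf("'module_sizes' must be positive integers")
  if (sum(module_sizes) > n_genes)
    .stopf("'module_sizes' sum to %d, exceeding 'n_genes' = %d",
           sum(module_sizes), n_genes)
  .check_number(regulator_effect, "regulator_effect")
  .check_number(noise_sd, "noise_sd", lower = 0)
  .check_number(survival_gamma, "survival_gamma")
  .check_number(baseline_hazard, "baseline_hazard", lower = 0,
                strict_lower = TRUE)
  .check_number(censor_rate, "censor_rate", lower = 0, upper = 1,
                strict_upper = TRUE)
  if (length(cna_segment_means) < 1L)
    .stopf("'cna_segment_means' must be nonempty")
  .check_count(cna_probes_per_segment, "cna_probes_per_segment")
  .check_count(cna_amp_segment, "cna_amp_segment")
  if (cna_amp_segment > length(cna_segment_means))
    .stopf("'cna_amp_segment' exceeds the number of segments")
  .check_number(cna_amp_mean, "cna_amp_mean", lower = 0, strict_lower = TRUE)
  .check_number(cna_noise_sd, "cna_noise_sd", lower = 0)
  for (nm in names(drug_params)) {
    p <- drug_params[[nm]]
    if (is.null(p$m) || is.null(p$Dm) || p$m <= 0 || p$Dm <= 0)
      .stopf("'drug_params' entry '%s' needs m > 0 and Dm > 0", nm)
  }
  .check_number(combo_ci, "combo_ci", lower = 0, strict_lower = TRUE)
  .check_number(dose_noise_sd, "dose_noise_sd", lower = 0)
  .check_count(seed, "seed", min = 0L)

  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    regulator_effect = regulator_effect, noise_sd = noise_sd,
    survival_gamma = survival_gamma, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    cna_segment_means = as.numeric(cna_segment_means),
    cna_probes_per_segment = as.integer(cna_probes_per_segment),
    cna_amp_segment = as.integer(cna_amp_segment),
    cna_amp_mean = cna_amp_mean, cna_noise_sd = cna_noise_sd,
    drug_params = drug_params, combo_ci = combo_ci,
    dose_noise_sd = dose_noise_sd, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d, genes: %d, planted modules: %s\n",
              x$n_samples, x$n_genes, paste(x$module_sizes, collapse = "/")))
  cat(sprintf("  beta = %g, sigma = %g, gamma = %g, censoring = %g\n",
              x$regulator_effect, x$noise_sd, x$survival_gamma,
              x$censor_rate))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Generate a synthetic expression cohort with planted modules
#'
#' Draws one latent activity per planted module (standard normal across
#' samples, centered to exact zero mean) and sets module-gene expression to
#' `beta * activity + N(0, sigma^2)`. Background genes are independent
#' standard normal noise. The first module's activity is the regulator
#' activity recorded in the ground truth; samples with positive activity are
#' marked amplification-positive at the designated copy-number locus.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` (genes x samples numeric matrix) and `truth`, a
#'   `synthetic_truth` list carrying `activity` (named per-sample vector),
#'   `module_labels` (named integer vector over planted genes),
#'   `amplified_samples`, and `regulator` (the planted regulator ID used by
#'   [generate_regulator_network()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream(config$seed, "cohort"))
  n <- config$n_samples
  g <- config$n_genes
  sizes <- config$module_sizes
  k <- length(sizes)
  samples <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(g))

  act <- matrix(stats::rnorm(k * n), nrow = k)
  act <- act - rowMeans(act)              # zero mean by construction
  rownames(act) <- sprintf("M%d", seq_len(k))
  colnames(act) <- samples

  expr <- matrix(stats::rnorm(g * n), nrow = g,
                 dimnames = list(genes, samples))
  labels <- integer(0)
  offset <- 0L
  for (m in seq_len(k)) {
    idx <- offset + seq_len(sizes[m])
    eps <- matrix(stats::rnorm(sizes[m] * n, sd = config$noise_sd),
                  nrow = sizes[m])
    expr[idx, ] <- config$regulator_effect *
      matrix(act[m, ], nrow = sizes[m], ncol = n, byrow = TRUE) + eps
    lab <- rep.int(m, sizes[m]); names(lab) <- genes[idx]
    labels <- c(labels, lab)
    offset <- offset + sizes[m]
  }

  activity <- act[1L, ]
  truth <- structure(list(
    activity = activity,
    module_labels = labels,
    amplified_samples = samples[activity > 0],
    regulator = "REG1",
    latent = act
  ), class = "synthetic_truth")
  list(expr = expr, truth = truth)
}

#' Generate exponential survival outcomes driven by a latent activity
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(survival_gamma * activity)`, the proportional
#' hazards model in its analytically simplest form. Censoring times are
#' drawn independently from an exponential whose rate
#' `baseline_hazard * censor_rate / (1 - censor_rate)` yields the stated
#' expected censoring fraction at baseline hazard; the record keeps the
#' earlier of event and censoring time.
#'
#' @param activity per-sample real vector (names become sample IDs).
#' @param config a [simulation_config()]; its length must match.
#' @return data.frame with columns `sample_id`, `time`, `event` (1 = event,
#'   0 = censored).
#' @export
generate_survival <- function(activity, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(activity) != config$n_samples)
    .stopf("'activity' has length %d but config expects %d samples",
           length(activity), config$n_samples)
  set.seed(.substream(config$seed, "survival"))
  rate <- config$baseline_hazard * exp(config$survival_gamma * activity)
  t_event <- stats::rexp(length(activity), rate = rate)
  if (config$censor_rate > 0) {
    c_rate <- config$baseline_hazard * config$censor_rate /
      (1 - config$censor_rate)
    t_cens <- stats::rexp(length(activity), rate = c_rate)
  } else {
    t_cens <- rep(Inf, length(activity))
  }
  ids <- names(activity)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(activity))
  data.frame(sample_id = ids, time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens), row.names = NULL)
}

#' Generate per-sample copy-number probe tracks
#'
#' Every sample shares a piecewise-constant baseline of per-segment log2
#' ratios (`cna_segment_means`, `cna_probes_per_segment` probes each, on one
#' chromosome at 10 kb spacing) plus Gaussian probe noise. Samples in
#' `truth$amplified_samples` have the designated segment's mean replaced by
#' `cna_amp_mean`, planting a positive-median amplified locus.
#'
#' @param config a [simulation_config()].
#' @param truth the `synthetic_truth` from [generate_cohort()].
#' @return list with `probes` (data.frame `probe_id`, `chrom`, `pos`),
#'   `values` (probes x samples matrix of log2 ratios), and `locus`
#'   (chrom/pos at the center of the amplified segment, for
#'   [amplification_call()]).
#' @export
generate_cna_profiles <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "synthetic_truth"))
  if (config$cna_probes_per_segment < 1L)
    .stopf("'cna_probes_per_segment' must be >= 1")
  set.seed(.substream(config$seed, "cna"))
  means <- config$cna_segment_means
  ppseg <- config$cna_probes_per_segment
  n_probes <- length(means) * ppseg
  pos <- 10000L * seq_len(n_probes)
  samples <- names(truth$activity)
  base <- rep(means, each = ppseg)
  amp <- base
  amp[(config$cna_amp_segment - 1L) * ppseg + seq_len(ppseg)] <-
    config$cna_amp_mean

  values <- vapply(samples, function(s) {
    mu <- if (s %in% truth$amplified_samples) amp else base
    mu + stats::rnorm(n_probes, sd = config$cna_noise_sd)
  }, numeric(n_probes))
  rownames(values) <- sprintf("P%04d", seq_len(n_probes))

  locus_idx <- (config$cna_amp_segment - 1L) * ppseg + (ppseg + 1L) %/% 2L
  list(
    probes = data.frame(probe_id = rownames(values), chrom = "chr1",
                        pos = pos, row.names = NULL),
    values = values,
    locus = list(chrom = "chr1", pos = pos[locus_idx])
  )
}

#' Generate median-effect dose-response tables with known combination index
#'
#' Single-agent viabilities follow the median-effect model
#' `fa/(1 - fa) = (D/Dm)^m` on an 8-point two-fold dose ladder that
#' includes `Dm` itself. Combination points are built at a non-constant ratio: for each
#' target fraction affected, the two agents contribute `lambda` and
#' `1 - lambda` of their respective effective doses `Dx`, both scaled by the
#' configured `combo_ci`, so the true combination index equals `combo_ci`
#' exactly at every design point (1 = Loewe additivity).
#'
#' @param config a [simulation_config()]; the first two `drug_params`
#'   entries define the combination.
#' @return list with `single` (named list of data.frames `dose`,
#'   `viability`), `combo` (data.frame `dose_a`, `dose_b`, `viability`), and
#'   `true_ci`.
#' @export
generate_dose_response <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$drug_params) < 2L)
    .stopf("need at least two entries in 'drug_params'")
  set.seed(.substream(config$seed, "dose"))
  noise <- config$dose_noise_sd

  single <- lapply(config$drug_params, function(p) {
    dose <- p$Dm * 2^seq(-3, 4, by = 1)   # 8 doses, includes Dm itself
    if (any(dose <= 0)) .stopf("nonpositive dose in design")
    fa <- 1 / (1 + (p$Dm / dose)^p$m)
    v <- 1 - fa + if (noise > 0) stats::rnorm(length(fa), sd = noise) else 0
    data.frame(dose = dose, viability = v)
  })

  pa <- config$drug_params[[1L]]
  pb <- config$drug_params[[2L]]
  fa_targets <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  lambdas <- c(0.3, 0.4, 0.5, 0.6, 0.7)   # non-constant ratio design
  dxa <- pa$Dm * (fa_targets / (1 - fa_targets))^(1 / pa$m)
  dxb <- pb$Dm * (fa_targets / (1 - fa_targets))^(1 / pb$m)
  v <- 1 - fa_targets +
    if (noise > 0) stats::rnorm(length(fa_targets), sd = noise) else 0
  combo <- data.frame(
    dose_a = config$combo_ci * lambdas * dxa,
    dose_b = config$combo_ci * (1 - lambdas) * dxb,
    viability = v)

  list(single = single, combo = combo, true_ci = config$combo_ci)
}

#' Build a signed regulator-target network around the planted module
#'
#' The planted regulator activates every gene of the driven module (all
#' edge signs +1, matching the positive loadings used by
#' [generate_cohort()]). Decoy regulators target the same genes but with
#' independently shuffled random signs, so direction-aware scoring should
#' rank the planted regulator first while overlap-only statistics cannot
#' separate them.
#'
#' @param truth `synthetic_truth` from [generate_cohort()].
#' @param n_decoys number of decoy regulators.
#' @param seed integer seed for the decoy signs.
#' @return data.frame with columns `regulator`, `target`, `sign`.
#' @export
generate_regulator_network <- function(truth, n_decoys = 5, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .check_count(n_decoys, "n_decoys", min = 0L)
  set.seed(.substream(seed, "network"))
  targets <- names(truth$module_labels)[truth$module_labels == 1L]
  net <- data.frame(regulator = truth$regulator, target = targets,
                    sign = 1L)
  for (d in seq_len(n_decoys)) {
    net <- rbind(net, data.frame(
      regulator = sprintf("DECOY%d", d), target = targets,
      sign = sample(c(-1L, 1L), length(targets), replace = TRUE)))
  }
  net
}

#' Split the planted module into annotation gene sets
#'
#' Produces disjoint chunks of the driven module (stand-ins for the
#' cancer-promoting annotation terms a curated knowledge base would supply)
#' plus random background gene sets of the same size.
#'
#' @param truth `synthetic_truth` from [generate_cohort()].
#' @param all_genes universe of gene IDs (e.g. rownames of the expression
#'   matrix) used to draw the background sets.
#' @param n_chunks number of module-derived annotation sets.
#' @param n_random number of random background sets.
#' @param seed integer seed.
#' @return named list of character vectors of gene IDs.
#' @export
generate_annotations <- function(truth, all_genes, n_chunks = 3,
                                 n_random = 3, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(.substream(seed, "annot"))
  members <- names(truth$module_labels)[truth$module_labels == 1L]
  chunks <- split(members, rep(seq_len(n_chunks), length.out = length(members)))
  sets <- stats::setNames(chunks, sprintf("ANNOT%d", seq_len(n_chunks)))
  size <- max(3L, length(members) %/% n_chunks)
  for (r in seq_len(n_random))
    sets[[sprintf("RANDOM%d", r)]] <- sample(all_genes, size)
  sets
}
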