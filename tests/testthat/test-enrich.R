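test_that("Fisher enrichment reproduces exact hypergeometric tails", {
  u <- paste0("G", 1:10)
  res <- fisher_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5L)
  expect_equal(res$fisher_p, 1 / choose(10, 5), tolerance = 1e-12)
  # forced-disjoint sets: no enrichment tail, p = 1
  res0 <- fisher_enrichment(u[1:5], u[6:10], u)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$fisher_p, 1)
  expect_error(fisher_enrichment(character(0), u[1:2], u), "query")
  expect_error(fisher_enrichment(u[1:2], u[1:2], character(0)), "universe")
  expect_error(fisher_enrichment(c("X1"), u[1:2], u), "outside")
})

test_that("Fisher p matches full enumeration on small universes", {
  for (N in c(5, 9, 14)) {
    u <- paste0("G", seq_len(N))
    for (K in 1:N) for (n in 1:N) {
      for (k in max(0, n + K - N):min(K, n)) {
        if (n - k > N - K) next
        query <- c(u[seq_len(K)][seq_len(k)],
                   if (n - k > 0) u[K + seq_len(n - k)])
        p <- fisher_enrichment(query, u[seq_len(K)], u)$fisher_p
        expect_equal(p, fisher_enumeration(N, K, n, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("activation z-score follows the weighted agreement formula", {
  expect_equal(activation_zscore(rep(1, 4), rep(1, 4)), 2)       # sqrt(4)
  expect_equal(activation_zscore(c(1, 1, -1, -1), rep(1, 4)), 0) # cancel
  expect_equal(activation_zscore(rep(1, 3), rep(1, 3), c(2, 1, 1)),
               4 / sqrt(6), tolerance = 1e-12)
  expect_error(activation_zscore(c(1, 1), c(1, 1), c(0, 0)), "zero")
  expect_error(activation_zscore(c(1, 2), c(1, 1)), "directions")
})

test_that("activation z-score is antisymmetric and scale-invariant", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    obs <- sample(c(-1, 1), n, replace = TRUE)
    exp_ <- sample(c(-1, 1), n, replace = TRUE)
    w <- runif(n)
    z <- activation_zscore(obs, exp_, w)
    expect_equal(activation_zscore(-obs, exp_, w), -z, tolerance = 1e-12)
    expect_equal(activation_zscore(obs, exp_, 7.3 * w), z, tolerance = 1e-12)
  }
})

test_that("upstream ranking puts the planted regulator first", {
  co <- generate_cohort(simulation_config(seed = 1))
  asn <- module_eigengene_and_membership(co$expr,
                                         assignment_from_labels(truth_labels(co)))
  net <- generate_regulator_network(co$truth, n_decoys = 5, seed = 1)
  ann <- generate_annotations(co$truth, rownames(co$expr), seed = 1)
  rk <- suppressMessages(rank_upstream_regulators(asn, 1L, net, ann))
  expect_identical(rk$regulator[1], co$truth$regulator)
  expect_gt(rk$summary_score[1], rk$summary_score[2])
})

test_that("balanced targets cancel and single annotations pass through", {
  genes <- paste0("G", 1:8)
  labels <- setNames(rep(1L, 8), genes)
  asn <- assignment_from_labels(labels)
  asn$membership <- setNames(rep(0.8, 8), genes)  # equal weights, all up
  net <- data.frame(regulator = "R", target = genes,
                    sign = rep(c(1L, -1L), each = 4))
  ann <- list(ALL = genes)
  rk <- rank_upstream_regulators(asn, 1L, net, ann)
  expect_equal(rk$summary_score, 0, tolerance = 1e-12)
  # single regulator, single annotation: summary equals that annotation's z
  net2 <- data.frame(regulator = "R", target = genes[1:4], sign = 1L)
  rk2 <- rank_upstream_regulators(asn, 1L, net2, list(A = genes[1:4]))
  expect_equal(rk2$summary_score,
               activation_zscore(rep(1, 4), rep(1, 4), rep(0.8, 4)),
               tolerance = 1e-12)
  # too few in-module targets -> excluded with a log entry
  net3 <- rbind(net2, data.frame(regulator = "TINY", target = genes[1:2],
                                 sign = 1L))
  expect_message(rank_upstream_regulators(asn, 1L, net3, list(A = genes[1:4])),
                 "TINY")
})

test_that("module enrichment singles out the annotation-enriched module", {
  co <- generate_cohort(simulation_config(n_samples = 30, n_genes = 120,
                                          module_sizes = c(30, 30), seed = 6))
  lab <- truth_labels(co)
  # relabel so the planted annotation module is NOT detected label 1
  lab_swapped <- lab
  lab_swapped[lab == 1L] <- 2L
  lab_swapped[lab == 2L] <- 1L
  asn <- assignment_from_labels(lab_swapped)
  ann <- list(TERM = names(lab)[lab == 1L][1:15])
  me <- module_enrichment(asn, ann)
  expect_identical(me$focus_module, 2L)
  expect_true(all(me$table$fisher_p > 0 & me$table$fisher_p <= 1))
})

test_that("combined score is the product of log p and rank z", {
  expect_equal(combined_score(exp(-4), 2.5), -10, tolerance = 1e-12)
  expect_equal(combined_score(0.01, 0), 0)
  expect_warning(c0 <- combined_score(0, 1), "clamped")
  expect_true(is.finite(c0))
  expect_error(combined_score(1.5, 1), "fisher_p")
})

test_that("rank z is standard normal-ish over the null ensemble", {
  set.seed(5)
  universe <- paste0("G", 1:80)
  terms <- list(T1 = universe[1:20], T2 = universe[15:40],
                T3 = universe[30:60], T4 = universe[50:80])
  zs <- vapply(1:60, function(i) {
    q <- sample(universe, 10)
    res <- enrichment_with_combined_score(q, terms, universe,
                                          n_random = 60, seed = 1000 + i)
    res$rank_z[res$term == "T2"]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.35)
  expect_gt(sd(zs), 0.6)
  expect_lt(sd(zs), 1.5)
})

test_that("promoter windows are strand-aware, half-open, and DE-gated", {
  tss <- data.frame(gene = c("UP", "FAR", "MINUS"),
                    chrom = c("chr1", "chr3", "chr2"),
                    pos = c(1000, 1000, 10000),
                    strand = c("+", "+", "-"))
  peaks <- data.frame(chrom = c("chr1", "chr3", "chr2"),
                      start = c(400, 6500, 9500),
                      end = c(600, 6600, 9600))
  de <- c("UP", "FAR", "MINUS")
  hits <- promoter_peak_targets(peaks, tss, de)
  expect_setequal(hits, c("UP", "MINUS"))  # FAR's peak is outside the window
  # DE gate: not differentially expressed -> not a target
  expect_identical(promoter_peak_targets(peaks, tss, "FAR"), character(0))
  # half-open end: peak [0, 100) does not reach a window starting at 100
  tss2 <- data.frame(gene = "EDGE", chrom = "chr1", pos = 5100, strand = "+")
  peak2 <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_identical(promoter_peak_targets(peak2, tss2, "EDGE"), character(0))
  peak3 <- data.frame(chrom = "chr1", start = 0, end = 101)
  expect_identical(promoter_peak_targets(peak3, tss2, "EDGE"), "EDGE")
  expect_error(promoter_peak_targets(peaks,
                                     transform(tss, strand = c("+", "*", "-")),
                                     de), "strand")
})
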