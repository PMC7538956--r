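test_that("adjacency matches its defining transform", {
  set.seed(1)
  x <- matrix(rnorm(10 * 15), nrow = 10,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:15)))
  for (p in c(1, 2, 6)) {
    a <- adjacency_matrix(x, p)
    cc <- cor(t(x))
    ref <- abs(cc)^p
    diag(ref) <- 1
    expect_equal(a, ref, tolerance = 1e-12)
  }
  # perfectly correlated pair -> adjacency 1 at any power
  y <- rbind(x, G11 = 2 * x[1, ] + 3)
  expect_equal(adjacency_matrix(y, 7)["G1", "G11"], 1, tolerance = 1e-12)
  # |cor| = 0.5 at beta 2 -> 0.25 checked via constructed pair
  z <- matrix(c(1, 0, 0, 1), nrow = 2) %*% matrix(rnorm(2 * 400), nrow = 2)
  z[2, ] <- 0.5 / sqrt(1 - 0.5^2) * z[1, ] + z[2, ]  # population cor 0.5
  expect_equal(abs(cor(z[1, ], z[2, ]))^2,
               adjacency_matrix(rbind(A = z[1, ], B = z[2, ]) |>
                                  `colnames<-`(paste0("S", 1:400)), 2)["A", "B"],
               tolerance = 1e-12)
})

test_that("adjacency rejects zero-variance genes by name", {
  x <- matrix(rnorm(20), nrow = 2,
              dimnames = list(c("OK", "FLAT"), paste0("S", 1:10)))
  x["FLAT", ] <- 5
  expect_error(adjacency_matrix(x, 2), "FLAT")
})

test_that("topological overlap reproduces hand-computed graphs", {
  k3 <- matrix(1, 3, 3)
  tom <- topological_overlap(k3)
  expect_equal(tom[upper.tri(tom)], rep(1, 3))
  path <- diag(3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  tom <- topological_overlap(path)
  expect_equal(tom[1, 2], 1)
  expect_equal(tom[1, 3], 0.5)
  expect_error(topological_overlap(matrix(c(0, 1, 0, 0), 2, 2)), "asymmetric")
})

test_that("topological overlap matches the triple-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    a <- matrix(runif(100), 10, 10)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_equal(topological_overlap(a), tom_brute_force(a),
                 tolerance = 1e-12)
  }
})

test_that("TOM is bounded, symmetric, and permutation-equivariant", {
  set.seed(7)
  x <- matrix(rnorm(20 * 30), nrow = 20,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:30)))
  a <- adjacency_matrix(x, 4)
  tom <- topological_overlap(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom))
  perm <- sample(rownames(a))
  expect_equal(topological_overlap(a[perm, perm]), tom[perm, perm],
               tolerance = 1e-12)
})

test_that("soft-threshold scan flags degenerate rank-one data", {
  f <- rnorm(20)
  x <- outer(2^(1:8), f)
  dimnames(x) <- list(paste0("G", 1:8), paste0("S", 1:20))
  rep <- pick_soft_threshold(x, powers = c(2, 4, 6), target_r2 = 0.8)
  expect_true(all(rep$report$degenerate))
  expect_identical(rep$chosen_power, 2L)
})

test_that("scale-free data reaches the target fit at the chosen power", {
  x <- scale_free_expression(seed = 11)
  rep <- pick_soft_threshold(x, powers = 1:10, target_r2 = 0.8)
  r2 <- rep$report$scale_free_r2[rep$report$power == rep$chosen_power]
  expect_gte(r2, 0.8)
  rep2 <- pick_soft_threshold(x, powers = 1:10, target_r2 = 0.8)
  expect_identical(rep$chosen_power, rep2$chosen_power)
})

test_that("noiseless planted blocks are detected exactly", {
  set.seed(5)
  f1 <- rnorm(30); f2 <- rnorm(30)
  x <- rbind(outer(runif(20, 0.5, 2), f1), outer(runif(20, 0.5, 2), f2))
  dimnames(x) <- list(sprintf("G%02d", 1:40), sprintf("S%02d", 1:30))
  tom <- topological_overlap(adjacency_matrix(x, 6))
  asn <- detect_modules(tom, min_module_size = 10)
  expect_equal(max(asn$labels), 2L)
  expect_equal(length(unique(asn$labels[1:20])), 1L)
  expect_equal(length(unique(asn$labels[21:40])), 1L)
  expect_true(asn$labels[1] != asn$labels[21])
})

test_that("module detection recovers the planted cohort structure", {
  co <- generate_cohort(simulation_config(seed = 1))
  tom <- topological_overlap(adjacency_matrix(co$expr, 6))
  asn <- detect_modules(tom)
  expect_gte(ari(asn$labels, truth_labels(co)), 0.9)
  # invariant to sample ordering
  perm <- sample(colnames(co$expr))
  tom2 <- topological_overlap(adjacency_matrix(co$expr[, perm], 6))
  asn2 <- detect_modules(tom2)
  expect_identical(asn$labels, asn2$labels)
})

test_that("pure-noise cohorts stay largely unassigned", {
  cfg <- simulation_config(n_samples = 40, n_genes = 300, module_sizes = 1,
                           regulator_effect = 0, seed = 2)
  co <- generate_cohort(cfg)
  tom <- topological_overlap(adjacency_matrix(co$expr, 6))
  asn <- detect_modules(tom)
  expect_gte(mean(asn$labels == 0), 0.9)
})

test_that("eigengene and kME behave on rank-one and oriented modules", {
  cfg <- simulation_config(n_samples = 30, n_genes = 20, module_sizes = 10,
                           noise_sd = 0, seed = 8)
  co <- generate_cohort(cfg)
  asn <- assignment_from_labels(truth_labels(co))
  asn <- module_eigengene_and_membership(co$expr, asn)
  expect_equal(abs(unname(asn$membership)), rep(1, 10), tolerance = 1e-9)
  expect_equal(sum(asn$eigengenes[1, ]^2), 1, tolerance = 1e-12)
  # flipping all member signs flips the eigengene, |kME| unchanged
  flipped <- co$expr
  members <- names(co$truth$module_labels)
  flipped[members, ] <- -flipped[members, ]
  asn2 <- module_eigengene_and_membership(flipped,
                                          assignment_from_labels(truth_labels(co)))
  expect_equal(abs(asn2$membership), abs(asn$membership), tolerance = 1e-9)
  expect_equal(unname(asn2$eigengenes[1, ]), -unname(asn$eigengenes[1, ]),
               tolerance = 1e-9)
})

test_that("module eigengene tracks the planted activity", {
  co <- generate_cohort(simulation_config(seed = 1))
  asn <- module_eigengene_and_membership(co$expr,
                                         assignment_from_labels(truth_labels(co)))
  expect_gte(abs(cor(asn$eigengenes["ME1", ], co$truth$activity)), 0.95)
})

test_that("hub network applies a strict TOM threshold and ranks hubs first", {
  tom <- diag(3)
  tom[1, 2] <- tom[2, 1] <- 0.12
  tom[1, 3] <- tom[3, 1] <- 0.13
  tom[2, 3] <- tom[3, 2] <- 0.14
  dimnames(tom) <- list(paste0("G", 1:3), paste0("G", 1:3))
  asn <- assignment_from_labels(c(G1 = 1L, G2 = 1L, G3 = 1L))
  hub <- hub_network(tom, asn, 1L, top_n = 3)
  expect_equal(nrow(hub$edges), 1L)
  expect_setequal(c(hub$edges$gene_a, hub$edges$gene_b), c("G2", "G3"))

  # star topology: the center dominates the degree ranking
  star <- diag(5)
  star[1, 2:5] <- star[2:5, 1] <- 0.5
  dimnames(star) <- list(paste0("G", 1:5), paste0("G", 1:5))
  asn <- assignment_from_labels(setNames(rep(1L, 5), paste0("G", 1:5)))
  hub <- hub_network(star, asn, 1L, top_n = 5)
  expect_identical(hub$ranking$gene[1], "G1")

  expect_warning(hub_network(star, asn, 1L, top_n = 10), "clamped")
})

test_that("hub edge list equals the brute-force filter on a random module", {
  set.seed(12)
  x <- matrix(rnorm(15 * 25), nrow = 15,
              dimnames = list(sprintf("G%02d", 1:15), sprintf("S%02d", 1:25)))
  tom <- topological_overlap(adjacency_matrix(x, 2))
  asn <- assignment_from_labels(setNames(rep(1L, 15), rownames(x)))
  hub <- hub_network(tom, asn, 1L, top_n = 15, tom_threshold = 0.13)
  idx <- which(upper.tri(tom) & tom > 0.13, arr.ind = TRUE)
  want <- sort(paste(pmin(rownames(tom)[idx[, 1]], rownames(tom)[idx[, 2]]),
                     pmax(rownames(tom)[idx[, 1]], rownames(tom)[idx[, 2]])))
  got <- sort(paste(pmin(hub$edges$gene_a, hub$edges$gene_b),
                    pmax(hub$edges$gene_a, hub$edges$gene_b)))
  expect_identical(got, want)
})
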