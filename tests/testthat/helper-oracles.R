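# Independent oracles: deliberately naive re-implementations used only to
# check the package's fast paths.

# Triple-loop topological overlap, directly from the formula with the sum
# over third parties u != i, j and connectivity excluding the diagonal.
tom_brute_force <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    out[i, j] <- (num + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(adj)
  out
}

# Exact upper-tail hypergeometric by explicit enumeration of the tail.
fisher_enumeration <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Pearson chi-square from the definition.
chisq_brute_force <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Rank-then-Pearson Spearman.
spearman_brute_force <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Full truth label vector (planted modules + 0 background) aligned to an
# expression matrix's genes.
truth_labels <- function(cohort) {
  lab <- integer(nrow(cohort$expr))
  names(lab) <- rownames(cohort$expr)
  lab[names(cohort$truth$module_labels)] <- cohort$truth$module_labels
  lab
}

# Build a module_assignment directly from known labels (bypassing
# detection) so recovery tests can isolate single stages.
assignment_from_labels <- function(labels) {
  structure(list(labels = labels, eigengenes = NULL, membership = NULL),
            class = "module_assignment")
}

# Expression whose weighted connectivity follows an approximate power law:
# a single latent factor with heavy-tailed gene loadings. Used to check the
# scale-free fit report on data that actually has scale-free topology.
scale_free_expression <- function(n_genes = 400, n_samples = 100,
                                  power = 6, seed = 11) {
  set.seed(seed)
  t <- stats::runif(n_genes)^1.5          # c^power ~ power law near 0
  cvals <- pmin(t^(1 / power), 0.995)
  f <- stats::rnorm(n_samples)
  w <- cvals / sqrt(1 - cvals^2)
  x <- outer(w, f) + matrix(stats::rnorm(n_genes * n_samples),
                            nrow = n_genes)
  dimnames(x) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  x
}
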