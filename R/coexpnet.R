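#' Pick a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the weighted connectivity `k_i = sum_j a_ij`
#' (diagonal excluded) is computed from the unsigned adjacency, log10(k) is
#' binned, and log10(frequency) is regressed on the mean log10(k) per bin.
#' The reported fit is the R-squared of that regression. The chosen power is
#' the smallest candidate whose fit reaches `target_r2`, or the
#' R-squared-maximizing power if none does. When connectivities are all
#' (numerically) identical the fit is undefined: the report flags the power
#' as degenerate and, if every candidate is degenerate, returns the smallest
#' candidate power.
#'
#' @param expr genes x samples numeric matrix.
#' @param powers positive integer candidates (default 1:20).
#' @param target_r2 scale-free fit target in (0, 1] (default 0.8).
#' @param n_bins number of log-connectivity bins (default 10).
#' @return object of class `soft_threshold_report`: data.frame `report`
#'   (power, scale_free_r2, mean_connectivity, degenerate) plus
#'   `chosen_power`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.8,
                                n_bins = 10) {
  expr <- .filter_expression(expr)
  if (ncol(expr) < 3L) .stopf("need at least 3 samples")
  if (any(powers < 1) || any(powers != round(powers)))
    .stopf("'powers' must be positive integers")
  .check_number(target_r2, "target_r2", lower = 0, upper = 1,
                strict_lower = TRUE)
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  rows <- lapply(powers, function(p) {
    k <- rowSums(ac^p)
    fit <- .scale_free_fit(k, n_bins)
    data.frame(power = p, scale_free_r2 = fit$r2,
               mean_connectivity = mean(k), degenerate = fit$degenerate)
  })
  report <- do.call(rbind, rows)
  usable <- !report$degenerate
  if (!any(usable)) {
    chosen <- min(powers)
  } else {
    ok <- usable & report$scale_free_r2 >= target_r2
    chosen <- if (any(ok)) min(report$power[ok])
              else report$power[usable][which.max(report$scale_free_r2[usable])]
  }
  structure(list(report = report, chosen_power = as.integer(chosen),
                 target_r2 = target_r2),
            class = "soft_threshold_report")
}

.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(signif(k, 8))) < 2L)
    return(list(r2 = NA_real_, degenerate = TRUE))
  logk <- log10(k)
  bins <- cut(logk, breaks = n_bins)
  freq <- tabulate(bins, nbins = n_bins)
  keep <- freq > 0
  if (sum(keep) < 3L) return(list(r2 = NA_real_, degenerate = TRUE))
  x <- tapply(logk, bins, mean)[keep]
  y <- log10(freq[keep] / sum(freq))
  fit <- stats::lm(y ~ x)
  list(r2 = summary(fit)$r.squared, degenerate = FALSE)
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat(sprintf("Soft-threshold scan (target R^2 = %g): chosen power = %d\n",
              x$target_r2, x$chosen_power))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Weighted co-expression adjacency matrix
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^power`; signed adjacency
#' `a_ij = ((1 + cor)/2)^power`. The diagonal is stored as 1 (the
#' convention expected by [topological_overlap()]); connectivity-based
#' computations exclude it.
#'
#' @param expr genes x samples numeric matrix.
#' @param power soft-thresholding power (>= 1).
#' @param signed use the signed transform (default FALSE).
#' @return symmetric genes x genes matrix in [0, 1] with unit diagonal.
#' @export
adjacency_matrix <- function(expr, power, signed = FALSE) {
  .check_expression(expr)
  .check_number(power, "power", lower = 1)
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0))
    .stopf("zero-variance gene(s): %s",
           paste(rownames(expr)[v == 0], collapse = ", "))
  cc <- stats::cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over third parties `u != i, j` and connectivity `k_i` excluding
#' the diagonal. The diagonal is set to 1 by convention.
#'
#' @param adjacency symmetric matrix in [0, 1] (diagonal ignored).
#' @param tol asymmetry tolerance (default 1e-10).
#' @return symmetric matrix in [0, 1] with unit diagonal.
#' @export
topological_overlap <- function(adjacency, tol = 1e-10) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    .stopf("'adjacency' must be a square matrix")
  if (max(abs(adjacency - t(adjacency))) > tol)
    .stopf("'adjacency' is asymmetric beyond tolerance %g", tol)
  if (min(adjacency) < -tol || max(adjacency) > 1 + tol)
    .stopf("'adjacency' values must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a                       # sum over u != i, j since diag(a) = 0
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules by static tree cut on 1 - TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height. Clusters smaller than `min_module_size` are
#' assigned label 0 (unassigned); surviving modules are relabeled 1, 2, ...
#' in decreasing size order (ties by first gene position, so labels are
#' deterministic).
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @param min_module_size smallest retained module (default 30, >= 2).
#' @param cut_height static cut height on the 1 - TOM dendrogram
#'   (default 0.95; most gene pairs have near-zero topological overlap, so
#'   the gene tree lives close to height 1 and meaningful merges happen
#'   just below it).
#' @return object of class `module_assignment`: named integer vector
#'   `labels` plus placeholders for eigengenes/membership filled by
#'   [module_eigengene_and_membership()].
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.95) {
  if (min_module_size < 2) .stopf("'min_module_size' must be >= 2")
  .check_number(cut_height, "cut_height", lower = 0, upper = 2)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  names(labels) <- rownames(tom)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  }
  structure(list(labels = labels, eigengenes = NULL, membership = NULL,
                 cut_height = cut_height, min_module_size = min_module_size),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Module assignment: %d genes, %d module(s), %d unassigned\n",
              length(x$labels), sum(names(tab) != "0"),
              if ("0" %in% names(tab)) tab[["0"]] else 0L))
  print(tab)
  if (!is.null(x$membership)) cat("kME membership computed\n")
  invisible(x)
}

#' Module eigengenes and module membership (kME)
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression across samples, scaled to unit length and
#' sign-oriented to correlate positively with the module's mean expression
#' profile. A gene's module membership kME is its correlation with its own
#' module's eigengene.
#'
#' @param expr genes x samples numeric matrix.
#' @param assignment `module_assignment` from [detect_modules()] (or built
#'   from known labels).
#' @return the assignment completed with `eigengenes` (module x sample
#'   matrix, unit-norm rows) and `membership` (named kME vector over
#'   assigned genes).
#' @export
module_eigengene_and_membership <- function(expr, assignment) {
  .check_expression(expr)
  stopifnot(inherits(assignment, "module_assignment"))
  labels <- assignment$labels
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) .stopf("assignment contains no modules")
  eig <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
                dimnames = list(paste0("ME", mods), colnames(expr)))
  kme <- stats::setNames(rep(NA_real_, sum(labels > 0)),
                         names(labels)[labels > 0])
  for (m in mods) {
    members <- names(labels)[labels == m]
    if (length(members) < 2L)
      .stopf("module %d has fewer than 2 genes", m)
    x <- t(expr[members, , drop = FALSE])      # samples x genes
    xs <- scale(x)
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    e <- pc$x[, 1L]
    if (stats::cor(e, rowMeans(x)) < 0) e <- -e
    e <- e / sqrt(sum(e^2))
    eig[paste0("ME", m), ] <- e
    kme[members] <- stats::cor(t(expr[members, , drop = FALSE]), e)[, 1L]
  }
  assignment$eigengenes <- eig
  assignment$membership <- kme
  assignment
}

#' Hub network of a module above a topological-overlap threshold
#'
#' Restricts a module to its `top_n` genes by intramodular connectivity
#' (row sums of TOM over the module, diagonal excluded), keeps edges with
#' TOM strictly above `tom_threshold`, and ranks genes by retained-edge
#' degree (hub genes first; ties broken by connectivity, then gene ID).
#'
#' @param tom topological overlap matrix.
#' @param assignment `module_assignment`.
#' @param module_id module label to extract.
#' @param top_n number of genes to keep (clamped to module size with a
#'   warning).
#' @param tom_threshold strict edge threshold (default 0.13).
#' @return list with `edges` (data.frame `gene_a`, `gene_b`, `tom`) and
#'   `ranking` (data.frame `gene`, `degree`, `connectivity`, hubs first).
#' @export
hub_network <- function(tom, assignment, module_id, top_n,
                        tom_threshold = 0.13) {
  stopifnot(inherits(assignment, "module_assignment"))
  members <- names(assignment$labels)[assignment$labels == module_id]
  if (!length(members)) .stopf("module %s does not exist", module_id)
  if (top_n > length(members)) {
    .warnf("top_n = %d exceeds module size %d; clamped", top_n,
           length(members))
    top_n <- length(members)
  }
  sub <- tom[members, members, drop = FALSE]
  diag(sub) <- 0
  conn <- rowSums(sub)
  keep <- members[order(-conn, members)][seq_len(top_n)]
  sub <- sub[keep, keep, drop = FALSE]
  idx <- which(upper.tri(sub) & sub > tom_threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = keep[idx[, 1L]], gene_b = keep[idx[, 2L]],
                      tom = sub[idx], row.names = NULL)
  degree <- stats::setNames(integer(length(keep)), keep)
  if (nrow(edges)) {
    tab <- table(c(edges$gene_a, edges$gene_b))
    degree[names(tab)] <- as.integer(tab)
  }
  ranking <- data.frame(gene = keep, degree = degree[keep],
                        connectivity = conn[keep], row.names = NULL)
  ranking <- ranking[order(-ranking$degree, -ranking$connectivity,
                           ranking$gene), ]
  rownames(ranking) <- NULL
  list(edges = edges, ranking = ranking, threshold = tom_threshold)
}
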