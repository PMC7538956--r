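#' Paired differential-expression test
#'
#' Per-gene paired t test between two replicate-matched groups of
#' log2-scale expression columns; pairing follows column order. Returns
#' one record per gene with the log2 fold change (mean paired difference)
#' and the paired-t p-value, ready for [de_filter()].
#'
#' @param case,control genes x replicates matrices with equal dimensions
#'   and matching gene rownames; replicate i of `case` is paired with
#'   replicate i of `control`.
#' @return data.frame `gene`, `log2_fold_change`, `p_value`.
#' @export
paired_de <- function(case, control) {
  if (!all(dim(case) == dim(control)))
    .stopf("'case' and 'control' must have identical dimensions")
  if (!identical(rownames(case), rownames(control)))
    .stopf("gene rownames must match between groups")
  if (ncol(case) < 2L) .stopf("need >= 2 replicate pairs")
  d <- case - control
  lfc <- rowMeans(d)
  se <- apply(d, 1L, stats::sd) / sqrt(ncol(d))
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = ncol(d) - 1L)
  data.frame(gene = rownames(case), log2_fold_change = lfc, p_value = p,
             row.names = NULL)
}

#' Differential-expression filter
#'
#' Keeps genes with `|log2 fold change| > lfc_cutoff` AND
#' `p < p_cutoff`, both strict (a record exactly at either boundary
#' fails). Records with a missing p-value are skipped with a log message.
#'
#' @param records data.frame with columns `gene`, `log2_fold_change`,
#'   `p_value` (e.g. from [paired_de()]).
#' @param lfc_cutoff default 0.263.
#' @param p_cutoff default 0.05.
#' @return list with `up` and `down` (passing gene IDs split by fold-change
#'   sign) and `records` (input annotated with a logical `passes` column).
#' @export
de_filter <- function(records, lfc_cutoff = 0.263, p_cutoff = 0.05) {
  need <- c("gene", "log2_fold_change", "p_value")
  if (!all(need %in% names(records)))
    .stopf("records need columns %s", paste(need, collapse = ", "))
  na_p <- is.na(records$p_value)
  if (any(na_p)) {
    .msgf("skipping %d record(s) with missing p-value", sum(na_p))
    records <- records[!na_p, , drop = FALSE]
  }
  records$passes <- abs(records$log2_fold_change) > lfc_cutoff &
    records$p_value < p_cutoff
  list(up = records$gene[records$passes & records$log2_fold_change > 0],
       down = records$gene[records$passes & records$log2_fold_change < 0],
       records = records)
}

#' Per-sample regulator activity score by PCA over target genes
#'
#' Standardizes the target genes and takes the principal component of the
#' sample x target submatrix that represents the regulator activation
#' state: PC1 unless its (orientation-checked) correlation with mean
#' target expression falls below `min_abs_cor` in magnitude, in which case
#' the top-correlating component is used. The score is sign-oriented to
#' correlate nonnegatively with the samples' mean target expression and
#' has zero mean.
#'
#' @param expr genes x samples numeric matrix.
#' @param target_genes gene IDs of the regulator's target signature.
#' @param min_abs_cor component-selection threshold (default 0.3).
#' @return object of class `activity_scores`: named per-sample `score`,
#'   `explained_variance_fraction`, `orientation_sign`, `pc_used`.
#' @export
activity_score <- function(expr, target_genes, min_abs_cor = 0.3) {
  .check_expression(expr)
  found <- intersect(target_genes, rownames(expr))
  if (length(found) < 2L)
    .stopf("fewer than 2 target genes found; missing: %s",
           paste(setdiff(target_genes, rownames(expr)), collapse = ", "))
  x <- t(expr[found, , drop = FALSE])       # samples x targets
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    .msgf("dropping %d constant target gene(s)", sum(v == 0))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2L) .stopf("fewer than 2 variable target genes")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  mean_expr <- rowMeans(x)
  cors <- suppressWarnings(stats::cor(pc$x, mean_expr))[, 1L]
  cors[is.na(cors)] <- 0
  use <- if (abs(cors[1L]) >= min_abs_cor) 1L else which.max(abs(cors))
  s <- if (cors[use] < 0) -1 else 1
  score <- s * pc$x[, use]
  evf <- pc$sdev[use]^2 / sum(pc$sdev^2)
  structure(list(score = score, explained_variance_fraction = evf,
                 orientation_sign = s, pc_used = as.integer(use)),
            class = "activity_scores")
}

#' @export
print.activity_scores <- function(x, ...) {
  cat(sprintf(
    "Activity scores: %d samples, PC%d, %.1f%% variance, orientation %+d\n",
    length(x$score), x$pc_used, 100 * x$explained_variance_fraction,
    x$orientation_sign))
  invisible(x)
}

#' Two-group patient stratification by 1-D k-means
#'
#' k = 2 clustering of the activity scores with 10 seeded k-means restarts;
#' the best within-cluster sum of squares is kept. Group1 is the cluster
#' with the higher mean score (higher predicted regulator activity).
#'
#' @param scores an `activity_scores` object or a named numeric vector.
#' @param seed integer seed.
#' @return named character vector of labels, `"Group1"` / `"Group2"`.
#' @export
kmeans_two_groups <- function(scores, seed = 1) {
  s <- if (inherits(scores, "activity_scores")) scores$score else scores
  if (length(s) < 4L) .stopf("need >= 4 samples")
  if (length(unique(s)) < 2L) .stopf("degenerate clustering: all scores identical")
  set.seed(seed)
  km <- stats::kmeans(matrix(s, ncol = 1L), centers = 2L, nstart = 10L)
  g1 <- which.max(km$centers[, 1L])
  labels <- ifelse(km$cluster == g1, "Group1", "Group2")
  names(labels) <- names(s)
  labels
}
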