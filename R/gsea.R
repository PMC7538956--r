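#' Rank genes between two sample groups
#'
#' Default metric: log2 ratio of group means computed on positive-shifted
#' data (if the global minimum is <= 0, the whole matrix is shifted by
#' |min| + 1 so the ratio is defined). Genes are ordered by decreasing
#' metric; ties are broken deterministically by ascending gene ID.
#'
#' @param expr genes x samples numeric matrix.
#' @param group_a,group_b disjoint character vectors of sample IDs.
#' @param metric `"log2_ratio"` (default) or `"diff_means"`.
#' @return object of class `ranked_list`: data.frame `gene`, `metric`,
#'   strictly ordered.
#' @export
rank_genes <- function(expr, group_a, group_b,
                       metric = c("log2_ratio", "diff_means")) {
  .check_expression(expr)
  metric <- match.arg(metric)
  if (length(intersect(group_a, group_b)))
    .stopf("groups overlap: %s",
           paste(intersect(group_a, group_b), collapse = ", "))
  if (!all(c(group_a, group_b) %in% colnames(expr)))
    .stopf("unknown sample IDs: %s",
           paste(setdiff(c(group_a, group_b), colnames(expr)),
                 collapse = ", "))
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (metric == "log2_ratio") {
    mn <- min(expr[, c(group_a, group_b)])
    shift <- if (mn <= 0) abs(mn) + 1 else 0
    m <- log2((rowMeans(a) + shift) / (rowMeans(b) + shift))
  } else {
    m <- rowMeans(a) - rowMeans(b)
  }
  ord <- order(-m, rownames(expr))
  structure(data.frame(gene = rownames(expr)[ord], metric = m[ord],
                       row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: genes in the set increment the running sum by
#' `|metric|^weight_p` normalized to the in-set total; genes outside
#' decrement by `1/(N - N_hit)`. The enrichment score is the running-sum
#' value of maximal magnitude. If all in-set metric weights are zero the
#' hit increments fall back to the unweighted `1/N_hit` step.
#'
#' @param ranked `ranked_list` from [rank_genes()] (or any data.frame with
#'   `gene` and `metric` in ranked order).
#' @param gene_set character vector of member gene IDs.
#' @param weight_p metric exponent (default 1).
#' @return list with `es`, `running_profile` (length N + 1, starting and
#'   ending at 0 when misses exist), and `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "metric") %in% names(ranked)))
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) .stopf("no overlap between gene set and ranked list")
  n <- nrow(ranked)
  nh <- sum(hit)
  w <- abs(ranked$metric)^weight_p
  nr <- sum(w[hit])
  delta <- numeric(n)
  delta[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  if (n > nh) delta[!hit] <- -1 / (n - nh)
  run <- cumsum(delta)
  i <- which.max(abs(run))
  es <- run[i]
  leading <- if (es >= 0) ranked$gene[seq_len(i)][hit[seq_len(i)]]
             else ranked$gene[i:n][hit[i:n]]
  list(es = es, running_profile = c(0, run), leading_edge = leading)
}

# Fast ES for permutations: positions of the hits in a ranked list with
# precomputed weights. Returns the signed maximal deviation only.
.es_at <- function(pos, w, n) {
  delta <- numeric(n)
  nr <- sum(w[pos])
  nh <- length(pos)
  delta[pos] <- if (nr > 0) w[pos] / nr else 1 / nh
  if (n > nh) delta[-pos] <- delta[-pos] - 1 / (n - nh)
  run <- cumsum(delta)
  run[which.max(abs(run))]
}

#' Permutation-normalized enrichment score with nominal P and FDR q
#'
#' Gene-label permutations: `n_perm` random same-size gene sets are drawn
#' from the ranked list and scored. `NES = ES / mean(same-sign permuted
#' ES)` (sign preserved); the nominal P is the fraction of same-sign
#' permuted ES at least as extreme as the observed ES; the FDR q compares
#' the observed NES against the same-sign permuted NES distribution. All
#' randomness flows from `seed`.
#'
#' @param ranked `ranked_list`.
#' @param gene_set character vector of member gene IDs.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param weight_p metric exponent (default 1).
#' @return object of class `gsea_result` with fields `es`, `nes`,
#'   `nominal_p`, `fdr_q`, `running_profile`, `leading_edge`, `n_perm`.
#' @export
normalize_and_test <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                               weight_p = 1) {
  if (n_perm < 100) .stopf("'n_perm' must be >= 100")
  obs <- enrichment_score(ranked, gene_set, weight_p)
  n <- nrow(ranked)
  nh <- sum(ranked$gene %in% gene_set)
  w <- abs(ranked$metric)^weight_p
  set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) .es_at(sample.int(n, nh), w, n), numeric(1))
  same <- perm[sign(perm) == sign(obs$es)]
  if (!length(same)) {
    .warnf("no same-sign permuted ES; q reported as 0")
    nes <- obs$es
    p <- 0
    q <- 0
  } else {
    denom <- abs(mean(same))
    nes <- obs$es / denom
    p <- mean(abs(same) >= abs(obs$es))
    nes_perm <- same / denom
    q <- min(1, mean(abs(nes_perm) >= abs(nes)))
  }
  structure(list(es = obs$es, nes = nes, nominal_p = p, fdr_q = q,
                 running_profile = obs$running_profile,
                 leading_edge = obs$leading_edge,
                 n_perm = n_perm, n_genes = n, set_size = nh),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "GSEA: ES = %.3f, NES = %.3f, nominal P = %.4g, FDR q = %.4g\n",
    x$es, x$nes, x$nominal_p, x$fdr_q))
  cat(sprintf("  %d-gene set in %d ranked genes, %d permutations, %d",
              x$set_size, x$n_genes, x$n_perm, length(x$leading_edge)),
      "leading-edge gene(s)\n")
  invisible(x)
}

#' @export
plot.gsea_result <- function(x, ...) {
  graphics::plot(seq_along(x$running_profile) - 1L, x$running_profile,
                 type = "l", xlab = "rank", ylab = "running ES",
                 main = sprintf("ES = %.3f, NES = %.3f", x$es, x$nes), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
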