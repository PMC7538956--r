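#' Right-tailed Fisher (hypergeometric) enrichment test
#'
#' Upper-tail probability of drawing at least the observed overlap between
#' a query gene list and an annotation term from a finite universe. The
#' term is intersected with the universe before testing.
#'
#' @param query character vector of gene IDs (must lie in `universe`).
#' @param term character vector of term member gene IDs.
#' @param universe character vector of all testable gene IDs.
#' @return list with `overlap`, `term_size`, `query_size`, `universe_size`,
#'   `fisher_p`.
#' @examples
#' u <- paste0("G", 1:10)
#' fisher_enrichment(u[1:5], u[1:5], u)$fisher_p  # 1/choose(10, 5)
#' @export
fisher_enrichment <- function(query, term, universe) {
  if (!length(universe)) .stopf("empty universe")
  if (!length(query)) .stopf("empty query")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    .stopf("query contains genes outside the universe: %s",
           paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  term <- intersect(unique(term), universe)
  k <- length(intersect(query, term))
  p <- stats::phyper(k - 1, m = length(term),
                     n = length(universe) - length(term),
                     k = length(query), lower.tail = FALSE)
  list(overlap = k, term_size = length(term), query_size = length(query),
       universe_size = length(universe), fisher_p = p)
}

#' Per-module annotation enrichment and focus-module selection
#'
#' Tests every detected module against every annotation gene set with the
#' right-tailed Fisher exact test. The focus ("malignancy") module of a
#' run is the one with the strongest single-term enrichment — the
#' programmatic counterpart of choosing the module whose annotation
#' profile marks it as the disease-relevant one.
#'
#' @param assignment `module_assignment`.
#' @param annotations named list of annotation gene sets.
#' @param universe gene universe for the tests (default: all assigned and
#'   unassigned genes in the assignment).
#' @return list with `table` (data.frame `module`, `term`, `overlap`,
#'   `fisher_p`) and `focus_module` (label of the best-enriched module).
#' @export
module_enrichment <- function(assignment, annotations,
                              universe = names(assignment$labels)) {
  stopifnot(inherits(assignment, "module_assignment"))
  mods <- sort(unique(assignment$labels[assignment$labels > 0]))
  if (!length(mods)) .stopf("assignment contains no modules")
  rows <- list()
  for (m in mods) {
    genes <- names(assignment$labels)[assignment$labels == m]
    for (tn in names(annotations)) {
      fe <- fisher_enrichment(genes, annotations[[tn]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, term = tn, overlap = fe$overlap, fisher_p = fe$fisher_p)
    }
  }
  tab <- do.call(rbind, rows)
  best <- tab$module[which.min(tab$fisher_p)]
  list(table = tab, focus_module = best)
}

#' Direction-aware activation z-score
#'
#' Measures agreement between the observed regulation direction of a
#' regulator's targets and the direction expected if the regulator were
#' active: `z = sum(w_i * x_i) / sqrt(sum(w_i^2))` where `x_i = +1` when
#' observed and expected directions match and `-1` otherwise. With unit
#' weights and N consistent targets, z = sqrt(N).
#'
#' @param observed named or plain vector of observed directions in
#'   \{+1, -1\} (one per target).
#' @param expected expected directions under activation, same length.
#' @param weights nonnegative per-target weights (default unit).
#' @return the activation z-score (a single real).
#' @export
activation_zscore <- function(observed, expected,
                              weights = rep(1, length(observed))) {
  if (length(observed) != length(expected) ||
      length(observed) != length(weights))
    .stopf("'observed', 'expected' and 'weights' must have equal length")
  if (!all(observed %in% c(-1, 1)) || !all(expected %in% c(-1, 1)))
    .stopf("directions must be +1 or -1")
  if (any(weights < 0)) .stopf("weights must be nonnegative")
  if (sum(weights^2) == 0) .stopf("all weights are zero")
  x <- observed * expected
  sum(weights * x) / sqrt(sum(weights^2))
}

#' Rank candidate upstream regulators of a module
#'
#' For every regulator in the signed network with at least `min_targets`
#' targets inside the module, computes (i) a right-tailed Fisher p for the
#' overlap of its target set with the module, (ii) a module-level
#' activation z-score using |kME| as weights and the kME sign as each
#' gene's observed direction, (iii) per-annotation activation z-scores over
#' its in-module targets falling in each annotation set, and (iv) a summary
#' score equal to the sum of activation z-scores over linked annotation
#' nodes. Regulators are ranked by summary score (descending), ties broken
#' by Fisher p (ascending) then lexical ID.
#'
#' @param assignment `module_assignment` with membership (kME) computed.
#' @param module_id module label whose regulators are sought.
#' @param network data.frame with columns `regulator`, `target`, `sign`
#'   (+1 activation, -1 repression).
#' @param annotations named list of character vectors (annotation gene
#'   sets).
#' @param min_targets minimum in-module targets for a regulator to be
#'   scored (default 3).
#' @return object of class `regulator_ranking`: data.frame with columns
#'   `regulator`, `n_targets`, `overlap_p`, `module_z`, `summary_score`,
#'   `rank`, plus attribute `annotation_z` (regulator x annotation matrix).
#' @export
rank_upstream_regulators <- function(assignment, module_id, network,
                                     annotations, min_targets = 3) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (is.null(assignment$membership))
    .stopf("assignment lacks kME membership; run ",
           "module_eigengene_and_membership() first")
  .validate_network(network)
  module_genes <- names(assignment$labels)[assignment$labels == module_id]
  if (!length(module_genes)) .stopf("module %s does not exist", module_id)
  universe <- names(assignment$labels)
  kme <- assignment$membership

  regs <- sort(unique(network$regulator))
  rows <- list()
  ann_z <- matrix(NA_real_, nrow = 0, ncol = length(annotations),
                  dimnames = list(NULL, names(annotations)))
  for (r in regs) {
    sub <- network[network$regulator == r, , drop = FALSE]
    in_mod <- sub[sub$target %in% module_genes, , drop = FALSE]
    in_mod <- in_mod[in_mod$target %in% names(kme), , drop = FALSE]
    if (nrow(in_mod) < min_targets) {
      .msgf("regulator %s excluded: %d in-module target(s) < %d",
            r, nrow(in_mod), min_targets)
      next
    }
    w <- abs(kme[in_mod$target])
    obs <- sign(kme[in_mod$target])
    obs[obs == 0] <- 1
    fp <- fisher_enrichment(intersect(sub$target, universe), module_genes,
                            universe)$fisher_p
    mz <- activation_zscore(obs, in_mod$sign, w)
    az <- vapply(annotations, function(set) {
      i <- in_mod$target %in% set
      if (!any(i)) return(NA_real_)
      activation_zscore(obs[i], in_mod$sign[i], w[i])
    }, numeric(1))
    rows[[r]] <- data.frame(regulator = r, n_targets = nrow(in_mod),
                            overlap_p = fp, module_z = mz,
                            summary_score = sum(az, na.rm = TRUE))
    ann_z <- rbind(ann_z, az)
    rownames(ann_z)[nrow(ann_z)] <- r
  }
  if (!length(rows)) .stopf("no regulator has >= %d in-module targets",
                            min_targets)
  tab <- do.call(rbind, rows)
  ord <- order(-tab$summary_score, tab$overlap_p, tab$regulator)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, annotation_z = ann_z[tab$regulator, , drop = FALSE],
            class = c("regulator_ranking", "data.frame"))
}

.validate_network <- function(network) {
  need <- c("regulator", "target", "sign")
  if (!is.data.frame(network) || !all(need %in% names(network)))
    .stopf("network needs columns regulator, target, sign")
  if (!all(network$sign %in% c(-1, 1)))
    .stopf("network signs must be +1 or -1")
  if (anyDuplicated(network[c("regulator", "target")]))
    .stopf("duplicate (regulator, target) pairs in network")
  invisible(network)
}

#' @export
print.regulator_ranking <- function(x, ...) {
  cat("Upstream regulator ranking (summary score = sum of activation",
      "z-scores over linked annotations)\n")
  print.data.frame(utils::head(x, 10L), row.names = FALSE, ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Combined enrichment score
#'
#' `c = log(P) * z` on the natural-log scale: the product of the log Fisher
#' exact p-value and a z-score measuring the deviation of the term's rank
#' from its expected rank under random queries (see
#' [enrichment_with_combined_score()]). Reported signed; an enriched term
#' (small p, better-than-expected rank, negative z) gets a positive score.
#'
#' @param fisher_p Fisher exact p in (0, 1] (0 is clamped to the smallest
#'   positive double with a warning).
#' @param rank_z rank-deviation z-score.
#' @return the combined score.
#' @export
combined_score <- function(fisher_p, rank_z) {
  if (any(fisher_p < 0) || any(fisher_p > 1))
    .stopf("'fisher_p' must lie in (0, 1]")
  if (any(fisher_p == 0)) {
    .warnf("p = 0 clamped to %g", .Machine$double.xmin)
    fisher_p[fisher_p == 0] <- .Machine$double.xmin
  }
  log(fisher_p) * rank_z
}

#' Term enrichment with rank-deviation combined scores
#'
#' Computes the Fisher exact p of each term for the query, then calibrates
#' each term's p-value rank against an ensemble of `n_random` seeded random
#' queries of the same size: `rank_z = (observed rank - mean null rank) /
#' sd(null rank)`, and `combined = log(p) * rank_z`. Over the null ensemble
#' itself, rank_z has mean ~0 and sd ~1 for every term.
#'
#' @param query character vector of gene IDs.
#' @param terms named list of term gene sets.
#' @param universe all testable gene IDs.
#' @param n_random size of the random-query ensemble (default 100).
#' @param seed integer seed for the ensemble.
#' @return data.frame with columns `term`, `overlap`, `fisher_p`, `rank_z`,
#'   `combined_score`, ordered by combined score (descending).
#' @export
enrichment_with_combined_score <- function(query, terms, universe,
                                           n_random = 100, seed = 1) {
  if (!length(terms)) .stopf("no terms supplied")
  .check_count(n_random, "n_random", min = 2L)
  ps <- vapply(terms, function(tm)
    fisher_enrichment(query, tm, universe)$fisher_p, numeric(1))
  ov <- vapply(terms, function(tm)
    length(intersect(intersect(unique(tm), universe), unique(query))),
    integer(1))
  obs_rank <- rank(ps, ties.method = "average")
  set.seed(seed)
  null_ranks <- matrix(NA_real_, nrow = n_random, ncol = length(terms))
  for (b in seq_len(n_random)) {
    q <- sample(universe, length(unique(query)))
    pb <- vapply(terms, function(tm)
      fisher_enrichment(q, tm, universe)$fisher_p, numeric(1))
    null_ranks[b, ] <- rank(pb, ties.method = "average")
  }
  mu <- colMeans(null_ranks)
  sd0 <- apply(null_ranks, 2L, stats::sd)
  sd0[sd0 == 0] <- NA_real_
  z <- (obs_rank - mu) / sd0
  out <- data.frame(term = names(terms), overlap = ov, fisher_p = ps,
                    rank_z = z,
                    combined_score = combined_score(ps, z),
                    row.names = NULL)
  out[order(-out$combined_score, out$fisher_p, out$term), ]
}

#' Promoter-window direct-target calling from binding peaks
#'
#' A gene is a direct target when at least one binding peak overlaps its
#' strand-aware promoter window (default TSS - 5 kb to TSS + 1 kb on the
#' plus strand, mirrored on the minus strand) and the gene is
#' differentially expressed. Peaks follow BED semantics: 0-based,
#' half-open `[start, end)`.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param tss data.frame with columns `gene`, `chrom`, `pos`, `strand`
#'   ("+" or "-").
#' @param de_genes character vector of differentially expressed gene IDs.
#' @param upstream window extent upstream of the TSS (default 5000).
#' @param downstream window extent downstream of the TSS (default 1000).
#' @return sorted character vector of direct-target gene IDs.
#' @export
promoter_peak_targets <- function(peaks, tss, de_genes,
                                  upstream = 5000, downstream = 1000) {
  need <- c("gene", "chrom", "pos", "strand")
  if (!all(need %in% names(tss)))
    .stopf("tss needs columns gene, chrom, pos, strand")
  if (!all(tss$strand %in% c("+", "-")))
    .stopf("unknown strand symbol: %s",
           paste(unique(setdiff(tss$strand, c("+", "-"))), collapse = ", "))
  if (any(peaks$start < 0) || any(tss$pos < 0))
    .stopf("coordinates must be nonnegative")
  if (!nrow(peaks) || !length(de_genes)) return(character(0))
  win_start <- ifelse(tss$strand == "+", tss$pos - upstream,
                      tss$pos - downstream)
  win_end <- ifelse(tss$strand == "+", tss$pos + downstream,
                    tss$pos + upstream)
  windows <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = pmax(win_start, 0) + 1, end = win_end + 1))
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  hit <- GenomicRanges::countOverlaps(windows, pk) > 0
  sort(intersect(tss$gene[hit], de_genes))
}
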