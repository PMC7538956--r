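# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV (genes in rows), GMT gene-set collections, BED peak
# intervals, TSS tables, survival/probe/dose CSVs. UTF-8 throughout, no
# quoting in identifiers, empty field = missing.

#' Read a genes x samples expression matrix from TSV
#'
#' First column = gene IDs, header = sample IDs, tab-separated. Duplicate
#' gene IDs and non-numeric values are hard errors naming the offender.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) .stopf("expression TSV needs gene IDs plus >= 1 sample")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    .stopf("duplicate gene IDs: %s",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals == "" | is.na(vals)), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-numeric value '%s' at gene %s, sample %s",
           vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
           colnames(vals)[bad[1L, 2L]])
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write an expression matrix as TSV (genes in rows)
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  .check_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then members. Lines with fewer than three fields are
#' parse errors (reported with their line number); duplicate members are
#' dropped with a log entry; an empty file yields an empty collection with
#' a warning.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    .warnf("empty GMT file: %s", path)
    return(structure(list(), descriptions = character(0)))
  }
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .stopf("GMT parse error at line %d: fewer than 3 fields", i)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      .stopf("GMT parse error at line %d: empty member list", i)
    if (anyDuplicated(members)) {
      .msgf("line %d ('%s'): %d duplicate member(s) removed", i, f[1L],
            sum(duplicated(members)))
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
    desc[f[1L]] <- f[2L]
  }
  structure(sets, descriptions = desc)
}

#' Read a BED3+ interval file
#'
#' 0-based half-open intervals: `[start, end)` covers positions
#' `start .. end - 1`. Malformed coordinates and `end <= start` are parse
#' errors reported with their line number.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) return(data.frame(chrom = character(0),
                                        start = numeric(0), end = numeric(0)))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .stopf("BED parse error at line %d: fewer than 3 fields", i)
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      .stopf("BED parse error at line %d: malformed coordinate", i)
    if (e <= s)
      .stopf("BED parse error at line %d: end <= start", i)
    data.frame(chrom = f[1L], start = s, end = e,
               name = if (length(f) >= 4L) f[4L] else NA_character_)
  })
  do.call(rbind, rows)
}

#' Read a TSS table (TSV: gene, chrom, pos, strand)
#' @param path file path.
#' @return data.frame `gene`, `chrom`, `pos`, `strand`.
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("gene", "chrom", "pos", "strand")
  if (!all(need %in% names(df)))
    .stopf("TSS table needs columns %s", paste(need, collapse = ", "))
  df
}

#' Read a survival CSV (sample_id, time, event)
#' @param path file path.
#' @return data.frame validated for the survival stage.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path)
  .check_survival(df)
  df
}

#' Pipeline configuration with the study's default thresholds
#'
#' Collects every stage toggle and tunable in one validated list. Defaults:
#' TOM hub threshold 0.13, DE cut-offs |log2FC| > 0.263 and p < 0.05,
#' adjacency power 6 (the unsigned-network convention; set `power = NULL`
#' to adopt the scale-free scan's choice instead), soft-threshold grid
#' 1..20 with scale-free target R^2 0.8, minimum module size 30, 1000 GSEA
#' permutations with weight 1. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above (e.g.
#'   `sim = simulation_config(...)`, `out_dir = "results"`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # stage toggles
    simulate = TRUE, modules = TRUE, upstream = TRUE, gsea = TRUE,
    stratify = TRUE, survive = TRUE, cna = TRUE, synergy = TRUE,
    # inputs (used when simulate = FALSE)
    expression_path = NULL, network_path = NULL, gmt_path = NULL,
    survival_path = NULL, probe_path = NULL, dose_path = NULL,
    # parameters
    sim = simulation_config(),
    power = 6, powers = 1:20, target_r2 = 0.8, cut_height = 0.95,
    min_module_size = 30, tom_hub_threshold = 0.13, hub_top_n = 59,
    gsea_permutations = 1000, gsea_weight = 1, gsea_seed = 1,
    lfc_cutoff = 0.263, p_cutoff = 0.05,
    kmeans_seed = 1, cna_penalty = NULL, min_targets = 3,
    out_dir = "malmod_run"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    .stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end discovery pipeline
#'
#' Executes the enabled stages in dependency order: simulate (or load
#' inputs), co-expression modules, upstream regulator ranking, GSEA of the
#' detected module in high- vs low-activity samples, activity
#' stratification, survival comparison of the two groups, copy-number
#' amplification calls, and drug-synergy analysis. Per-stage tables are
#' written as TSV/CSV under `config$out_dir`, together with a
#' `run_log.json` recording the resolved configuration and seeds;
#' re-running with an identical configuration reproduces every output
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if (config$simulate) {
    cohort <- generate_cohort(config$sim)
    expr <- cohort$expr
    truth <- cohort$truth
    network <- generate_regulator_network(truth, seed = config$sim$seed)
    annotations <- generate_annotations(truth, rownames(expr),
                                        seed = config$sim$seed)
    surv_tab <- generate_survival(truth$activity, config$sim)
    cna_data <- generate_cna_profiles(config$sim, truth)
    dose <- generate_dose_response(config$sim)
    write_expression(expr, file.path(config$out_dir, "expression.tsv"))
    res$truth <- truth
  } else {
    if (is.null(config$expression_path))
      .stopf("missing upstream artifact: expression_path")
    expr <- read_expression(config$expression_path)
    truth <- NULL
    network <- if (!is.null(config$network_path))
      utils::read.delim(config$network_path) else NULL
    annotations <- if (!is.null(config$gmt_path))
      read_gmt(config$gmt_path) else NULL
    surv_tab <- if (!is.null(config$survival_path))
      read_survival(config$survival_path) else NULL
    cna_data <- NULL
    if (config$cna) {
      if (is.null(config$probe_path))
        .stopf("missing upstream artifact: probe_path (CNA stage enabled)")
      probes <- utils::read.csv(config$probe_path)
      cna_data <- list(probes = probes[c("probe_id", "chrom", "pos")],
                       values = as.matrix(probes[, -(1:3), drop = FALSE]),
                       locus = NULL)
    }
    dose <- NULL
    if (config$synergy) {
      if (is.null(config$dose_path))
        .stopf("missing upstream artifact: dose_path (synergy stage enabled)")
    }
  }

  assignment <- NULL
  if (config$modules) {
    sft <- pick_soft_threshold(expr, config$powers, config$target_r2)
    power <- if (is.null(config$power)) sft$chosen_power else config$power
    adj <- adjacency_matrix(.filter_expression(expr, quiet = TRUE), power)
    tom <- topological_overlap(adj)
    assignment <- detect_modules(tom, config$min_module_size,
                                 config$cut_height)
    assignment <- module_eigengene_and_membership(expr, assignment)
    utils::write.table(
      data.frame(gene = names(assignment$labels),
                 module = assignment$labels,
                 kME = assignment$membership[names(assignment$labels)]),
      file.path(config$out_dir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res$soft_threshold <- sft
    res$assignment <- assignment
  }

  # focus module: the annotation-enriched one (the malignancy module of
  # the run); falls back to the largest module without annotations
  focus <- 1L
  if (!is.null(assignment) && !is.null(annotations)) {
    me <- module_enrichment(assignment, annotations)
    focus <- me$focus_module
    utils::write.table(me$table,
                       file.path(config$out_dir, "module_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$module_enrichment <- me
  }
  if (config$modules) {
    hub <- hub_network(tom, assignment, module_id = focus,
                       top_n = min(config$hub_top_n,
                                   sum(assignment$labels == focus)),
                       tom_threshold = config$tom_hub_threshold)
    utils::write.table(hub$edges,
                       file.path(config$out_dir, "hub_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$hub <- hub
  }

  if (config$upstream) {
    if (is.null(assignment))
      .stopf("missing upstream artifact: module assignment (enable 'modules')")
    if (is.null(network) || is.null(annotations))
      .stopf("missing upstream artifact: regulator network / annotations")
    ranking <- rank_upstream_regulators(assignment, focus, network,
                                        annotations, config$min_targets)
    utils::write.table(as.data.frame(ranking),
                       file.path(config$out_dir, "upstream_regulators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$upstream <- ranking
  }

  scores <- NULL
  groups <- NULL
  if (config$stratify || config$gsea) {
    if (is.null(assignment))
      .stopf("missing upstream artifact: module assignment (enable 'modules')")
    module_genes <- names(assignment$labels)[assignment$labels == focus]
    scores <- activity_score(expr, module_genes)
    groups <- kmeans_two_groups(scores, seed = config$kmeans_seed)
    utils::write.table(
      data.frame(sample_id = names(scores$score), score = scores$score,
                 group = groups),
      file.path(config$out_dir, "activity_groups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res$activity <- scores
    res$groups <- groups
  }

  if (config$gsea) {
    ranked <- rank_genes(expr, names(groups)[groups == "Group1"],
                         names(groups)[groups == "Group2"])
    module_genes <- names(assignment$labels)[assignment$labels == focus]
    gres <- normalize_and_test(ranked, module_genes,
                               n_perm = config$gsea_permutations,
                               seed = config$gsea_seed,
                               weight_p = config$gsea_weight)
    writeLines(jsonlite::toJSON(
      list(es = gres$es, nes = gres$nes, nominal_p = gres$nominal_p,
           fdr_q = gres$fdr_q), auto_unbox = TRUE, digits = NA),
      file.path(config$out_dir, "gsea.json"))
    res$gsea <- gres
  }

  if (config$survive) {
    if (is.null(surv_tab))
      .stopf("missing upstream artifact: survival records")
    if (is.null(groups))
      .stopf("missing upstream artifact: activity groups (enable 'stratify')")
    surv_tab$group <- groups[surv_tab$sample_id]
    lr <- logrank_test(surv_tab)
    utils::write.table(surv_tab,
                       file.path(config$out_dir, "survival_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$logrank <- lr
    res$km <- lapply(split(surv_tab, surv_tab$group), km_curve)
  }

  if (config$cna) {
    if (is.null(cna_data))
      .stopf("missing upstream artifact: probe tracks (CNA stage enabled)")
    calls <- vapply(colnames(cna_data$values), function(s) {
      track <- data.frame(chrom = cna_data$probes$chrom,
                          pos = cna_data$probes$pos,
                          value = cna_data$values[, s])
      segs <- segment_profile(track, config$cna_penalty)
      if (is.null(cna_data$locus)) "uncalled"
      else amplification_call(segs, cna_data$locus)
    }, character(1))
    utils::write.table(
      data.frame(sample_id = names(calls), call = calls),
      file.path(config$out_dir, "amplification_calls.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res$amplification <- calls
  }

  if (config$synergy) {
    if (is.null(dose)) {
      dtab <- utils::read.csv(config$dose_path)
      single_a <- dtab[dtab$dose_b == 0, ]
      single_b <- dtab[dtab$dose_a == 0, ]
      combo <- dtab[dtab$dose_a > 0 & dtab$dose_b > 0, ]
      fit_a <- fit_median_effect(single_a$dose_a, single_a$viability)
      fit_b <- fit_median_effect(single_b$dose_b, single_b$viability)
    } else {
      fit_a <- fit_median_effect(dose$single[[1L]]$dose,
                                 dose$single[[1L]]$viability)
      fit_b <- fit_median_effect(dose$single[[2L]]$dose,
                                 dose$single[[2L]]$viability)
      combo <- dose$combo
    }
    ci <- combination_index(fit_a, fit_b, combo)
    utils::write.table(ci, file.path(config$out_dir, "combination_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$synergy <- list(fit_a = fit_a, fit_b = fit_b, ci = ci)
  }

  log <- config
  class(log) <- NULL
  log$sim <- unclass(log$sim)
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE),
             file.path(config$out_dir, "run_log.json"))
  invisible(res)
}
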