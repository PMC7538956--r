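# Internal helpers shared across stages.

# One global seed fans out into fixed per-stage substreams so that any stage
# can be regenerated on its own. Offsets are arbitrary but fixed; results kept
# below 2^31 - 1 so they remain valid R integer seeds.
.stage_offsets <- c(
  cohort   = 101L,
  survival = 211L,
  cna      = 307L,
  dose     = 401L,
  network  = 503L,
  annot    = 601L
)

.substream <- function(seed, stage) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) * 1000 + off) %% (2^31 - 1))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.msgf <- function(fmt, ...) message(sprintf(fmt, ...))

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    .stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (if (strict_lower) x <= lower else x < lower)
    .stopf("'%s' must be %s %s", name, if (strict_lower) ">" else ">=", lower)
  if (if (strict_upper) x >= upper else x > upper)
    .stopf("'%s' must be %s %s", name, if (strict_upper) "<" else "<=", upper)
  invisible(x)
}

# Expression matrices are plain numeric matrices: genes in rows (rownames =
# gene IDs), samples in columns (colnames = sample IDs).
.check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    .stopf("expression must be a numeric genes x samples matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    .stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    .stopf("duplicate gene IDs: %s",
           paste(unique(rownames(expr)[duplicated(rownames(expr))]),
                 collapse = ", "))
  invisible(expr)
}

# Drop genes with missing values or zero variance; both violate the network
# stage's preconditions. Counts are reported, not silently swallowed.
.filter_expression <- function(expr, quiet = FALSE) {
  .check_expression(expr)
  has_na <- rowSums(is.na(expr)) > 0
  if (any(has_na)) {
    if (!quiet) .msgf("dropping %d gene(s) with missing values", sum(has_na))
    expr <- expr[!has_na, , drop = FALSE]
  }
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    if (!quiet) .msgf("dropping %d zero-variance gene(s)", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) == 0L) .stopf("no variable genes")
  expr
}
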