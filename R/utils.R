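# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a global seed; kept below 2^31.
derive_seed <- function(seed, stage_index) {
  (as.integer(seed) * 101L + as.integer(stage_index) * 7919L) %% 2147483647L
}

abort <- function(msg, class) {
  stop(structure(class = c(class, "abatime_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Column indices of samples matching a condition/timepoint (NULL = any).
sample_which <- function(em, condition = NULL, timepoint = NULL) {
  s <- em$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(condition)) keep <- keep & s$condition == condition
  if (!is.null(timepoint)) keep <- keep & s$timepoint_min == timepoint
  which(keep)
}

# Per-gene mean over a set of sample columns (matrix stays genes x samples).
row_group_means <- function(values, cols) {
  if (length(cols) == 1L) values[, cols] else rowMeans(values[, cols, drop = FALSE])
}

row_group_vars <- function(values, cols) {
  x <- values[, cols, drop = FALSE]
  n <- ncol(x)
  if (n < 2L) abort("need >= 2 replicates to compute a variance", "abatime_design_error")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
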