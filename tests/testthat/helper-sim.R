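# Shared fixture builders for the test suite.

# Small hand-built matrix: 2 conditions x 3 timepoints x n replicates with a
# deterministic replicate jitter (identical across genes) so within-group
# variances are exactly jitter_sd^2-scaled and group means are exact.
make_planted_matrix <- function(effects, baseline = 8, jitter = c(-0.01, 0, 0.01)) {
  tps <- c(30L, 60L, 180L)
  n_rep <- length(jitter)
  samples <- expand.grid(replicate = seq_len(n_rep), timepoint_min = tps,
                         condition = c("treated", "control"),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_t%03d_r%d",
                               substr(samples$condition, 1, 1),
                               samples$timepoint_min, samples$replicate)
  samples <- samples[c("sample_id", "condition", "timepoint_min", "replicate")]
  values <- matrix(0, nrow(effects), nrow(samples),
                   dimnames = list(rownames(effects), samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline + jitter[samples$replicate[j]]
    if (samples$condition[j] == "treated")
      mu <- mu + effects[, paste0("fc", samples$timepoint_min[j])]
    values[, j] <- mu
  }
  expression_matrix(values, samples)
}

planted_effects <- function(n_null = 5, n_resp = 5, fc = 2) {
  eff <- rbind(
    matrix(0, n_null, 3),
    matrix(rep(c(fc, fc, fc), each = n_resp), n_resp, 3)
  )
  dimnames(eff) <- list(sprintf("g%03d", seq_len(n_null + n_resp)),
                        c("fc30", "fc60", "fc180"))
  eff
}

# Random expression matrix with annotated samples, for IO round trips etc.
random_matrix <- function(n_genes = 20, n_rep = 2, seed = 42) {
  set.seed(seed)
  tps <- c(30L, 60L, 180L)
  samples <- expand.grid(replicate = seq_len(n_rep), timepoint_min = tps,
                         condition = c("treated", "control"),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("s%02d", seq_len(nrow(samples)))
  samples <- samples[c("sample_id", "condition", "timepoint_min", "replicate")]
  values <- matrix(rnorm(n_genes * nrow(samples), 8, 2), n_genes,
                   dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                                   samples$sample_id))
  expression_matrix(values, samples)
}
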