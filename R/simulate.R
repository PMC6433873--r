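#' Default log2 fold-change trajectories per response archetype
#'
#' Archetypes encode the temporal response classes observed in the early ABA
#' time course (30/60/180 min): genes induced immediately and maintained
#' (`early_sustained`), induced early but decayed by 180 min
#' (`early_transient`), transiently induced only at 60 min (`mid_transient`),
#' induced from 60 min onward (`mid_sustained`), induced only late
#' (`late_up`), and repressed only late (`late_down` — down-regulation was
#' observed only at 180 min).
#'
#' @return named list; each element is a numeric vector `c(fc30, fc60, fc180)`
#'   of log2 fold changes.
#' @export
default_archetype_effects <- function() {
  list(null           = c(0, 0, 0),
       early_sustained = c(2, 2, 2),
       early_transient = c(2, 2, 0),
       mid_transient   = c(0, 2, 0),
       mid_sustained   = c(0, 2, 2),
       late_up         = c(0, 0, 2),
       late_down       = c(0, 0, -2))
}

#' Simulation configuration for the synthetic ABA time course
#'
#' Defines a two-condition (treated/control) x three-timepoint (30/60/180 min)
#' x `n_replicates` design with planted response archetypes. Control samples
#' sit at each gene's baseline at every timepoint; treated samples add the
#' archetype's log2 fold change for that timepoint. Noise is additive Gaussian
#' on the log2 scale with a gene-specific SD drawn once per gene from a
#' scaled-inverse-chi-square style distribution
#' (`sd_g = noise_sd_scale * sqrt(shape / rchisq(df = shape))`), so gene
#' variances are heterogeneous — the regime the regularized t-test targets.
#'
#' @param n_genes number of genes.
#' @param archetype_fractions named numeric vector/list of archetype fractions
#'   summing to 1; names must match [default_archetype_effects()].
#' @param effect_log2fc named list of per-archetype `c(fc30, fc60, fc180)`
#'   log2 effects.
#' @param n_replicates replicates per condition x timepoint (>= 2).
#' @param noise_sd_shape,noise_sd_scale parameters of the gene-wise noise-SD
#'   draw; the typical SD is approximately `noise_sd_scale`.
#' @param baseline_mean,baseline_sd log2-scale distribution of gene baselines.
#' @param seed RNG seed; identical seeds give bit-identical simulations.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       archetype_fractions = c(null = 0.70,
                                               early_sustained = 0.06,
                                               early_transient = 0.04,
                                               mid_transient = 0.05,
                                               mid_sustained = 0.05,
                                               late_up = 0.07,
                                               late_down = 0.03),
                       effect_log2fc = default_archetype_effects(),
                       n_replicates = 3,
                       noise_sd_shape = 20,
                       noise_sd_scale = 0.25,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       seed = 1) {
  fr <- unlist(archetype_fractions)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    abort("archetype fractions must be non-negative and sum to 1",
          "abatime_config_error")
  if (!all(names(fr) %in% names(effect_log2fc)))
    abort("every archetype fraction needs an effect trajectory",
          "abatime_config_error")
  if (n_replicates < 2) abort("n_replicates must be >= 2", "abatime_config_error")
  if (noise_sd_shape <= 0 || noise_sd_scale <= 0)
    abort("noise SD parameters must be strictly positive", "abatime_config_error")
  structure(list(n_genes = as.integer(n_genes), archetype_fractions = fr,
                 effect_log2fc = effect_log2fc,
                 n_replicates = as.integer(n_replicates),
                 noise_sd_shape = noise_sd_shape,
                 noise_sd_scale = noise_sd_scale,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder apportionment of n among fractions (deterministic:
# remainder ties broken by position).
apportion_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic two-condition ABA time course with ground truth
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (an [expression_matrix()] over samples
#'   `treated`/`control` x timepoints 30/60/180 x replicates) and `truth`
#'   (data.frame: `gene_id`, `archetype`, `fc30`, `fc60`, `fc180` true log2
#'   fold changes).
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tps <- c(30L, 60L, 180L)
  with_seed(config$seed, {
    n <- config$n_genes
    counts <- apportion_counts(n, config$archetype_fractions)
    archetype <- rep(names(config$archetype_fractions), counts)
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    noise_sd <- config$noise_sd_scale *
      sqrt(config$noise_sd_shape /
             stats::rchisq(n, df = config$noise_sd_shape))
    eff <- do.call(rbind, config$effect_log2fc[archetype])
    dimnames(eff) <- list(gene_ids, paste0("fc", tps))

    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           timepoint_min = tps,
                           condition = c("treated", "control"),
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_t%03d_r%d",
                                 ifelse(samples$condition == "treated", "T", "C"),
                                 samples$timepoint_min, samples$replicate)
    samples <- samples[c("sample_id", "condition", "timepoint_min", "replicate")]

    values <- matrix(0, n, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline
      if (samples$condition[j] == "treated")
        mu <- mu + eff[, paste0("fc", samples$timepoint_min[j])]
      values[, j] <- stats::rnorm(n, mu, noise_sd)
    }
    truth <- data.frame(gene_id = gene_ids, archetype = archetype,
                        fc30 = eff[, "fc30"], fc60 = eff[, "fc60"],
                        fc180 = eff[, "fc180"], noise_sd = noise_sd,
                        row.names = NULL, stringsAsFactors = FALSE)
    list(matrix = expression_matrix(values, samples), truth = truth)
  })
}

#' Derive an external-study gene list from simulation truth
#'
#' Emulates a published differential-expression list from another study of
#' the same system: the truly responsive (non-null) genes with a fraction
#' randomly dropped (genes the other study missed) and a fraction of null
#' genes added (its false positives or platform-specific calls).
#'
#' @param truth truth data.frame from [generate_timecourse()].
#' @param dropout fraction of responsive genes removed (0..1).
#' @param contamination fraction of null genes added (0..1).
#' @param seed RNG seed.
#' @return character vector of gene ids.
#' @export
make_study_lists <- function(truth, dropout = 0, contamination = 0, seed = 1) {
  stopifnot(dropout >= 0, dropout <= 1, contamination >= 0, contamination <= 1)
  responsive <- truth$gene_id[truth$archetype != "null"]
  nulls <- truth$gene_id[truth$archetype == "null"]
  with_seed(seed, {
    n_drop <- round(dropout * length(responsive))
    keep <- responsive
    if (n_drop > 0)
      keep <- setdiff(responsive, sample(responsive, n_drop))
    n_add <- round(contamination * length(nulls))
    if (n_add > 0) keep <- c(keep, sample(nulls, n_add))
    sort(keep)
  })
}
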