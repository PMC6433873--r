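#' Signed linear-scale fold change from log2 group means
#'
#' Uses the symmetric reciprocal sign convention of the published tables: the
#' linear ratio `r = 2^(mt - mc)` is reported as `r` when `r >= 1` and as
#' `-1/r` otherwise, so the magnitude is always at least 1 and a 4-fold
#' repression prints as -4 rather than 0.25.
#'
#' @param mean_log2_treated,mean_log2_control finite log2-scale group means
#'   (vectorized).
#' @return signed fold change(s), never in the open interval (-1, 1).
#' @examples
#' signed_fold_change(5, 3)  # +4
#' signed_fold_change(3, 5)  # -4
#' @export
signed_fold_change <- function(mean_log2_treated, mean_log2_control) {
  if (any(!is.finite(mean_log2_treated)) || any(!is.finite(mean_log2_control)))
    abort("group means must be finite", "abatime_input_error")
  r <- 2^(mean_log2_treated - mean_log2_control)
  ifelse(r >= 1, r, -1 / r)
}

#' Regularization parameters for the Cyber-T style t-test
#'
#' @param window_size odd positive integer; number of expression-rank
#'   neighbours whose sample variances are averaged into the background
#'   variance (default 101).
#' @param nu0 non-negative prior weight (pseudo-observations) given to the
#'   background variance (default 10).
#' @return a `reg_params` list.
#' @export
reg_params <- function(window_size = 101, nu0 = 10) {
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size %% 2L == 0L)
    abort("window_size must be an odd positive integer", "abatime_param_error")
  if (nu0 < 0) abort("nu0 must be non-negative", "abatime_param_error")
  structure(list(window_size = window_size, nu0 = nu0), class = "reg_params")
}

#' Sliding-window background variance for one sample group
#'
#' Genes are ordered by their group-mean expression; each gene's background
#' variance is the mean of the within-group sample variances of the
#' `window_size` nearest genes in that ordering (the window keeps constant
#' size and is clipped at the edges, so with `window_size` equal to the number
#' of genes every gene receives the global mean sample variance). Intensity-
#' dependent variance pooling is the prior that stabilizes the per-gene
#' variance estimate at n = 3.
#'
#' @param em an [expression_matrix()].
#' @param condition `"treated"` or `"control"`.
#' @param timepoint timepoint in minutes.
#' @param params a [reg_params()].
#' @return named numeric vector of background variances, one per gene, in the
#'   matrix's gene order.
#' @export
background_variance <- function(em, condition, timepoint, params = reg_params()) {
  cols <- sample_which(em, condition, timepoint)
  if (length(cols) < 2L)
    abort("need >= 2 replicates in the group", "abatime_design_error")
  n <- nrow(em$values)
  w <- params$window_size
  if (w > n)
    abort("window_size exceeds the number of genes", "abatime_param_error")
  m <- row_group_means(em$values, cols)
  v <- row_group_vars(em$values, cols)
  ord <- order(m, em$gene_ids)   # deterministic tie-break by id
  v_sorted <- v[ord]
  cs <- cumsum(c(0, v_sorted))
  h <- (w - 1L) %/% 2L
  start <- pmin(pmax(seq_len(n) - h, 1L), n - w + 1L)
  bg_sorted <- (cs[start + w] - cs[start]) / w
  bg <- numeric(n)
  bg[ord] <- bg_sorted
  names(bg) <- em$gene_ids
  bg
}

#' Bayesian-regularized two-sample t-test at one timepoint
#'
#' Cyber-T style test of treated vs control at a matched timepoint. Each
#' group's variance is shrunk toward its sliding-window background variance:
#' \deqn{\tilde s^2_g = \frac{\nu_0\,bg_g + (n_g-1)\,s^2_g}{\nu_0 + n_g - 2}}
#' (when \eqn{\nu_0 + n_g > 2}, otherwise the raw \eqn{s^2_g}); the statistic
#' is \eqn{t = (m_T - m_C)/\sqrt{\tilde s^2_T/n_T + \tilde s^2_C/n_C}} with
#' \eqn{df = n_T + n_C - 2 + 2\nu_0} and a two-sided t-tail p-value. With
#' `nu0 = 0` this reduces to the ordinary pooled-variance t-test.
#'
#' @param em an [expression_matrix()].
#' @param timepoint timepoint in minutes at which to contrast conditions.
#' @param params a [reg_params()].
#' @return data.frame: `gene_id`, `mean_diff`, `t`, `df`, `p`, `degenerate`
#'   (TRUE where both regularized variances are zero; there `t = 0`, `p = 1`).
#' @export
regularized_t_test <- function(em, timepoint, params = reg_params()) {
  ct <- sample_which(em, "treated", timepoint)
  cc <- sample_which(em, "control", timepoint)
  if (length(ct) < 2L || length(cc) < 2L)
    abort("need >= 2 replicates per condition at the timepoint",
          "abatime_design_error")
  nt <- length(ct); nc <- length(cc)
  nu0 <- params$nu0
  mt <- row_group_means(em$values, ct)
  mc <- row_group_means(em$values, cc)
  st2 <- row_group_vars(em$values, ct)
  sc2 <- row_group_vars(em$values, cc)
  if (nu0 > 0) {
    bgt <- background_variance(em, "treated", timepoint, params)
    bgc <- background_variance(em, "control", timepoint, params)
    reg_t <- if (nu0 + nt > 2) (nu0 * bgt + (nt - 1) * st2) / (nu0 + nt - 2) else st2
    reg_c <- if (nu0 + nc > 2) (nu0 * bgc + (nc - 1) * sc2) / (nu0 + nc - 2) else sc2
  } else {
    # nu0 = 0 limit: pooled-variance two-sample t-test
    pooled <- ((nt - 1) * st2 + (nc - 1) * sc2) / (nt + nc - 2)
    reg_t <- reg_c <- pooled
  }
  se2 <- reg_t / nt + reg_c / nc
  degenerate <- se2 <= 0
  df <- nt + nc - 2 + 2 * nu0
  tstat <- ifelse(degenerate, 0, (mt - mc) / sqrt(pmax(se2, .Machine$double.xmin)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  data.frame(gene_id = em$gene_ids, mean_diff = mt - mc, t = tstat, df = df,
             p = p, degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (monotone in p, clipped at 1).
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]", "abatime_input_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes per timepoint and classify temporally
#'
#' Runs the regularized t-test treated-vs-control at each timepoint, adjusts
#' per timepoint by Benjamini-Hochberg, calls direction (`up`/`down`/`none`)
#' at `q <= q_cutoff` (a q-value exactly at the cutoff counts as called), and
#' derives each gene's temporal class from the pattern of calls across the
#' ordered timepoints via [classify_temporal()]. Signed fold changes are
#' reported for all genes at all timepoints regardless of call.
#'
#' @param em an [expression_matrix()] with both conditions at every timepoint.
#' @param q_cutoff FDR cutoff for the per-timepoint calls (default 0.05).
#' @param params a [reg_params()].
#' @return data.frame with one row per gene: `gene_id`, then per timepoint
#'   `fc_<t>`, `p_<t>`, `q_<t>`, `dir_<t>`, and `temporal_class`.
#' @export
call_degs <- function(em, q_cutoff = 0.05, params = reg_params()) {
  tps <- timepoints(em)
  out <- data.frame(gene_id = em$gene_ids, stringsAsFactors = FALSE)
  dirs <- matrix("none", nrow(out), length(tps),
                 dimnames = list(NULL, as.character(tps)))
  for (i in seq_along(tps)) {
    tp <- tps[i]
    tt <- regularized_t_test(em, tp, params)
    q <- bh_fdr(tt$p)
    called <- q <= q_cutoff
    dirs[, i] <- ifelse(called, ifelse(tt$mean_diff > 0, "up", "down"), "none")
    mt <- row_group_means(em$values, sample_which(em, "treated", tp))
    mc <- row_group_means(em$values, sample_which(em, "control", tp))
    out[[paste0("fc_", tp)]] <- signed_fold_change(mt, mc)
    out[[paste0("p_", tp)]] <- tt$p
    out[[paste0("q_", tp)]] <- q
    out[[paste0("dir_", tp)]] <- dirs[, i]
  }
  # the temporal vocabulary is defined over the 3-timepoint design
  out$temporal_class <- if (length(tps) == 3L)
    apply(dirs, 1, classify_temporal) else NA_character_
  out
}

#' Temporal class from per-timepoint call directions
#'
#' Maps the pattern of differential-expression calls across the three ordered
#' timepoints (30, 60, 180 min) to the temporal response vocabulary:
#' `(up,up,up)` early_sustained; `(up,up,none)` early_transient;
#' `(none,up,none)` mid_transient; `(none,up,up)` mid_sustained;
#' `(none,none,up)` late_up; `(none,none,down)` late_down; all `none` maps to
#' `none`; every other combination maps to `mixed`, so the classifier is
#' total over the 3^3 direction patterns.
#'
#' @param directions character vector of length 3 over
#'   `c("up", "down", "none")`, ordered by timepoint.
#' @return one of `early_sustained`, `early_transient`, `mid_transient`,
#'   `mid_sustained`, `late_up`, `late_down`, `none`, `mixed`.
#' @export
classify_temporal <- function(directions) {
  if (length(directions) != 3L || !all(directions %in% c("up", "down", "none")))
    abort("directions must be 3 tokens from {up, down, none}",
          "abatime_input_error")
  key <- paste(directions, collapse = ",")
  switch(key,
         "up,up,up" = "early_sustained",
         "up,up,none" = "early_transient",
         "none,up,none" = "mid_transient",
         "none,up,up" = "mid_sustained",
         "none,none,up" = "late_up",
         "none,none,down" = "late_down",
         "none,none,none" = "none",
         "mixed")
}

#' Classify the rows of a printed gene table temporally
#'
#' A printed fold-change cell counts as an `up` call if present and positive,
#' `down` if present and negative, and `none` if absent (`NA`, the printed
#' dash); [classify_temporal()] then applies.
#'
#' @param table a `printed_gene_table` from [load_fixture_table()].
#' @return character vector of temporal classes, one per row.
#' @export
classify_printed_table <- function(table) {
  fc <- as.matrix(table[c("fc_30", "fc_60", "fc_180")])
  apply(fc, 1, function(row) {
    d <- ifelse(is.na(row), "none", ifelse(row > 0, "up", "down"))
    classify_temporal(d)
  })
}
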