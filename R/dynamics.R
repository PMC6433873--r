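#' Rank genes by the strength of their temporal response
#'
#' For each gene, the per-timepoint replicate means are computed over the
#' treated samples ("after stimulation") and the variance across those
#' timepoint means measures the strength of the temporal response. Genes are
#' returned sorted by this variance, descending (strongest responders first),
#' with ties broken lexicographically by gene id for determinism. A variant
#' using treated-minus-control per-timepoint mean differences is available.
#'
#' @param em an [expression_matrix()] with treated samples at >= 2 timepoints.
#' @param use_control_baseline if TRUE, rank by the variance of the
#'   treated-minus-control timepoint mean differences instead.
#' @return data.frame ordered by decreasing `response_var`: `gene_id`,
#'   `response_var`, `rank`.
#' @export
temporal_response_rank <- function(em, use_control_baseline = FALSE) {
  tps <- timepoints(em)
  if (length(tps) < 2L)
    abort("need treated samples at >= 2 timepoints", "abatime_design_error")
  prof <- vapply(tps, function(tp) {
    m <- row_group_means(em$values, sample_which(em, "treated", tp))
    if (use_control_baseline)
      m <- m - row_group_means(em$values, sample_which(em, "control", tp))
    m
  }, numeric(nrow(em$values)))
  v <- apply(prof, 1, stats::var)
  ord <- order(-v, em$gene_ids)
  data.frame(gene_id = em$gene_ids[ord], response_var = v[ord],
             rank = seq_along(ord), row.names = NULL, stringsAsFactors = FALSE)
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Both vectors are discretized into `bins` equal-frequency bins via stable
#' ranks (ties resolved by first occurrence), and the plug-in mutual
#' information of the joint histogram is returned in nats. The estimator is
#' symmetric, non-negative, invariant under strictly monotone transforms of
#' either input, and equals the binned marginal entropy on identical inputs
#' (`log(bins)` when `bins` divides the length evenly). A constant input
#' yields MI = 0 with attribute `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length `>= bins`, all values finite.
#' @param bins number of equal-frequency bins.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y, bins) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length", "abatime_input_error")
  if (n < bins) abort("need length >= bins", "abatime_input_error")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("inputs must be finite", "abatime_input_error")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  bx <- equal_freq_bins(x, bins)
  by <- equal_freq_bins(y, bins)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

equal_freq_bins <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

# Default bin count for a subset of k genes.
auto_bins <- function(k) max(4L, as.integer(floor(sqrt(k))))

#' Pairwise association profile of a gene subset
#'
#' Computes the group-mean expression vector of every (condition, timepoint)
#' sample group restricted to the subset, then for every ordered pair of
#' distinct groups the Pearson correlation and the binned mutual information
#' across the subset's genes. Groups are ordered by condition
#' (control before treated) then timepoint; pairs are all ordered pairs
#' `(i, j), i != j` in that ordering (restriction to treated-only
#' consecutive-timepoint pairs available via `pairs`).
#'
#' @param em an [expression_matrix()].
#' @param genes non-empty character vector of gene ids (subset of the matrix).
#' @param bins number of equal-frequency MI bins; default
#'   `max(4, floor(sqrt(length(genes))))`.
#' @param pairs `"all"` (default) or `"treated_consecutive"`.
#' @return list of class `association_profile`: `pair_labels`, `pc_values`,
#'   `mi_values` (nats), `bins`.
#' @export
association_profile <- function(em, genes, bins = NULL,
                                pairs = c("all", "treated_consecutive")) {
  pairs <- match.arg(pairs)
  if (!length(genes)) abort("subset must be non-empty", "abatime_input_error")
  if (!all(genes %in% em$gene_ids))
    abort("subset contains genes absent from the matrix", "abatime_input_error")
  bins <- bins %||% auto_bins(length(genes))
  if (length(genes) < bins)
    abort("subset smaller than the MI bin count", "abatime_input_error")
  s <- em$samples
  groups <- unique(s[order(s$condition, s$timepoint_min),
                     c("condition", "timepoint_min")])
  # canonical gene order: makes profiles exactly invariant to subset ordering
  rows <- sort(match(genes, em$gene_ids))
  gm <- vapply(seq_len(nrow(groups)), function(i) {
    cols <- sample_which(em, groups$condition[i], groups$timepoint_min[i])
    row_group_means(em$values[rows, , drop = FALSE], cols)
  }, numeric(length(genes)))
  labels <- paste0(groups$condition, "_", groups$timepoint_min)
  idx <- if (pairs == "all") {
    expand.grid(j = seq_along(labels), i = seq_along(labels))[, c("i", "j")]
  } else {
    tr <- which(groups$condition == "treated")
    tr <- tr[order(groups$timepoint_min[tr])]
    data.frame(i = tr[-length(tr)], j = tr[-1])
  }
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  pc <- mi <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    xi <- gm[, idx$i[k]]; xj <- gm[, idx$j[k]]
    pc[k] <- stats::cor(xi, xj)
    mi[k] <- as.numeric(mutual_information(xi, xj, bins))
  }
  structure(list(pair_labels = paste(labels[idx$i], labels[idx$j], sep = "|"),
                 pc_values = pc, mi_values = mi, bins = bins),
            class = "association_profile")
}

#' Subset-dynamics distance curve along the temporal-response ranking
#'
#' Implements the global transcriptome analysis: genes are ranked by temporal
#' response ([temporal_response_rank()]), windows of sizes within the 50-500
#' range slide along the ranked list (stride = half the window size), and
#' each window's association profile is compared with the whole
#' transcriptome's by Euclidean distance over the paired PC and MI entries.
#' Since MI (nats) and PC live on different scales, each MI value is divided
#' by `log(bins)` of its own profile, mapping it into `[0, 1]` before the
#' Euclidean combination (set `normalize_mi = FALSE` to probe sensitivity).
#' A least-squares polynomial trend in start rank, fitted to all windows, is
#' attached as `fitted_distance`.
#'
#' @param em an [expression_matrix()] with at least `max(sizes)` genes.
#' @param sizes window sizes (default `c(50, 100, 200, 300, 400, 500)`).
#' @param normalize_mi divide MI entries by `log(bins)` (default TRUE).
#' @param trend_degree degree of the polynomial trend (default 3).
#' @param use_control_baseline passed to [temporal_response_rank()].
#' @return data.frame of class `distance_curve`: `start_rank`, `size`,
#'   `distance`, `fitted_distance`; the ranking is attached as attribute
#'   `ranking` and the reference profile as `reference`.
#' @export
subset_distance_curve <- function(em, sizes = c(50, 100, 200, 300, 400, 500),
                                  normalize_mi = TRUE, trend_degree = 3,
                                  use_control_baseline = FALSE) {
  n <- nrow(em$values)
  if (n < max(sizes))
    abort("matrix has fewer genes than the largest window", "abatime_input_error")
  ranking <- temporal_response_rank(em, use_control_baseline)
  ref <- association_profile(em, em$gene_ids)
  rows <- list()
  for (k in sizes) {
    stride <- max(1L, as.integer(k / 2))
    starts <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
    for (st in starts) {
      sub <- ranking$gene_id[st:(st + k - 1L)]
      prof <- association_profile(em, sub)
      rows[[length(rows) + 1L]] <-
        data.frame(start_rank = st, size = k,
                   distance = profile_distance(prof, ref, normalize_mi))
    }
  }
  curve <- do.call(rbind, rows)
  deg_eff <- min(trend_degree, length(unique(curve$start_rank)) - 1L)
  curve$fitted_distance <- if (deg_eff < 1) {
    rep(mean(curve$distance), nrow(curve))
  } else {
    fit <- stats::lm(distance ~ stats::poly(start_rank, degree = deg_eff),
                     data = curve)
    unname(stats::fitted(fit))
  }
  attr(curve, "ranking") <- ranking
  attr(curve, "reference") <- ref
  class(curve) <- c("distance_curve", "data.frame")
  curve
}

profile_distance <- function(prof, ref, normalize_mi = TRUE) {
  stopifnot(identical(prof$pair_labels, ref$pair_labels))
  d_pc <- prof$pc_values - ref$pc_values
  mi_a <- prof$mi_values
  mi_b <- ref$mi_values
  if (normalize_mi) {
    mi_a <- mi_a / log(prof$bins)
    mi_b <- mi_b / log(ref$bins)
  }
  sqrt(sum(d_pc^2) + sum((mi_a - mi_b)^2))
}

#' Select genes contributing to the global transcriptome change
#'
#' Union of (a) genes whose temporal response variance lies above the
#' `rank_quantile` of all response variances (the maximal temporal
#' responders) and (b) genes belonging to windows whose distance falls below
#' the `distance_quantile` of the fitted trend (the subsets whose association
#' structure best tracks the whole transcriptome). Loosening either quantile
#' never removes a selected gene.
#'
#' @param curve a [subset_distance_curve()] result.
#' @param rank_quantile quantile of response variance above which genes are
#'   selected directly (default 0.9).
#' @param distance_quantile quantile of the fitted trend below which a
#'   window's genes are selected (default 0.25).
#' @return character vector of selected gene ids.
#' @export
select_contributing_genes <- function(curve, rank_quantile = 0.9,
                                      distance_quantile = 0.25) {
  stopifnot(inherits(curve, "distance_curve"),
            rank_quantile > 0, rank_quantile < 1,
            distance_quantile > 0, distance_quantile < 1)
  ranking <- attr(curve, "ranking")
  thr_v <- stats::quantile(ranking$response_var, rank_quantile, names = FALSE)
  top <- ranking$gene_id[ranking$response_var > thr_v]
  thr_d <- stats::quantile(curve$fitted_distance, distance_quantile,
                           names = FALSE)
  low <- which(curve$distance < thr_d)
  in_windows <- unlist(lapply(low, function(i) {
    st <- curve$start_rank[i]
    ranking$gene_id[st:(st + curve$size[i] - 1L)]
  }))
  sort(unique(c(top, in_windows)))
}

#' Sample-level principal component analysis
#'
#' Genes are centered and the samples-by-genes matrix is decomposed by SVD
#' (via [stats::prcomp()]); in the ABA time course the leading component
#' separates treated from control transcriptomes.
#'
#' @param em an [expression_matrix()] with >= 3 samples.
#' @return list of class `pca_result`: `scores` (samples x components, with
#'   sample ids as rownames), `var_explained` (non-increasing fractions),
#'   `samples` (the sample sheet).
#' @export
sample_pca <- function(em) {
  if (ncol(em$values) < 3L) abort("need >= 3 samples", "abatime_input_error")
  pr <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, var_explained = ve, samples = em$samples),
            class = "pca_result")
}
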