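#' Exclusive Venn/UpSet partition of labeled sets
#'
#' Partitions the union of 2-8 labeled sets into exclusive regions (every
#' non-empty label combination), with the per-element membership scan
#' semantics of an UpSet combination matrix: each element of the union is
#' counted in exactly one region, so region counts sum to the union size.
#'
#' @param sets named list of character vectors (2-8 sets, unique labels).
#' @return data.frame of class `venn_partition`: `region` (labels joined by
#'   `&`), `degree` (number of labels), `count`, and list-column `members`.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L || length(sets) > 8L)
    abort("venn_partition takes 2-8 sets", "abatime_input_error")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets))))
    abort("sets must have unique non-empty labels", "abatime_input_error")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  split_members <- split(universe, key)
  region <- names(split_members)
  data_out <- data.frame(region = region,
                         degree = lengths(strsplit(region, "&", fixed = TRUE)),
                         count = lengths(split_members),
                         row.names = NULL, stringsAsFactors = FALSE)
  data_out$members <- unname(split_members)
  class(data_out) <- c("venn_partition", "data.frame")
  data_out
}

#' Collapse a gene set through a best-hit ortholog map
#'
#' Maps a source-species gene set through a many-to-one single-best-hit
#' ortholog table (each source gene maps to exactly one target gene), the
#' operation used to reduce ABA-regulated *P. patens* DEGs to unique
#' *A. thaliana* orthologs. Source genes mapping to the same target are
#' paralogs and collapse to one entry.
#'
#' @param genes character vector of source gene ids.
#' @param map named character vector: `names(map)` are source ids, values are
#'   target ids (see [read_ortholog_map()]).
#' @return list: `mapped` (sorted unique target ids), `unmapped` (source ids
#'   absent from the map), `paralog_groups` (named list target -> source ids,
#'   only preimages of size >= 2).
#' @export
collapse_orthologs <- function(genes, map) {
  genes <- unique(as.character(genes))
  hit <- genes[genes %in% names(map)]
  targets <- unname(map[hit])
  groups <- split(hit, targets)
  list(mapped = sort(unique(targets)),
       unmapped = sort(setdiff(genes, hit)),
       paralog_groups = groups[lengths(groups) >= 2])
}

#' Read a two-column ortholog map (source_id TAB target_id)
#'
#' @param path TSV file with columns `source_id`, `target_id` (header
#'   optional; detected by name).
#' @return named character vector mapping source to target.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(tab))) {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("source_id", "target_id"))
  }
  if (anyDuplicated(tab$source_id)) {
    conflicting <- tapply(tab$target_id, tab$source_id,
                          function(x) length(unique(x)) > 1)
    if (any(conflicting))
      abort("ortholog map assigns multiple targets to one source (single best hit required)",
            "abatime_format_error")
    tab <- tab[!duplicated(tab$source_id), ]
  }
  stats::setNames(as.character(tab$target_id), tab$source_id)
}

#' Cross-study overlap table
#'
#' Compares a focal gene set against external-study gene lists (all in one id
#' namespace, after ortholog collapse where applicable): pairwise overlaps
#' with the focal set, per-study unique counts, union size, and counts of
#' elements regulated in at least `k` of the sets, aggregated from the
#' exclusive Venn regions.
#'
#' @param our_set character vector (focal study's genes).
#' @param study_sets named list of character vectors.
#' @param our_label label for the focal set (default `"this_study"`).
#' @return list: `pairwise` (data.frame study/overlap/unique_in_study),
#'   `union_size`, `at_least_k` (named integer vector over k = 1..n_sets),
#'   `partition` (the underlying [venn_partition()]).
#' @export
cross_study_overlap <- function(our_set, study_sets, our_label = "this_study") {
  all_sets <- c(stats::setNames(list(unique(our_set)), our_label), study_sets)
  part <- venn_partition(all_sets)
  ours <- unique(as.character(our_set))
  pairwise <- do.call(rbind, lapply(names(study_sets), function(nm) {
    s <- unique(as.character(study_sets[[nm]]))
    others <- unique(unlist(c(list(ours), study_sets[names(study_sets) != nm])))
    data.frame(study = nm, size = length(s),
               overlap_with_ours = length(intersect(s, ours)),
               unique_in_study = length(setdiff(s, others)),
               stringsAsFactors = FALSE)
  }))
  nsets <- length(all_sets)
  at_least_k <- vapply(seq_len(nsets), function(k)
    sum(part$count[part$degree >= k]), integer(1))
  names(at_least_k) <- paste0("k", seq_len(nsets))
  list(pairwise = pairwise, union_size = sum(part$count),
       at_least_k = at_least_k, partition = part)
}

#' Genes expressed specifically in a target sample group
#'
#' A gene qualifies when the minimum of its expression over the target
#' replicates exceeds the maximum over all other samples in the dataset —
#' the specificity filter used to find genes with highest expression in
#' ABA-treated protonema or brown sporophytes.
#'
#' @param em an [expression_matrix()].
#' @param condition,timepoint define the target group (a strict subset of
#'   samples).
#' @return character vector of gene ids.
#' @export
condition_specific_genes <- function(em, condition, timepoint) {
  target <- sample_which(em, condition, timepoint)
  if (!length(target) || length(target) == ncol(em$values))
    abort("target group must be a non-empty strict subset of samples",
          "abatime_input_error")
  other <- setdiff(seq_len(ncol(em$values)), target)
  tmin <- apply(em$values[, target, drop = FALSE], 1, min)
  omax <- apply(em$values[, other, drop = FALSE], 1, max)
  em$gene_ids[tmin > omax]
}

#' Percent increase of a treated mean over a control mean
#'
#' @param mean_treated,mean_control group means; `mean_control` must be
#'   positive.
#' @return percentage `100 * (mean_treated - mean_control) / mean_control`,
#'   full precision, with the integer-rounded value attached as attribute
#'   `rounded`.
#' @examples
#' percent_increase(53, 37)  # 43.24...%, rounds to 43
#' @export
percent_increase <- function(mean_treated, mean_control) {
  if (mean_control <= 0)
    abort("control mean must be positive", "abatime_input_error")
  pct <- 100 * (mean_treated - mean_control) / mean_control
  attr(pct, "rounded") <- round(pct)
  pct
}

#' Two-sample t-test from group summary statistics
#'
#' Computes the two-sample t-test (Welch by default, given unequal group
#' SDs; pooled variant available) from means, SDs and group sizes alone, as
#' needed to check published morphometry claims such as the cell-wall
#' thickness comparison (53 +/- 11 um treated vs 37 +/- 8 um control,
#' n = 11 each).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`n >= 2`,
#'   `sd >= 0`).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list: `t`, `df`, `p_two_sided`, `degenerate` (TRUE when both SDs
#'   are zero; then p is 1 for equal means and 0 otherwise).
#' @export
two_sample_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                      variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n_a < 2 || n_b < 2) abort("n must be >= 2 in both groups", "abatime_input_error")
  if (sd_a < 0 || sd_b < 0) abort("sds must be non-negative", "abatime_input_error")
  if (sd_a == 0 && sd_b == 0) {
    eq <- isTRUE(all.equal(mean_a, mean_b))
    return(list(t = if (eq) 0 else Inf * sign(mean_a - mean_b),
                df = n_a + n_b - 2, p_two_sided = if (eq) 1 else 0,
                degenerate = TRUE))
  }
  if (variant == "welch") {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    tstat <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    tstat <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  list(t = tstat, df = df, p_two_sided = 2 * stats::pt(-abs(tstat), df),
       degenerate = FALSE)
}
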