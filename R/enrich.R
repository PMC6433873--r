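#' Two-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Tests whether `k` study genes carrying a term, out of a study of size `n`,
#' are compatible with `K` term carriers in a background of size `N`. The
#' exact two-sided p-value sums the hypergeometric probabilities of all
#' tables at most as probable as the observed one; the sample odds ratio is
#' taken from the 2x2 table directly.
#'
#' @param k study genes with the term.
#' @param K background genes with the term.
#' @param n study size.
#' @param N background size.
#' @return list: `p_two_sided`, `odds_ratio` (`NaN` flagged 0/0 convention
#'   when both off-terms vanish, `Inf` when only the denominator does).
#' @export
fisher_exact_2x2 <- function(k, K, n, N) {
  if (k > K || k > n || K > N || n > N || k < 0 ||
      k < max(0, K + n - N))
    abort("inconsistent contingency counts", "abatime_input_error")
  support <- max(0, K + n - N):min(K, n)
  d <- stats::dhyper(support, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  p <- sum(d[d <= obs * (1 + 1e-7)])
  odds <- (k * (N - K - n + k)) / ((K - k) * (n - k))
  list(p_two_sided = min(p, 1), odds_ratio = odds)
}

#' Read a gene-to-GO annotation table
#'
#' @param path two-column TSV `gene_id TAB term_id` (header optional),
#'   optionally with a third `term_name` column.
#' @param background optional character vector defining the background
#'   universe; defaults to all annotated genes.
#' @return list of class `annotation_map`: `terms` (named list term ->
#'   gene ids), `term_names` (named character), `background`.
#' @export
read_annotations <- function(path, background = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tab)))
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("gene_id", "term_id", "term_name")[
                               seq_len(ncol(tab))])
  annotation_map(tab$gene_id, tab$term_id,
                 term_names = if ("term_name" %in% names(tab))
                   tab$term_name else NULL,
                 background = background)
}

#' Build an annotation map from parallel vectors
#'
#' @param gene_id,term_id parallel character vectors (one row per
#'   association).
#' @param term_names optional parallel vector of term names.
#' @param background optional background universe; every annotated gene must
#'   belong to it. Defaults to all annotated genes.
#' @return an `annotation_map` (see [read_annotations()]).
#' @export
annotation_map <- function(gene_id, term_id, term_names = NULL,
                           background = NULL) {
  terms <- lapply(split(as.character(gene_id), as.character(term_id)), unique)
  terms <- terms[lengths(terms) > 0]
  background <- unique(as.character(background %||% unlist(terms)))
  annotated <- unique(unlist(terms))
  if (!all(annotated %in% background))
    abort("every annotated gene must be in the background", "abatime_input_error")
  nm <- character(0)
  if (!is.null(term_names)) {
    nm <- tapply(as.character(term_names), as.character(term_id),
                 function(x) x[1])
    nm <- stats::setNames(as.character(nm), names(nm))
  }
  structure(list(terms = terms, term_names = nm, background = background),
            class = "annotation_map")
}

#' GO term over-/under-representation of a study set
#'
#' One two-sided Fisher's exact test per term against the declared background,
#' with Bonferroni correction over the tested terms (`q = min(1, p m)`);
#' terms with `q < 0.05` are flagged significant, and direction is read off
#' the fold enrichment `(k/n)/(K/N)`. Study genes outside the background are
#' dropped with a message; terms are tested when they have at least one study
#' gene or an expected count of at least one, and at least `min_term_size`
#' background carriers.
#'
#' @param study character vector of study gene ids.
#' @param annotations an `annotation_map`.
#' @param alpha significance threshold on the Bonferroni q (default 0.05).
#' @param min_term_size minimum background carriers per tested term
#'   (default 2).
#' @return data.frame sorted by p: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `fold_enrichment`, `direction`, `p_value`, `q_value`, `significant`.
#' @export
run_enrichment <- function(study, annotations, alpha = 0.05,
                           min_term_size = 2) {
  stopifnot(inherits(annotations, "annotation_map"))
  study <- unique(as.character(study))
  dropped <- setdiff(study, annotations$background)
  if (length(dropped))
    message(length(dropped), " study gene(s) outside the background dropped")
  study <- intersect(study, annotations$background)
  if (!length(study))
    abort("study set empty after background intersection", "abatime_input_error")
  N <- length(annotations$background)
  n <- length(study)
  terms <- annotations$terms[lengths(annotations$terms) >= min_term_size]
  rows <- lapply(names(terms), function(tid) {
    genes <- terms[[tid]]
    K <- length(genes)
    k <- length(intersect(genes, study))
    if (k < 1 && (K * n / N) < 1) return(NULL)
    ft <- fisher_exact_2x2(k, K, n, N)
    data.frame(term_id = tid,
               term_name = annotations$term_names[tid] %|na|% tid,
               k = k, K = K, n = n, N = N,
               fold_enrichment = (k / n) / (K / N),
               direction = if ((k / n) / (K / N) > 1) "over" else "under",
               p_value = ft$p_two_sided, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(rows)
  m <- nrow(rows)
  rows$q_value <- pmin(1, rows$p_value * m)
  rows$significant <- rows$q_value < alpha
  rows <- rows[order(rows$p_value, rows$term_id), ]
  rownames(rows) <- NULL
  rows
}

`%|na|%` <- function(x, y) {
  if (is.null(x) || length(x) == 0 || is.na(x)) y else x
}
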