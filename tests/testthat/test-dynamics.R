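test_that("temporal response ranking orders genes by timepoint-mean variance", {
  # noise-free: sustained (2,2,2) has zero profile variance, late (0,0,2) does not
  eff <- rbind(flat = c(2, 2, 2), late = c(0, 0, 2), const = c(0, 0, 0))
  colnames(eff) <- c("fc30", "fc60", "fc180")
  em <- make_planted_matrix(eff, jitter = c(0, 0, 0))
  r <- temporal_response_rank(em)
  expect_equal(r$gene_id[1], "late")
  expect_equal(r$response_var[1], var(c(0, 0, 2)))   # = 4/3
  # zero-variance profiles rank last, ties broken lexicographically
  expect_equal(r$gene_id[2:3], c("const", "flat"))
  expect_equal(r$response_var[2:3], c(0, 0))
})

test_that("planted responders concentrate at the top of the ranking", {
  # 5% of genes carry a time-varying treated profile; their median rank should
  # land in the top decile of the variance ranking
  cfg <- sim_config(n_genes = 1000,
                    archetype_fractions = c(null = 0.95, mid_transient = 0.025,
                                            late_up = 0.025),
                    seed = 51)
  sim <- generate_timecourse(cfg)
  r <- temporal_response_rank(sim$matrix)
  resp <- sim$truth$gene_id[sim$truth$archetype != "null"]
  ranks <- r$rank[match(resp, r$gene_id)]
  expect_lt(median(ranks), 100)  # top decile of 1000
})

test_that("the MI estimator has the plug-in identities and invariances", {
  set.seed(61)
  x <- rnorm(1000)
  y <- rnorm(1000)
  # identity: MI(x, x) = binned marginal entropy = log(bins) for even splits
  expect_equal(as.numeric(mutual_information(x, x, 10)), log(10),
               tolerance = 1e-12)
  # symmetry
  expect_equal(as.numeric(mutual_information(x, y, 10)),
               as.numeric(mutual_information(y, x, 10)), tolerance = 1e-12)
  # invariance under strictly monotone transforms (rank binning)
  expect_equal(as.numeric(mutual_information(exp(x), y, 10)),
               as.numeric(mutual_information(x, y, 10)), tolerance = 1e-12)
  # non-negativity and degenerate constant input
  expect_gte(as.numeric(mutual_information(x, y, 10)), 0)
  mi_const <- mutual_information(rep(1, 100), y[1:100], 5)
  expect_equal(as.numeric(mi_const), 0)
  expect_true(attr(mi_const, "degenerate"))
  # independence bound at large n (plug-in bias ~ (bins-1)^2 / (2n))
  set.seed(62)
  expect_lt(as.numeric(mutual_information(rnorm(10000), rnorm(10000), 10)),
            0.02)
})

test_that("association profiles match direct correlation and entropy oracles", {
  em <- random_matrix(n_genes = 100, n_rep = 3, seed = 63)
  prof <- association_profile(em, em$gene_ids)
  # brute-force PC oracle over ordered pairs of group-mean vectors
  s <- em$samples
  groups <- unique(s[order(s$condition, s$timepoint_min),
                     c("condition", "timepoint_min")])
  gm <- sapply(seq_len(nrow(groups)), function(i)
    rowMeans(em$values[, s$condition == groups$condition[i] &
                         s$timepoint_min == groups$timepoint_min[i]]))
  k <- 0
  for (i in seq_len(6)) for (j in seq_len(6)) {
    if (i == j) next
    k <- k + 1
    expect_equal(prof$pc_values[k], cor(gm[, i], gm[, j]), tolerance = 1e-12)
  }
  expect_equal(k, length(prof$pc_values))

  # two identical group vectors: PC = 1 and maximal MI
  v <- em$values
  tr30 <- which(s$condition == "treated" & s$timepoint_min == 30)
  tr60 <- which(s$condition == "treated" & s$timepoint_min == 60)
  v[, tr60] <- v[, tr30]
  em2 <- expression_matrix(v, s)
  prof2 <- association_profile(em2, em2$gene_ids)
  pair <- which(prof2$pair_labels == "treated_30|treated_60")
  expect_equal(prof2$pc_values[pair], 1, tolerance = 1e-12)
  expect_equal(prof2$mi_values[pair], log(prof2$bins), tolerance = 1e-12)

  expect_error(association_profile(em, character(0)),
               class = "abatime_input_error")
  expect_error(association_profile(em, "not_a_gene"),
               class = "abatime_input_error")
})

test_that("distance curve vanishes on the full transcriptome and is stable", {
  sim <- generate_timecourse(sim_config(n_genes = 300, seed = 65))
  em <- sim$matrix
  full <- subset_distance_curve(em, sizes = 300)
  expect_identical(full$distance, 0)

  # profiles are exactly invariant to gene order within the subset
  p1 <- association_profile(em, em$gene_ids[1:100])
  p2 <- association_profile(em, rev(em$gene_ids[1:100]))
  expect_identical(p1$pc_values, p2$pc_values)
  expect_identical(p1$mi_values, p2$mi_values)

  c1 <- subset_distance_curve(em, sizes = c(50, 100))
  c2 <- subset_distance_curve(em, sizes = c(50, 100))
  expect_identical(c1$distance, c2$distance)
  expect_true(all(c1$distance >= 0))
  expect_true(all(diff(c1$start_rank[c1$size == 50]) > 0))
})

test_that("responder-containing windows differ systematically from null windows", {
  # strong planted block: the top-ranked genes are the only responders
  cfg <- sim_config(n_genes = 400,
                    archetype_fractions = c(null = 0.75, late_up = 0.25),
                    seed = 67)
  sim <- generate_timecourse(cfg)
  curve <- subset_distance_curve(sim$matrix, sizes = 100)
  ranking <- attr(curve, "ranking")
  resp <- sim$truth$gene_id[sim$truth$archetype != "null"]
  frac_resp <- vapply(seq_len(nrow(curve)), function(i) {
    genes <- ranking$gene_id[curve$start_rank[i]:(curve$start_rank[i] + 99)]
    mean(genes %in% resp)
  }, numeric(1))
  resp_windows <- which(frac_resp > 0.9)
  null_windows <- which(frac_resp < 0.1)
  expect_gt(length(resp_windows), 0)
  expect_gt(length(null_windows), 0)
  # responders dominate the global change, so their windows track it closer
  expect_lt(mean(curve$distance[resp_windows]),
            mean(curve$distance[null_windows]))
})

test_that("contributing-gene selection is monotone and recovers responders", {
  sim <- generate_timecourse(sim_config(n_genes = 600, seed = 69))
  curve <- subset_distance_curve(sim$matrix, sizes = c(50, 100, 200))
  sel <- select_contributing_genes(curve)
  resp <- sim$truth$gene_id[sim$truth$archetype != "null"]
  expect_gt(mean(resp %in% sel), 0.8)

  looser <- select_contributing_genes(curve, rank_quantile = 0.8,
                                      distance_quantile = 0.4)
  expect_true(all(sel %in% looser))
})

test_that("sample PCA has SVD structure and separates planted conditions", {
  em <- random_matrix(n_genes = 50, n_rep = 3, seed = 71)
  pca <- sample_pca(em)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_true(all(pca$var_explained >= 0) && sum(pca$var_explained) <= 1 + 1e-9)

  # reconstruction with all components reproduces the centered matrix
  pr <- prcomp(t(em$values), center = TRUE, scale. = FALSE)
  rec <- pr$x %*% t(pr$rotation)
  centered <- t(em$values) - matrix(colMeans(t(em$values)),
                                    nrow(rec), ncol(rec), byrow = TRUE)
  expect_equal(rec, centered, tolerance = 1e-9, ignore_attr = TRUE)

  # duplicated samples get identical scores
  v <- em$values
  v <- cbind(v, dup = v[, 1])
  sheet <- rbind(em$samples,
                 data.frame(sample_id = "dup", condition = "treated",
                            timepoint_min = 30, replicate = 99))
  colnames(v)[ncol(v)] <- "dup"
  pca2 <- sample_pca(expression_matrix(v, sheet))
  expect_equal(pca2$scores["dup", ], pca2$scores[em$samples$sample_id[1], ],
               tolerance = 1e-9)

  # planted group structure: PC1 separates treated from control in seeded runs
  for (seed in 1:5) {
    sim <- generate_timecourse(sim_config(n_genes = 400, seed = seed))
    p <- sample_pca(sim$matrix)
    cond <- p$samples$condition
    pc1 <- p$scores[, 1]
    gap <- abs(mean(pc1[cond == "treated"]) - mean(pc1[cond == "control"]))
    spread <- sd(pc1[cond == "treated"]) + sd(pc1[cond == "control"])
    expect_gt(gap, spread)
  }
})
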