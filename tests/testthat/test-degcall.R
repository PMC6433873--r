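test_that("signed fold change uses the reciprocal sign convention", {
  expect_equal(signed_fold_change(5, 3), 4)
  expect_equal(signed_fold_change(3, 5), -4)
  expect_equal(signed_fold_change(2, 2), 1)
  x <- signed_fold_change(rnorm(50), rnorm(50))
  expect_true(all(abs(x) >= 1))
})

test_that("background variance matches a direct window-average oracle", {
  em <- random_matrix(n_genes = 200, n_rep = 3, seed = 21)
  params <- reg_params(window_size = 51, nu0 = 10)
  bg <- background_variance(em, "treated", 60, params)

  # oracle: re-sort by group mean and average constant-size clipped windows
  cols <- which(em$samples$condition == "treated" & em$samples$timepoint_min == 60)
  m <- rowMeans(em$values[, cols])
  v <- apply(em$values[, cols], 1, var)
  ord <- order(m, em$gene_ids)
  w <- 51L; h <- 25L; n <- 200L
  expected <- numeric(n)
  for (pos in seq_len(n)) {
    st <- min(max(pos - h, 1L), n - w + 1L)
    expected[ord[pos]] <- mean(v[ord][st:(st + w - 1L)])
  }
  expect_equal(unname(bg), expected, tolerance = 1e-12)

  # full-window limit: everyone gets the global mean sample variance
  em_odd <- random_matrix(n_genes = 199, n_rep = 3, seed = 22)
  cols_o <- which(em_odd$samples$condition == "treated" &
                    em_odd$samples$timepoint_min == 60)
  v_odd <- apply(em_odd$values[, cols_o], 1, var)
  bg_full <- background_variance(em_odd, "treated", 60,
                                 reg_params(window_size = 199, nu0 = 10))
  expect_equal(unname(bg_full), rep(mean(v_odd), 199), tolerance = 1e-12)

  # constant input degenerates to zero background variance
  emc <- em
  emc$values[] <- 5
  expect_equal(unname(background_variance(emc, "treated", 60, params)),
               rep(0, n))

  expect_error(background_variance(em, "treated", 60,
                                   reg_params(window_size = 201)),
               class = "abatime_param_error")
})

test_that("nu0 = 0 reduces the regularized t-test to the pooled t-test", {
  set.seed(77)
  for (rep in 1:25) {
    em <- random_matrix(n_genes = 20, n_rep = 3, seed = 1000 + rep)
    res <- regularized_t_test(em, 30, reg_params(window_size = 5, nu0 = 0))
    ct <- em$samples$condition == "treated" & em$samples$timepoint_min == 30
    cc <- em$samples$condition == "control" & em$samples$timepoint_min == 30
    for (i in seq_len(20)) {
      tt <- t.test(em$values[i, ct], em$values[i, cc], var.equal = TRUE)
      expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
      expect_equal(res$df[i], unname(tt$parameter))
    }
  }
})

test_that("regularized variance follows the stated shrinkage formula", {
  # 3 genes, full window, group mean sample variance exactly 1, focal gene
  # s^2 = 0.25 in both groups and mean difference 1
  d <- sqrt(1.375)
  values <- rbind(
    g1 = c(1.5, 1, 0.5, 1.5, 1, 0.5, 1.5, 1, 0.5,
           0.5, 0, -0.5, 0.5, 0, -0.5, 0.5, 0, -0.5),
    g2 = rep(c(-d, 0, d), 6),
    g3 = rep(c(-d, 0, d), 6) + 10
  )
  tps <- rep(rep(c(30L, 60L, 180L), each = 3), 2)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:18),
    condition = rep(c("treated", "control"), each = 9),
    timepoint_min = tps,
    replicate = rep(1:3, 6))
  colnames(values) <- samples$sample_id
  em <- expression_matrix(values, samples)

  res <- regularized_t_test(em, 30, reg_params(window_size = 3, nu0 = 10))
  s2_reg <- (10 * 1 + 2 * 0.25) / (10 + 3 - 2)   # = 0.9545...
  expect_equal(res$t[1], 1 / sqrt(2 * s2_reg / 3), tolerance = 1e-12)
  expect_equal(res$df[1], 3 + 3 - 2 + 2 * 10)
  expect_equal(res$p[1], 2 * pt(-1 / sqrt(2 * s2_reg / 3), 24),
               tolerance = 1e-12)
})

test_that("identical treated and control data give t = 0, p = 1", {
  em <- random_matrix(n_genes = 11, n_rep = 3, seed = 9)
  v <- em$values
  tr <- em$samples$condition == "treated" & em$samples$timepoint_min == 30
  co <- em$samples$condition == "control" & em$samples$timepoint_min == 30
  v[, which(co)] <- v[, which(tr)]
  em2 <- expression_matrix(v, em$samples)
  res <- regularized_t_test(em2, 30, reg_params(window_size = 11, nu0 = 10))
  expect_equal(res$t, rep(0, 11))
  expect_equal(res$p, rep(1, 11))
})

test_that("BH q-values follow the step-up rule and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "abatime_input_error")

  set.seed(3)
  p <- runif(100)
  q <- bh_fdr(p)
  perm <- sample(100)
  expect_equal(bh_fdr(p[perm]), q[perm])           # permutation equivariance
  expect_true(all(diff(q[order(p)]) >= -1e-15))    # monotone in p
})

test_that("temporal classification is total and matches the class vocabulary", {
  expect_equal(classify_temporal(c("up", "up", "up")), "early_sustained")
  expect_equal(classify_temporal(c("up", "up", "none")), "early_transient")
  expect_equal(classify_temporal(c("none", "up", "none")), "mid_transient")
  expect_equal(classify_temporal(c("none", "up", "up")), "mid_sustained")
  expect_equal(classify_temporal(c("none", "none", "up")), "late_up")
  expect_equal(classify_temporal(c("none", "none", "down")), "late_down")
  expect_equal(classify_temporal(c("none", "none", "none")), "none")

  vocab <- c("early_sustained", "early_transient", "mid_transient",
             "mid_sustained", "late_up", "late_down", "none", "mixed")
  combos <- expand.grid(d1 = c("up", "down", "none"),
                        d2 = c("up", "down", "none"),
                        d3 = c("up", "down", "none"),
                        stringsAsFactors = FALSE)
  named_patterns <- c("up,up,up", "up,up,none", "none,up,none", "none,up,up",
                      "none,none,up", "none,none,down", "none,none,none")
  for (i in seq_len(nrow(combos))) {
    d <- unlist(combos[i, ], use.names = FALSE)
    cls <- classify_temporal(d)
    expect_true(cls %in% vocab)
    if (!paste(d, collapse = ",") %in% named_patterns)
      expect_equal(cls, "mixed")
  }
  expect_error(classify_temporal(c("up", "sideways", "none")),
               class = "abatime_input_error")
})

test_that("printed tables classify to the published temporal patterns", {
  t3 <- load_fixture_table("table3_early")
  cls <- classify_printed_table(t3)
  expect_equal(unname(cls[t3$gene_id == "Phypa_117954"]), "early_transient")

  t1 <- load_fixture_table("table1_cellwall")
  cls1 <- classify_printed_table(t1)
  expect_equal(unname(cls1[t1$gene_id == "Phypa_206446"]), "late_down")

  blank <- t3[1, ]
  blank[c("fc_30", "fc_60", "fc_180")] <- NA_real_
  expect_equal(unname(classify_printed_table(blank)), "none")
})

test_that("DEG calls recover planted truth exactly in the noise-free limit", {
  eff <- planted_effects(n_null = 6, n_resp = 5, fc = 2)
  em <- make_planted_matrix(eff)
  degs <- call_degs(em, q_cutoff = 0.05, params = reg_params(window_size = 11))
  called <- degs$temporal_class != "none"
  expect_equal(called, unname(rowSums(abs(eff)) > 0))
  expect_true(all(degs$temporal_class[called] == "early_sustained"))
  # fold changes are reported for all genes including the uncalled
  expect_true(all(is.finite(degs$fc_30)))
})

test_that("empirical FDR of DEG calls on mixed simulations is controlled", {
  cfg <- sim_config(n_genes = 2000,
                    archetype_fractions = c(null = 0.5, early_sustained = 0.2,
                                            mid_sustained = 0.15, late_up = 0.15),
                    seed = 31)
  sim <- generate_timecourse(cfg)
  degs <- call_degs(sim$matrix, q_cutoff = 0.05)
  truth_fc <- as.matrix(sim$truth[c("fc30", "fc60", "fc180")])
  called <- cbind(degs$dir_30, degs$dir_60, degs$dir_180) != "none"
  R <- sum(called)
  V <- sum(called & truth_fc == 0)
  expect_gt(R, 0)
  mc_se <- sqrt(0.05 * 0.95 / R)
  expect_lte(V / R, 0.05 + 3 * mc_se)
})
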