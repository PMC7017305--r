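test_that("the balanced 2x2 toy reproduces the hand-computed F statistics", {
  m <- make_gene_matrix(c(1, 2, 3, 4, 5, 6, 7, 8))
  a <- two_way_anova(m, balanced_2x2_meta())
  expect_equal(a$F_tissue, 64)
  expect_equal(a$F_state, 16)
  expect_equal(a$F_interaction, 0, tolerance = 1e-12)
  expect_equal(a$residual_df, 4)
  expect_false(a$degenerate)
})

test_that("Type-III agrees with the projection oracle and with Type I when balanced", {
  meta <- balanced_2x2_meta()
  set.seed(7)
  for (i in 1:20) {
    y <- rnorm(8)
    m <- make_gene_matrix(y)
    a3 <- two_way_anova(m, meta, ss_type = "III")
    a1 <- two_way_anova(m, meta, ss_type = "I")
    expect_equal(a3$F_tissue, a1$F_tissue)
    expect_equal(a3$F_state, a1$F_state)
    expect_equal(a3$F_interaction, a1$F_interaction)

    o <- anova_projection_oracle(y, meta$tissue, meta$state)
    expect_equal(a3$F_tissue, unname((o$ss["tissue"] / o$df["tissue"]) /
                                       (o$rss / o$df_e)))
    expect_equal(a3$F_interaction,
                 unname((o$ss["interaction"] / o$df["interaction"]) /
                          (o$rss / o$df_e)))
  }
})

test_that("Type-III matches the projection oracle on the unbalanced study layout", {
  gs <- default_group_sizes()
  meta <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_%d", gs$tissue[i], gs$state[i],
                                   seq_len(gs$n[i])),
               tissue = gs$tissue[i], state = gs$state[i])
  }))
  set.seed(12)
  for (i in 1:5) {
    y <- rnorm(nrow(meta)) + 0.6 * (meta$state == "SALS1")
    m <- make_gene_matrix(matrix(y, 1), samples = meta$sample_id)
    a <- two_way_anova(m, meta)
    o <- anova_projection_oracle(y, meta$tissue, meta$state)
    Fo <- (o$ss / o$df) / (o$rss / o$df_e)
    expect_equal(a$F_tissue, unname(Fo["tissue"]))
    expect_equal(a$F_state, unname(Fo["state"]))
    expect_equal(a$F_interaction, unname(Fo["interaction"]))
    expect_equal(a$residual_df, o$df_e)
  }
})

test_that("a pure interaction pattern makes the interaction F dominant", {
  # cell means 0,1,1,0 with tiny within-cell jitter
  y <- c(0, 0.01, 1, 1.01, 1, 1.01, 0, 0.01)
  a <- two_way_anova(make_gene_matrix(y), balanced_2x2_meta())
  expect_gt(a$F_interaction, a$F_tissue)
  expect_gt(a$F_interaction, a$F_state)
})

test_that("degenerate genes are flagged with limiting values, not errors", {
  a <- two_way_anova(make_gene_matrix(rep(1, 8)), balanced_2x2_meta())
  expect_true(a$degenerate)
  expect_equal(a$F_tissue, 0)
  expect_equal(a$p_tissue, 1)

  # zero residual variance but real effects
  a2 <- two_way_anova(make_gene_matrix(c(1, 1, 2, 2, 3, 3, 4, 4)),
                      balanced_2x2_meta())
  expect_true(a2$degenerate)
  expect_equal(a2$p_tissue, 0)

  meta_empty <- balanced_2x2_meta()
  meta_empty$state[meta_empty$tissue == "B" & meta_empty$state == "y"] <- "x"
  expect_error(two_way_anova(make_gene_matrix(rnorm(8)), meta_empty),
               "empty factorial cell")
})

test_that("BH adjustment matches the worked examples and a brute-force step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(benjamini_hochberg(p), bh_bruteforce(p))
  }
})

test_that("q-values dominate p-values and are monotone with them", {
  set.seed(5)
  spec <- design_spec(n_genes = 60, probes_per_gene = 1, seed = 5)
  sim <- simulate_expression(spec)
  genes <- collapse_probes(normalize_matrix(sim$expression), sim$probe_map)
  a <- two_way_anova(genes, sim$metadata)
  for (eff in c("tissue", "state", "interaction")) {
    p <- a[[paste0("p_", eff)]]; q <- a[[paste0("q_", eff)]]
    expect_true(all(q >= p - 1e-15))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

test_that("fold changes are group-mean differences on the log2 scale", {
  meta <- do.call(rbind, lapply(seq_len(nrow(default_group_sizes())), function(i) {
    gs <- default_group_sizes()[i, ]
    data.frame(sample_id = sprintf("%s_%s_%d", gs$tissue, gs$state, seq_len(gs$n)),
               tissue = gs$tissue, state = gs$state)
  }))
  v <- matrix(0, 2, nrow(meta),
              dimnames = list(c("G1", "G2"), meta$sample_id))
  v[1, meta$tissue == "motor_cortex" & meta$state == "SALS1"] <- 8
  v[1, meta$tissue == "motor_cortex" & meta$state == "CTRL"] <- 6
  v[2, meta$tissue == "motor_cortex" & meta$state == "SALS1"] <- 5
  v[2, meta$tissue == "motor_cortex" & meta$state == "CTRL"] <- 6.5
  m <- expr_matrix(v, level = "gene", stage = "normalized")
  pw <- pairwise_fold_changes(m, meta)
  r1 <- pw[pw$gene_id == "G1" & pw$contrast_id == "cortex_SALS1_vs_cortex_CTRL", ]
  expect_equal(r1$log2_fc, 2)
  expect_identical(r1$direction, "up")
  expect_equal(r1$fc, 4)
  r2 <- pw[pw$gene_id == "G2" & pw$contrast_id == "cortex_SALS1_vs_cortex_CTRL", ]
  expect_equal(r2$log2_fc, -1.5)
  expect_identical(r2$direction, "down")
  expect_equal(r2$fc, 2^1.5)
  expect_gt(r2$fc, 2)  # |FC| ~ 2.83 passes the cut
  r3 <- pw[pw$gene_id == "G1" & pw$contrast_id == "spinal_SALS1_vs_spinal_CTRL", ]
  expect_equal(r3$log2_fc, 0)
})

test_that("DEG selection uses strict thresholds and the gating rule", {
  anova <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    q_tissue = c(0.9, 0.9, 0.9, 0.9),
    q_state = c(0.04, 0.06, 0.01, 0.9),
    q_interaction = c(0.9, 0.9, 0.9, 0.01)
  )
  pw <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    contrast_id = "cortex_SALS1_vs_cortex_CTRL", type = "state",
    log2_fc = c(1.5, 3, 1, 2), direction = "up",
    fc = c(2^1.5, 8, 2, 4)
  )
  sel <- select_degs(anova, pw)
  expect_setequal(sel$degs$cortex_SALS1_vs_cortex_CTRL, c("G1", "G4"))
  # G2 fails q (0.06), G3 fails the strict FC cut (exactly 2)
  expect_false(sel$records$passes_threshold[sel$records$gene_id == "G2"])
  expect_false(sel$records$passes_threshold[sel$records$gene_id == "G3"])
  # interaction q rescues G4 for a state contrast under "effect" gating
  expect_true(sel$records$passes_threshold[sel$records$gene_id == "G4"])

  # tissue contrast gated on q_tissue/q_interaction, not q_state
  pw_t <- transform(pw, contrast_id = "cortex_CTRL_vs_spinal_CTRL",
                    type = "tissue")
  sel_t <- select_degs(anova, pw_t)
  expect_setequal(sel_t$degs$cortex_CTRL_vs_spinal_CTRL, "G4")
  sel_any <- select_degs(anova, pw_t, gating = "any")
  expect_setequal(sel_any$degs$cortex_CTRL_vs_spinal_CTRL, c("G1", "G4"))
})

test_that("DEG selection is monotone in alpha and fc_cut", {
  set.seed(21)
  anova <- data.frame(gene_id = paste0("G", 1:50),
                      q_tissue = runif(50), q_state = runif(50),
                      q_interaction = runif(50))
  lfc <- rnorm(50, 0, 2)
  pw <- data.frame(gene_id = paste0("G", 1:50), contrast_id = "c1",
                   type = "state", log2_fc = lfc,
                   direction = ifelse(lfc > 0, "up", "down"), fc = 2^abs(lfc))
  base <- select_degs(anova, pw, alpha = 0.05, fc_cut = 2)$degs$c1
  for (params in list(c(0.1, 2), c(0.05, 1.5), c(0.2, 1.2))) {
    relaxed <- select_degs(anova, pw, alpha = params[1],
                           fc_cut = params[2])$degs$c1
    expect_true(all(base %in% relaxed))
  }
})

test_that("Venn partitioning yields disjoint exhaustive regions", {
  vp <- venn_partition(list(A = c("a", "b"), B = c("b", "c")))
  reg <- setNames(vp$regions$count, vp$regions$region)
  expect_equal(reg[["A"]], 1)
  expect_equal(reg[["B"]], 1)
  expect_equal(reg[["A&B"]], 1)
  expect_equal(sum(vp$regions$count), 3)
  expect_false(any(duplicated(unlist(vp$members))))

  same <- venn_partition(list(X = c("a", "b"), Y = c("a", "b")))
  expect_identical(same$regions$region, "X&Y")

  disj <- venn_partition(list(X = "a", Y = "b"))
  expect_false("X&Y" %in% disj$regions$region)

  expect_error(venn_partition(list(A = "a")), "two sets")
  expect_error(venn_partition(setNames(list("a", "b"), c("A", "A"))), "unique")
})
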