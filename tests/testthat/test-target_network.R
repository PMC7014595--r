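test_that("correlate_pairs reproduces hand-computed Pearson values", {
  np <- 2
  design <- data.frame(sample_id = c("T1", "T2", "N1", "N2"),
                       group = rep(c("tumor", "normal"), each = np),
                       pair_id = rep(c("1", "2"), 2))
  mir <- matrix(c(1, 2, 3, 4,
                  4, 3, 2, 1), 2, 4, byrow = TRUE,
                dimnames = list(c("m1", "m2"), design$sample_id))
  gen <- matrix(c(1, 2, 3, 4,
                  2, 1, 4, 3), 2, 4, byrow = TRUE,
                dimnames = list(c("g1", "g2"), design$sample_id))
  me <- expr_matrix(mir, design); ge <- expr_matrix(gen, design)
  r <- correlate_pairs(me, ge, c("m1", "m2"), c("g1", "g2"))
  look <- function(m, g) r$r[r$mirna_id == m & r$gene_id == g]
  expect_equal(look("m1", "g1"), 1)                 # identical vectors
  expect_equal(look("m2", "g1"), -1)                # exact negation
  expect_equal(look("m1", "g2"), 0.6)               # hand-computed
  expect_equal(look("m1", "g2"), oracle_pearson(c(1, 2, 3, 4),
                                                c(2, 1, 4, 3)))
  # mismatched sample sets are an alignment error
  ge2 <- ge
  colnames(ge2$values) <- c("T1", "T2", "N1", "N9")
  ge2$design$sample_id <- colnames(ge2$values)
  expect_error(correlate_pairs(me, ge2, "m1", "g1"), "alignment")
})

test_that("zero-variance features yield NA correlations with a warning", {
  np <- 3
  design <- data.frame(sample_id = c(paste0("T", 1:np), paste0("N", 1:np)),
                       group = rep(c("tumor", "normal"), each = np),
                       pair_id = rep(as.character(1:np), 2))
  mir <- matrix(c(rep(5, 6), rnorm(6)), 2, 6, byrow = TRUE,
                dimnames = list(c("flat", "ok"), design$sample_id))
  gen <- matrix(rnorm(6), 1, 6, dimnames = list("g1", design$sample_id))
  expect_warning(
    r <- correlate_pairs(expr_matrix(mir, design),
                         expr_matrix(gen, design), c("flat", "ok"), "g1"),
    "zero-variance")
  expect_true(is.na(r$r[r$mirna_id == "flat"]))
  expect_false(is.na(r$r[r$mirna_id == "ok"]))
})

test_that("both filters must pass, with the stated boundary semantics", {
  cors <- data.frame(mirna_id = sprintf("m%d", 1:6),
                     gene_id = sprintf("g%d", 1:6),
                     r = c(-0.7, -0.7, -0.6, -0.59, -0.9, 0.7))
  pred <- data.frame(mirna_id = sprintf("m%d", c(1:5)),
                     gene_id = sprintf("g%d", c(1:5)),
                     w = rep(-0.2, 5),
                     pct = c(0.9, 0.5, 0.51, 0.9, 0.49))
  net <- build_target_network(cors, pred)
  # brute-force filter enumeration over the six candidates:
  # m1: r -0.7 <= -0.6, pct 0.9 > 0.5        -> kept
  # m2: pct exactly 0.5 (strict cut)          -> dropped
  # m3: r exactly -0.6 (inclusive), pct 0.51  -> kept
  # m4: r -0.59 above the cut                 -> dropped
  # m5: pct 0.49                              -> dropped
  # m6: no prediction row                     -> not a candidate
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$mirna_id, c("m1", "m3"))
  expect_equal(net$edges$w[net$edges$mirna_id == "m1"], -0.2)
})

test_that("filtering is idempotent and monotone in its cutoffs", {
  set.seed(33)
  cors <- data.frame(mirna_id = rep(sprintf("m%d", 1:10), each = 20),
                     gene_id = rep(sprintf("g%d", 1:20), times = 10),
                     r = runif(200, -1, 1))
  pred <- data.frame(mirna_id = rep(sprintf("m%d", 1:10), each = 20),
                     gene_id = rep(sprintf("g%d", 1:20), times = 10),
                     w = -abs(rnorm(200, 0.25, 0.1)),
                     pct = runif(200))
  net <- build_target_network(cors, pred)
  # rebuild from the network's own edge table: nothing changes
  own_cors <- net$edges[, c("mirna_id", "gene_id", "r")]
  own_pred <- data.frame(net$edges[, c("mirna_id", "gene_id", "w")],
                         pct = pred$pct[match(
                           paste(net$edges$mirna_id, net$edges$gene_id),
                           paste(pred$mirna_id, pred$gene_id))])
  net2 <- build_target_network(own_cors, own_pred)
  expect_equal(net2$edges, net$edges)
  # relaxing either cut never removes an edge
  for (cc in c(-0.5, -0.3, 0)) {
    bigger <- build_target_network(cors, pred, corr_cut = cc)
    expect_true(all(paste(net$edges$mirna_id, net$edges$gene_id) %in%
                      paste(bigger$edges$mirna_id, bigger$edges$gene_id)))
  }
  for (pc in c(0.4, 0.2, 0)) {
    bigger <- build_target_network(cors, pred, pct_cut = pc)
    expect_true(all(paste(net$edges$mirna_id, net$edges$gene_id) %in%
                      paste(bigger$edges$mirna_id, bigger$edges$gene_id)))
  }
})

test_that("planted miRNA-target edges are recovered on synthetic data", {
  recall <- false_rate <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_dataset(sim_config(seed = s, n_mirnas = 20,
                                       n_genes = 300, n_de_mirnas = 6,
                                       n_de_genes = 80,
                                       targets_per_mirna = 10,
                                       planted_pairs = list()))
    de_m <- de_features(paired_de(sim$mirna_expr))
    de_g <- de_features(paired_de(sim$mrna_expr))
    cors <- correlate_pairs(sim$mirna_expr, sim$mrna_expr, de_m, de_g)
    net <- build_target_network(cors, sim$predictions)
    truth_keys <- paste(sim$truth$edges$mirna_id, sim$truth$edges$gene_id)
    net_keys <- paste(net$edges$mirna_id, net$edges$gene_id)
    recall[s] <- mean(truth_keys %in% net_keys)
    false_rate[s] <- if (length(net_keys))
      mean(!(net_keys %in% truth_keys)) else 0
  }
  expect_gte(mean(recall), 0.8)
  expect_lte(mean(false_rate), 0.1)
})
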