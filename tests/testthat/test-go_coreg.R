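test_that("hypergeometric enrichment matches enumeration on a small universe", {
  universe <- sprintf("G%d", 1:10)
  term <- universe[1:5]
  targets <- universe[c(1, 2, 3, 4)]
  res <- enrich_targets(targets, list(T1 = term), universe)
  expect_equal(res$k, 4)
  # closed form C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # exhaustive enumeration over all 4-subsets of the universe
  expect_equal(res$p_value, oracle_hyper_enum(4, term, universe, 4),
               tolerance = 1e-12)
  # saturated term: k = n, p = 1
  res2 <- enrich_targets(targets, list(ALL = universe), universe)
  expect_equal(res2$p_value, 1)
  # contract errors
  expect_error(enrich_targets(character(0), list(T1 = term), universe),
               "empty target set")
  expect_error(enrich_targets(targets, list(T1 = term), character(0)),
               "empty universe")
})

test_that("hypergeometric p matches the choose-sum oracle on random instances", {
  set.seed(71)
  for (i in 1:300) {
    N <- sample(8:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- sprintf("G%d", 1:N)
    term <- sample(universe, K)
    targets <- sample(universe, n)
    k <- length(intersect(term, targets))
    if (k == 0) next
    res <- enrich_targets(targets, list(T1 = term), universe)
    expect_equal(res$p_value, oracle_hyper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("p-value rank order is stable under universe padding", {
  set.seed(5)
  universe <- sprintf("G%d", 1:50)
  anno <- lapply(1:8, function(i) sample(universe, 12))
  names(anno) <- sprintf("T%d", 1:8)
  targets <- sample(universe, 10)
  r1 <- enrich_targets(targets, anno, universe)
  r2 <- enrich_targets(targets, anno, c(universe, sprintf("PAD%d", 1:50)))
  shared <- intersect(r1$term_id, r2$term_id)
  o1 <- rank(r1$p_value[match(shared, r1$term_id)])
  o2 <- rank(r2$p_value[match(shared, r2$term_id)])
  expect_equal(o1, o2)
})

test_that("shared-term counting is symmetric with a strict high cut at N = 10", {
  mk <- function(id, terms, sig) {
    data.frame(mirna_id = id, term_id = terms, k = 2, K = 5, n = 5,
               N_univ = 100, p_value = 0.01, fdr = 0.01,
               significant = sig, stringsAsFactors = FALSE)
  }
  t12 <- sprintf("T%d", 1:12)
  a <- mk("ma", t12, TRUE)
  b <- mk("mb", t12, TRUE)
  cc <- count_shared_terms(a, b)
  expect_equal(cc$n_shared_terms, 12)
  expect_equal(cc$group, "high")
  expect_equal(count_shared_terms(b, a)$n_shared_terms, 12)
  # disjoint significant sets
  b2 <- mk("mb", sprintf("U%d", 1:12), TRUE)
  expect_equal(count_shared_terms(a, b2)$n_shared_terms, 0)
  expect_equal(count_shared_terms(a, b2)$group, "low")
  # exactly 10 shared terms is still the low group
  a10 <- mk("ma", sprintf("T%d", 1:10), TRUE)
  b10 <- mk("mb", sprintf("T%d", 1:10), TRUE)
  expect_equal(count_shared_terms(a10, b10)$group, "low")
  # N cannot exceed either significant set
  b5 <- mk("mb", t12, c(rep(TRUE, 5), rep(FALSE, 7)))
  expect_lte(count_shared_terms(a, b5)$n_shared_terms, 5)
})

test_that("random-group control: pair accounting, determinism, config error", {
  set.seed(8)
  universe <- sprintf("G%d", 1:80)
  anno <- lapply(1:20, function(i) sample(universe, 10))
  names(anno) <- sprintf("T%d", 1:20)
  sets <- lapply(1:8, function(i) sample(universe, 12))
  names(sets) <- sprintf("m%d", 1:8)
  ctl <- random_group_control(sets, group_size = 2, n_reps = 4,
                              annotation = anno, universe = universe,
                              seed = 3, observed_mirnas = c("m1", "m2"))
  expect_equal(ctl$pairs_per_replicate, 3)     # 2 self + 1 cross
  expect_length(ctl$null_high_fractions, 4)
  ctl2 <- random_group_control(sets, group_size = 2, n_reps = 4,
                               annotation = anno, universe = universe,
                               seed = 3, observed_mirnas = c("m1", "m2"))
  expect_identical(ctl$null_high_fractions, ctl2$null_high_fractions)
  expect_error(
    random_group_control(sets, group_size = 8, n_reps = 2,
                         annotation = anno, universe = universe),
    "config error")
})

test_that("planted synergistic pairs land in the high co-regulation group", {
  high <- null_lower <- logical(5)
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(seed = 400 + s, n_mirnas = 15,
                                       n_genes = 300, n_de_mirnas = 6,
                                       n_de_genes = 80, n_terms = 80))
    pt <- sim$truth$pairs[[1]]
    universe <- intersect(rownames(sim$mrna_expr$values),
                          unique(unlist(sim$annotation)))
    sets <- sim$truth$targets
    cc <- coregulation_counts(sets[c(pt$mirna_a, pt$mirna_b)],
                              sim$annotation, universe)
    high[s] <- cc$group[1] == "high"
    ctl <- random_group_control(sets, group_size = 3, n_reps = 10,
                                annotation = sim$annotation,
                                universe = universe, seed = s,
                                observed_mirnas = c(pt$mirna_a, pt$mirna_b,
                                                    sim$truth$de_mirnas[4]))
    null_lower[s] <- mean(ctl$null_high_fractions) <
      ctl$observed_high_fraction
  }
  expect_gte(sum(high), 4)
  expect_gte(sum(null_lower), 4)
})
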