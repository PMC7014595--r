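test_that("weight vectors partition the network's edge set", {
  cors <- data.frame(mirna_id = c("m1", "m1", "m1", "m2", "m2"),
                     gene_id = c("g1", "g2", "g3", "g2", "g4"),
                     r = rep(-0.8, 5))
  pred <- data.frame(mirna_id = cors$mirna_id, gene_id = cors$gene_id,
                     w = c(-0.1, -0.2, -0.3, -0.25, -0.4), pct = 0.9)
  net <- build_target_network(cors, pred)
  v <- build_weight_vectors(net)
  expect_named(v, c("m1", "m2"))
  expect_length(v$m1, 3)
  expect_equal(sum(lengths(v)), nrow(net$edges))
  expect_equal(v$m1[["g2"]], -0.2)
  # miRNA absent from the network has no vector
  expect_false("m3" %in% names(v))
})

test_that("synergism score: identity clamp, degenerate inputs, derived example", {
  va <- wvec(c(-0.1, -0.25, -0.4, -0.15))
  s <- synergism_score(va, va)
  expect_equal(s$r, 1)
  expect_equal(s$score, atanh(1 - 1e-7))   # clamp keeps the score finite
  # disjoint targets -> unscored
  vb <- wvec(c(-0.2, -0.3), genes = c("h1", "h2"))
  s2 <- synergism_score(va, vb)
  expect_false(s2$scored)
  expect_equal(s2$reason, "too_few_shared")
  # zero variance after alignment -> unscored with reason
  vc <- wvec(rep(-0.2, 4))
  s3 <- synergism_score(vc, vc)
  expect_false(s3$scored)
  expect_equal(s3$reason, "zero_variance")
  # derived 4-component alignment checked against the brute-force oracle
  a <- c(-0.1, -0.2, -0.3, 0)
  b <- c(-0.2, -0.4, -0.55, -0.1)
  s4 <- synergism_score(wvec(a[1:3]), wvec(b))
  expect_equal(s4$n_shared, 3)
  expect_equal(s4$r, oracle_pearson(a, b), tolerance = 1e-12)
  expect_equal(s4$score, atanh(oracle_pearson(a, b)), tolerance = 1e-12)
})

test_that("score is symmetric and r matches the oracle on random alignments", {
  set.seed(17)
  for (i in 1:250) {
    n_a <- sample(3:30, 1); n_b <- sample(3:30, 1)
    genes <- sprintf("g%d", 1:40)
    va <- wvec(-abs(rnorm(n_a, 0.25, 0.1)), sample(genes, n_a))
    vb <- wvec(-abs(rnorm(n_b, 0.25, 0.1)), sample(genes, n_b))
    sab <- synergism_score(va, vb, min_shared = 0)
    sba <- synergism_score(vb, va, min_shared = 0)
    expect_equal(sab$score, sba$score, tolerance = 1e-12)
    if (sab$scored) {
      genes_u <- union(names(va), names(vb))
      a <- setNames(rep(0, length(genes_u)), genes_u); b <- a
      a[names(va)] <- va; b[names(vb)] <- vb
      expect_equal(sab$r, oracle_pearson(a, b), tolerance = 1e-12)
    }
    # intersection alignment restricted to shared genes
    shared <- intersect(names(va), names(vb))
    if (length(shared) >= 3 && sd(va[shared]) > 0 && sd(vb[shared]) > 0) {
      si <- synergism_score(va, vb, alignment = "intersection")
      expect_equal(si$r, oracle_pearson(va[shared], vb[shared]),
                   tolerance = 1e-12)
    }
  }
})

test_that("fisher z is monotone in r and raw scale is available", {
  rs <- seq(-0.99, 0.99, by = 0.02)
  expect_true(all(diff(atanh(rs)) > 0))
  va <- wvec(c(-0.1, -0.2, -0.35, -0.05))
  vb <- wvec(c(-0.15, -0.22, -0.3, -0.1))
  expect_equal(synergism_score(va, vb, scale = "raw")$score,
               synergism_score(va, vb)$r)
})

test_that("exact randomization test enumerates all arrangements", {
  # 3 aligned components, observed arrangement uniquely maximal -> p = 1/6
  va <- wvec(c(-0.1, -0.2, -0.3))
  vb <- wvec(c(-0.15, -0.3, -0.5))
  obs <- synergism_score(va, vb)
  res <- randomization_test(va, vb, obs)
  expect_equal(res$method, "exact")
  expect_equal(res$n_arrangements, 6)
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$p_value, oracle_exact_perm(unname(va), unname(vb)))
  # self-comparison: observed is among the maxima
  obs2 <- synergism_score(va, va)
  res2 <- randomization_test(va, va, obs2)
  expect_lte(res2$p_value, 1 / 6 + 1e-12)
  # an unscored edge violates the contract
  expect_error(
    randomization_test(va, wvec(c(-0.2, -0.1), c("x1", "x2")),
                       synergism_score(va, wvec(c(-0.2, -0.1),
                                                c("x1", "x2")))),
    "contract error")
})

test_that("exact and Monte Carlo randomization p-values agree within 2 SE", {
  # 2 SE is a ~95% interval, so over several fixtures allow at most one
  # excursion rather than demanding every draw land inside it
  set.seed(29)
  ok <- logical(6)
  for (i in 1:6) {
    va <- wvec(-abs(rnorm(6, 0.25, 0.1)))
    vb <- wvec(-abs(rnorm(6, 0.25, 0.1)))
    obs <- synergism_score(va, vb)
    pe <- randomization_test(va, vb, obs)$p_value
    n_mc <- 2000
    pm <- randomization_test(va, vb, obs, exact_limit = 1, n_perm = n_mc,
                             seed = 1000 + i)$p_value
    se <- sqrt(pe * (1 - pe) / n_mc)
    ok[i] <- abs(pm - pe) <= 2 * se + 2 / n_mc
  }
  expect_gte(sum(ok), 5)
})

test_that("synergy network thresholding is inclusive at the score cut", {
  edges <- data.frame(mirna_a = c("a", "b", "c"),
                      mirna_b = c("b", "c", "d"),
                      n_shared = 5L, r = tanh(c(1.399, 1.400, 2.0)),
                      score = c(1.399, 1.400, 2.0), scored = TRUE,
                      reason = "", stringsAsFactors = FALSE)
  net <- build_synergy_network(edges)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("b", "c", "d"))
  # empty input -> empty network
  empty <- build_synergy_network(edges[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$nodes, 0)
  # self-loops never enter the reported network
  selfed <- rbind(edges,
                  data.frame(mirna_a = "a", mirna_b = "a", n_shared = 5L,
                             r = 0.99, score = 2.6, scored = TRUE,
                             reason = ""))
  expect_false(any(build_synergy_network(selfed)$edges$mirna_a ==
                     build_synergy_network(selfed)$edges$mirna_b))
})

test_that("hub ranking is deterministic with lexicographic tie-breaks", {
  tri <- data.frame(mirna_a = c("b", "a", "a"), mirna_b = c("c", "b", "c"),
                    n_shared = 3L, r = 0.9, score = 1.5, scored = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  h <- rank_hubs(build_synergy_network(tri))
  expect_equal(h$degree, c(2L, 2L, 2L))
  expect_equal(h$mirna_id, c("a", "b", "c"))
  star <- data.frame(mirna_a = c("c", "c", "c"), mirna_b = c("a", "b", "d"),
                     n_shared = 3L, r = 0.9, score = c(1.5, 1.6, 1.7),
                     scored = TRUE, reason = "", stringsAsFactors = FALSE)
  hs <- rank_hubs(build_synergy_network(star))
  expect_equal(hs$mirna_id[1], "c")
  expect_equal(hs$degree[1], 3L)
  # top pair is the maximum-score edge
  scores <- data.frame(mirna_a = c("a", "b", "c"), mirna_b = c("x", "y", "z"),
                       n_shared = 3L, r = 0.5, score = c(0.3, 2.31, 1.4),
                       scored = TRUE, reason = "", stringsAsFactors = FALSE)
  expect_equal(top_pair(scores)$score, 2.31)
  expect_equal(top_pair(scores)$mirna_a, "b")
})

test_that("score distribution report uses inclusive band membership", {
  mk <- function(s) data.frame(mirna_a = "a", mirna_b = "b", n_shared = 3L,
                               r = 0, score = s, scored = TRUE, reason = "")
  d <- score_distribution(mk(c(0.2, 1.3, 1.5)))
  expect_equal(d$frac_in_band, 2 / 3)
  expect_equal(d$frac_in_band + d$frac_above + d$frac_below, 1)
  expect_equal(score_distribution(mk(rep(0.7, 5)))$frac_in_band, 1)
  expect_equal(d$frac_high, 1 / 3)
})

test_that("pair accounting includes self-pairs: g(g+1)/2", {
  expect_equal(pair_count(28), 406)
  expect_equal(pair_count(2), 3)
  expect_equal(pair_count(1), 1)
})
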