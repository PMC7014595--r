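# Independent brute-force oracles. These deliberately avoid the code paths
# (and, where feasible, the library calls) used by the package itself.

# Pearson correlation from the raw covariance/sd definition
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# step-up BH by definition: adj_i = min over ranks j >= rank(i) of
# p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# one-sample t on a difference vector, by the textbook formula
oracle_t <- function(d) {
  n <- length(d)
  mn <- sum(d) / n
  s <- sqrt(sum((d - mn)^2) / (n - 1))
  mn / (s / sqrt(n))
}

# upper-tail hypergeometric P(X >= k) as an explicit choose() sum
oracle_hyper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# upper-tail hypergeometric by exhaustive enumeration of all n-subsets of
# the universe (feasible for small N only)
oracle_hyper_enum <- function(k, term, universe, n) {
  subs <- utils::combn(universe, n)
  mean(apply(subs, 2, function(s) length(intersect(s, term)) >= k))
}

# exact permutation p by direct enumeration over index permutations
oracle_exact_perm <- function(a, b) {
  n <- length(a)
  idx <- seq_len(n)
  perms <- expand.grid(rep(list(idx), n))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ]
  rs <- apply(perms, 1, function(r) oracle_pearson(a, b[as.integer(r)]))
  r_obs <- oracle_pearson(a, b)
  mean(rs >= r_obs - 1e-12)
}

# small expression fixture: nf features, np matched pairs; optional shift
# added to tumor columns of selected features
make_expr <- function(nf = 4, np = 3, shift = NULL, seed = 42,
                      noise = 0.5) {
  set.seed(seed)
  pair_ids <- sprintf("P%d", seq_len(np))
  design <- data.frame(
    sample_id = c(paste0("T", pair_ids), paste0("N", pair_ids)),
    group = rep(c("tumor", "normal"), each = np),
    pair_id = rep(pair_ids, 2), stringsAsFactors = FALSE)
  vals <- matrix(rnorm(nf * 2 * np, 8, noise), nf, 2 * np,
                 dimnames = list(sprintf("F%d", seq_len(nf)),
                                 design$sample_id))
  if (!is.null(shift))
    for (f in names(shift))
      vals[f, design$group == "tumor"] <-
        vals[f, design$group == "tumor"] + shift[[f]]
  expr_matrix(vals, design)
}

# named weight vector over gene ids g1..gn
wvec <- function(w, genes = sprintf("g%d", seq_along(w))) {
  stats::setNames(w, genes)
}
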