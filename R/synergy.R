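#' Target-weight vectors per miRNA
#'
#' For every miRNA in the network, the vector of context+ scores over its
#' network targets: V_M = (w(M, G1), w(M, G2), ...). The vectors jointly
#' partition the edge set.
#'
#' @param network a `mirna_target_network`.
#' @return named list of named numeric vectors (gene id -> w), one per miRNA.
#' @export
build_weight_vectors <- function(network) {
  stopifnot(inherits(network, "mirna_target_network"))
  e <- network$edges
  if (nrow(e) == 0) stop("empty network", call. = FALSE)
  split_w <- split(stats::setNames(e$w, e$gene_id), e$mirna_id)
  split_w[order(names(split_w))]
}

clamp_r <- 1 - 1e-7  # keeps atanh finite; atanh(1 - 1e-7) ~ 8.06

# align two weight vectors; returns list(a, b, n_shared) or NULL reason
align_vectors <- function(va, vb, alignment) {
  shared <- intersect(names(va), names(vb))
  genes <- if (alignment == "pair_union") union(names(va), names(vb)) else
    shared
  a <- stats::setNames(rep(0, length(genes)), genes)
  b <- a
  a[names(va)[names(va) %in% genes]] <- va[names(va) %in% genes]
  b[names(vb)[names(vb) %in% genes]] <- vb[names(vb) %in% genes]
  list(a = unname(a), b = unname(b), n_shared = length(shared))
}

#' Synergism score of a miRNA pair
#'
#' The two miRNAs' target-weight vectors are aligned on a common gene index:
#' by default the union of the two target sets with w = 0 where a miRNA
#' lacks the edge (`alignment = "pair_union"`), or the shared-target
#' intersection (`"intersection"`). The raw statistic r is the Pearson
#' correlation of the aligned vectors; the reported score is the Fisher
#' z-transform atanh(r) by default (r clamped to |r| <= 1 - 1e-7 so the
#' score stays finite), or r itself with `scale = "raw"`. Pairs sharing
#' fewer than `min_shared` targets, or with an aligned length below 3 or a
#' zero-variance aligned vector, are returned unscored with a reason code.
#'
#' @param va,vb named numeric weight vectors (gene id -> w), e.g. elements
#'   of [build_weight_vectors()].
#' @param alignment `"pair_union"` (default) or `"intersection"`.
#' @param scale `"fisher_z"` (default) or `"raw"`.
#' @param min_shared minimum shared-target count to score a pair, default 3.
#' @param mirna_a,mirna_b optional ids recorded in the result.
#' @return one-row data.frame: mirna_a, mirna_b, n_shared, r, score, scored,
#'   reason.
#' @export
synergism_score <- function(va, vb,
                            alignment = c("pair_union", "intersection"),
                            scale = c("fisher_z", "raw"), min_shared = 3,
                            mirna_a = "a", mirna_b = "b") {
  alignment <- match.arg(alignment)
  scale <- match.arg(scale)
  if (length(va) == 0 || length(vb) == 0)
    stop("empty weight vector", call. = FALSE)
  al <- align_vectors(va, vb, alignment)
  res <- data.frame(mirna_a = mirna_a, mirna_b = mirna_b,
                    n_shared = al$n_shared, r = NA_real_, score = NA_real_,
                    scored = FALSE, reason = "", stringsAsFactors = FALSE)
  if (al$n_shared < min_shared) {
    res$reason <- "too_few_shared"
    return(res)
  }
  if (length(al$a) < 3) {
    res$reason <- "aligned_too_short"
    return(res)
  }
  if (stats::sd(al$a) == 0 || stats::sd(al$b) == 0) {
    res$reason <- "zero_variance"
    return(res)
  }
  r <- stats::cor(al$a, al$b)
  res$r <- r
  res$score <- if (scale == "fisher_z") atanh(max(-clamp_r, min(clamp_r, r)))
  else r
  res$scored <- TRUE
  res
}

#' Score all miRNA pairs of a network
#'
#' Applies [synergism_score()] to every unordered pair of the network's
#' weight vectors (self-pairs excluded by default; include them only for
#' pair-accounting controls).
#'
#' @param vectors output of [build_weight_vectors()].
#' @param include_self also score each miRNA against itself (default FALSE).
#' @inheritParams synergism_score
#' @return data.frame, one row per pair, ordered by (mirna_a, mirna_b).
#' @export
score_all_pairs <- function(vectors, alignment = "pair_union",
                            scale = "fisher_z", min_shared = 3,
                            include_self = FALSE) {
  ids <- names(vectors)
  rows <- list()
  for (i in seq_along(ids)) {
    jj <- if (include_self) i:length(ids) else
      if (i < length(ids)) (i + 1):length(ids) else integer(0)
    for (j in jj) {
      rows[[length(rows) + 1L]] <-
        synergism_score(vectors[[i]], vectors[[j]], alignment = alignment,
                        scale = scale, min_shared = min_shared,
                        mirna_a = ids[i], mirna_b = ids[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# all permutations of 1..n as an (n! x n) index matrix
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    blk <- nrow(sub)
    out[row:(row + blk - 1L), 1L] <- k
    out[row:(row + blk - 1L), -1L] <- matrix(rest[sub], blk, n - 1L)
    row <- row + blk
  }
  out
}

# correlations of fixed a against each row-permutation of b (rows of B)
perm_cors <- function(a, B) {
  n <- length(a)
  ac <- a - mean(a)
  sa <- sqrt(sum(ac^2))
  bc <- B - mean(B[1, ])        # permutation leaves mean/sd unchanged
  sb <- sqrt(sum(bc[1, ]^2))
  as.vector(bc %*% ac) / (sa * sb)
}

#' Randomization test for a synergism score
#'
#' Null distribution generated by permuting the gene-to-weight assignment of
#' the second miRNA's aligned components while fixing the first. When the
#' number of arrangements m! is at most `exact_limit` (default 8! = 40320)
#' all permutations are enumerated and the exact one-sided p-value
#' #\{r_perm >= r_obs\} / m! is returned; otherwise Monte Carlo sampling with
#' the add-one estimate p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1). High
#' scores indicate synergy, so the test is one-sided upward; the comparison
#' is on r (the Fisher z-scale is monotone, so the p-value is identical on
#' either scale).
#'
#' @inheritParams synergism_score
#' @param observed a scored row from [synergism_score()].
#' @param n_perm Monte Carlo permutation count, default 1000.
#' @param exact_limit enumerate exhaustively when m! <= this, default 40320.
#' @param seed integer seed for the Monte Carlo branch.
#' @return list with elements p_value, method ("exact"/"monte_carlo"),
#'   n_arrangements.
#' @export
randomization_test <- function(va, vb, observed,
                               alignment = c("pair_union", "intersection"),
                               n_perm = 1000, exact_limit = 40320,
                               seed = NULL) {
  alignment <- match.arg(alignment)
  if (!isTRUE(observed$scored))
    stop("contract error: randomization test requires a scored edge",
         call. = FALSE)
  al <- align_vectors(va, vb, alignment)
  a <- al$a; b <- al$b
  m <- length(a)
  r_obs <- stats::cor(a, b)
  tol <- 1e-12
  if (factorial(m) <= exact_limit) {
    P <- perm_matrix(m)
    B <- matrix(b[P], nrow(P), m)
    rs <- perm_cors(a, B)
    list(p_value = mean(rs >= r_obs - tol), method = "exact",
         n_arrangements = nrow(P))
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- t(replicate(n_perm, sample(b)))
    rs <- perm_cors(a, B)
    list(p_value = (1 + sum(rs >= r_obs - tol)) / (n_perm + 1),
         method = "monte_carlo", n_arrangements = n_perm)
  }
}

#' Attach randomization p-values to a scored-pairs table
#'
#' @param pairs output of [score_all_pairs()].
#' @param vectors the weight vectors used to score them.
#' @inheritParams randomization_test
#' @return `pairs` with columns p_value and perm_method added (NA for
#'   unscored rows).
#' @export
test_all_pairs <- function(pairs, vectors, alignment = "pair_union",
                           n_perm = 1000, exact_limit = 40320, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs$p_value <- NA_real_
  pairs$perm_method <- NA_character_
  for (i in seq_len(nrow(pairs))) {
    if (!pairs$scored[i]) next
    res <- randomization_test(vectors[[pairs$mirna_a[i]]],
                              vectors[[pairs$mirna_b[i]]],
                              observed = pairs[i, ], alignment = alignment,
                              n_perm = n_perm, exact_limit = exact_limit)
    pairs$p_value[i] <- res$p_value
    pairs$perm_method[i] <- res$method
  }
  pairs
}

#' Thresholded miRNA-miRNA synergy network
#'
#' Keeps scored edges with score >= `score_threshold` (inclusive) and, when
#' `p_cut` is given, randomization p-value < `p_cut`. Self-loops are never
#' part of the reported network.
#'
#' @param edges scored-pairs data.frame ([score_all_pairs()], optionally
#'   with p-values from [test_all_pairs()]).
#' @param score_threshold default 1.400 (on the Fisher-z reporting scale;
#'   equivalent to raw r >= tanh(1.400) ~ 0.885).
#' @param p_cut optional p-value cut (strict), default NULL = no p filter.
#' @return object of class `synergy_network`: list(edges, nodes).
#' @export
build_synergy_network <- function(edges, score_threshold = 1.400,
                                  p_cut = NULL) {
  keep <- !is.na(edges$score) & edges$score >= score_threshold &
    edges$mirna_a != edges$mirna_b
  if (!is.null(p_cut)) keep <- keep & !is.na(edges$p_value) &
      edges$p_value < p_cut
  e <- edges[keep, , drop = FALSE]
  e <- e[order(e$mirna_a, e$mirna_b), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e,
                 nodes = sort(unique(c(e$mirna_a, e$mirna_b)))),
            class = "synergy_network")
}

#' @export
print.synergy_network <- function(x, ...) {
  cat("synergy network:", length(x$nodes), "miRNAs,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Rank hub miRNAs of a synergy network
#'
#' Degree and summed edge score per node, ranked by degree, then summed
#' score, ties broken lexicographically by miRNA id.
#'
#' @param network a `synergy_network`.
#' @return data.frame mirna_id, degree, sum_score (ranked).
#' @export
rank_hubs <- function(network) {
  stopifnot(inherits(network, "synergy_network"))
  e <- network$edges
  ids <- network$nodes
  if (length(ids) == 0)
    return(data.frame(mirna_id = character(0), degree = integer(0),
                      sum_score = numeric(0)))
  deg <- sapply(ids, function(m) sum(e$mirna_a == m) + sum(e$mirna_b == m))
  ss <- sapply(ids, function(m)
    sum(e$score[e$mirna_a == m]) + sum(e$score[e$mirna_b == m]))
  out <- data.frame(mirna_id = ids, degree = as.integer(deg), sum_score = ss,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$sum_score, out$mirna_id), ]
  rownames(out) <- NULL
  out
}

#' Maximum-score synergy edge
#' @param edges scored-pairs data.frame.
#' @return the single highest-score row (ties broken by pair ids).
#' @export
top_pair <- function(edges) {
  e <- edges[!is.na(edges$score), , drop = FALSE]
  if (nrow(e) == 0) stop("no scored edges", call. = FALSE)
  e <- e[order(-e$score, e$mirna_a, e$mirna_b), , drop = FALSE]
  e[1, , drop = FALSE]
}

#' Distribution summary of synergism scores
#'
#' Fraction of scored pairs falling inside a band (inclusive at both ends),
#' above it, below it, and at/above a high cut-off.
#'
#' @param edges scored-pairs data.frame.
#' @param band numeric length-2, default c(0.2, 1.3).
#' @param high_cut default 1.400.
#' @return list with n_pairs, frac_in_band, frac_below, frac_above,
#'   frac_high.
#' @export
score_distribution <- function(edges, band = c(0.2, 1.3), high_cut = 1.400) {
  s <- edges$score[!is.na(edges$score)]
  n <- length(s)
  list(n_pairs = n,
       frac_in_band = if (n) mean(s >= band[1] & s <= band[2]) else NA_real_,
       frac_below = if (n) mean(s < band[1]) else NA_real_,
       frac_above = if (n) mean(s > band[2]) else NA_real_,
       frac_high = if (n) mean(s >= high_cut) else NA_real_)
}

#' Unordered-pair count including self-pairs
#'
#' For a group of g miRNAs the pairwise accounting that includes each
#' miRNA paired with itself yields g(g+1)/2 pairs (28 miRNAs -> 406).
#'
#' @param g group size.
#' @return pair count.
#' @export
pair_count <- function(g) {
  stopifnot(g >= 0)
  g * (g + 1) / 2
}
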