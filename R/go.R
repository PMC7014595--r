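#' Hypergeometric over-representation of a miRNA's target set
#'
#' For each annotation term, tests whether the target set overlaps the term
#' more than expected by chance in the gene universe: with universe size
#' N, term size K (after intersecting the term with the universe), target
#' set size n and overlap k, the upper-tail hypergeometric p-value
#' P(X >= k), X ~ Hypergeom(N, K, n). Terms with zero overlap are skipped.
#' BH adjustment is applied across the tested terms of this one target set;
#' terms with adjusted p below `fdr_cut` are flagged significant.
#'
#' @param target_set character vector of gene ids (a miRNA's network
#'   targets); genes outside the universe are ignored.
#' @param annotation named list of gene-id vectors (term -> genes), e.g.
#'   from [read_gmt()].
#' @param universe character vector of background gene ids.
#' @param fdr_cut significance cut-off on the adjusted p, default 0.05.
#' @param mirna_id optional id recorded in the result.
#' @return data.frame: mirna_id, term_id, k, K, n, N_univ, p_value, fdr,
#'   significant.
#' @export
enrich_targets <- function(target_set, annotation, universe,
                           fdr_cut = 0.05, mirna_id = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0)
    stop("contract error: empty universe", call. = FALSE)
  targets <- intersect(unique(target_set), universe)
  if (length(targets) == 0)
    stop("contract error: empty target set (after universe intersection)",
         call. = FALSE)
  N <- length(universe)
  n <- length(targets)
  rows <- lapply(names(annotation), function(tid) {
    term <- intersect(annotation[[tid]], universe)
    K <- length(term)
    if (K == 0) return(NULL)
    k <- length(intersect(targets, term))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(mirna_id = mirna_id, term_id = tid, k = k, K = K, n = n,
               N_univ = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(0), term_id = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N_univ = integer(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$fdr < fdr_cut
  rownames(out) <- NULL
  out
}

significant_terms <- function(enrichment) {
  enrichment$term_id[enrichment$significant]
}

# significant-term set, tolerating target sets that miss the universe
# entirely (no annotated target -> nothing can be enriched)
sig_terms_safe <- function(targets, annotation, universe, fdr_cut, id) {
  if (length(intersect(targets, universe)) == 0) return(character(0))
  significant_terms(enrich_targets(targets, annotation, universe,
                                   fdr_cut = fdr_cut, mirna_id = id))
}

#' Count co-regulated GO terms for a miRNA pair
#'
#' N = number of terms significantly enriched in both miRNAs' target sets;
#' a pair is classed `"high"` when N > `threshold` (strict) and `"low"`
#' otherwise. Both enrichments must come from the same annotation and
#' universe for N to be meaningful.
#'
#' @param res_a,res_b enrichment tables from [enrich_targets()].
#' @param threshold high/low split, default 10.
#' @return list with mirna_a, mirna_b, n_shared_terms, group.
#' @export
count_shared_terms <- function(res_a, res_b, threshold = 10) {
  n <- length(intersect(significant_terms(res_a),
                        significant_terms(res_b)))
  list(mirna_a = if (nrow(res_a)) res_a$mirna_id[1] else NA_character_,
       mirna_b = if (nrow(res_b)) res_b$mirna_id[1] else NA_character_,
       n_shared_terms = n,
       group = if (n > threshold) "high" else "low")
}

# shared-term counts for every unordered pair (incl. self) of a group,
# given precomputed significant-term sets
pairwise_shared_counts <- function(sig_sets) {
  ids <- names(sig_sets)
  g <- length(ids)
  rows <- vector("list", pair_count(g))
  idx <- 1L
  for (i in seq_len(g)) for (j in i:g) {
    n <- length(intersect(sig_sets[[i]], sig_sets[[j]]))
    rows[[idx]] <- data.frame(mirna_a = ids[i], mirna_b = ids[j],
                              n_shared_terms = n, stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-regulation counts for a set of miRNAs
#'
#' Enriches each miRNA's target set and counts shared significant terms for
#' every pair. Self-pairs are excluded from reported co-regulation edges
#' (they are included only in the [random_group_control()] accounting).
#'
#' @param target_sets named list mapping miRNA id -> target gene ids.
#' @param annotation,universe,fdr_cut as in [enrich_targets()].
#' @param threshold high/low split on the shared-term count, default 10.
#' @return data.frame mirna_a, mirna_b, n_shared_terms, group.
#' @export
coregulation_counts <- function(target_sets, annotation, universe,
                                fdr_cut = 0.05, threshold = 10) {
  sig <- lapply(names(target_sets), function(m)
    sig_terms_safe(target_sets[[m]], annotation, universe, fdr_cut, m))
  names(sig) <- names(target_sets)
  out <- pairwise_shared_counts(sig)
  out <- out[out$mirna_a != out$mirna_b, , drop = FALSE]
  out$group <- ifelse(out$n_shared_terms > threshold, "high", "low")
  rownames(out) <- NULL
  out
}

#' Random-group control for functional co-regulation
#'
#' Repeatedly samples `group_size` miRNAs from the background mapping,
#' computes the pairwise shared significant-term count over all unordered
#' pairs including self-pairs — group_size (group_size + 1)/2 pairs, i.e.
#' 406 for 28 miRNAs — and records the fraction of pairs in the high group
#' (N > `threshold`). When `observed_mirnas` is supplied, the same fraction
#' is computed for that group and compared to the null with an add-one
#' empirical p-value (one-sided: observed fraction at least as high).
#'
#' @param target_sets named list mapping miRNA id -> target gene ids
#'   (background to sample from; must contain more than `group_size` ids).
#' @param group_size miRNAs per random group, default 28.
#' @param n_reps number of random groups.
#' @param annotation,universe,fdr_cut as in [enrich_targets()].
#' @param threshold high/low split, default 10.
#' @param seed integer RNG seed.
#' @param observed_mirnas optional character vector (e.g. the synergy
#'   network's nodes) whose high-group fraction is compared to the null.
#' @return list: observed_high_fraction (NA if no observed group),
#'   null_high_fractions (length n_reps), p_value, pairs_per_replicate.
#' @export
random_group_control <- function(target_sets, group_size = 28, n_reps = 50,
                                 annotation, universe, fdr_cut = 0.05,
                                 threshold = 10, seed = 1,
                                 observed_mirnas = NULL) {
  ids <- names(target_sets)
  if (length(ids) <= group_size)
    stop("config error: background must be larger than group_size",
         call. = FALSE)
  sig <- lapply(ids, function(m)
    sig_terms_safe(target_sets[[m]], annotation, universe, fdr_cut, m))
  names(sig) <- ids
  high_frac <- function(members) {
    cnt <- pairwise_shared_counts(sig[members])
    mean(cnt$n_shared_terms > threshold)
  }
  set.seed(seed)
  nulls <- replicate(n_reps, high_frac(sample(ids, group_size)))
  obs <- NA_real_
  p <- NA_real_
  if (!is.null(observed_mirnas)) {
    missing <- setdiff(observed_mirnas, ids)
    if (length(missing))
      stop("observed miRNA(s) absent from background: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    obs <- high_frac(observed_mirnas)
    p <- (1 + sum(nulls >= obs)) / (n_reps + 1)
  }
  list(observed_high_fraction = obs, null_high_fractions = nulls,
       p_value = p,
       pairs_per_replicate = pair_count(group_size))
}
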