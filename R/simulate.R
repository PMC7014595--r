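#' Simulation configuration for matched tumor/normal miRNA+mRNA data
#'
#' Defines the generative conditions for the synthetic study: a paired
#' tumor/normal design, planted differentially expressed miRNAs and genes,
#' repressive miRNA-target links producing negative expression correlation,
#' a prediction table with context+ weights and conservation probabilities,
#' planted synergistic miRNA pairs sharing targets with calibrated weight
#' profiles, and a gene-set annotation in which shared targets of planted
#' pairs co-occur in many terms.
#'
#' @param n_pairs matched tumor/normal pairs (default 17).
#' @param n_mirnas,n_genes feature counts (defaults 50 and 1000).
#' @param n_de_mirnas,n_de_genes planted differential features (defaults 10
#'   and 150). Planted targets are drawn from the DE gene pool.
#' @param effect_size mean |log2 fold change| of planted DE features
#'   (default 1.0); planted DE miRNAs are down-regulated in tumors.
#' @param noise_sd per-observation Gaussian noise, log2 scale (default 0.5).
#' @param pair_sd sd of the per-pair random intercept shared by a pair's
#'   tumor and normal columns (default 0.3), so the paired design matters.
#' @param repression_strength slope linking a planted miRNA's (centred)
#'   expression to its targets' expression; negative (default -0.8).
#' @param targets_per_mirna planted targets per DE miRNA (default 20).
#' @param planted_pairs list of lists with fields `a`, `b` (indices into
#'   the DE miRNAs, optional; consecutive DE miRNAs by default),
#'   `n_shared` (shared-target count) and `profile_cor` (target correlation
#'   of the two miRNAs' weights over the shared targets). Default: one pair
#'   sharing 20 targets at profile correlation 0.95.
#' @param n_bg_predictions background (non-planted) prediction rows
#'   (default 10 * n_mirnas), with pct straddling the 0.5 filter.
#' @param n_terms background annotation terms (default 150).
#' @param term_size_range size range of background terms (default 10..50).
#' @param n_planted_terms terms per planted pair built around its shared
#'   targets so the pair lands in the high co-regulation group (default 15).
#' @param seed integer RNG seed; fixes the full output byte-for-byte.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 17, n_mirnas = 50, n_genes = 1000,
                       n_de_mirnas = 10, n_de_genes = 150,
                       effect_size = 1.0, noise_sd = 0.5, pair_sd = 0.3,
                       repression_strength = -0.8, targets_per_mirna = 20,
                       planted_pairs = list(list(n_shared = 20,
                                                 profile_cor = 0.95)),
                       n_bg_predictions = 10 * n_mirnas,
                       n_terms = 150, term_size_range = c(10, 50),
                       n_planted_terms = 15, seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_mirnas = n_mirnas, n_genes = n_genes,
              n_de_mirnas = n_de_mirnas, n_de_genes = n_de_genes,
              effect_size = effect_size, noise_sd = noise_sd,
              pair_sd = pair_sd, repression_strength = repression_strength,
              targets_per_mirna = targets_per_mirna,
              planted_pairs = planted_pairs,
              n_bg_predictions = n_bg_predictions, n_terms = n_terms,
              term_size_range = term_size_range,
              n_planted_terms = n_planted_terms, seed = as.integer(seed))
  counts <- c(n_pairs = n_pairs, n_mirnas = n_mirnas, n_genes = n_genes)
  if (any(counts <= 0))
    stop("config error: counts must be positive", call. = FALSE)
  if (n_de_mirnas < 0 || n_de_mirnas > n_mirnas)
    stop("config error: n_de_mirnas must lie in [0, n_mirnas]",
         call. = FALSE)
  if (n_de_genes < 0 || n_de_genes > n_genes)
    stop("config error: n_de_genes must lie in [0, n_genes]", call. = FALSE)
  if (n_de_mirnas > 0 && targets_per_mirna > n_de_genes)
    stop("config error: targets_per_mirna exceeds the DE gene pool",
         call. = FALSE)
  np <- length(planted_pairs)
  if (np > 0) {
    if (n_de_mirnas < 2 * np && is.null(planted_pairs[[1]]$a))
      stop("config error: not enough DE miRNAs for the planted pairs",
           call. = FALSE)
    for (pp in planted_pairs) {
      if (is.null(pp$n_shared) || is.null(pp$profile_cor))
        stop("config error: planted pair needs n_shared and profile_cor",
             call. = FALSE)
      if (pp$n_shared > n_de_genes || pp$n_shared > targets_per_mirna)
        stop("config error: planted n_shared exceeds targets_per_mirna or ",
             "the DE gene pool", call. = FALSE)
      if (abs(pp$profile_cor) >= 1)
        stop("config error: profile_cor must lie in (-1, 1)", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# context+ scores: negative half-normal around -0.25
draw_w <- function(n) -abs(stats::rnorm(n, 0.25, 0.1))

# second weight profile with target correlation rho to x, kept negative
correlated_w <- function(x, rho) {
  z <- (x - mean(x)) / stats::sd(x)
  e <- stats::rnorm(length(x))
  e <- (e - mean(e)) / stats::sd(e)
  # orthogonalize the noise against the signal so the sample correlation
  # lands near rho, not just in expectation
  e <- e - z * sum(e * z) / sum(z * z)
  e <- e / stats::sd(e)
  y <- -0.25 + 0.1 * (rho * z + sqrt(1 - rho^2) * e)
  pmin(y, -0.01)
}

#' Generate a full synthetic dataset with planted structure
#'
#' Baseline log2 expression is Normal(8, 2) per feature; a per-feature,
#' per-pair random intercept (sd `pair_sd`) is shared by a pair's tumor and
#' normal columns; observation noise is Normal(0, `noise_sd`). Planted DE
#' miRNAs receive -`effect_size` in tumor columns. Each planted target
#' gene's expression adds `repression_strength` times the sum of its
#' targeting miRNAs' centred realized expression, so (i) targets of
#' down-regulated miRNAs are up-regulated in tumors and (ii) the pooled
#' tumor+normal correlation between a planted miRNA and each of its targets
#' is negative. DE genes that end up targeted by no miRNA receive a direct
#' tumor effect of random sign. Planted prediction rows carry pct ~
#' Beta(8, 2); background rows pct ~ Beta(2, 2), so the PCT > 0.5 filter is
#' exercised in both directions. Annotation terms are random gene sets plus,
#' per planted pair, `n_planted_terms` terms built around its shared
#' targets.
#'
#' @param config a [sim_config].
#' @return list with elements `mirna_expr`, `mrna_expr` ([expr_matrix]),
#'   `predictions` (data.frame mirna_id, gene_id, w, pct), `annotation`
#'   (named list, GMT-compatible), and `truth` — a list recording every
#'   planted fact: `de_mirnas`, `de_genes`, `edges` (planted miRNA-target
#'   rows), `pairs` (planted synergistic pairs with their shared targets),
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  mirna_ids <- sprintf("miR-%03d", seq_len(cf$n_mirnas))
  gene_ids <- sprintf("GENE%04d", seq_len(cf$n_genes))
  pair_ids <- sprintf("P%02d", seq_len(cf$n_pairs))
  design <- data.frame(
    sample_id = c(paste0("T", pair_ids), paste0("N", pair_ids)),
    group = rep(c("tumor", "normal"), each = cf$n_pairs),
    pair_id = rep(pair_ids, 2), stringsAsFactors = FALSE)
  tumor_col <- design$group == "tumor"

  de_mirnas <- sort(sample(mirna_ids, cf$n_de_mirnas))
  de_genes <- sort(sample(gene_ids, cf$n_de_genes))

  # planted target assignment: each DE miRNA samples its targets from the
  # DE gene pool; planted pairs overwrite part of both lists with a common
  # shared set
  targets <- lapply(de_mirnas, function(m)
    sample(de_genes, cf$targets_per_mirna))
  names(targets) <- de_mirnas
  pairs_truth <- list()
  next_free <- 1L
  for (pp in cf$planted_pairs) {
    if (is.null(pp$a)) {
      ia <- next_free; ib <- next_free + 1L; next_free <- next_free + 2L
    } else {
      ia <- pp$a; ib <- pp$b
    }
    if (ib > length(de_mirnas))
      stop("config error: planted pair index exceeds n_de_mirnas",
           call. = FALSE)
    a <- de_mirnas[ia]; b <- de_mirnas[ib]
    shared <- sample(de_genes, pp$n_shared)
    own <- cf$targets_per_mirna - pp$n_shared
    targets[[a]] <- c(shared, sample(setdiff(de_genes, shared), own))
    targets[[b]] <- c(shared, sample(setdiff(de_genes, shared), own))
    pairs_truth[[length(pairs_truth) + 1L]] <-
      list(mirna_a = a, mirna_b = b, n_shared = pp$n_shared,
           profile_cor = pp$profile_cor, shared_targets = shared)
  }

  # planted prediction weights; planted pairs get calibrated shared profiles
  w_tab <- list()
  for (m in de_mirnas)
    w_tab[[m]] <- stats::setNames(draw_w(length(targets[[m]])), targets[[m]])
  for (pt in pairs_truth) {
    wa <- w_tab[[pt$mirna_a]][pt$shared_targets]
    w_tab[[pt$mirna_b]][pt$shared_targets] <-
      correlated_w(wa, pt$profile_cor)
  }
  planted_pred <- do.call(rbind, lapply(de_mirnas, function(m)
    data.frame(mirna_id = m, gene_id = names(w_tab[[m]]),
               w = unname(w_tab[[m]]),
               pct = stats::rbeta(length(w_tab[[m]]), 8, 2),
               stringsAsFactors = FALSE)))

  # background predictions: random non-planted (miRNA, gene) rows
  bg_m <- sample(mirna_ids, cf$n_bg_predictions, replace = TRUE)
  bg_g <- sample(gene_ids, cf$n_bg_predictions, replace = TRUE)
  bg <- data.frame(mirna_id = bg_m, gene_id = bg_g,
                   w = draw_w(cf$n_bg_predictions),
                   pct = stats::rbeta(cf$n_bg_predictions, 2, 2),
                   stringsAsFactors = FALSE)
  key_p <- paste(planted_pred$mirna_id, planted_pred$gene_id)
  bg <- bg[!(paste(bg$mirna_id, bg$gene_id) %in% key_p), , drop = FALSE]
  bg <- bg[!duplicated(paste(bg$mirna_id, bg$gene_id)), , drop = FALSE]
  predictions <- rbind(if (length(de_mirnas)) planted_pred else NULL, bg)
  predictions <- predictions[order(predictions$mirna_id,
                                   predictions$gene_id), , drop = FALSE]
  rownames(predictions) <- NULL

  # expression: miRNAs first (targets depend on their realized values)
  ns <- 2 * cf$n_pairs
  base_m <- stats::rnorm(cf$n_mirnas, 8, 2)
  mir_vals <- matrix(stats::rnorm(cf$n_mirnas * ns, 0, cf$noise_sd),
                     cf$n_mirnas, ns,
                     dimnames = list(mirna_ids, design$sample_id))
  pair_int_m <- matrix(stats::rnorm(cf$n_mirnas * cf$n_pairs, 0,
                                    cf$pair_sd), cf$n_mirnas, cf$n_pairs)
  mir_vals <- mir_vals + base_m +
    pair_int_m[, match(design$pair_id, pair_ids), drop = FALSE]
  mir_vals[de_mirnas, tumor_col] <-
    mir_vals[de_mirnas, tumor_col] - cf$effect_size

  base_g <- stats::rnorm(cf$n_genes, 8, 2)
  gene_vals <- matrix(stats::rnorm(cf$n_genes * ns, 0, cf$noise_sd),
                      cf$n_genes, ns,
                      dimnames = list(gene_ids, design$sample_id))
  pair_int_g <- matrix(stats::rnorm(cf$n_genes * cf$n_pairs, 0, cf$pair_sd),
                       cf$n_genes, cf$n_pairs)
  gene_vals <- gene_vals + base_g +
    pair_int_g[, match(design$pair_id, pair_ids), drop = FALSE]

  targeted <- unique(unlist(targets, use.names = FALSE))
  for (m in de_mirnas) {
    centred <- mir_vals[m, ] - mean(mir_vals[m, ])
    for (g in targets[[m]])
      gene_vals[g, ] <- gene_vals[g, ] + cf$repression_strength * centred
  }
  direct_de <- setdiff(de_genes, targeted)
  if (length(direct_de)) {
    signs <- sample(c(-1, 1), length(direct_de), replace = TRUE)
    gene_vals[direct_de, tumor_col] <- gene_vals[direct_de, tumor_col] +
      signs * cf$effect_size
  }

  annotation <- simulate_annotation(cf, gene_ids, pairs_truth)

  truth_edges <- do.call(rbind, c(list(
    data.frame(mirna_id = character(0), gene_id = character(0),
               w = numeric(0), stringsAsFactors = FALSE)),
    lapply(de_mirnas, function(m)
      data.frame(mirna_id = m, gene_id = names(w_tab[[m]]),
                 w = unname(w_tab[[m]]), stringsAsFactors = FALSE))))
  rownames(truth_edges) <- NULL

  list(mirna_expr = expr_matrix(mir_vals, design),
       mrna_expr = expr_matrix(gene_vals, design),
       predictions = predictions,
       annotation = annotation,
       truth = list(de_mirnas = de_mirnas, de_genes = de_genes,
                    targets = targets, edges = truth_edges,
                    pairs = pairs_truth, config = cf))
}

# background terms are random gene sets; each planted pair contributes
# n_planted_terms terms built around most of its shared targets, so its
# miRNAs' target sets are both enriched in > 10 common terms
simulate_annotation <- function(cf, gene_ids, pairs_truth) {
  sets <- list()
  for (i in seq_len(cf$n_terms)) {
    sz <- sample(cf$term_size_range[1]:cf$term_size_range[2], 1)
    sets[[sprintf("GO:BG%04d", i)]] <- sample(gene_ids,
                                              min(sz, length(gene_ids)))
  }
  pi <- 0L
  for (pt in pairs_truth) {
    pi <- pi + 1L
    for (j in seq_len(cf$n_planted_terms)) {
      core_n <- max(3, ceiling(0.7 * length(pt$shared_targets)))
      core <- sample(pt$shared_targets, core_n)
      pool <- setdiff(gene_ids, pt$shared_targets)
      filler <- sample(pool, min(20, length(pool)))
      sets[[sprintf("GO:PL%02d_%02d", pi, j)]] <- c(core, filler)
    }
  }
  attr(sets, "descriptions") <- stats::setNames(
    rep("synthetic term", length(sets)), names(sets))
  sets
}

#' Write all simulated outputs to a directory
#'
#' Expression + design TSVs for both assays, the prediction table, the GMT
#' annotation and the truth table (planted facts) as TSVs.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  write_expression(sim$mirna_expr, f("mirna_expression.tsv"),
                   f("mirna_design.tsv"))
  write_expression(sim$mrna_expr, f("mrna_expression.tsv"),
                   f("mrna_design.tsv"))
  write_predictions(sim$predictions, f("predictions.tsv"))
  write_gmt(sim$annotation, f("annotation.gmt"))
  utils::write.table(sim$truth$edges, f("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pairs <- do.call(rbind, lapply(sim$truth$pairs, function(pt)
    data.frame(mirna_a = pt$mirna_a, mirna_b = pt$mirna_b,
               n_shared = pt$n_shared, profile_cor = pt$profile_cor,
               shared_targets = paste(pt$shared_targets, collapse = ","),
               stringsAsFactors = FALSE)))
  if (is.null(pairs))
    pairs <- data.frame(mirna_a = character(0), mirna_b = character(0),
                        n_shared = integer(0), profile_cor = numeric(0),
                        shared_targets = character(0))
  utils::write.table(pairs, f("truth_pairs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$truth$de_mirnas, f("truth_de_mirnas.txt"))
  writeLines(sim$truth$de_genes, f("truth_de_genes.txt"))
  invisible(list.files(dir, full.names = TRUE))
}
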