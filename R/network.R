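#' Pearson correlation between DE-miRNAs and DE-mRNAs
#'
#' Computes the sample Pearson correlation of each differentially expressed
#' miRNA against each differentially expressed gene across the shared
#' samples. Both matrices must carry an identical ordered sample set; by
#' default all samples (tumor and matched normal pooled) are used, which
#' maximizes the dynamic range contributed by the differential features.
#'
#' @param mirna_expr,mrna_expr [expr_matrix] objects over the same samples.
#' @param de_mirnas,de_genes character vectors of feature ids to correlate
#'   (typically [de_features()] of the two DE tables).
#' @param samples `"pooled"` (default) to use all columns, `"tumor"` to
#'   restrict to tumor columns.
#' @return data.frame with columns mirna_id, gene_id, r; r is NA (with a
#'   warning) for pairs involving a zero-variance feature.
#' @export
correlate_pairs <- function(mirna_expr, mrna_expr, de_mirnas, de_genes,
                            samples = c("pooled", "tumor")) {
  samples <- match.arg(samples)
  stopifnot(inherits(mirna_expr, "expr_matrix"),
            inherits(mrna_expr, "expr_matrix"))
  if (!identical(colnames(mirna_expr$values), colnames(mrna_expr$values)))
    stop("alignment error: miRNA and mRNA matrices must share an identical ",
         "ordered sample set", call. = FALSE)
  miss <- setdiff(de_mirnas, rownames(mirna_expr$values))
  if (length(miss)) stop("unknown miRNA id(s): ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  miss <- setdiff(de_genes, rownames(mrna_expr$values))
  if (length(miss)) stop("unknown gene id(s): ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  cols <- if (samples == "pooled") colnames(mirna_expr$values) else
    mirna_expr$design$sample_id[mirna_expr$design$group == "tumor"]
  m <- t(mirna_expr$values[de_mirnas, cols, drop = FALSE])
  g <- t(mrna_expr$values[de_genes, cols, drop = FALSE])
  zv_m <- apply(m, 2, stats::sd) == 0
  zv_g <- apply(g, 2, stats::sd) == 0
  if (any(zv_m) || any(zv_g))
    warning("zero-variance feature(s); their correlations are NA",
            call. = FALSE)
  r <- suppressWarnings(stats::cor(m, g))
  r[zv_m, ] <- NA_real_
  r[, zv_g] <- NA_real_
  out <- data.frame(mirna_id = rep(de_mirnas, times = length(de_genes)),
                    gene_id = rep(de_genes, each = length(de_mirnas)),
                    r = as.vector(r), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the bipartite miRNA-target network
#'
#' An edge (miRNA M, gene G) is kept iff the expression correlation satisfies
#' r <= `corr_cut` (inclusive; strong anti-correlation) AND a prediction row
#' for (M, G) exists with pct > `pct_cut` (strict). The edge carries the
#' prediction's context+ score w and the correlation r. Pairs without a
#' prediction row are not candidates; no score imputation. Features left
#' without any edge are dropped.
#'
#' @param correlations data.frame from [correlate_pairs()].
#' @param predictions data.frame from [read_predictions()] (columns
#'   mirna_id, gene_id, w, pct).
#' @param corr_cut correlation cut-off, default -0.6.
#' @param pct_cut probability-of-conserved-targeting cut-off, default 0.5.
#' @return object of class `mirna_target_network`: list with `edges`
#'   (data.frame mirna_id, gene_id, w, r), `mirnas`, `genes`.
#' @export
build_target_network <- function(correlations, predictions,
                                 corr_cut = -0.6, pct_cut = 0.5) {
  keep <- correlations[!is.na(correlations$r) &
                         correlations$r <= corr_cut, , drop = FALSE]
  pred <- predictions[predictions$pct > pct_cut, , drop = FALSE]
  m <- merge(keep, pred[, c("mirna_id", "gene_id", "w")],
             by = c("mirna_id", "gene_id"))
  edges <- m[order(m$mirna_id, m$gene_id),
             c("mirna_id", "gene_id", "w", "r"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna_id)),
                 genes = sort(unique(edges$gene_id))),
            class = "mirna_target_network")
}

#' @export
print.mirna_target_network <- function(x, ...) {
  cat("miRNA-target network:", length(x$mirnas), "miRNAs,",
      length(x$genes), "target genes,", nrow(x$edges), "edges\n")
  invisible(x)
}
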