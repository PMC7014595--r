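#' Construct a validated expression matrix with a matched-pairs design
#'
#' The central expression container of the pipeline: a dense matrix of log2
#' expression values (features x samples) together with a design table that
#' labels every sample as `tumor` or `normal` and links each tumor sample to
#' its matched normal through a shared pair identifier. Expression is assumed
#' to be already log2-scale and normalized; normalization is upstream
#' preprocessing, not part of this package.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   have unique, non-empty row and column names and only finite entries.
#' @param design data.frame with columns `sample_id`, `group`
#'   (`"tumor"`/`"normal"`) and `pair_id`; one row per column of `values`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `design` (design rows reordered to match the column order).
#' @export
expr_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  fids <- rownames(values); sids <- colnames(values)
  if (is.null(fids) || anyNA(fids) || any(fids == ""))
    stop("format error: missing feature ids (rownames)", call. = FALSE)
  if (is.null(sids) || anyNA(sids) || any(sids == ""))
    stop("format error: missing sample ids (colnames)", call. = FALSE)
  if (anyDuplicated(fids))
    stop("format error: duplicate feature id(s): ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sids))
    stop("format error: duplicate sample id(s): ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("format error: non-finite expression values", call. = FALSE)
  req <- c("sample_id", "group", "pair_id")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design error: design needs columns sample_id, group, pair_id",
         call. = FALSE)
  design <- as.data.frame(design)[, req]
  design[] <- lapply(design, as.character)
  if (anyDuplicated(design$sample_id))
    stop("design error: duplicate sample id in design", call. = FALSE)
  if (!setequal(design$sample_id, sids))
    stop("design error: design samples do not match expression columns",
         call. = FALSE)
  design <- design[match(sids, design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  if (!all(design$group %in% c("tumor", "normal")))
    stop("design error: group must be 'tumor' or 'normal'", call. = FALSE)
  # every tumor's pair id must match exactly one normal, and vice versa
  for (g in c("tumor", "normal")) {
    other <- setdiff(c("tumor", "normal"), g)
    pg <- design$pair_id[design$group == g]
    po <- design$pair_id[design$group == other]
    if (anyDuplicated(pg))
      stop("design error: pair id used by more than one ", g, " sample",
           call. = FALSE)
    bad <- setdiff(pg, po)
    if (length(bad))
      stop("design error: ", g, " sample(s) with pair id ",
           paste(bad, collapse = ", "), " have no matched ", other,
           call. = FALSE)
  }
  structure(list(values = values, design = design), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$design$group == "tumor"), "matched pairs )\n")
  invisible(x)
}

#' Number of matched tumor/normal pairs
#' @param x an `expr_matrix`
#' @return integer pair count
#' @export
n_pairs <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  sum(x$design$group == "tumor")
}

#' Read an expression matrix and its matched-pairs design from TSV
#'
#' The expression file is tab-separated with a header row of sample ids and
#' feature ids in the first column; the design file maps `sample_id` to
#' `group` and `pair_id`. Lines starting with `#` are ignored in both files.
#' Rows containing any non-numeric cell are rejected, not repaired.
#'
#' @param path expression TSV.
#' @param design_path design TSV with columns sample_id, group, pair_id.
#' @return an [expr_matrix].
#' @export
read_expression <- function(path, design_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("format error: expression file needs >= 2 columns",
                          call. = FALSE)
  fids <- tab[[1]]
  num <- suppressWarnings(
    vapply(tab[-1], function(col) as.numeric(col), numeric(nrow(tab))))
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(fids, names(tab)[-1]))
  bad <- rowSums(is.na(num)) > 0
  if (any(bad))
    stop("format error: non-numeric value(s) in row(s): ",
         paste(utils::head(fids[bad], 5), collapse = ", "), call. = FALSE)
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              quote = "", comment.char = "#",
                              stringsAsFactors = FALSE)
  expr_matrix(num, design)
}

#' Write an expression matrix (and its design) to TSV
#'
#' Inverse of [read_expression()]; values are written at full double
#' precision so read-after-write reproduces the matrix exactly.
#'
#' @param x an `expr_matrix`.
#' @param path expression TSV to write.
#' @param design_path design TSV to write.
#' @return invisibly, `x`.
#' @export
write_expression <- function(x, path, design_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a target-prediction table
#'
#' Tab-separated table with columns `mirna_id`, `gene_id`, `context_score`
#' (the context+ score w, typically negative; more negative = stronger
#' predicted repression) and `pct` (probability of conserved targeting, in
#' \[0, 1\]). Duplicate (miRNA, gene) rows collapse to the record with the
#' more negative w, with a warning.
#'
#' @param path prediction TSV.
#' @return data.frame with columns mirna_id, gene_id, w, pct.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "context_score", "pct")
  if (!all(need %in% names(tab)))
    stop("format error: prediction table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- data.frame(mirna_id = as.character(tab$mirna_id),
                    gene_id = as.character(tab$gene_id),
                    w = as.numeric(tab$context_score),
                    pct = as.numeric(tab$pct),
                    stringsAsFactors = FALSE)
  validate_predictions(out)
}

validate_predictions <- function(out) {
  if (anyNA(out$w) || anyNA(out$pct))
    stop("format error: non-numeric context_score/pct", call. = FALSE)
  if (any(out$pct < 0 | out$pct > 1))
    stop("value error: pct outside [0, 1]", call. = FALSE)
  key <- paste(out$mirna_id, out$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsing duplicate (miRNA, gene) predictions to the more ",
            "negative context+ score", call. = FALSE)
    out <- out[order(key, out$w), , drop = FALSE]
    out <- out[!duplicated(paste(out$mirna_id, out$gene_id, sep = "\r")), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a target-prediction table to TSV
#' @param predictions data.frame as returned by [read_predictions()].
#' @param path output TSV.
#' @return invisibly, the table.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(mirna_id = predictions$mirna_id,
                    gene_id = predictions$gene_id,
                    context_score = format(predictions$w, digits = 17,
                                           trim = TRUE, scientific = FALSE),
                    pct = format(predictions$pct, digits = 17, trim = TRUE,
                                 scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(predictions)
}

#' Read gene-set annotations in GMT format
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' `term_id`, `description`, then one or more gene ids. Empty gene lists are
#' rejected.
#'
#' @param path GMT file.
#' @return a named list of character vectors (term id -> gene ids), with the
#'   term descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- descs <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("format error: GMT line ", i, " has fewer than 3 fields",
           call. = FALSE)
    ids[i] <- f[1]; descs[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids))
    stop("format error: duplicate GMT term id(s)", call. = FALSE)
  names(sets) <- ids
  names(descs) <- ids
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene-set annotations in GMT format
#' @param sets named list of character vectors as returned by [read_gmt()].
#' @param path output file.
#' @return invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("NA", length(sets)),
                                               names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, descs[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Export a weighted network as an edge-list TSV
#'
#' Works for both the bipartite miRNA-target network and the miRNA-miRNA
#' synergy network; columns are `node1`, `node2`, `weight` and, when
#' available, `p_value`. An empty network yields a header-only file.
#'
#' @param network a `mirna_target_network` or `synergy_network`.
#' @param path output TSV.
#' @return invisibly, the edge data.frame written.
#' @export
write_edge_list <- function(network, path) {
  ed <- network_edge_frame(network)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ed)
}

network_edge_frame <- function(network) {
  if (inherits(network, "mirna_target_network")) {
    e <- network$edges
    data.frame(node1 = e$mirna_id, node2 = e$gene_id, weight = e$w,
               r = e$r, stringsAsFactors = FALSE)
  } else if (inherits(network, "synergy_network")) {
    e <- network$edges
    out <- data.frame(node1 = e$mirna_a, node2 = e$mirna_b, weight = e$score,
                      stringsAsFactors = FALSE)
    if ("p_value" %in% names(e)) out$p_value <- e$p_value
    out
  } else stop("unsupported network class", call. = FALSE)
}

#' Export a network as GraphML
#'
#' Edge weights (and p-values when present) are written as edge attributes;
#' the result loads in Cytoscape and any GraphML-aware tool.
#'
#' @inheritParams write_edge_list
#' @return invisibly, the igraph object written.
#' @export
write_graphml <- function(network, path) {
  ed <- network_edge_frame(network)
  if (nrow(ed) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
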