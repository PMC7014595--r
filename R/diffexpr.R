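#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up BH adjusted p-values, order-preserving with the input indexing,
#' monotone in ranks and capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("value error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Paired differential-expression testing
#'
#' For each feature the within-pair difference d_i = tumor_i - normal_i is
#' formed and logFC = mean(d) tested against zero. `mode = "ordinary"` is the
#' one-sample t-test on d. `mode = "moderated"` (default) shrinks each
#' feature's variance toward a common prior by empirical Bayes: with
#' per-feature sample variance s^2 on df = n - 1 degrees of freedom and a
#' scaled-F prior s^2 ~ s0^2 F(df, d0), the posterior variance is
#' s_post^2 = (d0 s0^2 + df s^2) / (d0 + df) and t = logFC / (s_post/sqrt(n))
#' on df + d0 degrees of freedom. The prior (d0, s0^2) is estimated by
#' moment-matching the log sample variances (mean and spread of
#' log s^2 against their theoretical digamma/trigamma values), the standard
#' moderated-t construction. P-values are two-sided; BH adjustment is applied
#' across all features.
#'
#' A feature is flagged differentially expressed when |logFC| exceeds
#' `logfc_cut` and FDR is below `fdr_cut`. The default cut-off 0.585
#' corresponds to a 1.5-fold change (2^0.585 ~ 1.5).
#'
#' @param expr an [expr_matrix] with at least 2 matched pairs.
#' @param mode `"moderated"` (default) or `"ordinary"`.
#' @param logfc_cut absolute log2 fold-change cut-off (default 0.585).
#' @param fdr_cut FDR cut-off (default 0.05).
#' @return data.frame with columns feature_id, logFC, t_stat, p_value, fdr,
#'   is_de (one row per feature, input order).
#' @export
paired_de <- function(expr, mode = c("moderated", "ordinary"),
                      logfc_cut = 0.585, fdr_cut = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"))
  d <- pair_differences(expr)
  n <- ncol(d)
  if (n < 2)
    stop("insufficient replication: need >= 2 matched pairs", call. = FALSE)
  logfc <- rowMeans(d)
  s2 <- apply(d, 1, stats::var)
  df <- n - 1

  if (mode == "ordinary") {
    se <- sqrt(s2 / n)
    t_stat <- logfc / se
    p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
    zv <- s2 == 0
    if (any(zv)) {
      warning(sum(zv), " zero-variance feature(s); p set to 0/1 by logFC",
              call. = FALSE)
      p[zv] <- ifelse(logfc[zv] != 0, 0, 1)
      t_stat[zv] <- ifelse(logfc[zv] != 0, Inf * sign(logfc[zv]), 0)
    }
  } else {
    prior <- fit_f_dist(s2, df)
    d0 <- prior$df_prior; s02 <- prior$var_prior
    s2_post <- if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df) else
      rep(s02, length(s2))
    t_stat <- logfc / sqrt(s2_post / n)
    # cap the total df at the pooled residual df: with an infinite prior df
    # the information cannot exceed what all features jointly provide
    df_total <- min(df + d0, df * length(s2))
    p <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  }

  fdr <- bh_adjust(p)
  data.frame(feature_id = rownames(expr$values),
             logFC = logfc, t_stat = t_stat, p_value = p, fdr = fdr,
             is_de = abs(logfc) > logfc_cut & fdr < fdr_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

# tumor - normal matrix, one column per pair, ordered by pair id
pair_differences <- function(expr) {
  des <- expr$design
  tum <- des[des$group == "tumor", ]
  nor <- des[des$group == "normal", ]
  tum <- tum[order(tum$pair_id), ]
  nor <- nor[match(tum$pair_id, nor$pair_id), ]
  d <- expr$values[, tum$sample_id, drop = FALSE] -
    expr$values[, nor$sample_id, drop = FALSE]
  colnames(d) <- tum$pair_id
  d
}

#' Ids of features flagged differentially expressed
#' @param de_table output of [paired_de()].
#' @return character vector of feature ids with `is_de == TRUE`.
#' @export
de_features <- function(de_table) de_table$feature_id[de_table$is_de]

# Moment estimation of the scaled-F prior for sample variances.
# z = log(s^2) has E z = digamma(df/2) - log(df/2) + log(s0^2) +
# digamma(d0/2)... more precisely for s^2 ~ s0^2 F(df, d0):
#   E log s^2 = log s0^2 + digamma(df/2) - log(df/2)
#                        - digamma(d0/2) + log(d0/2)
#   Var log s^2 = trigamma(df/2) + trigamma(d0/2)
# Solve Var for d0 by inverting trigamma, then back out s0^2.
fit_f_dist <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- mean(e)
  vz <- sum((e - ev)^2) / (length(e) - 1)
  excess <- vz - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    # no detectable spread beyond sampling noise: completely pooled variance
    d0 <- Inf
    s02 <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, var_prior = s02)
}

# Newton inversion of the trigamma function on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
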