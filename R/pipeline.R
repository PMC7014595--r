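#' Pipeline configuration
#'
#' Collects every stage's thresholds (defaults are the study cut-offs:
#' |logFC| > 0.585, FDR < 0.05, correlation <= -0.6, PCT > 0.5, synergism
#' score >= 1.400, high co-regulation at N > 10), the global seed, stage
#' toggles and input paths. When `simulate` is enabled the inputs are
#' generated by [simulate_dataset()]; otherwise the four input paths must
#' point to existing files.
#'
#' @param out_dir run directory for all stage outputs and the manifest.
#' @param seed global seed; per-stage seeds are derived by fixed offsets so
#'   stages are individually reproducible.
#' @param simulate generate inputs with [simulate_dataset()] (default TRUE).
#' @param sim a [sim_config] used when `simulate = TRUE`; its seed is
#'   overridden by the derived stage seed.
#' @param mirna_expr,mirna_design,mrna_expr,mrna_design,predictions,gmt
#'   input paths used when `simulate = FALSE`.
#' @param de_mode `"moderated"` or `"ordinary"`.
#' @param logfc_cut,fdr_cut,corr_cut,pct_cut,score_threshold,n_threshold
#'   stage thresholds (study defaults).
#' @param n_perm Monte Carlo permutations for the randomization test.
#' @param p_cut optional p-value cut for the synergy network (NULL = none).
#' @param control_group_size,control_reps random-group control parameters;
#'   `control_reps = 0` skips the control stage.
#' @param run_de run the DE stage (default TRUE); when disabled,
#'   `de_mirnas`/`de_genes` id vectors must be supplied.
#' @param de_mirnas,de_genes precomputed DE feature ids (only when
#'   `run_de = FALSE`).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE,
                            sim = sim_config(),
                            mirna_expr = NULL, mirna_design = NULL,
                            mrna_expr = NULL, mrna_design = NULL,
                            predictions = NULL, gmt = NULL,
                            de_mode = "moderated",
                            logfc_cut = 0.585, fdr_cut = 0.05,
                            corr_cut = -0.6, pct_cut = 0.5,
                            score_threshold = 1.400, n_threshold = 10,
                            n_perm = 200, p_cut = NULL,
                            control_group_size = NULL, control_reps = 0,
                            run_de = TRUE, de_mirnas = NULL,
                            de_genes = NULL) {
  cfg <- as.list(environment())
  if (!simulate) {
    paths <- c(mirna_expr, mirna_design, mrna_expr, mrna_design,
               predictions, gmt)
    if (length(paths) < 6)
      stop("config error: simulate = FALSE requires all six input paths",
           call. = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("config error: missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!run_de && (is.null(de_mirnas) || is.null(de_genes)))
    stop("config error: DE stage disabled but no de_mirnas/de_genes ",
         "supplied", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, offset) (cfg$seed %% 100000L) * 10L + offset

#' Run the full pipeline
#'
#' simulate (or load) -> paired DE on both assays -> anti-correlation +
#' prediction-filtered miRNA-target network -> pairwise synergism scoring
#' with randomization p-values and thresholded synergy network -> GO
#' co-regulation counts (and optional random-group control). Every stage
#' writes its table under `out_dir`; a JSON manifest records the seed, the
#' configuration, per-stage row counts and md5 checksums, so a rerun with
#' the same config and seed is byte-identical.
#'
#' @param cfg a [pipeline_config].
#' @return invisibly, a list with the in-memory stage results (`sim`, `de_mirna`,
#'   `de_mrna`, `network`, `pairs`, `synergy_net`, `hubs`, `score_dist`,
#'   `coreg`, `control`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(cfg$out_dir, x)
  log_stage <- function(...) message("[synmir] ", ...)

  if (cfg$simulate) {
    log_stage("simulate: generating synthetic dataset")
    sim <- cfg$sim
    sim$seed <- stage_seed(cfg, 1L)
    inputs <- simulate_dataset(sim)
    write_simulation(inputs, file.path(cfg$out_dir, "inputs"))
  } else {
    log_stage("load: reading inputs")
    inputs <- list(
      mirna_expr = read_expression(cfg$mirna_expr, cfg$mirna_design),
      mrna_expr = read_expression(cfg$mrna_expr, cfg$mrna_design),
      predictions = read_predictions(cfg$predictions),
      annotation = read_gmt(cfg$gmt), truth = NULL)
  }

  if (cfg$run_de) {
    log_stage("de: paired differential expression (", cfg$de_mode, ")")
    de_mirna <- paired_de(inputs$mirna_expr, mode = cfg$de_mode,
                          logfc_cut = cfg$logfc_cut, fdr_cut = cfg$fdr_cut)
    de_mrna <- paired_de(inputs$mrna_expr, mode = cfg$de_mode,
                         logfc_cut = cfg$logfc_cut, fdr_cut = cfg$fdr_cut)
    utils::write.table(de_mirna, f("de_mirna.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(de_mrna, f("de_mrna.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    de_m <- de_features(de_mirna); de_g <- de_features(de_mrna)
  } else {
    de_mirna <- de_mrna <- NULL
    de_m <- cfg$de_mirnas; de_g <- cfg$de_genes
  }
  log_stage("de: ", length(de_m), " DE miRNAs, ", length(de_g),
            " DE genes")

  log_stage("network: anti-correlation + prediction filtering")
  if (length(de_m) == 0 || length(de_g) == 0) {
    network <- structure(list(
      edges = data.frame(mirna_id = character(0), gene_id = character(0),
                         w = numeric(0), r = numeric(0)),
      mirnas = character(0), genes = character(0)),
      class = "mirna_target_network")
  } else {
    cors <- correlate_pairs(inputs$mirna_expr, inputs$mrna_expr, de_m, de_g)
    network <- build_target_network(cors, inputs$predictions,
                                    corr_cut = cfg$corr_cut,
                                    pct_cut = cfg$pct_cut)
  }
  write_edge_list(network, f("target_network.tsv"))
  write_graphml(network, f("target_network.graphml"))
  log_stage("network: ", length(network$mirnas), " miRNAs, ",
            length(network$genes), " genes, ", nrow(network$edges),
            " edges")

  log_stage("synergy: scoring miRNA pairs")
  if (nrow(network$edges) == 0) {
    pairs <- data.frame(mirna_a = character(0), mirna_b = character(0),
                        n_shared = integer(0), r = numeric(0),
                        score = numeric(0), scored = logical(0),
                        reason = character(0), p_value = numeric(0))
    vectors <- list()
  } else {
    vectors <- build_weight_vectors(network)
    pairs <- score_all_pairs(vectors)
    pairs <- test_all_pairs(pairs, vectors, n_perm = cfg$n_perm,
                            seed = stage_seed(cfg, 2L))
  }
  utils::write.table(pairs, f("synergy_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  synergy_net <- build_synergy_network(pairs,
                                       score_threshold = cfg$score_threshold,
                                       p_cut = cfg$p_cut)
  write_edge_list(synergy_net, f("synergy_network.tsv"))
  write_graphml(synergy_net, f("synergy_network.graphml"))
  hubs <- rank_hubs(synergy_net)
  utils::write.table(hubs, f("hubs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sd_sum <- score_distribution(pairs, high_cut = cfg$score_threshold)
  log_stage("synergy: ", sum(pairs$scored), " scored pairs, ",
            nrow(synergy_net$edges), " network edges")

  log_stage("go: co-regulation analysis")
  target_sets <- split(network$edges$gene_id, network$edges$mirna_id)
  universe <- intersect(rownames(inputs$mrna_expr$values),
                        unique(unlist(inputs$annotation,
                                      use.names = FALSE)))
  coreg <- NULL
  if (length(target_sets) >= 2 && length(universe) > 0) {
    coreg <- coregulation_counts(target_sets, inputs$annotation, universe,
                                 fdr_cut = cfg$fdr_cut,
                                 threshold = cfg$n_threshold)
    utils::write.table(coreg, f("coregulation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  control <- NULL
  if (cfg$control_reps > 0) {
    gs <- if (is.null(cfg$control_group_size))
      max(2, length(synergy_net$nodes)) else cfg$control_group_size
    all_sets <- c(target_sets,
                  background_target_sets(inputs$predictions, target_sets))
    if (length(all_sets) > gs) {
      control <- random_group_control(
        all_sets, group_size = gs, n_reps = cfg$control_reps,
        annotation = inputs$annotation, universe = universe,
        fdr_cut = cfg$fdr_cut, threshold = cfg$n_threshold,
        seed = stage_seed(cfg, 3L),
        observed_mirnas = if (length(synergy_net$nodes) >= 2)
          synergy_net$nodes else NULL)
    } else log_stage("go: background too small for the random-group ",
                     "control; skipped")
  }

  manifest <- list(
    package = "synmir",
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = serializable_config(cfg),
    rows = list(de_mirna = if (!is.null(de_mirna)) nrow(de_mirna),
                de_mrna = if (!is.null(de_mrna)) nrow(de_mrna),
                network_edges = nrow(network$edges),
                scored_pairs = sum(pairs$scored),
                synergy_edges = nrow(synergy_net$edges),
                coreg_pairs = if (!is.null(coreg)) nrow(coreg)),
    score_distribution = sd_sum,
    checksums = as.list(tools::md5sum(
      list.files(cfg$out_dir, pattern = "\\.(tsv|graphml)$",
                 full.names = TRUE, recursive = TRUE))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done: ", cfg$out_dir)
  invisible(list(sim = inputs, de_mirna = de_mirna, de_mrna = de_mrna,
                 network = network, vectors = vectors, pairs = pairs,
                 synergy_net = synergy_net, hubs = hubs,
                 score_dist = sd_sum, coreg = coreg, control = control,
                 manifest = manifest))
}

# candidate target sets for miRNAs outside the network, from high-PCT
# predictions, so the random-group control has a background to sample
background_target_sets <- function(predictions, exclude) {
  pred <- predictions[predictions$pct > 0.5, , drop = FALSE]
  sets <- split(pred$gene_id, pred$mirna_id)
  sets <- sets[!(names(sets) %in% names(exclude))]
  sets[vapply(sets, length, integer(1)) >= 3]
}

serializable_config <- function(cfg) {
  out <- unclass(cfg)
  out$sim <- if (!is.null(out$sim)) unclass(out$sim)
  out[!vapply(out, is.null, logical(1))]
}
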