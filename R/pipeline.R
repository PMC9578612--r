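# End-to-end pipeline and command-line entry point. The run configuration is
# a flat JSON file (schema-validated; unknown keys rejected) holding every
# decision knob, and each run writes a manifest (seed, package version,
# parameters) so reruns are reproducible.

.config_defaults <- function() list(
  tumor_expr = NULL, normal_expr = NULL, cellline_expr = NULL,
  essentiality = NULL, ppi = NULL, targets = NULL, combos = NULL,
  line = NULL, out_dir = ".",
  score_min = 400, scheme = "diffusion", scope = "local",
  k_max = 10, hartigan_threshold = 10, kmeans_restarts = 10,
  seed = 1, min_samples = 3, walk_steps = NULL, diffusion_ratio = FALSE,
  bliss_threshold = 0.12)

#' Validate a run configuration
#'
#' @param config named list or path to a JSON file with configuration keys.
#'   Unknown keys are rejected.
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) dscn_config_error("config must be a list or JSON path")
  defs <- .config_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    dscn_config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defs, config)
  if (!out$scheme %in% c("most_probable", "random_walk", "diffusion")) {
    dscn_config_error(sprintf("unknown scheme '%s'", out$scheme))
  }
  if (!out$scope %in% c("global", "local")) {
    dscn_config_error(sprintf("unknown scope '%s'", out$scope))
  }
  out
}

#' Run the full double-target selection pipeline
#'
#' Reads all inputs, builds the analysis context (networks, clustering),
#' ranks every target pair, writes the ranking, the cluster table, the
#' subnetwork similarity table and a run manifest to `out_dir`, and — when a
#' drug-combination table is configured — the synergy association analysis.
#'
#' @param config config list or JSON path (see [run_config()]).
#' @return invisibly, a list with `ctx`, `ranking`, `similarity`, and (if
#'   computed) `association`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  for (k in c("tumor_expr", "normal_expr", "cellline_expr", "essentiality",
              "ppi", "targets")) {
    if (is.null(cfg[[k]])) dscn_config_error(sprintf("config key '%s' is required", k))
    if (!file.exists(cfg[[k]])) dscn_input_error(sprintf("%s: file not found: %s", k, cfg[[k]]))
  }
  tumor <- read_expression(cfg$tumor_expr, "tumor")
  normal <- read_expression(cfg$normal_expr, "normal")
  cellline <- read_expression(cfg$cellline_expr, "cellline")
  ess <- read_essentiality(cfg$essentiality)
  skeleton <- read_ppi(cfg$ppi, score_min = cfg$score_min)
  targets <- read_targets(cfg$targets)

  ctx <- if (is.null(cfg$line)) {
    dscn_context(tumor, normal, cellline, ess, skeleton,
                 scheme = cfg$scheme, scope = cfg$scope, k_max = cfg$k_max,
                 hartigan_threshold = cfg$hartigan_threshold,
                 kmeans_restarts = cfg$kmeans_restarts, seed = cfg$seed,
                 min_samples = cfg$min_samples, walk_steps = cfg$walk_steps,
                 diffusion_ratio = cfg$diffusion_ratio)
  } else {
    dscni_context(tumor, normal, cellline, ess, skeleton, line = cfg$line,
                  scheme = cfg$scheme, scope = cfg$scope, k_max = cfg$k_max,
                  hartigan_threshold = cfg$hartigan_threshold,
                  kmeans_restarts = cfg$kmeans_restarts, seed = cfg$seed,
                  min_samples = cfg$min_samples, walk_steps = cfg$walk_steps,
                  diffusion_ratio = cfg$diffusion_ratio)
  }
  ranking <- rank_all_pairs(ctx, targets)
  similarity <- subnet_similarity_table(ctx)

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  write_pair_ranking(ranking, file.path(cfg$out_dir, "pairs.tsv"))
  utils::write.table(
    data.frame(gene = ctx$assign$genes, cluster = ctx$assign$labels),
    file.path(cfg$out_dir, "clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(similarity, file.path(cfg$out_dir, "subnet_distance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  association <- NULL
  if (!is.null(cfg$combos)) {
    combos <- read_drug_combos(cfg$combos)
    tab <- build_contingency(combos, ranking, targets, threshold = cfg$bliss_threshold)
    test <- tryCatch(chi_square_test(tab), dscn_input_error = function(e) list(statistic = NA, p_value = NA))
    association <- list(table = tab, chi_square = test, odds_ratio = odds_ratio(tab))
    utils::write.table(
      data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 chi_square = test$statistic, p_value = test$p_value,
                 odds_ratio = association$odds_ratio),
      file.path(cfg$out_dir, "association.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- cfg
  manifest$package_version <- as.character(utils::packageVersion("dscn"))
  manifest$n_genes <- length(ctx$genes)
  manifest$K_prime <- ctx$assign$K_prime
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(ctx = ctx, ranking = ranking, similarity = similarity,
                 association = association))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic dataset), `rank` (full
#' pipeline), `dscni` (per-line pipeline; config must set `line`), `assoc`
#' (pipeline plus drug-synergy association; config must set `combos`), and
#' `similarity` (pipeline; the similarity table is always written). All take
#' `--config <file.json>`; `simulate` takes `--out <dir>` and optional
#' `--seed <int>`.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 ok, 1 input error, 2 internal), invisibly.
#' @export
dscn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: dscn <simulate|rank|dscni|similarity|assoc> --config file.json [--out dir] [--seed n]"
  status <- tryCatch({
    if (length(args) < 1L) dscn_config_error(usage)
    cmd <- args[[1L]]
    opt <- list()
    i <- 2L
    while (i < length(args) + 1L) {
      if (startsWith(args[[i]], "--") && i < length(args)) {
        opt[[substring(args[[i]], 3L)]] <- args[[i + 1L]]
        i <- i + 2L
      } else dscn_config_error(usage)
    }
    if (cmd == "simulate") {
      out <- if (is.null(opt$out)) "." else opt$out
      seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
      sim <- generate_dataset(generator_spec(seed = seed))
      write_dataset(sim, out)
    } else if (cmd %in% c("rank", "dscni", "similarity", "assoc")) {
      if (is.null(opt$config)) dscn_config_error("missing --config")
      run_pipeline(opt$config)
    } else dscn_config_error(usage)
    0L
  },
  dscn_config_error = function(e) { message(conditionMessage(e)); 1L },
  dscn_input_error = function(e) { message(conditionMessage(e)); 1L },
  dscn_format_error = function(e) { message(conditionMessage(e)); 1L },
  dscn_degenerate_error = function(e) { message(conditionMessage(e)); 1L },
  error = function(e) { message("internal error: ", conditionMessage(e)); 2L })
  invisible(status)
}
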