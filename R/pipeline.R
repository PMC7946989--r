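# End-to-end orchestration: synthetic simulation or TSV ingestion, per-
# cohort feature selection, ranking and model merging, network building and
# subgroup dissimilarity, with per-stage manifests for reproducibility.

write_manifest <- function(dir, stage, params, inputs = character(0),
                           outputs = character(0), seed = NA) {
  man <- list(stage = stage, params = params, seed = seed,
              package_version = as.character(packageVersion("rulenet")),
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

require_file <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  path
}

#' Serialize a rule model as JSON lines plus a JSON summary
#' @param model a `rule_model`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_rule_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rules_path <- file.path(dir, "rules.jsonl")
  con <- file(rules_path, "w")
  on.exit(close(con))
  for (r in model$rules) {
    rec <- list(conditions = as.list(r$conditions), decision = r$decision,
                rs_lhs = r$rs_lhs, rs_rhs = r$rs_rhs, ra = r$ra,
                rc_rhs = r$rc_rhs, p_value = r$p_value,
                p_adjusted = r$p_adjusted %||% NA,
                support_set = r$support_set, provenance = r$provenance)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  summary_path <- file.path(dir, "model.json")
  jsonlite::write_json(list(
    n_rules = length(model$rules),
    class_totals = as.list(model$class_totals),
    quality = model$quality,
    provenance = model$provenance), summary_path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(rules_path, summary_path))
}

#' Read rules written by [write_rule_model()]
#' @param dir model directory.
#' @return a `rule_model` (quality and table fields as serialized).
#' @export
read_rule_model <- function(dir) {
  rules_path <- require_file(file.path(dir, "rules.jsonl"), "rules")
  summary <- jsonlite::read_json(require_file(file.path(dir, "model.json"),
                                              "model summary"),
                                 simplifyVector = TRUE)
  rules <- lapply(readLines(rules_path), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    r <- new_rule(unlist(rec$conditions), rec$decision)
    r$rs_lhs <- rec$rs_lhs; r$rs_rhs <- rec$rs_rhs; r$ra <- rec$ra
    r$rc_rhs <- rec$rc_rhs; r$p_value <- rec$p_value
    if (!is.null(rec$p_adjusted) && !is.na(rec$p_adjusted))
      r$p_adjusted <- rec$p_adjusted
    r$support_set <- rec$support_set %||% character(0)
    r$provenance <- rec$provenance %||% character(0)
    r
  })
  structure(list(rules = rules,
                 class_totals = unlist(summary$class_totals),
                 quality = summary$quality,
                 provenance = summary$provenance,
                 scheme = NULL, table = NULL, cv = NULL),
            class = "rule_model")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest -> per-cohort feature selection (Monte Carlo
#' ranking, critical-angle threshold, model-quality adjustment) -> ranking
#' merge -> per-cohort rule learning on the merged feature set -> model
#' merge with recalculated statistics -> FDR filtering -> per-class
#' networks -> subgroup dissimilarity, writing every artifact plus a
#' manifest (input checksums, parameters, seeds, package version) under
#' `out_dir`. One master seed deterministically derives each stage's seed,
#' so reruns are bit-identical.
#'
#' @param config nested list (or path to a JSON file). Keys: `seed`;
#'   either `synthetic` (arguments to [synthetic_spec()]) or `cohorts`
#'   (list of `{expression, meta}` TSV paths); optional `id_map` (TSV with
#'   `source`, `target`); stage sections `mcfs` (`s`, `t`, `m`, `u`, `v`),
#'   `adjust` (`enabled`, `k_max`, `folds`), `learn` (`folds`, `n_bins`),
#'   `fdr` (`alpha`), `network` (`top_nodes_n`, `top_edge_fraction`),
#'   `subgroups` (`enabled`, `n_perm`, `n_balance`, `subtype_column`).
#' @param out_dir results directory (created).
#' @return invisibly, a list with the cohorts, rankings, models, merged
#'   model, networks and distance results.
#' @export
run_pipeline <- function(config, out_dir = "rulenet_results") {
  if (is.character(config))
    config <- jsonlite::read_json(require_file(config, "config"),
                                  simplifyVector = TRUE)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- stage: simulate / ingest ---------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec,
                    c(config$synthetic,
                      if (is.null(config$synthetic$seed))
                        list(seed = derive_seed(seed, "simulate"))))
    cohorts <- generate_cohorts(spec)
    paths <- unlist(lapply(seq_along(cohorts), function(i)
      write_expression_matrix(cohorts[[i]],
                              file.path(out_dir, sprintf("cohort%d", i)))))
    write_manifest(out_dir, "simulate", config$synthetic, outputs = paths,
                   seed = spec$seed)
  } else if (!is.null(config$cohorts)) {
    cohorts <- lapply(config$cohorts, function(cc) {
      read_expression_matrix(require_file(cc$expression, "expression"),
                             require_file(cc$meta, "metadata"))
    })
    write_manifest(out_dir, "ingest", config["cohorts"],
                   inputs = unlist(lapply(config$cohorts, unlist)),
                   seed = seed)
  } else stop("config must provide either `synthetic` or `cohorts`")

  mc <- config$mcfs %||% list()
  ad <- config$adjust %||% list()
  ln <- config$learn %||% list()
  id_map <- NULL
  if (!is.null(config$id_map)) {
    id_map <- read.delim(require_file(config$id_map, "id_map"),
                         stringsAsFactors = FALSE)
    # cross-platform remapping: translate cohort feature ids into the
    # shared space before selection and learning
    cohorts <- lapply(cohorts, function(em) {
      hit <- match(em$gene_ids, id_map$source)
      em$gene_ids[!is.na(hit)] <- id_map$target[hit[!is.na(hit)]]
      colnames(em$values) <- em$gene_ids
      em
    })
  }

  # -- stage: per-cohort feature selection ----------------------------------
  rankings <- lapply(seq_along(cohorts), function(i) {
    em <- cohorts[[i]]
    rk <- mcfs_rank(em$values, em$sample_meta$class,
                    s = mc$s %||% 100L, t = mc$t %||% 5L, m = mc$m,
                    u = mc$u %||% 1, v = mc$v %||% 1,
                    seed = derive_seed(seed, paste0("mcfs", i)),
                    provenance = unique(em$sample_meta$cohort_id))
    k0 <- suppressWarnings(critical_angle_threshold(rk))
    k <- if (isFALSE(ad$enabled)) k0 else
      adjust_fr(rk, em, k0 = k0, k_max = ad$k_max %||% 50L,
                learner_config = list(folds = ad$folds %||% 10L,
                                      seed = derive_seed(seed, paste0("adj", i))))
    truncate_ranking(rk, as.integer(k))
  })
  rank_paths <- vapply(seq_along(rankings), function(i)
    write_ranking(rankings[[i]], file.path(out_dir, sprintf("ranking_c%d.tsv", i))),
    character(1))

  # -- stage: merge rankings ------------------------------------------------
  merged_fr <- merge_rankings(rankings, id_map = id_map)
  fr_path <- write_ranking(merged_fr, file.path(out_dir, "ranking_merged.tsv"))
  write_manifest(out_dir, "select_features",
                 list(mcfs = mc, adjust = ad), outputs = c(rank_paths, fr_path),
                 seed = seed)

  # -- stage: per-cohort learning on the merged FR --------------------------
  models <- lapply(seq_along(cohorts), function(i)
    crossvalidate(cohorts[[i]], features = merged_fr$feature_id,
                  folds = ln$folds %||% 10L,
                  seed = derive_seed(seed, paste0("learn", i)),
                  n_bins = ln$n_bins %||% 3L))
  model_paths <- lapply(seq_along(models), function(i)
    write_rule_model(models[[i]], file.path(out_dir, sprintf("model_c%d", i))))
  write_manifest(out_dir, "learn", ln, outputs = unlist(model_paths),
                 seed = seed)

  # -- stage: merge models --------------------------------------------------
  merged_table <- combine_tables(cohorts, features = merged_fr$feature_id,
                                 n_bins = ln$n_bins %||% 3L)
  merged <- merge_models(models, merged_table)
  merged_paths <- write_rule_model(merged, file.path(out_dir, "model_merged"))
  write_manifest(out_dir, "merge", list(), outputs = merged_paths, seed = seed)

  # -- stage: FDR filter + networks -----------------------------------------
  alpha <- (config$fdr %||% list())$alpha %||% 0.05
  sig_rules <- fdr_filter(merged$rules, alpha = alpha)
  nw <- config$network %||% list()
  classes <- sort(unique(vapply(merged$rules, `[[`, character(1), "decision")))
  networks <- lapply(classes, function(cl) {
    net <- normalize_connections(build_network(sig_rules, class_filter = cl))
    if (nrow(net$nodes) > 0) {
      net <- detect_hubs(net)
      if (!is.null(nw$top_nodes_n))
        net <- top_nodes(net, nw$top_nodes_n, fraction = nw$top_edge_fraction)
    }
    net
  })
  names(networks) <- classes
  net_paths <- unlist(lapply(classes, function(cl)
    write_network(networks[[cl]], file.path(out_dir, paste0("network_", cl)))))
  write_manifest(out_dir, "network", list(alpha = alpha, network = nw),
                 outputs = net_paths, seed = seed)

  # -- stage: subgroup dissimilarity ----------------------------------------
  sg <- config$subgroups %||% list()
  meta <- do.call(rbind, lapply(cohorts, `[[`, "sample_meta"))
  distances <- NULL
  if (!isFALSE(sg$enabled)) {
    distances <- permutation_test(
      merged, meta,
      n_perm = sg$n_perm %||% 500L, n_balance = sg$n_balance %||% 20L,
      seed = derive_seed(seed, "subgroups"),
      subtype_column = sg$subtype_column %||% "subtype")
    dist_path <- file.path(out_dir, "subgroup_distances.tsv")
    write.table(distances, dist_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_manifest(out_dir, "subgroups", sg, outputs = dist_path, seed = seed)
  }

  # -- stage: report --------------------------------------------------------
  report <- list(
    n_cohorts = length(cohorts),
    merged_features = length(merged_fr$feature_id),
    per_cohort_quality = lapply(models, `[[`, "quality"),
    merged_rules = length(merged$rules),
    significant_rules = length(sig_rules),
    distances = distances)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohorts = cohorts, rankings = rankings,
                 merged_ranking = merged_fr, models = models,
                 merged_model = merged, significant_rules = sig_rules,
                 networks = networks, distances = distances,
                 out_dir = out_dir))
}

# Minimal "--flag value" parser for the CLI.
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    out[[sub("^--", "", a)]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `select-features`, `learn`, `merge`, `network`,
#' `subgroups`, `report`, `pipeline`. Invoke from a shell as e.g.
#' `Rscript -e 'rulenet::rulenet_cli()' pipeline --config cfg.json --out res`.
#'
#' @param args character vector; defaults to `commandArgs(trailingOnly=TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
rulenet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: rulenet <subcommand> [--flag value ...]")
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  res <- switch(
    cmd,
    simulate = {
      cfg <- jsonlite::read_json(require_file(opt$spec, "spec"),
                                 simplifyVector = TRUE)
      spec <- do.call(synthetic_spec, c(cfg, list(seed = seed)))
      cohorts <- generate_cohorts(spec)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(cohorts))
        write_expression_matrix(cohorts[[i]],
                                file.path(opt$out, sprintf("cohort%d", i)))
      cohorts
    },
    `select-features` = {
      tab <- read_decision_table(require_file(opt$table, "table"))
      rk <- mcfs_rank(tab, s = as.integer(opt$s %||% 100),
                      t = as.integer(opt$t %||% 5),
                      m = if (is.null(opt$m)) NULL else as.integer(opt$m),
                      seed = seed)
      write_ranking(rk, opt$out)
      rk
    },
    learn = {
      em <- read_expression_matrix(require_file(opt$table, "expression"),
                                   require_file(opt$meta, "metadata"))
      features <- if (is.null(opt$features)) NULL
                  else read_ranking(opt$features)$feature_id
      mdl <- crossvalidate(em, features,
                           folds = as.integer(opt$folds %||% 10), seed = seed)
      write_rule_model(mdl, opt$out)
      mdl
    },
    merge = {
      dirs <- strsplit(opt$models, ",")[[1]]
      models <- lapply(dirs, read_rule_model)
      merged <- merge_models(models, recalculate = FALSE)
      write_rule_model(merged, opt$out)
      merged
    },
    network = {
      mdl <- read_rule_model(opt$model)
      rules <- fdr_filter(mdl$rules, alpha = as.numeric(opt$alpha %||% 0.05))
      cl <- opt$class %||% "all"
      net <- build_network(rules,
                           class_filter = if (cl == "all") NULL else cl)
      net <- normalize_connections(net)
      if (nrow(net$nodes)) {
        net <- detect_hubs(net)
        if (!is.null(opt$`top-nodes`))
          net <- top_nodes(net, as.integer(opt$`top-nodes`),
                           fraction = if (is.null(opt$`top-edge-fraction`))
                             NULL else as.numeric(opt$`top-edge-fraction`))
      }
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_network(net, file.path(opt$out, paste0("network_", cl)))
      net
    },
    subgroups = {
      mdl <- read_rule_model(opt$model)
      meta <- read.delim(require_file(opt$meta, "metadata"),
                         stringsAsFactors = FALSE)
      res <- permutation_test(mdl, meta,
                              n_perm = as.integer(opt$`n-perm` %||% 500),
                              n_balance = as.integer(opt$`n-balance` %||% 20),
                              seed = seed)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write.table(res, file.path(opt$out, "subgroup_distances.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    },
    report = {
      mdl <- read_rule_model(opt$model)
      rep <- list(n_rules = length(mdl$rules),
                  class_totals = as.list(mdl$class_totals),
                  quality = mdl$quality, provenance = mdl$provenance)
      jsonlite::write_json(rep, opt$out, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      rep
    },
    pipeline = run_pipeline(require_file(opt$config, "config"),
                            out_dir = opt$out %||% "rulenet_results"),
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
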