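#' Assemble a pipeline run configuration
#'
#' Collects the inputs and parameters of a full analysis run. Defaults
#' follow the standard protocol: 250 hits per direction, K = 40 partners
#' per gene, 50 predicted genes, 100 random lists for every null
#' distribution.
#'
#' @param expression Path to a replicate expression TSV, or a `dex_table`.
#' @param partner_db Path to a partner-database TSV, or a `coex_db`.
#' @param out_dir Output directory for reports and exports.
#' @param target_ranking Optional path or `target_ranking` for target-class
#'   enrichment.
#' @param experiments Optional named list of external experiment tables
#'   (paths or `dex_table`s) to profile clusters across.
#' @param n_hits Hits per direction (default 250).
#' @param K Partner depth (default 40).
#' @param m_predicted Predicted genes to integrate (default 50).
#' @param n_null_lists Random lists per null (default 100).
#' @param min_cluster_size Smallest marked cluster (default 3).
#' @param directions Directions to analyze (default both).
#' @param cluster_override Optional path or data frame (`gene`, `cluster`)
#'   of manual cluster labels.
#' @param refine Split network components by greedy modularity?
#' @param profile_replicates Also profile clusters across the individual
#'   replicates of the main experiment? Default `TRUE`.
#' @param seed RNG seed for every stochastic step (default 1).
#' @return A `run_config` (a classed list).
#' @export
run_config <- function(expression, partner_db, out_dir,
                       target_ranking = NULL, experiments = list(),
                       n_hits = 250L, K = 40L, m_predicted = 50L,
                       n_null_lists = 100L, min_cluster_size = 3L,
                       directions = c("up", "down"),
                       cluster_override = NULL, refine = FALSE,
                       profile_replicates = TRUE, seed = 1L) {
  structure(list(expression = expression, partner_db = partner_db,
                 out_dir = out_dir, target_ranking = target_ranking,
                 experiments = experiments, n_hits = as.integer(n_hits),
                 K = as.integer(K), m_predicted = as.integer(m_predicted),
                 n_null_lists = as.integer(n_null_lists),
                 min_cluster_size = as.integer(min_cluster_size),
                 directions = directions, cluster_override = cluster_override,
                 refine = refine, profile_replicates = profile_replicates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the [run_config()] arguments; `experiments` is a
#' mapping of experiment label to table path.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Validate a run configuration
#'
#' @param config A `run_config`.
#' @return Character vector of violations; `character(0)` when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (cond) v <<- c(v, msg)
  chk(is.null(config$expression), "expression input missing")
  chk(is.character(config$expression) && !file.exists(config$expression),
      "expression table path does not exist")
  chk(is.null(config$partner_db), "partner database missing")
  chk(is.character(config$partner_db) && !file.exists(config$partner_db),
      "partner database path does not exist")
  chk(is.character(config$target_ranking) && !file.exists(config$target_ranking),
      "target ranking path does not exist")
  chk(!length(config$out_dir), "out_dir missing")
  chk(config$n_hits < 1L, "n_hits must be positive")
  chk(config$K < 1L, "K must be positive")
  chk(config$m_predicted < 1L, "m_predicted must be positive")
  chk(config$n_null_lists < 2L, "n_null_lists must be at least 2")
  chk(config$min_cluster_size < 1L, "min_cluster_size must be positive")
  chk(!all(config$directions %in% c("up", "down")),
      "directions must be a subset of up, down")
  chk(length(config$experiments) > 0L && is.null(names(config$experiments)),
      "experiments must be a named list")
  v
}

load_expression_input <- function(x) {
  if (inherits(x, "dex_table")) x else read_expression_table(x)
}

# evaluate the three network metrics for each random control list
network_null_metrics <- function(lists, db, ranking, m_predicted) {
  res <- lapply(lists, function(l) {
    net <- build_network(l, db)
    pred <- predict_genes(l, db, m_predicted)
    crs <- if (length(pred) > 0L)
      tryCatch(co_reg_score(pred, ranking, n_hits = length(l))$score,
               error = function(e) NA_real_)
    else NA_real_
    c(inclusion = hit_inclusion_fraction(net),
      connections = connections_per_hit(net),
      coreg = crs)
  })
  do.call(rbind, res)
}

null_from_values <- function(values) {
  dropped <- sum(is.na(values))
  values <- values[!is.na(values)]
  stop_if(length(values) < 2L, "metric defined on fewer than 2 random lists")
  structure(list(values = values, mean = mean(values), sd = sd(values),
                 n_lists = length(values), n_dropped = dropped),
            class = "null_dist")
}

#' Run the full coexpression-clustering analysis
#'
#' Composes the pipeline for each configured direction: replicate
#' averaging, ranking, hit selection, network construction, gene
#' prediction, CoRegScore and connectivity with random-list significance,
#' cluster assignment, a cluster-by-experiment UpRegScore profile with
#' per-cluster nulls, optional target-class enrichment, and Cytoscape
#' exports. All reports are written under `config$out_dir`; the assembled
#' results are returned invisibly.
#'
#' @param config A `run_config`.
#' @param quiet Suppress stage logging? Default `FALSE`.
#' @return A `coex_run` list (per-direction results plus shared inputs),
#'   invisibly.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  violations <- validate_config(config)
  stop_if(length(violations) > 0L,
          "invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  say <- function(...) if (!quiet) message("[coexcluster] ", ...)

  stage <- "input"
  result <- tryCatch({
    table <- load_expression_input(config$expression)
    db <- if (inherits(config$partner_db, "coex_db")) config$partner_db
          else load_partner_db(config$partner_db, K = config$K)
    tr <- config$target_ranking
    if (is.character(tr)) tr <- read_target_ranking(tr)
    override <- config$cluster_override
    if (is.character(override)) override <- read.delim(override, stringsAsFactors = FALSE)
    say("inputs: ", length(table$genes), " genes x ", length(table$replicates),
        " replicates; database covers ", length(db$entries), " genes (K = ",
        db$K, ")")

    stage <- "averaging"
    summaries <- average_replicates(table)
    universe <- summaries$gene
    up_ranking <- rank_genes(summaries, "up")
    coding <- setNames(table$coding, table$genes)

    # rankings every UpRegScore is computed against (most upregulated on top)
    stage <- "experiment rankings"
    exp_rankings <- list(main = up_ranking)
    if (isTRUE(config$profile_replicates) && length(table$replicates) > 1L) {
      for (r in table$replicates) {
        v <- table$values[, r]
        keep <- !is.na(v)
        exp_rankings[[paste0("replicate_", r)]] <-
          rank_genes(data.frame(gene = table$genes[keep], mean = v[keep]), "up")
      }
    }
    for (ex in names(config$experiments)) {
      ext_sum <- average_replicates(load_expression_input(config$experiments[[ex]]))
      exp_rankings[[ex]] <- rank_genes(ext_sum, "up")
    }

    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    per_direction <- list()
    for (d in config$directions) {
      stage <- paste0("direction ", d)
      ranking <- if (d == "up") up_ranking else rank_genes(summaries, "down")
      hits <- select_hits(ranking, config$n_hits, coding)
      say(d, ": ", length(hits$genes), " hits retained of ", config$n_hits,
          " requested")

      predicted <- predict_genes(hits, db, config$m_predicted)
      net <- build_network(hits, db, summaries, predicted = predicted)
      say(d, ": network with ", nrow(net$edges), " edges over ",
          nrow(net$nodes), " nodes (", sum(net$nodes$db_absent),
          " hits absent from database); ",
          format(net$considered_pairs, big.mark = ","), " considered pairs")

      clusters <- assign_clusters(net, config$min_cluster_size,
                                  refine = config$refine, override = override)
      coreg <- if (length(predicted) > 0L)
        co_reg_score(predicted, ranking, n_hits = length(hits$genes)) else NULL

      stage <- paste0("null (", d, ")")
      lists <- random_gene_lists(universe, length(hits$genes),
                                 config$n_null_lists,
                                 seed = substream_seed(config$seed, paste0("null:", d)))
      nm <- network_null_metrics(lists, db, ranking, config$m_predicted)
      nulls <- list(inclusion = null_from_values(nm[, "inclusion"]),
                    connections = null_from_values(nm[, "connections"]),
                    coreg = null_from_values(nm[, "coreg"]))
      sig <- list(
        inclusion = significance(hit_inclusion_fraction(net), nulls$inclusion),
        connections = significance(connections_per_hit(net), nulls$connections))
      if (!is.null(coreg))
        sig$coreg <- significance(coreg$score, nulls$coreg)

      stage <- paste0("cluster profile (", d, ")")
      profile <- NULL; profile_sig <- NULL
      members <- attr(clusters, "clusters")
      if (length(members) > 0L) {
        profile <- cluster_profile(clusters, exp_rankings)
        profile_sig <- list()
        for (cl in names(members)) {
          size <- length(members[[cl]])
          cl_lists <- random_gene_lists(
            universe, min(size, length(universe)), config$n_null_lists,
            seed = substream_seed(config$seed, paste0("cluster:", d, ":", cl)))
          for (ex in names(exp_rankings)) {
            obs <- profile$scores[cl, ex]
            if (is.na(obs)) next
            nd <- null_from_values(vapply(cl_lists, function(l) {
              tryCatch(up_reg_score(l, exp_rankings[[ex]])$score,
                       error = function(e) NA_real_)
            }, numeric(1)))
            profile_sig[[paste0(cl, "|", ex)]] <-
              significance(obs, nd, direction = if (d == "up") "upper" else "lower")
          }
        }
      }

      stage <- paste0("target enrichment (", d, ")")
      enrichment <- NULL
      if (!is.null(tr) && length(members) > 0L) {
        enrichment <- lapply(members, function(gs)
          tryCatch(target_fraction_enrichment(gs, tr), error = function(e) NULL))
        enrichment <- Filter(Negate(is.null), enrichment)
      }

      stage <- paste0("export (", d, ")")
      prefix <- file.path(config$out_dir, paste0("network_", d))
      export_network(net, clusters, prefix,
                     params = list(n_hits = config$n_hits, K = config$K,
                                   m_predicted = config$m_predicted,
                                   seed = config$seed, direction = d))
      scores_out <- list()
      if (!is.null(coreg)) scores_out$CoRegScore <- coreg
      if (length(members) > 0L)
        for (cl in names(members))
          scores_out[[paste0("cluster_", cl, "_main")]] <-
            profile$details[[cl]][["main"]]
      write_score_report(Filter(Negate(is.null), scores_out),
                         file.path(config$out_dir, paste0("scores_", d, ".tsv")))
      write_significance_report(sig,
                                file.path(config$out_dir, paste0("significance_", d, ".tsv")),
                                seed = config$seed)
      if (!is.null(profile_sig) && length(profile_sig) > 0L)
        write_significance_report(profile_sig,
                                  file.path(config$out_dir, paste0("cluster_significance_", d, ".tsv")),
                                  seed = config$seed)
      if (!is.null(profile))
        write.table(data.frame(cluster = rownames(profile$scores),
                               round(profile$scores, 4), check.names = FALSE),
                    file.path(config$out_dir, paste0("cluster_profile_", d, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(enrichment) && length(enrichment) > 0L) {
        edf <- do.call(rbind, lapply(names(enrichment), function(cl) {
          e <- enrichment[[cl]]
          data.frame(cluster = cl, observed_pct = e$observed_pct,
                     expected_pct = e$expected_pct, p = e$p,
                     class1_pct = e$class1_pct, class2_pct = e$class2_pct,
                     n_found = e$n_found, stringsAsFactors = FALSE)
        }))
        write.table(edf, file.path(config$out_dir, paste0("target_enrichment_", d, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }

      per_direction[[d]] <- list(ranking = ranking, hits = hits,
                                 predicted = predicted, network = net,
                                 clusters = clusters, coreg = coreg,
                                 nulls = nulls, significance = sig,
                                 profile = profile, profile_sig = profile_sig,
                                 enrichment = enrichment)
    }

    stage <- "manifest"
    jsonlite::write_json(
      list(n_hits = config$n_hits, K = config$K,
           m_predicted = config$m_predicted,
           n_null_lists = config$n_null_lists, seed = config$seed,
           directions = config$directions,
           n_genes = length(table$genes),
           n_replicates = length(table$replicates),
           experiments = names(exp_rankings)),
      file.path(config$out_dir, "run_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)

    structure(list(directions = per_direction, summaries = summaries,
                   experiment_rankings = exp_rankings, config = config),
              class = "coex_run")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  say("done; reports under ", config$out_dir)
  invisible(result)
}

#' @export
print.coex_run <- function(x, ...) {
  cat("Coexpression-clustering run (seed ", x$config$seed, ")\n", sep = "")
  for (d in names(x$directions)) {
    r <- x$directions[[d]]
    cat("-- direction ", d, ": ", length(r$hits$genes), " hits, ",
        nrow(r$network$edges), " edges, ",
        length(attr(r$clusters, "clusters")), " marked cluster(s)\n", sep = "")
    if (!is.null(r$coreg))
      cat(sprintf("   CoRegScore %.1f (z = %.1f, p = %.2g)\n",
                  r$coreg$score, r$significance$coreg$z, r$significance$coreg$p))
    cat(sprintf("   hit inclusion %.1f%% (null %.1f%%), connections/hit %.1f (null %.1f)\n",
                r$significance$inclusion$observed, r$significance$inclusion$null_mean,
                r$significance$connections$observed, r$significance$connections$null_mean))
  }
  invisible(x)
}
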