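new_rank_score <- function(score, added_real, added_best, added_worst,
                           n_evaluated, omitted, kind) {
  structure(list(score = score, added_real = added_real,
                 added_best = added_best, added_worst = added_worst,
                 n_evaluated = n_evaluated, omitted = omitted, kind = kind),
            class = "rank_score")
}

#' @export
print.rank_score <- function(x, ...) {
  cat(x$kind, ": ", format(round(x$score, 2)), "\n", sep = "")
  cat("  position sums — real: ", x$added_real, ", best: ", x$added_best,
      ", worst: ", x$added_worst, "\n", sep = "")
  cat("  genes evaluated: ", x$n_evaluated,
      if (length(x$omitted)) paste0(" (", length(x$omitted), " omitted)"),
      "\n", sep = "")
  invisible(x)
}

rank_score_core <- function(added_real, added_best, added_worst) {
  100 - 200 * (added_real - added_best) / (added_worst - added_best)
}

#' CoRegScore: predictive accuracy of a coexpression network
#'
#' Scores how highly the predicted genes sit in the experiment's
#' differential-expression ranking. The sum of their 1-based positions
#' (AddedRealPositions) is compared with the best possible placement — the
#' m positions immediately below the hit block, `n_hits + 1 .. n_hits + m`
#' (AddedIdealPositions) — and the worst — the bottom m positions
#' (AddedWorstPositions):
#'
#' \deqn{CoRegScore = 100 - 200 \frac{real - ideal}{worst - ideal}}
#'
#' 100 means a perfect prediction (the predicted genes are exactly the next
#' strongest-regulated genes after the hits), -100 the worst possible.
#'
#' @param predicted Character vector of predicted genes (must not be hits).
#' @param ranking A `gene_ranking` covering the genome.
#' @param n_hits Size of the hit block at the top of the ranking
#'   (default 250).
#' @return A `rank_score` object with `score` in \[-100, 100\] and the three
#'   position sums.
#' @examples
#' r <- gene_ranking(sprintf("g%03d", 1:500))
#' co_reg_score(sprintf("g%03d", 251:300), r, n_hits = 250)$score  # 100
#' @export
co_reg_score <- function(predicted, ranking, n_hits = 250L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  predicted <- as.character(predicted)
  stop_if(length(predicted) == 0L, "CoRegScore is undefined for an empty prediction")
  pos <- ranking$positions[predicted]
  omitted <- predicted[is.na(pos)]
  pos <- pos[!is.na(pos)]
  stop_if(length(pos) == 0L, "no predicted gene found in the ranking")
  m <- length(pos)
  G <- length(ranking$genes)
  stop_if(G < n_hits + m, "ranking must cover at least n_hits + m genes")
  added_real <- sum(as.numeric(pos))
  added_best <- pos_sum(n_hits + 1, n_hits + m)
  added_worst <- pos_sum(G - m + 1, G)
  stop_if(added_worst == added_best,
          "degenerate ranking: best and worst placements coincide")
  new_rank_score(rank_score_core(added_real, added_best, added_worst),
                 added_real, added_best, added_worst, m, omitted, "CoRegScore")
}

#' UpRegScore: regulation of a gene set in one experiment
#'
#' Scores how far toward the top of an experiment's expression ranking
#' (most upregulated first) a gene set lies. With n genes found in the
#' ranking, the sum of their positions (AddedRealPositions) is compared
#' with the top-n placement `1 + 2 + ... + n` (AddedIdealUpPositions) and
#' the bottom-n placement (AddedIdealDownPositions):
#'
#' \deqn{UpRegScore = 100 - 200 \frac{real - idealUp}{idealDown - idealUp}}
#'
#' 100 = perfect up-regulation, -100 = perfect down-regulation. Genes not
#' measured in the experiment are omitted and n shrinks accordingly.
#'
#' @param gene_set Character vector of gene ids.
#' @param ranking A `gene_ranking` (direction "up").
#' @return A `rank_score` object.
#' @examples
#' r <- gene_ranking(letters[1:10])
#' up_reg_score(c("a", "b", "c"), r)$score  # 100
#' @export
up_reg_score <- function(gene_set, ranking) {
  stopifnot(inherits(ranking, "gene_ranking"))
  gene_set <- unique(as.character(gene_set))
  pos <- ranking$positions[gene_set]
  omitted <- gene_set[is.na(pos)]
  pos <- pos[!is.na(pos)]
  stop_if(length(pos) == 0L, "UpRegScore is undefined: no set gene in the ranking")
  n <- length(pos)
  G <- length(ranking$genes)
  added_real <- sum(as.numeric(pos))
  added_best <- pos_sum(1, n)
  added_worst <- pos_sum(G - n + 1, G)
  stop_if(added_worst == added_best,
          "degenerate ranking: set covers the whole ranking")
  new_rank_score(rank_score_core(added_real, added_best, added_worst),
                 added_real, added_best, added_worst, n, omitted, "UpRegScore")
}

#' Cluster-by-experiment regulation profile
#'
#' Computes the UpRegScore of every cluster in every experiment's ranking —
#' the comparison that shows which transcriptional programs are shared
#' between conditions and which are condition-specific.
#'
#' @param clusters A `cluster_assignment`, or a named list of gene-id
#'   vectors.
#' @param rankings Named list of `gene_ranking` objects, one per experiment.
#' @return A `cluster_profile`: list with `scores` (cluster x experiment
#'   numeric matrix, `NA` where every cluster gene was absent from the
#'   experiment), `n_evaluated` and `n_omitted` matrices, and `details`
#'   (nested list of `rank_score` objects).
#' @export
cluster_profile <- function(clusters, rankings) {
  sets <- if (inherits(clusters, "cluster_assignment")) attr(clusters, "clusters")
          else clusters
  stop_if(length(sets) == 0L, "no clusters to profile")
  stop_if(length(rankings) == 0L, "no experiment rankings supplied")
  stop_if(is.null(names(rankings)), "rankings must be a named list")
  scores <- matrix(NA_real_, length(sets), length(rankings),
                   dimnames = list(names(sets), names(rankings)))
  n_eval <- n_omit <- matrix(0L, length(sets), length(rankings),
                             dimnames = dimnames(scores))
  details <- list()
  for (cl in names(sets)) {
    details[[cl]] <- list()
    for (ex in names(rankings)) {
      res <- tryCatch(up_reg_score(sets[[cl]], rankings[[ex]]),
                      error = function(e) NULL)
      if (is.null(res)) {
        n_omit[cl, ex] <- length(sets[[cl]])
      } else {
        scores[cl, ex] <- res$score
        n_eval[cl, ex] <- res$n_evaluated
        n_omit[cl, ex] <- length(res$omitted)
        details[[cl]][[ex]] <- res
      }
    }
  }
  structure(list(scores = scores, n_evaluated = n_eval, n_omitted = n_omit,
                 details = details),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("UpRegScore profile (clusters x experiments):\n")
  print(round(x$scores, 1))
  if (any(is.na(x$scores)))
    cat("NA = cluster entirely absent from that experiment\n")
  invisible(x)
}

#' Bar chart of a cluster regulation profile
#'
#' @param x A `cluster_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.cluster_profile <- function(x, ...) {
  graphics::barplot(t(x$scores), beside = TRUE, ylim = c(-100, 100),
                    legend.text = colnames(x$scores),
                    ylab = "UpRegScore", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Project an external experiment onto a network
#'
#' Recolors the network nodes with the expression values measured in a
#' different experiment, so a response can be compared across conditions on
#' the same layout. Genes not measured in the external experiment are
#' flagged omitted.
#'
#' @param net A `coexnet`.
#' @param external Data frame (`gene`, `mean`) of the external experiment's
#'   per-gene mean log2 differences, e.g. from [average_replicates()].
#' @return Data frame (`gene`, `role`, `mean`, `color_bin`, `omitted`).
#' @export
project_experiment <- function(net, external) {
  stopifnot(inherits(net, "coexnet"))
  i <- match(net$nodes$gene, external$gene)
  mean_ext <- external$mean[i]
  omitted <- is.na(i)
  data.frame(gene = net$nodes$gene, role = net$nodes$role,
             mean = mean_ext,
             color_bin = ifelse(omitted, NA_character_,
                                color_bin(ifelse(omitted, 0, mean_ext))),
             omitted = omitted, stringsAsFactors = FALSE)
}

#' Write a score report
#'
#' @param scores Named list of `rank_score` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scores, path) {
  df <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    data.frame(name = nm, kind = s$kind, score = s$score,
               added_real = s$added_real, added_best = s$added_best,
               added_worst = s$added_worst, n_evaluated = s$n_evaluated,
               n_omitted = length(s$omitted), stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
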