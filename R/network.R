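#' Build the hit-to-hit coexpression connection network
#'
#' For every hit gene with a database entry the full (K+1) x (K+1) pair
#' matrix over its neighborhood — the hit itself plus its top-K partners —
#' is enumerated; with 250 hits and K = 40 that is 250 x 41 x 41 = 420,250
#' considered connection slots. An undirected edge is materialized only when
#' both members of an enumerated pair are hit genes (or, when `predicted`
#' genes are integrated, one hit and one predicted gene); its weight sums,
#' over every neighborhood containing the pair, the product of the two
#' members' multiplicity counts in that neighborhood (the hit anchoring a
#' neighborhood counts once). Pairs between two non-hit partners are
#' enumerated — they count toward `considered_pairs` — but never
#' materialized. Hits absent from the database become isolated nodes
#' flagged `db_absent`.
#'
#' @param hits A `hit_list` or character vector of hit gene ids.
#' @param db A `coex_db`.
#' @param summaries Optional data frame (`gene`, `mean`) used to attach mean
#'   log2 differences and display bins to nodes.
#' @param predicted Optional character vector of predicted (non-hit) genes
#'   to integrate, typically from [predict_genes()].
#' @return A `coexnet` object with `nodes` (gene, role, db_absent, mean,
#'   color_bin), `edges` (a, b, weight), `considered_pairs`, `K` and
#'   `direction`.
#' @examples
#' db <- coex_db(list(h1 = list(partner = "h2", count = 1),
#'                    h2 = list(partner = "h1", count = 1)), K = 1)
#' net <- build_network(c("h1", "h2"), db)
#' net$edges
#' @export
build_network <- function(hits, db, summaries = NULL, predicted = NULL) {
  stopifnot(inherits(db, "coex_db"))
  direction <- if (inherits(hits, "hit_list")) hits$direction else NA_character_
  hit_genes <- if (inherits(hits, "hit_list")) hits$genes else as.character(hits)
  stop_if(length(hit_genes) == 0L, "hit list is empty")
  stop_if(anyDuplicated(hit_genes) > 0L, "duplicated gene in hit list")
  predicted <- as.character(predicted %||% character())
  stop_if(any(predicted %in% hit_genes), "predicted genes must not be hits")

  allowed <- c(hit_genes, predicted)
  is_hit <- setNames(c(rep(TRUE, length(hit_genes)), rep(FALSE, length(predicted))),
                     allowed)
  ea <- character(); eb <- character(); ew <- numeric()
  n_with_entry <- 0L
  absent <- character()
  for (h in hit_genes) {
    nb <- db$entries[[h]]
    if (is.null(nb)) {
      absent <- c(absent, h)
      next
    }
    n_with_entry <- n_with_entry + 1L
    genes <- c(h, nb$partner)
    mult <- c(1L, nb$count)
    keep <- genes %in% allowed
    g <- genes[keep]; m <- mult[keep]
    if (length(g) < 2L) next
    idx <- which(upper.tri(matrix(0, length(g), length(g))), arr.ind = TRUE)
    a <- g[idx[, 1L]]; b <- g[idx[, 2L]]
    w <- m[idx[, 1L]] * m[idx[, 2L]]
    # predicted-predicted pairs are enumerated but never materialized
    mat <- is_hit[a] | is_hit[b]
    ea <- c(ea, a[mat]); eb <- c(eb, b[mat]); ew <- c(ew, w[mat])
  }

  edges <- if (length(ea)) {
    swap <- ea > eb
    a <- ifelse(swap, eb, ea); b <- ifelse(swap, ea, eb)
    key <- paste(a, b, sep = "\r")
    agg <- tapply(ew, key, sum)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    df <- data.frame(a = vapply(parts, `[[`, "", 1L),
                     b = vapply(parts, `[[`, "", 2L),
                     weight = as.numeric(agg), stringsAsFactors = FALSE)
    df[order(df$a, df$b, method = "radix"), , drop = FALSE]
  } else {
    data.frame(a = character(), b = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL

  nodes <- data.frame(gene = allowed,
                      role = c(rep("hit", length(hit_genes)),
                               rep("predicted", length(predicted))),
                      db_absent = allowed %in% absent,
                      stringsAsFactors = FALSE)
  if (!is.null(summaries)) {
    i <- match(nodes$gene, summaries$gene)
    nodes$mean <- summaries$mean[i]
    nodes$color_bin <- ifelse(is.na(nodes$mean), NA_character_,
                              color_bin(ifelse(is.na(nodes$mean), 0, nodes$mean)))
  } else {
    nodes$mean <- NA_real_
    nodes$color_bin <- NA_character_
  }

  structure(list(nodes = nodes, edges = edges,
                 considered_pairs = as.numeric(n_with_entry) * (db$K + 1)^2,
                 K = db$K, direction = direction,
                 n_hits = length(hit_genes)),
            class = "coexnet")
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$gene)
  if (nrow(net$edges) > 0L)
    g <- igraph::add_edges(g, rbind(net$edges$a, net$edges$b),
                           weight = net$edges$weight)
  g
}

#' @export
print.coexnet <- function(x, ...) {
  cat("Coexpression connection network",
      if (!is.na(x$direction)) paste0(" (", x$direction, ")"), "\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), " (", sum(x$nodes$role == "hit"), " hits, ",
      sum(x$nodes$role == "predicted"), " predicted; ",
      sum(x$nodes$db_absent), " absent from database)\n", sep = "")
  cat("  edges: ", nrow(x$edges), ", total weight ", sum(x$edges$weight),
      "\n", sep = "")
  cat("  considered pairs: ", format(x$considered_pairs, big.mark = ","),
      " (K = ", x$K, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.coexnet <- function(object, ...) {
  out <- list(n_nodes = nrow(object$nodes),
              n_hits = sum(object$nodes$role == "hit"),
              n_predicted = sum(object$nodes$role == "predicted"),
              n_db_absent = sum(object$nodes$db_absent),
              n_edges = nrow(object$edges),
              total_weight = sum(object$edges$weight),
              considered_pairs = object$considered_pairs,
              hit_inclusion_fraction = hit_inclusion_fraction(object),
              connections_per_hit = connections_per_hit(object))
  class(out) <- "summary.coexnet"
  out
}

#' @export
print.summary.coexnet <- function(x, ...) {
  cat("nodes:", x$n_nodes, "| hits:", x$n_hits, "| predicted:", x$n_predicted,
      "| db-absent:", x$n_db_absent, "\n")
  cat("edges:", x$n_edges, "| total weight:", x$total_weight,
      "| considered pairs:", x$considered_pairs, "\n")
  cat(sprintf("hit inclusion: %.1f%% | connections per hit: %.2f\n",
              x$hit_inclusion_fraction, x$connections_per_hit))
  invisible(x)
}

#' Plot a connection network
#'
#' Force-directed display with nodes shaded by expression bin and predicted
#' genes outlined in pink, mirroring the usual Cytoscape rendering.
#'
#' @param x A `coexnet`.
#' @param clusters Optional `cluster_assignment` used for labels.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.coexnet <- function(x, clusters = NULL, ...) {
  g <- as_igraph(x)
  fill <- ifelse(is.na(x$nodes$color_bin), "#DDDDDD", bin_colors(
    ifelse(is.na(x$nodes$color_bin), "neutral", x$nodes$color_bin)))
  frame <- ifelse(x$nodes$role == "predicted", "#FF69B4", "#333333")
  igraph::plot.igraph(g, vertex.color = fill, vertex.frame.color = frame,
                      vertex.size = 6, vertex.label.cex = 0.5,
                      edge.width = 0.5 + log1p(igraph::E(g)$weight %||% 1), ...)
  invisible(x)
}

#' Percentage of hit genes included in the network
#'
#' A hit counts as included when it has at least one coexpression edge to
#' another hit gene.
#'
#' @param net A `coexnet`.
#' @return Percentage in \[0, 100\].
#' @export
hit_inclusion_fraction <- function(net) {
  stopifnot(inherits(net, "coexnet"))
  hits <- net$nodes$gene[net$nodes$role == "hit"]
  stop_if(length(hits) == 0L, "network has no hit nodes")
  e <- net$edges
  hh <- e$a %in% hits & e$b %in% hits
  included <- unique(c(e$a[hh], e$b[hh]))
  100 * sum(hits %in% included) / length(hits)
}

#' Average connection counts per hit gene
#'
#' Mean, over hit nodes, of the summed weights of their incident edges; a
#' gene pair contributes many counts when it is marked coexpressed several
#' times in the database.
#'
#' @param net A `coexnet`.
#' @return Non-negative number.
#' @export
connections_per_hit <- function(net) {
  stopifnot(inherits(net, "coexnet"))
  hits <- net$nodes$gene[net$nodes$role == "hit"]
  stop_if(length(hits) == 0L, "network has no hit nodes")
  w <- setNames(numeric(length(hits)), hits)
  e <- net$edges
  for (col in c("a", "b")) {
    inc <- e[[col]] %in% hits
    if (any(inc)) {
      s <- tapply(e$weight[inc], e[[col]][inc], sum)
      w[names(s)] <- w[names(s)] + s
    }
  }
  mean(w)
}

#' Predict additional coregulated genes from the database
#'
#' Ranks non-hit genes by their summed connection counts to the hit list —
#' the sum of their multiplicity counts over all hit neighborhoods that list
#' them — and returns the top `m`. These are the candidates a complete
#' transcriptional response should also regulate; scoring their positions in
#' the expression ranking gives the CoRegScore.
#'
#' @param hits A `hit_list` or character vector.
#' @param db A `coex_db`.
#' @param m Number of genes to predict (default 50).
#' @return Character vector of predicted genes (count >= 1 each), descending
#'   by count with lexicographic tie-break; attribute `counts` carries the
#'   scores and attribute `shortfall` is `TRUE` when fewer than `m`
#'   connected non-hit genes exist.
#' @export
predict_genes <- function(hits, db, m = 50L) {
  stopifnot(inherits(db, "coex_db"))
  stop_if(m < 1L, "m must be >= 1")
  hit_genes <- if (inherits(hits, "hit_list")) hits$genes else as.character(hits)
  part <- character(); cnt <- integer()
  for (h in hit_genes) {
    e <- db$entries[[h]]
    if (is.null(e)) next
    part <- c(part, e$partner); cnt <- c(cnt, e$count)
  }
  keep <- !(part %in% hit_genes)
  if (!any(keep)) {
    out <- character()
    attr(out, "counts") <- numeric()
    attr(out, "shortfall") <- TRUE
    return(out)
  }
  tot <- tapply(cnt[keep], part[keep], sum)
  ord <- order(-as.numeric(tot), names(tot), method = "radix")
  tot <- tot[ord]
  n_take <- min(m, length(tot))
  out <- names(tot)[seq_len(n_take)]
  attr(out, "counts") <- as.numeric(tot)[seq_len(n_take)]
  attr(out, "shortfall") <- n_take < m
  out
}
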