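#' Assign cluster labels to network nodes
#'
#' Deterministic replacement for reading clusters off a force-directed
#' layout by eye: connected components of at least `min_size` nodes become
#' numbered clusters (largest first; ties broken by the lexicographically
#' smallest member). Nodes outside all marked clusters are labeled `"0"`,
#' and hits absent from the coexpression database are labeled `"-"`.
#'
#' With `refine = TRUE` each large component is additionally split by greedy
#' modularity optimization; refined communities of at least `min_size`
#' become the numbered clusters, and a node left outside them whose
#' neighbors span two or more numbered clusters receives the `"+"`-joined
#' label of those clusters (a gene sitting in between marked clusters).
#'
#' A manual grouping can replace the automatic labels via `override`, a
#' data frame (`gene`, `cluster`) — the route for curated cluster tables.
#'
#' @param net A `coexnet`.
#' @param min_size Minimum cluster size (default 3).
#' @param refine Split components by greedy modularity? Default `FALSE`.
#' @param override Optional data frame (`gene`, `cluster`) of manual labels;
#'   genes not listed keep their automatic label.
#' @return A `cluster_assignment`: named character vector (gene -> label)
#'   with attribute `clusters`, a named list of member vectors for the
#'   numbered labels.
#' @export
assign_clusters <- function(net, min_size = 3L, refine = FALSE, override = NULL) {
  stopifnot(inherits(net, "coexnet"))
  stop_if(min_size < 1L, "min_size must be >= 1")
  genes <- net$nodes$gene
  labels <- setNames(rep("0", length(genes)), genes)

  g <- as_igraph(net)
  memb <- igraph::components(g)$membership
  if (refine && igraph::ecount(g) > 0L) {
    comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    memb <- igraph::membership(comm)
  }
  groups <- split(names(memb), memb)
  groups <- Filter(function(x) length(x) >= min_size, groups)
  if (length(groups) > 0L) {
    first <- vapply(groups, function(x) min(x), "")
    ord <- order(-vapply(groups, length, 0L), first, method = "radix")
    groups <- groups[ord]
    names(groups) <- as.character(seq_along(groups))
    for (lab in names(groups)) labels[groups[[lab]]] <- lab
  }

  if (refine && length(groups) > 1L) {
    # bridge nodes: unlabeled but adjacent to >= 2 numbered clusters
    for (gname in genes[labels[genes] == "0"]) {
      nb <- igraph::neighbors(g, gname)$name
      touched <- sort(unique(labels[nb][labels[nb] %in% names(groups)]))
      if (length(touched) >= 2L)
        labels[gname] <- paste(touched, collapse = "+")
    }
  }

  labels[genes[net$nodes$db_absent]] <- "-"

  if (!is.null(override)) {
    stop_if(!all(c("gene", "cluster") %in% names(override)),
            "override needs columns gene, cluster")
    known <- override$gene %in% genes
    labels[override$gene[known]] <- as.character(override$cluster[known])
    groups <- cluster_members(labels)
  } else {
    groups <- cluster_members(labels)
  }

  structure(labels, clusters = groups, class = "cluster_assignment")
}

cluster_members <- function(labels) {
  real <- labels[!labels %in% c("0", "-") & !grepl("+", labels, fixed = TRUE)]
  if (length(real) == 0L) return(list())
  groups <- split(names(real), real)
  groups[order(names(groups), method = "radix")]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  groups <- attr(x, "clusters")
  cat("Cluster assignment:", length(groups), "marked cluster(s)\n")
  for (lab in names(groups))
    cat("  cluster ", lab, ": ", length(groups[[lab]]), " genes\n", sep = "")
  cat("  outside clusters ('0'): ", sum(unclass(x) == "0"),
      " | between clusters ('+'): ", sum(grepl("+", x, fixed = TRUE)),
      " | db-absent ('-'): ", sum(unclass(x) == "-"), "\n", sep = "")
  invisible(x)
}

#' Export a network for Cytoscape
#'
#' Writes the standard trio of files: `<prefix>.sif` with one
#' `geneA coex geneB` line per undirected edge, `<prefix>_edges.tsv` with
#' the occurrence-count weights, `<prefix>_nodes.tsv` with node attributes
#' (role, mean log2 difference, display bin, cluster label) and
#' `<prefix>_manifest.json` recording parameters.
#'
#' @param net A `coexnet`.
#' @param clusters Optional `cluster_assignment`.
#' @param out_prefix Output path prefix.
#' @param params Optional named list recorded in the manifest.
#' @return Character vector of the written paths, invisibly.
#' @export
export_network <- function(net, clusters = NULL, out_prefix, params = list()) {
  stopifnot(inherits(net, "coexnet"))
  dir <- dirname(out_prefix)
  stop_if(!dir.exists(dir), "output directory does not exist: ", dir)

  sif <- paste0(out_prefix, ".sif")
  e <- net$edges
  writeLines(if (nrow(e)) paste(e$a, "coex", e$b, sep = "\t") else character(), sif)

  edges_path <- paste0(out_prefix, "_edges.tsv")
  write.table(e, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)

  nodes <- net$nodes
  nodes$cluster <- if (is.null(clusters)) NA_character_
                   else unname(unclass(clusters)[nodes$gene])
  nodes_path <- paste0(out_prefix, "_nodes.tsv")
  write.table(nodes, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest_path <- paste0(out_prefix, "_manifest.json")
  manifest <- c(list(n_nodes = nrow(nodes), n_edges = nrow(e),
                     considered_pairs = net$considered_pairs,
                     K = net$K, direction = net$direction), params)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(sif, edges_path, nodes_path, manifest_path))
}

#' Re-import an exported edge table
#'
#' Reads `<prefix>_edges.tsv` back; with the matching node table this
#' round-trips [export_network()].
#'
#' @param out_prefix Prefix used at export time.
#' @return Data frame (`a`, `b`, `weight`).
#' @export
read_network_edges <- function(out_prefix) {
  path <- paste0(out_prefix, "_edges.tsv")
  stop_if(!file.exists(path), "edge table not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  df
}
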