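#' Genome-wide target-class ranking
#'
#' A total order of the genome by a transcription factor's regulatory
#' effect, with the top `n_class1` genes called Class I targets (activated)
#' and the bottom `n_class2` genes Class II targets (repressed, e.g. by
#' DAF-16 together with PQM-1); the middle band is non-target. Class
#' membership is purely positional.
#'
#' @param ordered_genes Character vector, strongest Class I target first.
#' @param n_class1 Number of top-ranked Class I targets.
#' @param n_class2 Number of bottom-ranked Class II targets.
#' @return A `target_ranking` object.
#' @export
target_ranking <- function(ordered_genes, n_class1, n_class2) {
  ordered_genes <- as.character(ordered_genes)
  stop_if(anyDuplicated(ordered_genes) > 0L, "duplicated gene in target ranking")
  G <- length(ordered_genes)
  stop_if(n_class1 < 0L || n_class2 < 0L, "class sizes must be non-negative")
  stop_if(n_class1 + n_class2 > G, "class sizes exceed the ranking (",
          n_class1, " + ", n_class2, " > ", G, ")")
  structure(list(genes = ordered_genes,
                 positions = setNames(seq_len(G), ordered_genes),
                 n_class1 = as.integer(n_class1),
                 n_class2 = as.integer(n_class2)),
            class = "target_ranking")
}

#' @export
print.target_ranking <- function(x, ...) {
  G <- length(x$genes)
  cat("Target ranking: ", G, " genes — ", x$n_class1, " Class I (top), ",
      x$n_class2, " Class II (bottom), ", G - x$n_class1 - x$n_class2,
      " non-target\n", sep = "")
  invisible(x)
}

target_class_of <- function(tr, position) {
  G <- length(tr$genes)
  ifelse(position <= tr$n_class1, "ClassI",
         ifelse(position > G - tr$n_class2, "ClassII", "non-target"))
}

#' Read / write a target ranking
#'
#' The file format is a comment header `# n_class1=<int> n_class2=<int>`
#' followed by a TSV (`gene`, `rank`) with a header row.
#'
#' @param path File path.
#' @return A `target_ranking`.
#' @export
read_target_ranking <- function(path) {
  stop_if(!file.exists(path), "target ranking not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("#\\s*n_class1=(\\d+)\\s+n_class2=(\\d+)", first))[[1L]]
  stop_if(length(m) != 3L,
          "target ranking must start with '# n_class1=<int> n_class2=<int>'")
  df <- read.delim(path, sep = "\t", skip = 1L, stringsAsFactors = FALSE)
  stop_if(!all(c("gene", "rank") %in% names(df)),
          "target ranking needs columns gene, rank")
  df <- df[order(df$rank), , drop = FALSE]
  stop_if(!identical(as.integer(df$rank), seq_len(nrow(df))),
          "ranks must be a permutation of 1..G")
  target_ranking(df$gene, as.integer(m[2L]), as.integer(m[3L]))
}

#' @rdname read_target_ranking
#' @param tr A `target_ranking`.
#' @return `write_target_ranking`: `path`, invisibly.
#' @export
write_target_ranking <- function(tr, path) {
  stopifnot(inherits(tr, "target_ranking"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_class1=%d n_class2=%d", tr$n_class1, tr$n_class2), con)
  write.table(data.frame(gene = tr$genes, rank = seq_along(tr$genes)),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positions of cluster members in a target ranking
#'
#' @param cluster Character vector of gene ids.
#' @param tr A `target_ranking`.
#' @return Data frame (`gene`, `position`, `class`) for the genes found in
#'   the ranking; genes not found are reported in attribute `not_found`.
#' @export
member_positions <- function(cluster, tr) {
  stopifnot(inherits(tr, "target_ranking"))
  cluster <- unique(as.character(cluster))
  pos <- tr$positions[cluster]
  found <- !is.na(pos)
  out <- data.frame(gene = cluster[found], position = unname(pos[found]),
                    class = target_class_of(tr, unname(pos[found])),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "not_found") <- cluster[!found]
  out
}

#' Histogram of member positions along the target ranking
#'
#' @param positions Output of [member_positions()].
#' @param bins Either a single bin count or a vector of bin edges covering
#'   `1..G`; the default three-bin layout separates the Class I block, the
#'   non-target band and the Class II block.
#' @param tr The `target_ranking` (needed for the default edges and range
#'   checking).
#' @return Named integer vector of counts, summing to `nrow(positions)`.
#' @export
class_histogram <- function(positions, bins = NULL, tr = NULL) {
  if (is.null(bins)) {
    stop_if(is.null(tr), "supply bins or the target ranking for default edges")
    G <- length(tr$genes)
    bins <- c(0, tr$n_class1, G - tr$n_class2, G)
  } else if (length(bins) == 1L) {
    stop_if(is.null(tr), "supply the target ranking to derive edges from a count")
    G <- length(tr$genes)
    bins <- unique(round(seq(0, G, length.out = bins + 1L)))
  }
  stop_if(is.unsorted(bins, strictly = TRUE), "bin edges must be increasing")
  stop_if(nrow(positions) > 0L &&
            (min(positions$position) <= bins[1L] ||
             max(positions$position) > bins[length(bins)]),
          "bin edges must cover all member positions")
  cuts <- cut(positions$position, breaks = bins)
  counts <- table(cuts)
  setNames(as.integer(counts), names(counts))
}

#' Target-fraction enrichment of a cluster
#'
#' Fraction of a cluster's genes (among those found in the ranking) that
#' are targets of either class, compared with the genome-wide target
#' fraction expected for a random gene set, with an exact binomial test.
#'
#' @param cluster Character vector of gene ids.
#' @param tr A `target_ranking`.
#' @param alternative Test direction for [stats::binom.test()]; default
#'   `"greater"` (enrichment).
#' @return List: `observed_pct`, `expected_pct`, `p`, plus per-class
#'   percentages `class1_pct`/`class2_pct`, counts and `n_found`.
#' @examples
#' tr <- target_ranking(sprintf("g%02d", 1:20), n_class1 = 5, n_class2 = 5)
#' target_fraction_enrichment(sprintf("g%02d", 1:5), tr)$observed_pct  # 100
#' @export
target_fraction_enrichment <- function(cluster, tr,
                                       alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(tr, "target_ranking"))
  mp <- member_positions(cluster, tr)
  n_found <- nrow(mp)
  stop_if(n_found == 0L, "no cluster gene found in the target ranking")
  G <- length(tr$genes)
  expected_frac <- (tr$n_class1 + tr$n_class2) / G
  k1 <- sum(mp$class == "ClassI")
  k2 <- sum(mp$class == "ClassII")
  k <- k1 + k2
  p <- binom.test(k, n_found, p = expected_frac, alternative = alternative)$p.value
  list(observed_pct = 100 * k / n_found,
       expected_pct = 100 * expected_frac,
       p = p,
       class1_pct = 100 * k1 / n_found,
       class2_pct = 100 * k2 / n_found,
       n_targets = k, n_found = n_found,
       not_found = attr(mp, "not_found"))
}
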