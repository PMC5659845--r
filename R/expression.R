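#' Read a replicate differential-expression table
#'
#' Reads a tab-separated table of per-gene, per-replicate log2 differential
#' expression values, the kind of table an RMA-normalized microarray
#' comparison exports. The first column holds the gene identifier, an
#' optional `coding` column flags protein-coding genes, and every remaining
#' column is one biological replicate. `"NA"` cells are recorded as missing,
#' never as zero.
#'
#' @param path Path to a TSV file with a header row.
#' @param sep Field separator, tab by default.
#' @param na_string String encoding a missing value. Default `"NA"`.
#' @return A `dex_table` object: a list with `genes` (character),
#'   `replicates` (character), `values` (numeric matrix, genes x replicates,
#'   `NA` = missing) and `coding` (logical, `TRUE` when no coding column is
#'   present).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tr1\tr2", "a\t1.0\t1.2", "b\t-0.5\tNA"), tf)
#' tab <- read_expression_table(tf)
#' tab$values
#' @export
read_expression_table <- function(path, sep = "\t", na_string = "NA") {
  stop_if(!file.exists(path), "expression table not found: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    stringsAsFactors = FALSE)
  stop_if(ncol(raw) < 2L, "expression table needs a gene column and >= 1 replicate column")
  genes <- raw[[1L]]
  stop_if(any(!nzchar(genes)), "empty gene id at row ", which(!nzchar(genes))[1L])
  dup <- genes[duplicated(genes)]
  stop_if(length(dup) > 0L, "duplicated gene id in expression table: ", dup[1L])

  cols <- names(raw)[-1L]
  coding_col <- match("coding", cols)
  coding <- rep(TRUE, length(genes))
  if (!is.na(coding_col)) {
    coding <- tolower(raw[[coding_col + 1L]]) %in% c("true", "t", "1", "yes")
    cols <- cols[-coding_col]
  }
  stop_if(length(cols) < 1L, "expression table has no replicate columns")

  values <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                   dimnames = list(genes, cols))
  for (j in seq_along(cols)) {
    cell <- raw[[cols[j]]]
    missing <- cell == na_string | !nzchar(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !missing)
    stop_if(length(bad) > 0L,
            "non-numeric value '", cell[bad[1L]], "' at row ", bad[1L],
            " (gene ", genes[bad[1L]], "), column '", cols[j], "'")
    num[missing] <- NA_real_
    values[, j] <- num
  }
  new_dex_table(genes, cols, values, coding)
}

new_dex_table <- function(genes, replicates, values, coding) {
  structure(list(genes = genes, replicates = replicates,
                 values = values, coding = coding),
            class = "dex_table")
}

#' Construct a differential-expression table in memory
#'
#' @param values Numeric matrix, genes in rows (rownames required),
#'   replicates in columns; `NA` marks a missing measurement.
#' @param coding Logical vector, one flag per gene; recycled if length 1.
#' @return A `dex_table` object.
#' @export
dex_table <- function(values, coding = TRUE) {
  stop_if(is.null(rownames(values)), "values matrix must carry gene rownames")
  stop_if(anyDuplicated(rownames(values)) > 0L, "duplicated gene id")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  coding <- rep_len(as.logical(coding), nrow(values))
  new_dex_table(rownames(values), colnames(values), values, coding)
}

#' Write a differential-expression table to TSV
#'
#' Inverse of [read_expression_table()]; the round trip preserves values,
#' missingness and the coding flags.
#'
#' @param table A `dex_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "dex_table"))
  df <- data.frame(gene = table$genes,
                   coding = table$coding,
                   as.data.frame(table$values, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.dex_table <- function(x, ...) {
  cat("Differential-expression table:", length(x$genes), "genes x",
      length(x$replicates), "replicates\n")
  cat("  replicates:", paste(x$replicates, collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$values)),
      " | non-coding genes:", sum(!x$coding), "\n")
  invisible(x)
}

#' Average replicates into per-gene mean and standard deviation
#'
#' Replicate log2 differences are averaged per gene; the spread across
#' replicates is the sample (n-1) standard deviation, 0 by convention when
#' only a single value is present. Missing replicate values are skipped per
#' gene; genes with no value at all are dropped with a warning.
#'
#' @param table A `dex_table`.
#' @return A data frame with columns `gene`, `mean`, `sd`, `n_present`, in
#'   the table's gene order.
#' @examples
#' tab <- dex_table(matrix(c(1, 3, 2, 2), 2, 2,
#'                  dimnames = list(c("a", "b"), c("r1", "r2"))))
#' average_replicates(tab)
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "dex_table"))
  n_present <- rowSums(!is.na(table$values))
  empty <- n_present == 0L
  if (any(empty))
    warning(sum(empty), " gene(s) with no present replicate value dropped: ",
            paste(head(table$genes[empty], 5L), collapse = ", "), call. = FALSE)
  keep <- !empty
  vals <- table$values[keep, , drop = FALSE]
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else sd(v)
  })
  data.frame(gene = table$genes[keep], mean = unname(m), sd = unname(s),
             n_present = unname(n_present[keep]), stringsAsFactors = FALSE)
}

#' Rank genes by mean differential expression
#'
#' Produces a 1-based total order over genes. Direction `"up"` puts the
#' largest mean log2 difference at position 1, `"down"` the most negative.
#' Ties are broken by lexicographic gene id so rankings are deterministic.
#'
#' @param summaries Data frame from [average_replicates()] (columns `gene`,
#'   `mean`), or any data frame with those columns.
#' @param direction `"up"` or `"down"`.
#' @return A `gene_ranking` object: `genes` in rank order, `positions`
#'   (named integer vector), `direction`.
#' @export
rank_genes <- function(summaries, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stop_if(nrow(summaries) < 1L, "no gene summaries to rank")
  means <- summaries$mean
  ord <- order(if (direction == "up") -means else means,
               summaries$gene, method = "radix")
  gene_ranking(summaries$gene[ord], direction)
}

#' Construct a ranking from an ordered gene list
#'
#' @param genes Character vector of gene ids, best-ranked first.
#' @param direction `"up"` or `"down"` (annotation only).
#' @return A `gene_ranking` object.
#' @export
gene_ranking <- function(genes, direction = "up") {
  stop_if(anyDuplicated(genes) > 0L, "duplicated gene id in ranking")
  stop_if(length(genes) < 1L, "empty ranking")
  structure(list(genes = as.character(genes),
                 positions = setNames(seq_along(genes), genes),
                 direction = direction),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat("Gene ranking (", x$direction, "): ", length(x$genes), " genes; top: ",
      paste(head(x$genes, 5L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select the strongest-affected hit genes
#'
#' Takes the top `n` genes of a ranking and then removes non-protein-coding
#' genes. The filter is applied after truncation and the list is not
#' refilled, so fewer than `n` hits may be returned; set
#' `refill = TRUE` to keep drawing coding genes from further down the
#' ranking until `n` are collected.
#'
#' @param ranking A `gene_ranking`.
#' @param n Number of top genes to retain before filtering (default 250).
#' @param coding Named logical vector (gene -> protein-coding flag); genes
#'   absent from it count as coding.
#' @param refill Refill with lower-ranked coding genes after filtering?
#'   Default `FALSE`.
#' @return A `hit_list` object: `genes` in ranking order, `direction`,
#'   `n_requested`.
#' @export
select_hits <- function(ranking, n = 250L, coding = NULL, refill = FALSE) {
  stopifnot(inherits(ranking, "gene_ranking"))
  stop_if(n <= 0L, "n must be a positive integer")
  stop_if(n > length(ranking$genes), "n exceeds the number of ranked genes")
  is_coding <- function(g) {
    if (is.null(coding)) rep(TRUE, length(g))
    else ifelse(is.na(coding[g]), TRUE, coding[g])
  }
  if (refill) {
    pool <- ranking$genes[is_coding(ranking$genes)]
    genes <- head(pool, n)
  } else {
    top <- head(ranking$genes, n)
    genes <- top[is_coding(top)]
  }
  structure(list(genes = genes, direction = ranking$direction,
                 n_requested = as.integer(n)),
            class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cat("Hit list (", x$direction, "): ", length(x$genes), " genes (requested ",
      x$n_requested, ")\n", sep = "")
  invisible(x)
}

#' Bin log2 expression differences into display shades
#'
#' Five bins follow the four-shade network-coloring convention: strong
#' down below -1, weak down below -0.25, white in between, weak up above
#' 0.25, strong up above 1. The thresholds are strict, so boundary values
#' fall into the weaker bin (`|x| = 1` is weak, `|x| = 0.25` is neutral).
#'
#' @param x Numeric vector of log2 differential expression values; must be
#'   finite.
#' @return Character vector with levels `down-strong`, `down-weak`,
#'   `neutral`, `up-weak`, `up-strong`.
#' @examples
#' color_bin(c(-1.5, -0.5, 0, 0.5, 1.5))
#' @export
color_bin <- function(x) {
  stop_if(any(!is.finite(x)), "color_bin requires finite values")
  out <- rep("neutral", length(x))
  out[x < -0.25] <- "down-weak"
  out[x < -1]    <- "down-strong"
  out[x > 0.25]  <- "up-weak"
  out[x > 1]     <- "up-strong"
  out
}

#' Hex colors for the display bins
#'
#' @param bins Character vector of bin labels from [color_bin()].
#' @return Hex color strings (blue shades down, white neutral, red shades up).
#' @export
bin_colors <- function(bins) {
  pal <- c("down-strong" = "#08519C", "down-weak" = "#9ECAE1",
           "neutral" = "#FFFFFF", "up-weak" = "#FCAE91",
           "up-strong" = "#A50F15")
  unname(pal[bins])
}

#' Write a per-gene summary report
#'
#' One row per gene with mean, sd, both rank positions and the display bin.
#'
#' @param summaries Output of [average_replicates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  up <- rank_genes(summaries, "up")
  down <- rank_genes(summaries, "down")
  df <- data.frame(gene = summaries$gene, mean = summaries$mean,
                   sd = summaries$sd,
                   rank_up = unname(up$positions[summaries$gene]),
                   rank_down = unname(down$positions[summaries$gene]),
                   color_bin = color_bin(summaries$mean),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
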