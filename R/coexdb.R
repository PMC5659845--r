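#' Load a gene-to-partner coexpression database
#'
#' Reads a precomputed coexpression-partner resource (modSEEK-style): for
#' every gene, a ranked list of its most strongly coregulated partner genes,
#' each with a multiplicity count recording how often the pair is marked
#' coexpressed. Lists are truncated to the top `K` partners by rank;
#' self-pairs are dropped with a warning. Lists are directed as stored —
#' gene A may list B without B listing A; symmetry is imposed only at
#' network-construction time.
#'
#' @param path TSV file with header and columns `gene`, `partner`, `rank`
#'   and optionally `count` (multiplicity, defaults to 1 when absent).
#' @param K Partners to retain per gene (default 40).
#' @return A `coex_db` object: `K` plus `entries`, a named list mapping each
#'   gene to a list with `partner` (character), `rank` (integer) and
#'   `count` (integer) in rank order.
#' @export
load_partner_db <- function(path, K = 40L) {
  stop_if(!file.exists(path), "partner database not found: ", path)
  stop_if(K < 1L, "K must be a positive integer")
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "partner", "rank")
  stop_if(!all(need %in% names(df)),
          "partner database needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$count)) df$count <- 1L
  stop_if(any(df$count < 1L), "multiplicity counts must be positive integers")

  self <- df$gene == df$partner
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped from partner database", call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  key <- paste(df$gene, df$rank, sep = "\r")
  dup <- duplicated(key)
  stop_if(any(dup), "duplicate rank within gene '", df$gene[dup][1L],
          "' (rank ", df$rank[dup][1L], ")")

  df <- df[order(df$gene, df$rank, method = "radix"), , drop = FALSE]
  entries <- lapply(split(df[c("partner", "rank", "count")], df$gene), function(e) {
    keep <- seq_len(min(nrow(e), K))
    list(partner = e$partner[keep], rank = as.integer(e$rank[keep]),
         count = as.integer(e$count[keep]))
  })
  coex_db(entries, K)
}

#' Construct a coexpression database in memory
#'
#' @param entries Named list: gene id -> list with `partner`, `rank`,
#'   `count` vectors (rank order). `rank`/`count` default to `1..n` / all 1
#'   when missing.
#' @param K Partner depth the database was truncated to.
#' @return A `coex_db` object.
#' @export
coex_db <- function(entries, K = 40L) {
  entries <- lapply(entries, function(e) {
    if (is.character(e)) e <- list(partner = e)
    n <- length(e$partner)
    list(partner = as.character(e$partner),
         rank = as.integer(e$rank %||% seq_len(n)),
         count = as.integer(e$count %||% rep(1L, n)))
  })
  for (g in names(entries)) {
    e <- entries[[g]]
    stop_if(length(e$partner) > K, "partner list for '", g, "' exceeds K = ", K)
    stop_if(g %in% e$partner, "self-pair in partner list of '", g, "'")
    stop_if(any(e$count < 1L), "multiplicity counts must be >= 1 ('", g, "')")
  }
  structure(list(K = as.integer(K), entries = entries), class = "coex_db")
}

#' Look up a gene's coexpression neighborhood
#'
#' @param db A `coex_db`.
#' @param gene Gene id.
#' @return A data frame (`partner`, `rank`, `count`) in rank order, with
#'   attribute `absent = TRUE` and zero rows when the gene is not in the
#'   database (the "not found in the used coexpression database" case).
#' @export
neighborhood <- function(db, gene) {
  stopifnot(inherits(db, "coex_db"))
  e <- db$entries[[gene]]
  if (is.null(e)) {
    out <- data.frame(partner = character(), rank = integer(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "absent") <- TRUE
    return(out)
  }
  out <- data.frame(partner = e$partner, rank = e$rank, count = e$count,
                    stringsAsFactors = FALSE)
  attr(out, "absent") <- FALSE
  out
}

#' Write a coexpression database to TSV
#'
#' Inverse of [load_partner_db()].
#'
#' @param db A `coex_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partner_db <- function(db, path) {
  stopifnot(inherits(db, "coex_db"))
  genes <- names(db$entries)
  n <- vapply(db$entries, function(e) length(e$partner), integer(1))
  df <- data.frame(gene = rep(genes, n),
                   partner = unlist(lapply(db$entries, `[[`, "partner"), use.names = FALSE),
                   rank = unlist(lapply(db$entries, `[[`, "rank"), use.names = FALSE),
                   count = unlist(lapply(db$entries, `[[`, "count"), use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.coex_db <- function(x, ...) {
  n <- vapply(x$entries, function(e) length(e$partner), integer(1))
  cat("Coexpression database: ", length(x$entries), " genes, K = ", x$K,
      ", mean partners/gene = ", round(mean(n), 1), "\n", sep = "")
  invisible(x)
}
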