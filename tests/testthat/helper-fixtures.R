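# Shared fixture builders; everything is generated in code, no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny expression table with known values
toy_table <- function() {
  m <- matrix(c(1, 3,
                2, 2,
                -4, -2,
                0.1, NA),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("r1", "r2")))
  dex_table(m)
}

# partner database over genes h1..h<n> plus fillers x1..x<k>
toy_db <- function() {
  coex_db(list(
    h1 = list(partner = c("h2", "x1", "x2"), count = c(1, 2, 1)),
    h2 = list(partner = c("h1", "x1", "x3"), count = c(1, 1, 3)),
    h3 = list(partner = c("x4", "x5", "x6"), count = c(1, 1, 1))
  ), K = 3)
}

# write a small partner-db TSV and return the path
write_toy_db_file <- function(n_partners = 100, gene = "g1") {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = gene,
                   partner = sprintf("p%03d", seq_len(n_partners)),
                   rank = seq_len(n_partners),
                   count = rep(c(1L, 2L), length.out = n_partners))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force rank-sum score oracle: enumerates all possible
# placements of n genes over the eligible positions to find best/worst sums
oracle_score <- function(real_positions, eligible_positions) {
  n <- length(real_positions)
  sums <- combn(eligible_positions, n, FUN = sum)
  best <- min(sums); worst <- max(sums)
  100 - 200 * (sum(real_positions) - best) / (worst - best)
}
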