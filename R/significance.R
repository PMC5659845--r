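#' Generate random gene lists for a null distribution
#'
#' Uniform samples without replacement from the gene universe, the control
#' construction behind every significance statement in the pipeline:
#' "similar-sized random lists of genes" analyzed in an identical manner.
#'
#' @param universe Character vector of candidate gene ids.
#' @param size Genes per list.
#' @param n_lists Number of lists (default 100).
#' @param seed RNG seed; identical seeds reproduce identical lists.
#' @return List of character vectors.
#' @export
random_gene_lists <- function(universe, size, n_lists = 100L, seed = 1L) {
  universe <- as.character(universe)
  stop_if(size > length(universe), "size exceeds the universe (",
          size, " > ", length(universe), ")")
  stop_if(size < 1L || n_lists < 1L, "size and n_lists must be positive")
  set.seed(seed)
  lapply(seq_len(n_lists), function(i) sample(universe, size))
}

#' Evaluate a metric over random lists
#'
#' @param metric Function taking one gene list and returning a single
#'   number (e.g. an UpRegScore, a CoRegScore after rebuilding the network,
#'   or a connectivity measure).
#' @param lists Output of [random_gene_lists()].
#' @return A `null_dist`: `values`, `mean`, `sd`, `n_lists`, `n_dropped`
#'   (lists on which the metric was undefined, dropped with a warning).
#' @export
null_distribution <- function(metric, lists) {
  stop_if(length(lists) < 2L, "need at least 2 random lists")
  vals <- vapply(lists, function(l) {
    tryCatch(as.numeric(metric(l)), error = function(e) NA_real_)
  }, numeric(1))
  dropped <- sum(is.na(vals))
  if (dropped > 0L)
    warning("metric undefined on ", dropped, " random list(s); dropped",
            call. = FALSE)
  vals <- vals[!is.na(vals)]
  stop_if(length(vals) < 2L, "metric defined on fewer than 2 lists")
  structure(list(values = vals, mean = mean(vals), sd = sd(vals),
                 n_lists = length(vals), n_dropped = dropped),
            class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf("Random-list null: %d lists, mean %.2f, sd %.2f",
              x$n_lists, x$mean, x$sd))
  if (x$n_dropped > 0L) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Z-score significance of an observed value against a random-list null
#'
#' Computes `z = (observed - null mean) / null sd` and the one-tailed
#' standard-normal p-value: the upper tail when testing for values larger
#' than chance (up-regulation, connectivity), the lower tail when testing
#' for down-regulation. An empirical tail probability over the null values
#' is reported alongside.
#'
#' @param observed Observed value of the metric.
#' @param null A `null_dist`.
#' @param direction `"upper"` or `"lower"` tail.
#' @return A `signif_result`: `observed`, `z`, `p`, `p_empirical`,
#'   `direction`, plus the null mean/sd.
#' @export
significance <- function(observed, null, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  stopifnot(inherits(null, "null_dist"))
  stop_if(null$sd == 0, "degenerate null: standard deviation is zero")
  z <- (observed - null$mean) / null$sd
  p <- if (direction == "upper") pnorm(z, lower.tail = FALSE) else pnorm(z)
  # smoothed empirical tail so it is never exactly 0
  p_emp <- (sum(if (direction == "upper") null$values >= observed
                else null$values <= observed) + 1) / (null$n_lists + 1)
  structure(list(observed = observed, z = z, p = p, p_empirical = p_emp,
                 direction = direction, null_mean = null$mean,
                 null_sd = null$sd, n_lists = null$n_lists),
            class = "signif_result")
}

#' @export
print.signif_result <- function(x, ...) {
  cat(sprintf("observed %.2f vs null %.2f +/- %.2f (n = %d)\n",
              x$observed, x$null_mean, x$null_sd, x$n_lists))
  cat(sprintf("z = %.2f, one-tailed (%s) p = %.3g (empirical %.3g)\n",
              x$z, x$direction, x$p, x$p_empirical))
  invisible(x)
}

#' Write a significance report
#'
#' @param results Named list of `signif_result` objects.
#' @param path Output TSV path.
#' @param seed Seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_significance_report <- function(results, path, seed = NA_integer_) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]
    data.frame(metric = nm, observed = s$observed, null_mean = s$null_mean,
               null_sd = s$null_sd, z = s$z, p = s$p,
               p_empirical = s$p_empirical, direction = s$direction,
               n_lists = s$n_lists, seed = seed, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
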