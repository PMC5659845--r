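#' Generate a ground-truthed synthetic world
#'
#' Builds a synthetic genome with planted coexpression modules: disjoint
#' gene sets that are both coregulated (a shared mean log2 expression shift
#' per experiment) and coexpressed (their partner-database lists point at
#' co-members with fidelity `f`). Every downstream emitter —
#' [emit_partner_db()], [emit_expression()], [emit_target_ranking()] — is a
#' pure function of the world, so a given `(parameters, seed)` pair
#' reproduces identical outputs byte for byte. The `truth` record keeps
#' memberships and effects for parameter-recovery checks.
#'
#' @param G Genome size (number of genes).
#' @param modules List of module definitions; each a list with `name`,
#'   `size`, `f` (coexpression fidelity in \[0, 1\], default 0.9) and
#'   `effects` (named numeric, mean log2 shift per experiment; a bare
#'   number means experiment `"main"`).
#' @param noise_sd Gaussian replicate noise sd (log2 units, default 1).
#' @param n_replicates Replicates per experiment (default 3).
#' @param K Partner-list depth of the emitted database (default 40).
#' @param seed RNG seed.
#' @param replicate_scale Optional numeric vector (length `n_replicates`)
#'   scaling the planted effect per replicate, emulating replicates that
#'   differ in response strength. Default all 1.
#' @param missing Optional named list: experiment -> fraction of genes not
#'   measured in that experiment (dropped from its table).
#' @param frac_noncoding Fraction of genes flagged non-protein-coding
#'   (default 0).
#' @return A `synthetic_world` object.
#' @examples
#' w <- generate_world(G = 500, modules = list(
#'   list(name = "m1", size = 20, f = 1, effects = c(main = 3))), seed = 7)
#' length(w$truth$members$m1)
#' @export
generate_world <- function(G = 2000L,
                           modules = list(),
                           noise_sd = 1,
                           n_replicates = 3L,
                           K = 40L,
                           seed = 1L,
                           replicate_scale = NULL,
                           missing = list(),
                           frac_noncoding = 0) {
  stop_if(G < 2L, "G must be >= 2")
  modules <- lapply(modules, function(m) {
    stop_if(is.null(m$name) || is.null(m$size), "each module needs name and size")
    if (is.null(names(m$effects)) && length(m$effects) == 1L)
      m$effects <- c(main = unname(m$effects))
    m$f <- m$f %||% 0.9
    stop_if(m$f < 0 || m$f > 1, "module fidelity f must be in [0, 1]")
    stop_if(any(!is.finite(m$effects)), "module effects must be finite")
    m
  })
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  stop_if(sum(sizes) > G, "module sizes exceed the genome")
  nms <- vapply(modules, `[[`, "", "name")
  stop_if(anyDuplicated(nms) > 0L, "duplicated module name")

  genes <- sprintf("g%05d", seq_len(G))
  set.seed(substream_seed(seed, "world"))
  pool <- sample(genes)           # random placement of module members
  members <- list()
  at <- 1L
  for (i in seq_along(modules)) {
    members[[nms[i]]] <- sort(pool[at:(at + sizes[i] - 1L)])
    at <- at + sizes[i]
  }
  coding <- setNames(rep(TRUE, G), genes)
  if (frac_noncoding > 0)
    coding[sample(genes, round(frac_noncoding * G))] <- FALSE

  experiments <- unique(unlist(lapply(modules, function(m) names(m$effects))))
  if (length(experiments) == 0L) experiments <- "main"
  replicate_scale <- replicate_scale %||% rep(1, n_replicates)
  stop_if(length(replicate_scale) != n_replicates,
          "replicate_scale must have one entry per replicate")

  effects <- matrix(0, length(modules), length(experiments),
                    dimnames = list(nms, experiments))
  for (m in modules) effects[m$name, names(m$effects)] <- m$effects

  structure(list(G = as.integer(G), genes = genes, modules = modules,
                 experiments = experiments,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 K = as.integer(K), seed = as.integer(seed),
                 replicate_scale = replicate_scale, missing = missing,
                 coding = coding,
                 truth = list(members = members, effects = effects,
                              f = setNames(vapply(modules, `[[`, 0, "f"), nms))),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world: G =", x$G, "| seed", x$seed, "| K =", x$K, "\n")
  for (m in x$modules)
    cat("  module ", m$name, ": ", m$size, " genes, f = ", m$f,
        ", effects [", paste(names(m$effects), round(m$effects, 2),
                             sep = "=", collapse = ", "), "]\n", sep = "")
  cat("  experiments:", paste(x$experiments, collapse = ", "),
      "| replicates:", x$n_replicates, "| noise sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Emit the world's coexpression partner database
#'
#' Each module member's top-K partner list points at a random co-member
#' with probability `f` per slot and at a uniformly drawn non-member
#' otherwise; partners within a list are distinct and slot order is random.
#' Non-module genes receive uniformly random partner lists. Multiplicity
#' counts are drawn from \{1, 2, 3\} with probabilities (0.6, 0.3, 0.1).
#'
#' @param world A `synthetic_world`.
#' @return A `coex_db`.
#' @export
emit_partner_db <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(substream_seed(world$seed, "db"))
  G <- world$G; K <- world$K; genes <- world$genes
  module_of <- setNames(rep(NA_character_, G), genes)
  for (nm in names(world$truth$members))
    module_of[world$truth$members[[nm]]] <- nm

  sample_others <- function(g, n, exclude) {
    # distinct uniform draws from genes \ ({g} U exclude), O(n) by rejection
    out <- character(0)
    while (length(out) < n) {
      cand <- genes[unique(sample.int(G, n - length(out) + 8L, replace = TRUE))]
      cand <- setdiff(cand, c(g, exclude, out))
      out <- c(out, cand)
    }
    out[seq_len(n)]
  }

  entries <- vector("list", G)
  names(entries) <- genes
  for (i in seq_len(G)) {
    g <- genes[i]
    mod <- module_of[[g]]
    if (!is.na(mod)) {
      co <- setdiff(world$truth$members[[mod]], g)
      f <- world$truth$f[[mod]]
      n_co <- min(rbinom(1L, K, f), length(co), K)
      co_part <- if (n_co > 0L) sample(co, n_co) else character(0)
      fillers <- sample_others(g, K - n_co, co_part)
      partners <- sample(c(co_part, fillers))
    } else {
      partners <- sample_others(g, K, character(0))
    }
    entries[[i]] <- list(partner = partners,
                         rank = seq_len(K),
                         count = sample(1:3, K, replace = TRUE,
                                        prob = c(0.6, 0.3, 0.1)))
  }
  coex_db(entries, K)
}

#' Emit a replicate differential-expression table for one experiment
#'
#' Each replicate value is the module's planted effect in that experiment
#' (0 for non-members), scaled by the replicate's response-strength factor,
#' plus Gaussian noise. An experiment's missing-gene fraction removes genes
#' from the table entirely, emulating platforms that did not measure them.
#'
#' @param world A `synthetic_world`.
#' @param experiment Experiment label defined in the world.
#' @return A `dex_table`.
#' @export
emit_expression <- function(world, experiment = "main") {
  stopifnot(inherits(world, "synthetic_world"))
  stop_if(!experiment %in% world$experiments,
          "unknown experiment '", experiment, "'")
  set.seed(substream_seed(world$seed, paste0("expr:", experiment)))
  effect <- setNames(rep(0, world$G), world$genes)
  for (nm in rownames(world$truth$effects))
    effect[world$truth$members[[nm]]] <- world$truth$effects[nm, experiment]
  R <- world$n_replicates
  vals <- outer(effect, world$replicate_scale) +
    matrix(rnorm(world$G * R, sd = world$noise_sd), world$G, R)
  dimnames(vals) <- list(world$genes, paste0("rep", seq_len(R)))
  frac <- world$missing[[experiment]] %||% 0
  if (frac > 0) {
    drop <- sample(world$genes, round(frac * world$G))
    vals <- vals[!rownames(vals) %in% drop, , drop = FALSE]
  }
  dex_table(vals, coding = world$coding[rownames(vals)])
}

#' Emit a genome-wide target-class ranking
#'
#' Produces a permutation of the genome with the top `n_class1` positions
#' forming the Class I block and the bottom `n_class2` the Class II block.
#' Each member of `enriched_module` is placed uniformly inside the Class I
#' block with probability `strength`; all remaining genes are shuffled over
#' the remaining positions.
#'
#' @param world A `synthetic_world`.
#' @param n_class1,n_class2 Class block sizes.
#' @param enriched_module Module name to enrich in Class I, or `NULL`.
#' @param strength Per-member placement probability in \[0, 1\].
#' @return A `target_ranking`.
#' @export
emit_target_ranking <- function(world, n_class1, n_class2,
                                enriched_module = NULL, strength = 0) {
  stopifnot(inherits(world, "synthetic_world"))
  stop_if(n_class1 + n_class2 > world$G, "class sizes exceed the genome")
  stop_if(strength < 0 || strength > 1, "strength must be in [0, 1]")
  set.seed(substream_seed(world$seed, "target"))
  ordered <- rep(NA_character_, world$G)
  placed <- character(0)
  if (!is.null(enriched_module) && strength > 0) {
    mem <- world$truth$members[[enriched_module]]
    stop_if(is.null(mem), "unknown module '", enriched_module, "'")
    placed <- mem[rbinom(length(mem), 1L, strength) == 1L]
    placed <- placed[seq_len(min(length(placed), n_class1))]
    if (length(placed) > 0L)
      ordered[sample.int(n_class1, length(placed))] <- placed
  }
  rest <- setdiff(world$genes, placed)
  ordered[is.na(ordered)] <- sample(rest)
  target_ranking(ordered, n_class1, n_class2)
}

#' Prebuilt world configurations
#'
#' `"desk"` is a fast validation world: G = 2000 genes, three planted
#' 60-gene modules (two upregulated, one downregulated in the main
#' experiment; a companion experiment shares only the first module), noise
#' sd 1, 3 replicates, K = 40. `"paper_scale"` is a genome-scale world of
#' 26,959 genes with a single planted 60-gene module (effect +3, noise sd
#' 1, fidelity 0.9) for parameter-recovery runs with 250-gene hit lists and
#' K = 40.
#'
#' @param name `"desk"` or `"paper_scale"`.
#' @param seed RNG seed.
#' @return A `synthetic_world`.
#' @export
world_preset <- function(name = c("desk", "paper_scale"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    desk = generate_world(
      G = 2000L,
      modules = list(
        list(name = "up1",   size = 60L, f = 0.9,
             effects = c(main = 3,  companion = 3)),
        list(name = "up2",   size = 60L, f = 0.9,
             effects = c(main = 2.5, companion = 0)),
        list(name = "down1", size = 60L, f = 0.9,
             effects = c(main = -3, companion = 0))),
      noise_sd = 1, n_replicates = 3L, K = 40L, seed = seed,
      missing = list(companion = 0.05)),
    paper_scale = generate_world(
      G = 26959L,
      modules = list(
        list(name = "planted", size = 60L, f = 0.9, effects = c(main = 3))),
      noise_sd = 1, n_replicates = 3L, K = 40L, seed = seed))
}

#' Write all of a world's inputs to a directory
#'
#' Emits the expression tables (one per experiment), the partner database
#' and a manifest, in the dialects the readers accept — a complete input
#' bundle for [run_analysis()].
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @param n_class1,n_class2,enriched_module,strength Optional target-ranking
#'   parameters; the ranking is written when `n_class1` is given.
#' @return Named list of written paths, invisibly.
#' @export
write_world <- function(world, dir, n_class1 = NULL, n_class2 = NULL,
                        enriched_module = NULL, strength = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ex in world$experiments) {
    p <- file.path(dir, paste0("expression_", ex, ".tsv"))
    write_expression_table(emit_expression(world, ex), p)
    paths[[paste0("expression_", ex)]] <- p
  }
  paths$partner_db <- file.path(dir, "partner_db.tsv")
  write_partner_db(emit_partner_db(world), paths$partner_db)
  if (!is.null(n_class1)) {
    paths$target_ranking <- file.path(dir, "target_ranking.tsv")
    write_target_ranking(
      emit_target_ranking(world, n_class1, n_class2, enriched_module, strength),
      paths$target_ranking)
  }
  paths$manifest <- file.path(dir, "world_manifest.json")
  jsonlite::write_json(
    list(G = world$G, K = world$K, seed = world$seed,
         noise_sd = world$noise_sd, n_replicates = world$n_replicates,
         experiments = world$experiments,
         modules = lapply(world$modules, function(m)
           list(name = m$name, size = m$size, f = m$f,
                effects = as.list(m$effects)))),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
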