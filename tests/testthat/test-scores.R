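test_that("CoRegScore hits the documented extremes and derived example", {
  r <- gene_ranking(sprintf("g%04d", 1:1000))
  # predicted genes exactly in the block after the hits: perfect prediction
  expect_equal(co_reg_score(sprintf("g%04d", 251:300), r, 250)$score, 100)
  # predicted genes at the very bottom: worst possible prediction
  expect_equal(co_reg_score(sprintf("g%04d", 951:1000), r, 250)$score, -100)

  # G = 10, n_hits = 3, predicted at positions 4 and 7
  r10 <- gene_ranking(letters[1:10])
  res <- co_reg_score(c("d", "g"), r10, n_hits = 3)
  expect_equal(res$added_real, 11)
  expect_equal(res$added_best, 9)
  expect_equal(res$added_worst, 19)
  expect_equal(res$score, oracle_score(c(4, 7), 4:10))

  expect_error(co_reg_score(character(), r10, 3), "empty")
  # degenerate: predicted fill every non-hit position
  expect_error(co_reg_score(letters[4:10], r10, 3), "degenerate")
})

test_that("UpRegScore hits the extremes and the derived example", {
  r <- gene_ranking(letters[1:10])
  expect_equal(up_reg_score(c("a", "b", "c"), r)$score, 100)
  expect_equal(up_reg_score(c("h", "i", "j"), r)$score, -100)

  res <- up_reg_score(c("a", "e", "j"), r)
  expect_equal(res$added_real, 16)
  expect_equal(res$added_best, 6)
  expect_equal(res$added_worst, 27)
  expect_equal(res$score, oracle_score(c(1, 5, 10), 1:10))

  # genes absent from the experiment are omitted and n shrinks
  res2 <- up_reg_score(c("a", "b", "zz"), r)
  expect_equal(res2$n_evaluated, 2L)
  expect_equal(res2$omitted, "zz")
  expect_equal(res2$score, 100)
  expect_error(up_reg_score("zz", r), "undefined")
})

test_that("score invariances: antisymmetry, neutrality, monotonicity, relabeling", {
  set.seed(19)
  genes <- sprintf("g%03d", 1:200)
  for (i in 1:10) {
    ord <- sample(genes)
    r <- gene_ranking(ord)
    rrev <- gene_ranking(rev(ord))
    S <- sample(genes, sample(3:30, 1))
    # reversing the ranking flips the score's sign
    expect_equal(up_reg_score(S, r)$score, -up_reg_score(S, rrev)$score)
  }

  # Monte-Carlo null expectation is ~0
  r <- gene_ranking(genes)
  vals <- vapply(1:400, function(i) up_reg_score(sample(genes, 20), r)$score,
                 numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-9)

  # moving an evaluated gene up never decreases the score
  ord <- sprintf("g%03d", 1:200)
  S <- c("g050", "g120")
  base <- up_reg_score(S, gene_ranking(ord))$score
  better <- replace(ord, c(40, 50), ord[c(50, 40)])  # g050 moves to pos 40
  expect_gte(up_reg_score(S, gene_ranking(better))$score, base)

  # relabeling genes outside the evaluated set changes nothing
  relab <- ord
  out <- setdiff(seq_along(ord), match(S, ord))
  relab[out] <- paste0("x", relab[out])
  expect_equal(up_reg_score(S, gene_ranking(relab))$score, base)
  cr_base <- co_reg_score(S, gene_ranking(ord), 10)$score
  expect_equal(co_reg_score(S, gene_ranking(relab), 10)$score, cr_base)
})

test_that("cluster profiles agree with direct scores and flag absent clusters", {
  r1 <- gene_ranking(sprintf("g%02d", 1:50))
  prof <- cluster_profile(list(c1 = c("g01", "g02")), list(expA = r1))
  expect_equal(dim(prof$scores), c(1L, 1L))
  expect_equal(prof$scores["c1", "expA"],
               up_reg_score(c("g01", "g02"), r1)$score)

  # a cluster with no gene in an experiment is an NA cell, not an error
  r2 <- gene_ranking(sprintf("h%02d", 1:50))
  prof2 <- cluster_profile(list(c1 = c("g01", "g02")),
                           list(expA = r1, expB = r2))
  expect_false(is.na(prof2$scores["c1", "expA"]))
  expect_true(is.na(prof2$scores["c1", "expB"]))
})

test_that("planted shared and unshared clusters separate in the profile", {
  w <- world_preset("desk", seed = 21)
  rank_of <- function(ex) rank_genes(average_replicates(emit_expression(w, ex)), "up")
  rankings <- list(main = rank_of("main"), companion = rank_of("companion"))
  prof <- cluster_profile(list(up1 = w$truth$members$up1,
                               up2 = w$truth$members$up2), rankings)
  # up1 is regulated in both experiments, up2 only in main
  expect_gt(prof$scores["up1", "main"], 80)
  expect_gt(prof$scores["up1", "companion"], 80)
  expect_gt(prof$scores["up2", "main"], 80)
  expect_lt(prof$scores["up2", "companion"], 40)
  expect_gt(prof$scores["up2", "main"] - prof$scores["up2", "companion"], 40)
})

test_that("experiment projection recolors nodes and flags unmeasured genes", {
  db <- coex_db(list(h1 = list(partner = "h2"), h2 = list(partner = "h1")), K = 1)
  s <- data.frame(gene = c("h1", "h2"), mean = c(2, -2))
  net <- build_network(c("h1", "h2"), db, s)
  # identity projection reproduces the original coloring
  proj <- project_experiment(net, s)
  expect_equal(proj$color_bin, net$nodes$color_bin)
  expect_false(any(proj$omitted))
  # a node missing externally is flagged omitted
  proj2 <- project_experiment(net, s[1, , drop = FALSE])
  expect_true(proj2$omitted[proj2$gene == "h2"])
  expect_true(is.na(proj2$mean[proj2$gene == "h2"]))
})
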