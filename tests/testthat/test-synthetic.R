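test_that("worlds are deterministic, disjoint, and validated", {
  mods <- list(list(name = "m1", size = 30, f = 1, effects = c(main = 3)),
               list(name = "m2", size = 30, f = 0.5, effects = c(main = -2)))
  w1 <- generate_world(G = 500, modules = mods, seed = 9)
  w2 <- generate_world(G = 500, modules = mods, seed = 9)
  expect_identical(w1, w2)
  expect_length(intersect(w1$truth$members$m1, w1$truth$members$m2), 0)
  expect_identical(emit_partner_db(w1), emit_partner_db(w1))
  expect_identical(emit_expression(w1, "main"), emit_expression(w2, "main"))
  w3 <- generate_world(G = 500, modules = mods, seed = 10)
  expect_false(identical(emit_expression(w1, "main"),
                         emit_expression(w3, "main")))

  expect_error(generate_world(G = 50, modules = mods), "exceed")
  expect_error(generate_world(G = 500, modules = list(
    list(name = "bad", size = 10, f = 2, effects = 1))), "f must be")
  expect_error(emit_expression(w1, "nope"), "unknown experiment")
})

test_that("fidelity saturates at f = 1 and falls to chance at f = 0", {
  w <- generate_world(G = 400, modules = list(
    list(name = "m", size = 41, f = 1, effects = c(main = 3))),
    K = 40, seed = 4)
  db <- emit_partner_db(w)
  mem <- w$truth$members$m
  for (g in mem[1:10]) {
    nb <- neighborhood(db, g)
    expect_true(all(nb$partner %in% mem))
    expect_equal(nrow(nb), 40L)
  }

  # f = 0: co-member fraction in members' lists is at the chance level
  w0 <- generate_world(G = 400, modules = list(
    list(name = "m", size = 41, f = 0, effects = c(main = 3))),
    K = 40, seed = 4)
  db0 <- emit_partner_db(w0)
  mem0 <- w0$truth$members$m
  frac <- mean(vapply(mem0, function(g)
    mean(neighborhood(db0, g)$partner %in% mem0), numeric(1)))
  chance <- 40 / 399  # co-members among eligible partners
  expect_lt(abs(frac - chance), 3 * sqrt(chance * (1 - chance) / (41 * 40)))
})

test_that("expression emission reproduces planted effects", {
  w <- generate_world(G = 300, modules = list(
    list(name = "up", size = 20, f = 1, effects = c(main = 3))),
    noise_sd = 0, n_replicates = 3, seed = 6)
  tab <- emit_expression(w, "main")
  mem <- w$truth$members$up
  expect_true(all(tab$values[mem, ] == 3))
  expect_true(all(tab$values[setdiff(tab$genes, mem), ] == 0))

  # with noise, the planted up-module dominates the top of the ranking
  wn <- generate_world(G = 2000, modules = list(
    list(name = "up", size = 60, f = 1, effects = c(main = 3))),
    noise_sd = 1, n_replicates = 3, seed = 6)
  r <- rank_genes(average_replicates(emit_expression(wn, "main")), "up")
  top60 <- head(r$genes, 60)
  expect_gt(mean(top60 %in% wn$truth$members$up), 0.9)

  # per-experiment missing mask drops genes from the table
  wm <- generate_world(G = 300, modules = list(
    list(name = "up", size = 20, f = 1, effects = c(main = 1, other = 1))),
    missing = list(other = 0.2), seed = 2)
  expect_equal(length(emit_expression(wm, "main")$genes), 300L)
  expect_equal(length(emit_expression(wm, "other")$genes), 240L)
})

test_that("planted module networks dwarf random-list networks", {
  w <- world_preset("desk", seed = 14)
  db <- emit_partner_db(w)
  planted <- build_network(w$truth$members$up1, db)
  expect_equal(hit_inclusion_fraction(planted), 100)

  set.seed(15)
  rand <- build_network(sample(w$genes, 60), db)
  expect_gt(connections_per_hit(planted), 50 * max(1, connections_per_hit(rand)))
  expect_lt(hit_inclusion_fraction(rand), hit_inclusion_fraction(planted))
})

test_that("synthetic target rankings carry the requested enrichment", {
  w <- generate_world(G = 1000, modules = list(
    list(name = "m", size = 40, f = 1, effects = c(main = 2))), seed = 8)
  tr1 <- emit_target_ranking(w, 100, 100, enriched_module = "m", strength = 1)
  e1 <- target_fraction_enrichment(w$truth$members$m, tr1)
  expect_equal(e1$observed_pct, 100)
  expect_equal(e1$class1_pct, 100)

  tr0 <- emit_target_ranking(w, 100, 100, enriched_module = "m", strength = 0)
  e0 <- target_fraction_enrichment(w$truth$members$m, tr0)
  expect_lt(abs(e0$observed_pct - e0$expected_pct),
            100 * 4 * sqrt(0.2 * 0.8 / 40))

  expect_error(emit_target_ranking(w, 600, 600), "exceed")
})

test_that("end-to-end hit selection recovers the planted module", {
  w <- generate_world(G = 2000, modules = list(
    list(name = "up", size = 60, f = 0.9, effects = c(main = 3))),
    noise_sd = 1, n_replicates = 3, K = 40, seed = 23)
  db <- emit_partner_db(w)
  tab <- emit_expression(w, "main")
  s <- average_replicates(tab)
  hits <- select_hits(rank_genes(s, "up"), 250)
  recovered <- mean(w$truth$members$up %in% hits$genes)
  expect_gte(recovered, 0.9)

  # the members' network is one dominant cluster
  net <- build_network(intersect(hits$genes, w$truth$members$up), db)
  cl <- assign_clusters(net, min_size = 3)
  groups <- attr(cl, "clusters")
  expect_gte(length(groups), 1L)
  expect_gt(length(groups[["1"]]) / nrow(net$nodes), 0.9)
})
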