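test_that("mutual listing yields one edge with weights summed over neighborhoods", {
  db <- coex_db(list(h1 = list(partner = "h2", count = 1),
                     h2 = list(partner = "h1", count = 1)), K = 1)
  net <- build_network(c("h1", "h2"), db)
  expect_equal(nrow(net$edges), 1L)
  # (h1,h2) occurs in both neighborhoods, once each
  expect_equal(net$edges$weight, 2)
  expect_equal(net$considered_pairs, 2 * (1 + 1)^2)
})

test_that("considered-pairs arithmetic holds across sizes and K", {
  for (n_hits in c(3L, 17L, 50L)) {
    for (K in c(2L, 5L, 40L)) {
      genes <- sprintf("h%03d", seq_len(n_hits))
      fill <- sprintf("f%03d", seq_len(K))
      entries <- setNames(lapply(genes, function(g) list(partner = fill)), genes)
      # drop one entry so hits_with_db_entry < n_hits
      db <- coex_db(entries[-1], K = K)
      net <- build_network(genes, db)
      expect_equal(net$considered_pairs, (n_hits - 1) * (K + 1)^2)
      expect_true(net$nodes$db_absent[net$nodes$gene == genes[1]])
    }
  }
})

test_that("network matches a brute-force pair enumeration oracle", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:30)
  entries <- setNames(lapply(genes, function(g) {
    p <- sample(setdiff(genes, g), 5)
    list(partner = p, count = sample(1:3, 5, replace = TRUE))
  }), genes)
  db <- coex_db(entries, K = 5)
  hits <- sample(genes, 12)
  net <- build_network(hits, db)

  # independent enumeration: loop over every neighborhood and ordered pair
  acc <- new.env()
  for (h in hits) {
    e <- entries[[h]]
    nbg <- c(h, e$partner); nbm <- c(1L, e$count)
    for (i in seq_along(nbg)) for (j in seq_along(nbg)) {
      if (i >= j) next
      a <- nbg[i]; b <- nbg[j]
      if (!(a %in% hits) || !(b %in% hits)) next
      key <- paste(sort(c(a, b)), collapse = "|")
      acc[[key]] <- (acc[[key]] %||% 0) + nbm[i] * nbm[j]
    }
  }
  got <- setNames(net$edges$weight, paste(net$edges$a, net$edges$b, sep = "|"))
  want <- unlist(as.list(acc))
  expect_equal(got[sort(names(got))], want[sort(names(want))])

  # invariant to hit-list order
  net2 <- build_network(rev(hits), db)
  expect_equal(net2$edges, net$edges)

  # sum of node-incident weights is twice the total edge weight
  inc <- tapply(c(net$edges$weight, net$edges$weight),
                c(net$edges$a, net$edges$b), sum)
  expect_equal(sum(inc), 2 * sum(net$edges$weight))
})

test_that("disjoint neighborhoods give an edgeless network of isolated hits", {
  entries <- list(h1 = list(partner = c("x1", "x2")),
                  h2 = list(partner = c("y1", "y2")),
                  h3 = list(partner = c("z1", "z2")))
  net <- build_network(names(entries), coex_db(entries, K = 2))
  expect_equal(nrow(net$edges), 0L)
  expect_equal(hit_inclusion_fraction(net), 0)
  expect_equal(connections_per_hit(net), 0)
})

test_that("inclusion fraction and connections per hit follow direct counts", {
  # complete mutual listing: everyone included
  genes <- c("h1", "h2", "h3")
  entries <- setNames(lapply(genes, function(g)
    list(partner = setdiff(genes, g))), genes)
  tri <- build_network(genes, coex_db(entries, K = 2))
  expect_equal(hit_inclusion_fraction(tri), 100)

  # triangle of unit edges: each node touches two edges of weight 1
  db1 <- coex_db(list(h1 = list(partner = "h2"),
                      h2 = list(partner = "h3"),
                      h3 = list(partner = "h1")), K = 1)
  tri1 <- build_network(genes, db1)
  expect_equal(nrow(tri1$edges), 3L)
  expect_true(all(tri1$edges$weight == 1))
  expect_equal(connections_per_hit(tri1), 2)

  # one isolated hit out of three
  db2 <- coex_db(list(h1 = list(partner = "h2"),
                      h2 = list(partner = "h1"),
                      h3 = list(partner = "x9")), K = 1)
  net2 <- build_network(genes, db2)
  expect_equal(hit_inclusion_fraction(net2), 100 * 2 / 3, tolerance = 1e-12)

  # single edge of weight 4 between two hits: mean (4 + 4) / 2
  db3 <- coex_db(list(h1 = list(partner = "h2", count = 2),
                      h2 = list(partner = "h1", count = 2)), K = 1)
  net3 <- build_network(c("h1", "h2"), db3)
  expect_equal(net3$edges$weight, 4)
  expect_equal(connections_per_hit(net3), 4)
})

test_that("gene prediction ranks non-hits by summed counts with tie-breaks", {
  entries <- list(
    h1 = list(partner = c("x", "y"), count = c(2L, 3L)),
    h2 = list(partner = c("x", "z"), count = c(1L, 1L)),
    h3 = list(partner = c("y", "h1"), count = c(1L, 1L)))
  db <- coex_db(entries, K = 2)
  hits <- c("h1", "h2", "h3")
  # counts: x = 3, y = 4, z = 1 by direct addition
  pred <- predict_genes(hits, db, 2)
  expect_equal(as.character(pred)[1:2], c("y", "x"))
  expect_equal(attr(pred, "counts"), c(4, 3))
  expect_false(attr(pred, "shortfall"))

  # equal counts fall back to lexicographic order
  tie_db <- coex_db(list(h1 = list(partner = c("x", "y", "z"),
                                   count = c(3L, 3L, 1L))), K = 3)
  tie <- predict_genes("h1", tie_db, 2)
  expect_equal(as.character(tie), c("x", "y"))

  # nothing connected: empty result flagged
  lone <- predict_genes("h9", db, 2)
  expect_equal(length(lone), 0L)
  expect_true(attr(lone, "shortfall"))
})

test_that("predicted genes integrate with hit-predicted edges only", {
  entries <- list(h1 = list(partner = c("p1", "p2")),
                  h2 = list(partner = c("p1", "h1")))
  db <- coex_db(entries, K = 2)
  net <- build_network(c("h1", "h2"), db, predicted = c("p1", "p2"))
  expect_setequal(net$nodes$gene, c("h1", "h2", "p1", "p2"))
  expect_equal(net$nodes$role[net$nodes$gene == "p1"], "predicted")
  # p1-p2 co-occur in h1's neighborhood but both are predicted: no edge
  pp <- net$edges$a == "p1" & net$edges$b == "p2"
  expect_false(any(pp))
  # every predicted node has at least one edge to a hit
  for (p in c("p1", "p2")) {
    touching <- net$edges[net$edges$a == p | net$edges$b == p, ]
    other <- ifelse(touching$a == p, touching$b, touching$a)
    expect_true(any(other %in% c("h1", "h2")))
  }
  # considered pairs counts hit neighborhoods only
  expect_equal(net$considered_pairs, 2 * (2 + 1)^2)
})

test_that("cluster assignment labels components, outsiders, and absent genes", {
  # two disjoint mutually-listing cliques plus an isolated and an absent hit
  genes <- c("a1", "a2", "a3", "b1", "b2", "b3", "iso", "gone")
  entries <- list(
    a1 = list(partner = c("a2", "a3")), a2 = list(partner = c("a1", "a3")),
    a3 = list(partner = c("a1", "a2")), b1 = list(partner = c("b2", "b3")),
    b2 = list(partner = c("b1", "b3")), b3 = list(partner = c("b1", "b2")),
    iso = list(partner = c("q1", "q2")))
  net <- build_network(genes, coex_db(entries, K = 2))
  cl <- assign_clusters(net, min_size = 3)
  groups <- attr(cl, "clusters")
  expect_equal(length(groups), 2L)
  expect_setequal(groups[["1"]], c("a1", "a2", "a3"))
  expect_setequal(groups[["2"]], c("b1", "b2", "b3"))
  expect_equal(unname(unclass(cl)["iso"]), "0")
  expect_equal(unname(unclass(cl)["gone"]), "-")

  # manual override replaces automatic labels
  cl2 <- assign_clusters(net, min_size = 3,
                         override = data.frame(gene = "iso", cluster = "manual"))
  expect_equal(unname(unclass(cl2)["iso"]), "manual")
})

test_that("exports round-trip and empty networks stay valid", {
  db <- coex_db(list(h1 = list(partner = c("h2", "h3")),
                     h2 = list(partner = c("h1", "h3")),
                     h3 = list(partner = c("h1", "h2"))), K = 2)
  s <- data.frame(gene = c("h1", "h2", "h3"), mean = c(2, -0.5, 0.1))
  net <- build_network(c("h1", "h2", "h3"), db, s)
  cl <- assign_clusters(net, min_size = 3)
  prefix <- file.path(tempdir(), "nettest")
  paths <- export_network(net, cl, prefix, params = list(seed = 1))
  expect_true(all(file.exists(paths)))
  expect_equal(length(readLines(paths[1])), 3L)  # triangle: 3 SIF lines
  nodes <- read.delim(paths[3])
  expect_equal(nrow(nodes), 3L)
  back <- read_network_edges(prefix)
  expect_equal(back$a, net$edges$a)
  expect_equal(back$weight, net$edges$weight)

  empty <- build_network("h9", coex_db(list(h9 = list(partner = "x")), K = 1))
  p2 <- export_network(empty, NULL, file.path(tempdir(), "emptynet"))
  expect_true(all(file.exists(p2)))
  expect_equal(length(readLines(p2[1])), 0L)
})
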