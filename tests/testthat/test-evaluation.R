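test_that("pure-random nulls conserve size, are seed-deterministic and uniform", {
  template <- gene_network(cbind(c("a", "a", "b", "c"), c("b", "c", "d", "e")))
  r1 <- random_network(template, "pure_random", seed = 9)
  expect_length(r1$genes, 5L)
  expect_equal(nrow(r1$edges), 4L)
  expect_setequal(r1$genes, template$genes)
  r2 <- random_network(template, "pure_random", seed = 9)
  expect_true(network_equal(r1, r2))
  expect_false(network_equal(r1, random_network(template, "pure_random", seed = 10)))
  expect_error(random_network(gene_network(genes = "a"), "pure_random", 1),
               "at least 2 genes")
  # asking the sampler for more distinct pairs than exist is an error
  expect_error(sample_edge_set(c("a", "b", "c"), 4L), "only 3 pairs")

  # uniformity over the C(6,2) = 15 pair outcomes for a 1-edge draw
  tm <- gene_network(cbind("g1", "g2"), genes = paste0("g", 1:6))
  counts <- table(vapply(1:3000, function(s) {
    e <- random_network(tm, "pure_random", seed = s)$edges
    paste(e[1, 1], e[1, 2])
  }, character(1)))
  expect_length(counts, 15L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("scale-free nulls keep the gene set and approximate the edge count", {
  withr::with_seed(4, {
    tmpl <- random_net(25, 0.2)
  })
  sf <- random_network(tmpl, "scale_free", seed = 2)
  expect_setequal(sf$genes, tmpl$genes)
  expect_lt(abs(nrow(sf$edges) - nrow(tmpl$edges)) / nrow(tmpl$edges), 0.35)
  expect_true(network_equal(sf, random_network(tmpl, "scale_free", seed = 2)))
  # heavier tail than the template on average (degree heterogeneity)
  deg <- table(factor(as.vector(sf$edges), levels = sf$genes))
  expect_gt(max(deg), stats::quantile(deg, 0.5))
})

test_that("sample-size formula matches the standard proportion formula", {
  expect_equal(sample_size(0.95, 0.05, 0.5), 385L)
  # z from a printed normal table (2.576) gives ceil(2.576^2 * 0.25 / 0.0025) = 664
  expect_equal(sample_size(0.99, 0.05, 0.5), 664L)
  expect_equal(sample_size(0.95, 0.03, 0.5), 1068L)
  expect_error(sample_size(0.95, 0.05, 0), "proportion")
  expect_error(sample_size(0.95, 0, 0.5), "margin")
  expect_error(sample_size(1, 0.05, 0.5), "confidence")
})

test_that("the default threshold grid has 101 values from 0 to 1", {
  g <- default_thresholds()
  expect_length(g, 101L)
  expect_equal(g[1], 0)
  expect_equal(g[101], 1)
  expect_equal(diff(g), rep(0.01, 100))
})

test_that("ROC endpoints: perfect separation gives AUC 1, identical classes 0.5", {
  # all real validities strictly above all null validities, both positive
  res <- roc_from_scores(c(0.9, 0.95, 1.0), c(0.1, 0.2, 0.15))
  expect_equal(res$auc, 1.0)
  expect_equal(nrow(res$points), 101L)
  # at T = 0 every evaluation is predicted positive
  expect_equal(res$points$tpr[1], 1)
  expect_equal(res$points$fpr[1], 1)
  # identical real and null score sets sit on the diagonal
  s <- c(0.3, 0.6, 0.8)
  res2 <- roc_from_scores(s, s)
  expect_equal(res2$points$tpr, res2$points$fpr)
  expect_equal(res2$auc, 0.5)
})

test_that("confusion counts follow the strict threshold rule (hand check)", {
  pos <- c(0.8, 0.5)   # one real network scored on two pathways
  neg <- c(0.5, 0.2)   # one null network on the same two pathways
  res <- roc_from_scores(pos, neg, thresholds = c(0, 0.4, 0.6, 1))
  # T=0:   pos>0: both; neg>0: both        -> tp=2 fp=2 tn=0 fn=0
  # T=0.4: pos: both; neg: only 0.5        -> tp=2 fp=1 tn=1 fn=0
  # T=0.6: pos: only 0.8; neg: none        -> tp=1 fp=0 tn=2 fn=1
  # T=1:   none (strict inequality)        -> tp=0 fp=0 tn=2 fn=2
  expect_equal(res$points$tp, c(2L, 2L, 1L, 0L))
  expect_equal(res$points$fp, c(2L, 1L, 0L, 0L))
  expect_equal(res$points$tn, c(0L, 1L, 2L, 2L))
  expect_equal(res$points$fn, c(0L, 0L, 1L, 2L))
  expect_equal(res$points$tp + res$points$fp + res$points$tn + res$points$fn,
               rep(4L, 4))
  # a score equal to the threshold is classified negative
  expect_equal(roc_from_scores(c(0.4), c(0.1), c(0.4))$points$tp, 0L)
})

test_that("trapezoid AUC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    for (i in 1:20) {
      pos <- runif(30)
      neg <- runif(40)
      # cut exactly at the observed scores so the staircase is complete
      cuts <- sort(unique(c(0, pos, neg)))
      mine <- roc_from_scores(pos, neg, thresholds = cuts)$auc
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = c(rep(1, 30), rep(0, 40)),
        predictor = c(pos, neg), quiet = TRUE, direction = "<"
      )))
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  })
})

test_that("roc_study wires validity scoring into the sweep", {
  gp <- worked_example_gold()
  real <- gp # identical to the pathway: V = 1
  # null that still hits something weak: level-2 pairs only
  null <- gene_network(cbind(c("3", "2"), c("7", "5")), genes = gp$genes)
  res <- roc_study(real, list(gp), list(null), n = 2)
  expect_equal(attr(res, "pos_scores"), 1)
  expect_true(attr(res, "neg_scores") > 0 && attr(res, "neg_scores") < 1)
  expect_equal(res$auc, 1.0)
  expect_error(roc_study(real, list(), list(null)), "non-empty")
})

test_that("noise study: no-op perturbation, determinism, and degradation", {
  gp <- worked_example_gold()
  # 3-edge network: 10% of 3 edges rounds to 0 -> iteration 1 is a no-op
  prof <- noise_study(gp, gp, n = 1, iterations = 2, replicates = 5, seed = 1)
  expect_equal(prof$mean_validity[1], 1)
  expect_equal(prof$noise_fraction, c(0.1, 0.2))
  prof2 <- noise_study(gp, gp, n = 1, iterations = 2, replicates = 5, seed = 1)
  expect_equal(prof, prof2)

  # self-comparison on a 5-node graph: at full replacement the mean validity
  # approaches the enumeration-based expected match rate of a uniformly
  # random edge set of the same size
  withr::with_seed(8, {
    g5 <- random_net(5, 0.5)
  })
  ne <- nrow(g5$edges)
  # expected V_1 of a uniform distinct-pair sample: hypergeometric mean,
  # (edges in gold / all pairs)
  exp_v1 <- ne / choose(5, 2)
  prof3 <- noise_study(g5, g5, n = 1, iterations = 10, replicates = 400, seed = 3)
  expect_equal(prof3$mean_validity[10], exp_v1, tolerance = 0.05)
  # mean validity degrades (non-increasing trend up to Monte-Carlo error)
  fit <- stats::lm(mean_validity ~ noise_fraction, data = prof3)
  expect_lt(stats::coef(fit)[2], 0)
})

test_that("the global network is the union of its pathways", {
  a <- gene_network(cbind(c("x", "y"), c("y", "z")), label = "a")
  b <- gene_network(cbind(c("p", "q"), c("q", "r")), label = "b")
  expect_true(network_equal(build_kgn(list(a)), a))
  # edge-disjoint pathways: edge counts add
  expect_equal(nrow(build_kgn(list(a, b))$edges), 4L)
  # shared edges counted once, idempotent, order-independent
  c2 <- gene_network(cbind(c("x", "x"), c("y", "w")), label = "c")
  u <- build_kgn(list(a, c2))
  expect_equal(nrow(u$edges), 3L)
  expect_true(network_equal(u, build_kgn(list(c2, a))))
  expect_true(network_equal(u, build_kgn(list(a, c2, a, c2))))
})

test_that("functional assignment ranks the best-fitting pathway first", {
  gi <- gene_network(cbind(c("a", "b"), c("b", "c")), label = "in")
  exact <- gene_network(cbind(c("a", "b"), c("b", "c")), label = "exact")
  disjoint <- gene_network(cbind("x", "y"), label = "far")
  tab <- functional_assignment(gi, list(exact = exact, far = disjoint), n = 2)
  expect_equal(tab$label[1], "exact")
  expect_equal(tab$validity[1], 1)
  expect_true(is.na(tab$validity[2])) # nothing left after pruning sorts last

  # a pathway holding the edges at level 1 beats one holding them at level 2
  lvl1 <- gene_network(cbind(c("a", "b"), c("b", "c")), label = "lvl1")
  lvl2 <- gene_network(cbind(c("a", "m", "b", "k"), c("m", "b", "k", "c")),
                       label = "lvl2")
  tab2 <- functional_assignment(gi, list(lvl2 = lvl2, lvl1 = lvl1), n = 2)
  expect_equal(tab2$label, c("lvl1", "lvl2"))
  expect_equal(tab2$validity, c(1, 0.5))

  # overlapping related pathways both surface with high validity
  related <- gene_network(cbind(c("a", "b", "c"), c("b", "c", "d")), label = "rel")
  tab3 <- functional_assignment(gi, list(exact = exact, rel = related), n = 2)
  expect_true(all(tab3$validity >= 0.9))
})
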