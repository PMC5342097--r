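toy_network <- function() {
  data.frame(mirna_id = c("A", "A", "B"),
             gene_id = c("g1", "g2", "g1"),
             support = c("functional_strong", "other", "functional_strong"),
             stringsAsFactors = FALSE)
}

test_that("network filtering restricts support and measured features", {
  net <- toy_network()
  strong <- filter_network(net, "functional_strong")
  expect_true(all(strong$support == "functional_strong"))
  all_edges <- filter_network(net, "all")
  expect_true(nrow(all_edges) >= nrow(strong))
  expect_true(all(paste(strong$mirna_id, strong$gene_id) %in%
                    paste(all_edges$mirna_id, all_edges$gene_id)))

  kept <- filter_network(net, "all", measured_genes = c("g1"))
  expect_equal(unique(kept$gene_id), "g1")
  expect_error(filter_network(net, "all", measured_mirnas = "nope"),
               "no interactions")
})

test_that("edge weights are expression shares over each miRNA's targets", {
  net <- toy_network()
  w <- compute_edge_weights(net, c(g1 = 30, g2 = 10))
  e <- w$edges
  expect_equal(e$weight[e$mirna_id == "A" & e$gene_id == "g1"], 0.75)
  expect_equal(e$weight[e$mirna_id == "A" & e$gene_id == "g2"], 0.25)
  expect_equal(e$weight[e$mirna_id == "B"], 1) # single target

  expect_warning(u <- compute_edge_weights(net, c(g1 = 0, g2 = 0)),
                 "uniform")
  expect_equal(sort(u$edges$weight[u$edges$mirna_id == "A"]), c(0.5, 0.5))

  expect_error(compute_edge_weights(net, c(g1 = 5)), "g2")
  expect_error(compute_edge_weights(net, c(g1 = -1, g2 = 2)),
               "nonnegative")
})

test_that("weights sum to one per miRNA on random networks", {
  set.seed(409)
  for (i in 1:50) {
    net <- generate_interaction_network(sample(3:10, 1), sample(10:30, 1),
                                        sample(2:5, 1))
    means <- setNames(rexp(length(unique(net$gene_id))) + 0.1,
                      unique(net$gene_id))
    w <- compute_edge_weights(net, means)
    sums <- tapply(w$edges$weight, w$edges$mirna_id, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
    expect_true(all(w$edges$weight >= 0 & w$edges$weight <= 1))
  }
})

test_that("joint influence scores reproduce the worked toy example", {
  net <- toy_network()
  w <- compute_edge_weights(net, c(g1 = 30, g2 = 10))
  sc <- joint_influence_scores(w, c(A = 4, B = 1), c(A = 2, B = 5))
  g1 <- sc[sc$gene_id == "g1", ]
  g2 <- sc[sc$gene_id == "g2", ]
  expect_equal(g1$s_control, 4)    # 0.75*4 + 1*1
  expect_equal(g1$s_cancer, 6.5)   # 0.75*2 + 1*5
  expect_equal(g1$delta, 2.5)
  expect_equal(g2$s_control, 1)
  expect_equal(g2$s_cancer, 0.5)
  expect_equal(g2$delta, -0.5)
  expect_equal(g1$degree, 2)

  # a gene with no targeting miRNA scores zero
  sc2 <- joint_influence_scores(w, c(A = 4, B = 1), c(A = 2, B = 5),
                                genes = c("g1", "g2", "orphan"))
  orphan <- sc2[sc2$gene_id == "orphan", ]
  expect_equal(orphan$s_control, 0)
  expect_equal(orphan$s_cancer, 0)
  expect_equal(orphan$delta, 0)
  expect_equal(orphan$degree, 0)

  expect_error(joint_influence_scores(w, c(A = 4), c(A = 2)), "B")

  pred <- predict_directions(sc2)
  expect_equal(pred$predicted_direction[pred$gene_id == "g1"], "down")
  expect_equal(pred$predicted_direction[pred$gene_id == "g2"], "up")
  expect_equal(pred$predicted_direction[pred$gene_id == "orphan"],
               "no_call")
})

test_that("the model is invariant to expression rescaling", {
  set.seed(410)
  net <- generate_interaction_network(6, 20, 3)
  genes <- unique(net$gene_id)
  mirnas <- unique(net$mirna_id)
  gmeans <- setNames(rexp(length(genes)) + 0.1, genes)
  mc <- setNames(rexp(length(mirnas)) + 0.1, mirnas)
  mt <- setNames(rexp(length(mirnas)) + 0.1, mirnas)

  w1 <- compute_edge_weights(net, gmeans)
  w2 <- compute_edge_weights(net, 7.3 * gmeans)
  expect_equal(w1$edges$weight, w2$edges$weight, tolerance = 1e-12)

  s1 <- predict_directions(joint_influence_scores(w1, mc, mt))
  s2 <- predict_directions(joint_influence_scores(w1, 3.1 * mc, 3.1 * mt))
  expect_equal(s2$delta, 3.1 * s1$delta, tolerance = 1e-12)
  expect_equal(s2$predicted_direction, s1$predicted_direction)

  # single-target-gene identity: prediction opposes the miRNA's own change
  deg1 <- s1$gene_id[s1$degree == 1]
  for (g in deg1) {
    m <- net$mirna_id[net$gene_id == g]
    expected <- if (mt[[m]] > mc[[m]]) "down" else "up"
    expect_equal(s1$predicted_direction[s1$gene_id == g], expected)
  }
})

test_that("vectorized scores equal a per-edge loop on a random network", {
  set.seed(411)
  net <- generate_interaction_network(200, 500, 4)
  genes <- sort(unique(net$gene_id))
  mirnas <- sort(unique(net$mirna_id))
  gmeans <- setNames(rexp(length(genes)) * 10, genes)
  mc <- setNames(rexp(length(mirnas)) * 5, mirnas)
  mt <- setNames(rexp(length(mirnas)) * 5, mirnas)
  w <- compute_edge_weights(net, gmeans)
  sc <- joint_influence_scores(w, mc, mt)

  # loop oracle straight from the two defining formulas
  s_n <- setNames(rep(0, length(genes)), genes)
  s_c <- s_n
  for (m in mirnas) {
    targets <- net$gene_id[net$mirna_id == m]
    denom <- sum(gmeans[targets])
    for (g in targets) {
      w_mg <- gmeans[[g]] / denom
      s_n[g] <- s_n[g] + w_mg * mc[[m]]
      s_c[g] <- s_c[g] + w_mg * mt[[m]]
    }
  }
  expect_equal(sc$s_control, unname(s_n[sc$gene_id]), tolerance = 1e-10)
  expect_equal(sc$s_cancer, unname(s_c[sc$gene_id]), tolerance = 1e-10)
})

test_that("degree-stratified accuracy counts correct direction calls", {
  preds <- data.frame(gene_id = paste0("g", 1:6),
                      degree = c(1, 1, 2, 2, 3, 9),
                      delta = c(1, -1, 1, 1, -1, 2))
  preds <- predict_directions(preds)
  res <- fake_results(paste0("g", 1:6),
                      c("down", "up", "up", "down", "up", "down"),
                      c(rep(0.001, 5), 0.9))
  acc <- evaluate_by_degree(preds, res, min_degrees = c(1, 2, 3, 5))
  # g6 not significant; g3 mispredicted; others correct
  expect_equal(acc$n_evaluated, c(5, 3, 1, 0))
  expect_equal(acc$n_correct, c(4, 2, 1, 0))
  expect_equal(acc$accuracy_pct[1], 80)
  expect_true(is.na(acc$accuracy_pct[4]))
  expect_equal(acc$p_value[1], accuracy_pvalue(4, 5))

  all_right <- evaluate_by_degree(preds[preds$gene_id != "g3", ], res,
                                  min_degrees = 1)
  expect_equal(all_right$accuracy_pct, 100)
})

test_that("accuracy p-values are exact binomial tails", {
  expect_equal(accuracy_pvalue(12, 13), 14 / 8192, tolerance = 1e-12)
  expect_equal(accuracy_pvalue(5, 10), 0.6230469, tolerance = 1e-6)
  expect_true(is.na(accuracy_pvalue(0, 0)))
})

test_that("influence networks export with weights and fold changes", {
  net <- toy_network()
  w <- compute_edge_weights(net, c(g1 = 30, g2 = 10))
  res <- fake_results(c("g1", "g2"), c("up", "down"), c(0.01, 0.01))
  res$log2_fold_change <- c(1.5, -2)
  g <- influence_graph(w, gene_results = res)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(unique(igraph::V(g)$type)), c(FALSE, TRUE))
  lfc <- igraph::V(g)$log2_fold_change
  expect_equal(lfc[igraph::V(g)$name == "g1"], 1.5)
})
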