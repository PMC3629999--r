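test_that("MBSI matches hand-computed weighted averages", {
  # n = 3 miRNAs, 1 phenotype; S(m1,m2) = 0.8, S(m1,m3) = 0.2, a = (0,1,0)
  s <- make_msim(matrix(c(1, 0.8, 0.2,
                          0.8, 1, 0.5,
                          0.2, 0.5, 1), 3, 3, byrow = TRUE))
  net <- make_net(matrix(c(0, 1, 0), ncol = 1))
  sc <- mbsi_scores(s, net)$scores
  expect_equal(unname(sc[1, 1]), 0.8 / (0.8 + 0.2))
  expect_equal(unname(sc[2, 1]), 0 / (0.8 + 0.5))
  expect_equal(unname(sc[3, 1]), 0.5 / (0.2 + 0.5))
})

test_that("MBSI with uniform similarities reduces to neighbour fractions", {
  adj <- matrix(c(1, 0, 1, 1, 0, 0, 1, 0), 4, 2)
  net <- make_net(adj)
  s <- make_msim(matrix(0.4, 4, 4))
  sc <- mbsi_scores(s, net)$scores
  for (i in 1:4) for (j in 1:2) {
    expect_equal(unname(sc[i, j]), sum(adj[-i, j]) / 3)
  }
})

test_that("MBSI handles zero similarity support and rescaling", {
  s_vals <- matrix(c(1, 0, 0,
                     0, 1, 0.5,
                     0, 0.5, 1), 3, 3, byrow = TRUE)
  net <- make_net(matrix(c(1, 1, 0, 1, 0, 1), 3, 2))
  sc <- mbsi_scores(make_msim(s_vals), net)$scores
  expect_equal(unname(sc[1, ]), c(0, 0))  # miRNA 1 has no similar neighbours
  # positive rescaling leaves scores untouched
  sc2 <- mbsi_scores(make_msim(7.3 * s_vals), net)$scores
  expect_equal(sc2, sc, tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("MBSI on a constant-column network returns that constant", {
  net <- make_net(matrix(c(1, 1, 1, 0, 0, 0), 3, 2))
  d <- small_signal_data()
  s <- make_msim(d$sm$values[1:3, 1:3])
  sc <- mbsi_scores(s, net)$scores
  expect_equal(unname(sc[, 1]), rep(1, 3))
  expect_equal(unname(sc[, 2]), rep(0, 3))
})

test_that("PBSI matches hand-computed values", {
  # m = 3 phenotypes, 1 miRNA; S(p1,p2) = S(p1,p3) = 0.5; a = (0,1,1)
  sp <- make_psim(matrix(c(1, 0.5, 0.5,
                           0.5, 1, 0.3,
                           0.5, 0.3, 1), 3, 3, byrow = TRUE))
  net <- make_net(matrix(c(0, 1, 1), nrow = 1))
  sc <- pbsi_scores(sp, net)$scores
  expect_equal(unname(sc[1, 1]), (0.5 * 1 + 0.5 * 1) / (0.5 + 0.5))  # = 1
  expect_equal(unname(sc[1, 2]), (0.5 * 0 + 0.3 * 1) / (0.5 + 0.3))
})

test_that("PBSI: a miRNA with no associations scores zero everywhere", {
  d <- small_signal_data()
  net <- d$net
  net$adjacency[3, ] <- 0
  net <- assoc_network(net$adjacency, net$mirna_ids, net$phenotype_ids)
  sc <- pbsi_scores(d$sp, net)$scores
  expect_equal(unname(sc[3, ]), rep(0, ncol(sc)))
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("PBSI with uniform similarities reduces to fractions over other phenotypes", {
  adj <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3)
  net <- make_net(adj)
  sp <- make_psim(matrix(0.2, 3, 3))
  sc <- pbsi_scores(sp, net)$scores
  for (i in 1:2) for (j in 1:3) {
    expect_equal(unname(sc[i, j]), sum(adj[i, -j]) / 2)
  }
})

test_that("relevance propagation matches the Neumann-series oracle", {
  withr::local_seed(42)
  for (alpha in c(0.1, 0.5, 0.9)) {
    for (rep in 1:3) {
      s <- make_sim(random_column_stochastic(10), normalized = TRUE)
      q <- query_indicator("mirna", s$ids, sample.int(10, 1))
      x <- laplacian_relevance(s, q, alpha)
      expect_equal(unname(x), neumann_oracle(s$values, q$vector, alpha, 2000),
                   tolerance = 1e-8)
      # mass conservation under a column-stochastic operator
      expect_equal(sum(x), sum(q$vector), tolerance = 1e-8)
    }
  }
})

test_that("relevance propagation limits: identity operator and alpha near zero", {
  q <- c(0, 1, 0, 0)
  id <- make_sim(diag(4), normalized = TRUE)
  for (alpha in c(0.1, 0.5, 0.9)) {
    expect_equal(unname(laplacian_relevance(id, q, alpha)), q, tolerance = 1e-12)
  }
  withr::local_seed(7)
  s <- make_sim(random_column_stochastic(6), normalized = TRUE)
  x <- laplacian_relevance(s, c(1, 0, 0, 0, 0, 0), 1e-9)
  expect_equal(unname(x), c(1, 0, 0, 0, 0, 0), tolerance = 1e-6)
})

test_that("relevance propagation validates its inputs", {
  s <- make_sim(diag(3), normalized = TRUE)
  expect_error(laplacian_relevance(s, c(1, 0, 0), 0), class = "netcbi_parameter_error")
  expect_error(laplacian_relevance(s, c(1, 0, 0), 1), class = "netcbi_parameter_error")
  expect_error(laplacian_relevance(s, c(1, 0), 0.5), class = "netcbi_validation_error")
  un <- make_sim(diag(3))
  expect_error(laplacian_relevance(un, c(1, 0, 0), 0.5),
               class = "netcbi_validation_error")
  # multi-entity queries are accepted
  x <- laplacian_relevance(s, c(1, 0, 1), 0.5)
  expect_equal(unname(x), c(1, 0, 1))
})

test_that("NetCBI matches a full brute-force oracle on a 3 x 2 instance", {
  sm <- normalize_columns(make_msim(matrix(c(1, 0.6, 0.1,
                                             0.6, 1, 0.3,
                                             0.1, 0.3, 1), 3, 3, byrow = TRUE)))
  sp <- normalize_columns(make_psim(matrix(c(1, 0.4,
                                             0.4, 1), 2, 2, byrow = TRUE)))
  net <- make_net(matrix(c(1, 0, 0, 1, 1, 0), 3, 2))
  alpha <- beta <- 0.5
  sc <- netcbi_scores(sm, sp, net, query_indicator("mirna", net$mirna_ids, 1),
                      alpha, beta)
  mtil <- neumann_oracle(sm$values, c(1, 0, 0), alpha, 3000)
  for (j in 1:2) {
    p <- c(0, 0); p[j] <- 1
    ptil <- neumann_oracle(sp$values, p, beta, 3000)
    expected <- pearson_oracle(as.numeric(net$adjacency %*% ptil), mtil)
    expect_equal(unname(sc[j]), expected, tolerance = 1e-10)
  }
})

test_that("NetCBI degenerate and boundary behaviour", {
  d <- small_signal_data()
  smn <- normalize_columns(d$sm); spn <- normalize_columns(d$sp)
  # empty network: zero-variance projected vector, all scores 0, warning
  empty <- assoc_network(matrix(0, 20, 10), d$net$mirna_ids, d$net$phenotype_ids)
  expect_warning(sc <- netcbi_scores(smn, spn, empty,
                                     query_indicator("mirna", d$net$mirna_ids, 1),
                                     0.1, 0.1),
                 "no edges")
  expect_equal(unname(sc), rep(0, 10))
  # scores bounded in [-1, 1] on real inputs
  sc2 <- netcbi_score_table(smn, spn, d$net, 0.3, 0.7)$scores
  expect_true(all(sc2 >= -1 & sc2 <= 1))
  # a perfectly proportional projection scores exactly 1
  one_m <- make_sim(diag(2), ids = c("m1", "m2"), normalized = TRUE)
  one_p <- make_sim(diag(2), ids = c("p1", "p2"), normalized = TRUE)
  net1 <- assoc_network(diag(2), c("m1", "m2"), c("p1", "p2"))
  s1 <- netcbi_scores(one_m, one_p, net1,
                      query_indicator("mirna", c("m1", "m2"), "m1"), 0.5, 0.5)
  expect_equal(unname(s1["p1"]), 1)
})

test_that("identical adjacency columns give identical NetCBI scores for every phenotype", {
  # with a[, l] the same for all l, a %*% p~_j = a[, 1] * sum(p~_j) = a[, 1]
  # by mass conservation, so every phenotype receives the same correlation
  d <- small_signal_data()
  smn <- normalize_columns(d$sm)
  spn <- normalize_columns(d$sp)
  col <- d$net$adjacency[, 1]
  if (sum(col) == 0) col[1:3] <- 1
  net <- assoc_network(matrix(col, nrow = 20, ncol = 10),
                       d$net$mirna_ids, d$net$phenotype_ids)
  sc <- netcbi_scores(smn, spn, net,
                      query_indicator("mirna", d$net$mirna_ids, 4), 0.2, 0.2)
  expect_equal(max(sc) - min(sc), 0, tolerance = 1e-10)
})

test_that("the vectorized LOOCV score matrix equals literal per-query removal", {
  d <- small_signal_data()
  smn <- normalize_columns(d$sm); spn <- normalize_columns(d$sp)
  for (params in list(c(0.1, 0.1), c(0.6, 0.3))) {
    mt <- netcbi:::relevance_basis(smn, params[1])
    pt <- netcbi:::relevance_basis(spn, params[2])
    fast <- netcbi:::netcbi_loocv_matrix(mt, pt, d$net$adjacency)
    for (i in c(1, 7, 20)) {
      reduced <- assoc_network(`[<-`(d$net$adjacency, i, , 0),
                               d$net$mirna_ids, d$net$phenotype_ids)
      slow <- netcbi_scores(smn, spn, reduced,
                            query_indicator("mirna", d$net$mirna_ids, i),
                            params[1], params[2])
      expect_equal(unname(fast[i, ]), unname(slow), tolerance = 1e-10)
    }
  }
})

test_that("prediction ranking excludes known pairs and breaks ties lexicographically", {
  net <- make_net(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  tab <- netcbi:::score_table(matrix(c(0.9, 0.5, 0.7, 0.2), 2, 2, byrow = TRUE),
                              net$mirna_ids, net$phenotype_ids, "MBSI")
  out <- rank_predictions(tab, net, 10)
  expect_equal(out$score, c(0.7, 0.5, 0.2))
  expect_false(any(out$mirna_id == "miR-1" & out$phenotype_id == "OMIM-1"))
  expect_equal(out$rank, 1:3)

  # ties: ordered by miRNA then phenotype ID
  tie <- netcbi:::score_table(matrix(0.4, 2, 2),
                              net$mirna_ids, net$phenotype_ids, "MBSI")
  out2 <- rank_predictions(tie, net, 3)
  expect_equal(out2$mirna_id, c("miR-1", "miR-2", "miR-2"))
  expect_equal(out2$phenotype_id, c("OMIM-2", "OMIM-1", "OMIM-2"))

  expect_equal(nrow(rank_predictions(tab, net, 0)), 0)
  expect_message(all_out <- rank_predictions(tab, net, 99), "returning all")
  expect_equal(nrow(all_out), 3)
})
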