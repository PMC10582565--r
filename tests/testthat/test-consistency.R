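signed_triangle <- function(s_ab, s_bc, s_ac = NULL) {
  edges <- rbind(
    data.frame(region_a = "A", region_b = "B", sign = s_ab),
    data.frame(region_a = "B", region_b = "C", sign = s_bc))
  if (!is.null(s_ac)) {
    edges <- rbind(edges,
                   data.frame(region_a = "A", region_b = "C", sign = s_ac))
  }
  signed_core_network(edges, triangle_tracts())
}

test_that("sign propagation multiplies edge signs along a path", {
  net <- signed_triangle(1L, -1L)
  expect_identical(propagate_sign(c("A", "B", "C"), net), -1L)
  expect_identical(propagate_sign(c("A", "B", "C"),
                                  signed_triangle(1L, 1L)), 1L)
  expect_identical(propagate_sign(c("A", "B", "C"),
                                  signed_triangle(-1L, -1L)), 1L)
  expect_error(propagate_sign(c("A", "C"), net), ">= 2 edges")
  expect_error(propagate_sign(c("A", "C", "B"), net), "not an edge")

  # associativity: the product over a concatenated path equals the
  # product of segment propagations
  tracts <- tract_map(lapply(1:4, function(i) c(LETTERS[i], LETTERS[i + 1])))
  for (code in 0:15) {
    signs <- ifelse(bitwAnd(code, bitwShiftL(1L, 0:3)) > 0, 1L, -1L)
    net5 <- signed_core_network(
      data.frame(region_a = LETTERS[1:4], region_b = LETTERS[2:5],
                 sign = signs), tracts)
    whole <- propagate_sign(LETTERS[1:5], net5)
    expect_identical(whole,
                     propagate_sign(LETTERS[1:3], net5) *
                       propagate_sign(LETTERS[3:5], net5))
  }
})

test_that("implied signs use direct edges, then shortest tract paths", {
  net <- signed_triangle(1L, -1L, s_ac = 1L)
  expect_identical(implied_sign(c("A", "C"), net), 1L)

  chain <- signed_triangle(1L, -1L)  # A-B +, B-C -, no direct A-C edge
  expect_identical(implied_sign(c("A", "C"), chain), -1L)

  # two shortest paths implying different signs -> indeterminate
  sq_tracts <- tract_map(list(c("A", "B"), c("B", "C"), c("A", "D"),
                              c("C", "D")))
  frustrated <- signed_core_network(
    data.frame(region_a = c("A", "B", "A", "C"),
               region_b = c("B", "C", "D", "D"),
               sign = c(1L, 1L, 1L, -1L)), sq_tracts)
  expect_true(is.na(implied_sign(c("A", "C"), frustrated)))

  # disconnected pair -> indeterminate
  sparse <- signed_core_network(
    data.frame(region_a = "A", region_b = "B", sign = 1L), sq_tracts)
  expect_true(is.na(implied_sign(c("A", "C"), sparse)))

  expect_error(implied_sign(c("A", "Z"), net), "not in network")
})

test_that("implied signs agree with exhaustive path enumeration", {
  for (s in 1:30) {
    withr::with_seed(600 + s, {
      n <- sample(4:5, 1)
      A <- matrix(0L, n, n)
      pairs <- t(utils::combn(n, 2))
      on <- runif(nrow(pairs)) < 0.6
      A[pairs[on, , drop = FALSE]] <- 1L
      A <- A + t(A)
      R <- diag(1, n) + A
      Rk <- R
      for (k in seq_len(n - 2)) Rk <- Rk %*% R
      if (any(Rk == 0)) next  # disconnected draw; skip

      signs <- matrix(NA_integer_, n, n)
      sgn <- sample(c(-1L, 1L), sum(on), replace = TRUE)
      signs[pairs[on, , drop = FALSE]] <- sgn
      signs[pairs[on, c(2, 1), drop = FALSE]] <- sgn
      nodes <- LETTERS[1:n]
      epairs <- pairs[on, , drop = FALSE]
      tracts <- tract_map(data.frame(region_a = nodes[epairs[, 1]],
                                     region_b = nodes[epairs[, 2]]))
      net <- signed_core_network(
        data.frame(region_a = nodes[epairs[, 1]],
                   region_b = nodes[epairs[, 2]], sign = sgn), tracts)
      for (i in seq_len(nrow(pairs))) {
        a <- pairs[i, 1]; b <- pairs[i, 2]
        expect_identical(implied_sign(c(nodes[a], nodes[b]), net),
                         oracle_implied_sign(A, signs, a, b))
      }
    })
  }
})

test_that("structurally balanced networks imply a sign for every pair", {
  # signs from node spins: every cycle has positive product, so all
  # shortest paths between a connected pair agree
  for (s in 1:25) {
    withr::with_seed(700 + s, {
      n <- 5
      g <- igraph::sample_gnp(n, 0.6)
      if (!igraph::is_connected(g)) g <- igraph::make_ring(n)
      spins <- sample(c(-1L, 1L), n, replace = TRUE)
      el <- igraph::as_edgelist(g)
      nodes <- LETTERS[1:n]
      df <- data.frame(region_a = nodes[el[, 1]], region_b = nodes[el[, 2]],
                       sign = spins[el[, 1]] * spins[el[, 2]])
      net <- signed_core_network(df, tract_map(df[, 1:2]))
      for (p in utils::combn(nodes, 2, simplify = FALSE)) {
        s_impl <- implied_sign(p, net)
        expect_false(is.na(s_impl))
        expect_identical(s_impl,
                         spins[match(p[1], nodes)] * spins[match(p[2], nodes)])
      }
    })
  }
})

test_that("consistency reports score observed changes", {
  obs_all <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "B", "C", direction = -1),
    rec_row("s3", "A", "C", direction = -1)
  ))
  chain <- signed_triangle(1L, -1L)
  rep <- consistency_report(chain, obs_all)
  expect_identical(rep$fraction, 1)

  # frustrated triangle: implied A-C is +, observed is -
  obs_bad <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "B", "C", direction = 1),
    rec_row("s3", "A", "C", direction = -1)
  ))
  two_pos <- signed_triangle(1L, 1L)
  rep2 <- consistency_report(two_pos, obs_bad)
  expect_equal(rep2$fraction, 2 / 3)
  expect_identical(rep2$violated$implied, 1L)
  expect_identical(rep2$violated$observed, -1L)

  # pre-exclusion denominator: 13 satisfied of 15 evaluated plus 2
  # excluded conflicts gives 86.7% and 88.2%
  expect_equal(consistency_report(chain, obs_all, n_excluded = 0)$fraction, 1)
  fake <- list(fraction = 13 / 15,
               fraction_pre_exclusion = (13 + 2) / (15 + 2))
  expect_equal(round(100 * fake$fraction, 1), 86.7)
  expect_equal(round(100 * fake$fraction_pre_exclusion, 1), 88.2)
  rep3 <- consistency_report(two_pos, obs_bad, n_excluded = 1)
  expect_equal(rep3$fraction_pre_exclusion, 3 / 4)

  out <- record_set(rec_row("s1", "A", "Z", direction = 1))
  expect_error(consistency_report(chain, out), "outside core")
})

test_that("consistency fractions are invariant under region relabeling", {
  obs <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "B", "C", direction = 1),
    rec_row("s3", "A", "C", direction = -1)
  ))
  rep1 <- consistency_report(signed_triangle(1L, 1L), obs)

  relab <- c(A = "X", B = "Y", C = "Z")
  obs2 <- as.data.frame(obs)
  obs2$region_a <- unname(relab[obs2$region_a])
  obs2$region_b <- unname(relab[obs2$region_b])
  tracts2 <- tract_map(list(c("X", "Y"), c("Y", "Z"), c("X", "Z")))
  net2 <- signed_core_network(
    data.frame(region_a = c("X", "Y"), region_b = c("Y", "Z"),
               sign = c(1L, 1L)), tracts2)
  rep2 <- consistency_report(net2, record_set(obs2))
  expect_identical(rep1$fraction, rep2$fraction)
})

test_that("exhaustive search matches the brute-force oracle", {
  fixtures <- list(
    list(tracts = triangle_tracts(),
         obs = rec_df(rec_row("s1", "A", "B", direction = 1),
                      rec_row("s2", "B", "C", direction = 1),
                      rec_row("s3", "A", "C", direction = -1))),
    list(tracts = tract_map(list(c("A", "B"), c("B", "C"), c("C", "D"),
                                 c("A", "D"))),
         obs = rec_df(rec_row("s1", "A", "B", direction = 1),
                      rec_row("s2", "B", "C", direction = -1),
                      rec_row("s3", "C", "D", direction = 1),
                      rec_row("s4", "A", "D", direction = 1))),
    list(tracts = tract_map(list(c("A", "B"), c("B", "C"), c("C", "D"),
                                 c("D", "E"), c("A", "E"), c("B", "D"))),
         obs = rec_df(rec_row("s1", "A", "B", direction = 1),
                      rec_row("s2", "C", "D", direction = -1),
                      rec_row("s3", "A", "E", direction = -1),
                      rec_row("s4", "B", "D", direction = 1)))
  )
  for (fx in fixtures) {
    obs <- record_set(fx$obs)
    found <- search_max_consistent(fx$tracts, obs, mode = "exhaustive")
    expect_equal(found$report$fraction, oracle_best_fraction(fx$tracts, obs))
    # greedy never beats exhaustive
    greedy <- search_max_consistent(fx$tracts, obs, mode = "greedy",
                                    seed = 3, n_restarts = 10)
    expect_lte(greedy$report$fraction, found$report$fraction + 1e-12)
  }
})

test_that("fully consistent observations admit a perfect network", {
  obs <- record_set(rec_df(
    rec_row("s1", "A", "B", direction = 1),
    rec_row("s2", "B", "C", direction = -1),
    rec_row("s3", "A", "C", direction = -1)
  ))
  found <- search_max_consistent(triangle_tracts(), obs)
  expect_identical(found$report$fraction, 1)
  expect_error(
    search_max_consistent(triangle_tracts(),
                          record_set(rec_df(
                            rec_row("s1", "A", "B", direction = 1),
                            rec_row("s2", "A", "B", direction = -1)))),
    "conflicting")
})

test_that("mean core betweenness averages across modes", {
  p3 <- path_net(3)
  tri <- complete_net(3)
  igraph::V(p3)$name <- igraph::V(tri)$name <- c("a", "b", "c")
  p3 <- as_brain_network(p3)
  tri <- as_brain_network(tri)
  single <- mean_core_betweenness(list(p3))
  expect_equal(single, betweenness_centrality(p3)[names(single)])
  both <- mean_core_betweenness(list(p3, tri))
  expect_equal(unname(both["b"]), 0.5)
  expect_error(mean_core_betweenness(list(p3, complete_net(4))), "differ")
  expect_error(mean_core_betweenness(list()), "no modes")
})
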