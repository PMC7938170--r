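test_that("softmax allocations match direct evaluation and normalise", {
  # symmetric genes give thirds
  p <- softmax_allocations(0, 0)
  expect_equal(unlist(p), c(p_x = 1/3, p_y = 1/3, p_z = 1/3))

  # both genes very negative: everything goes to reproduction
  p <- softmax_allocations(-40, -40)
  expect_equal(p$p_z, 1, tolerance = 1e-12)
  expect_lt(p$p_x, 1e-15)

  # frozen expected values at (x = 1, y = -1), computed as
  # e^1 / (1 + e^1 + e^-1) etc. with exp(1) = 2.718281828459045
  p <- softmax_allocations(1, -1)
  expect_equal(p$p_x, 0.66524095577482, tolerance = 1e-12)
  expect_equal(p$p_y, 0.09003057317038, tolerance = 1e-12)
  expect_equal(p$p_x + p$p_y + p$p_z, 1, tolerance = 1e-12)
  expect_true(p$p_x > p$p_z && p$p_z > p$p_y)

  # property: sums to one and strictly positive on random finite genes
  set.seed(42)
  g <- matrix(rnorm(200, sd = 4), ncol = 2)
  pr <- softmax_allocations(g[, 1], g[, 2])
  expect_true(all(as.matrix(pr) > 0))
  expect_equal(rowSums(as.matrix(pr)), rep(1, nrow(pr)), tolerance = 1e-12)

  expect_error(softmax_allocations(Inf, 0), "finite")
  expect_error(softmax_allocations(NA_real_, 0), "finite")
})

test_that("resource shares are proportional and scale invariant", {
  expect_equal(unlist(resource_shares(1, 1)),
               c(share_1 = 0.5, share_2 = 0.5))
  expect_equal(resource_shares(3, 1)$share_1, 0.75)
  set.seed(7)
  s <- rexp(50) + 0.01
  k <- rexp(50) + 0.01
  base <- resource_shares(s, rev(s))
  scaled <- resource_shares(s * k, rev(s) * k)
  expect_equal(base$share_1, scaled$share_1, tolerance = 1e-12)
  expect_equal(base$share_1 + base$share_2, rep(1, 50), tolerance = 1e-12)
  expect_error(resource_shares(0, 1), "positive")
  expect_error(resource_shares(1, -2), "positive")
})

test_that("continuous mutation respects rates and the stated Gaussian", {
  g <- genotype(x = c(0.3, -0.2), y = c(1, 2), signal = c(2, 0.5),
                retention = c(0.4, 0.6))
  set.seed(1)
  expect_identical(mutate_continuous(g, quiet_params()), g)
  # mu = 1 with zero effect size changes nothing
  same <- mutate_continuous(g, tiny_params(mu = 1, sigma = 0, mu_d = 0))
  expect_equal(same, g, tolerance = 1e-15)

  # Monte-Carlo: with mu = 1 the increment of one gene is Gaussian(0, sigma)
  set.seed(99)
  p <- tiny_params(mu = 1, sigma = 0.5, mu_d = 0)
  n <- 3e4
  inc <- vapply(seq_len(n),
                function(i) mutate_continuous(g, p)$x[1] - g$x[1],
                numeric(1))
  expect_lt(abs(mean(inc)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(inc) - 0.5), 3 * 0.5 / sqrt(2 * n))

  # retention mutations stay inside [0, 1] and keep genotypes valid
  set.seed(5)
  p2 <- tiny_params(mu = 1, sigma = 3, mu_d = 1)
  out <- g
  for (i in 1:200) {
    out <- mutate_continuous(out, p2)
    expect_silent(bicellum:::validate_genotype(out))
  }
  expect_true(all(out$retention >= 0 & out$retention <= 1))
  expect_true(all(out$signal > 0))
})

test_that("viability mutation is biased, bounded and round-aware", {
  g <- genotype()
  all_del <- genotype(viability = rep(1L, 16))
  set.seed(3)
  expect_identical(mutate_viability(g, quiet_params()), g)
  # forced back-mutation empties an all-deleterious genotype
  p_force <- tiny_params(mu_v0 = 0, mu_v1 = 1)
  expect_identical(mutate_viability(all_del, p_force)$viability,
                   integer(16))

  # binomial expectation: 16 loci at mu_v0 = 0.001 per round
  set.seed(11)
  p <- tiny_params(mu_v0 = 0.001, mu_v1 = 1e-4)
  n <- 5e4
  hits <- vapply(seq_len(n),
                 function(i) sum(mutate_viability(g, p)$viability),
                 numeric(1))
  expected <- 16 * 0.001
  se <- sqrt(16 * 0.001 * 0.999 / n)
  expect_lt(abs(mean(hits) - expected), 3 * se)

  # two rounds double the expected load for an all-neutral start
  set.seed(12)
  hits2 <- vapply(seq_len(2e4),
                  function(i) sum(mutate_viability(g, p, rounds = 2)$viability),
                  numeric(1))
  expect_gt(mean(hits2), mean(hits))

  # with no back-mutation the expected load never decreases across rounds
  set.seed(13)
  p_fwd <- tiny_params(mu_v0 = 0.05, mu_v1 = 0)
  cur <- g
  loads <- numeric(6)
  for (i in 1:6) {
    cur <- mutate_viability(cur, p_fwd)
    loads[i] <- sum(cur$viability)
  }
  expect_true(all(diff(loads) >= 0))
})

test_that("genotype validation rejects malformed state", {
  expect_error(genotype(x = c(0, Inf)), "finite")
  expect_error(genotype(signal = c(1, 0)), "positive")
  expect_error(genotype(retention = c(-0.1, 0.5)), "retention")
  expect_error(genotype(viability = rep(2L, 16)), "viability")
  expect_error(genotype(viability = integer(15)), "viability")
})
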