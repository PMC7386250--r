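test_that("expected_contact follows the floored power law", {
  p <- hic_params(1, 1, 0.01)
  expect_equal(expected_contact(10, p), 0.1)
  expect_equal(expected_contact(1000, p), 0.01)   # floor
  expect_equal(expected_contact(123, p, is_intra = FALSE), 0.01)
  expect_error(expected_contact(-1, p), "distance")
  # non-increasing in s
  s <- sort(10^runif(50, 0, 7))
  expect_true(all(diff(expected_contact(s, hic_params(3, 0.8, 1e-4))) <= 0))
})

test_that("hic_params validates its domain", {
  expect_error(hic_params(0, 1, 1), "A")
  expect_error(hic_params(1, 0, 1), "alpha")
  expect_error(hic_params(1, 1, 0), "delta")
})

test_that("genomic_distance uses cumulative bp centers", {
  bins <- make_bins(1, 4, bp = 100)
  st <- identity_structure(bins)
  expect_equal(genomic_distance(st, 0, 1), 100)
  expect_equal(genomic_distance(st, 0, 3), 300)
  expect_equal(genomic_distance(st, 2, 2), 0)
  st2 <- genome_structure(list(1:2, 3:4), bins)
  expect_equal(genomic_distance(st2, 0, 2), Inf)
})

test_that("log-likelihood of a 2-bin scaffold matches hand arithmetic", {
  bins <- make_bins(1, 2, bp = 1000)
  st <- identity_structure(bins)
  map <- contact_map(0L, 1L, 2, bins)
  # lambda at the one intra pair: A * u^-alpha with u = 1000 -> 1
  p <- hic_params(A = 1000, alpha = 1, delta = 0.01)
  expect_equal(log_likelihood(st, map, p), 2 * log(1) - 1)
})

test_that("sparse likelihood equals the dense oracle on random instances", {
  p <- hic_params(5, 1.1, 0.05)
  for (s in 1:40) {
    inst <- rand_instance(sample(5:50, 1), s)
    expect_equal(log_likelihood(inst$st, inst$map, p),
                 dense_loglik(inst$st, inst$map, p), tolerance = 1e-11)
  }
})

test_that("incremental delta equals a full recomputation", {
  p <- hic_params(5, 1.1, 0.05)
  for (s in 1:60) {
    inst <- rand_instance(sample(5:40, 1), 1000 + s)
    mu <- random_mutation(inst$map$n_bins, 2000 + s)
    d1 <- delta_log_likelihood(inst$st, inst$map, p, mu)
    st2 <- apply_mutation(inst$st, mu)
    d2 <- log_likelihood(st2, inst$map, p) - log_likelihood(inst$st, inst$map, p)
    expect_equal(d1, d2, tolerance = 1e-6)
  }
})

test_that("delta at sub-bin resolution matches a full recomputation", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  emap <- pyramid_level(sim$pyr, 1)
  st <- structure_from_map(map)
  p <- estimate_parameters(expand_structure(st, map, emap), emap)
  full0 <- log_likelihood(st, map, p, emap)
  for (s in 1:40) {
    mu <- random_mutation(map$n_bins, 300 + s)
    d1 <- delta_log_likelihood(st, map, p, mu, eval_map = emap)
    st2 <- apply_mutation(st, mu)
    d2 <- log_likelihood(st2, map, p, emap) - full0
    expect_equal(d1, d2, tolerance = 1e-6)
  }
})

test_that("a flipped bin with a single sub-bin has zero delta", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  emap <- pyramid_level(sim$pyr, 1)
  st <- structure_from_map(map)
  p <- estimate_parameters(expand_structure(st, map, emap), emap)
  m_per_bin <- table(factor(emap$bins$parent, levels = 0:(map$n_bins - 1)))
  atomic <- as.integer(names(m_per_bin))[m_per_bin == 1]
  skip_if(length(atomic) == 0)
  expect_equal(delta_log_likelihood(st, map, p,
                                    mutation("flip", atomic[1]),
                                    eval_map = emap), 0)
})

test_that("estimate_parameters recovers alpha from a noise-free power law", {
  nb <- 200L
  bins <- make_bins(1, nb, bp = 1000)
  st <- identity_structure(bins)
  pr_i <- rep(1:(nb - 1), times = (nb - 1):1)
  pr_j <- sequence((nb - 1):1) + pr_i
  cnt <- round(50 * (pr_j - pr_i)^(-1))
  keep <- cnt > 0
  map <- contact_map(pr_i[keep] - 1L, pr_j[keep] - 1L, cnt[keep], bins)
  p <- estimate_parameters(st, map)
  expect_lt(abs(p$alpha - 1), 0.05)
})

test_that("estimate_parameters recovers alpha from Poisson counts", {
  nb <- 500L
  bins <- make_bins(1, nb, bp = 1000)
  st <- identity_structure(bins)
  set.seed(1)
  pr_i <- rep(1:(nb - 1), times = (nb - 1):1)
  pr_j <- sequence((nb - 1):1) + pr_i
  d <- pr_j - pr_i
  mu <- 2 * pmax(5 * d^(-1.1), 0.05)
  cnt <- rpois(length(mu), mu)
  keep <- cnt > 0
  map <- contact_map(pr_i[keep] - 1L, pr_j[keep] - 1L, cnt[keep], bins)
  p <- estimate_parameters(st, map)
  expect_lt(abs(p$alpha - 1.1) / 1.1, 0.1)
})

test_that("delta clamps to 1e-9 with zero inter-scaffold contacts", {
  bins <- make_bins(2, 15, bp = 1000)
  st <- genome_structure(list(1:15, 16:30), bins)
  pr_i <- rep(0:13, times = 14:1)
  pr_j <- sequence(14:1) + pr_i
  cnt <- round(40 / (pr_j - pr_i))
  keep <- cnt > 0
  map <- contact_map(c(pr_i[keep], pr_i[keep] + 15L),
                     c(pr_j[keep], pr_j[keep] + 15L),
                     rep(cnt[keep], 2), bins)
  p <- estimate_parameters(st, map)
  expect_equal(p$delta, 1e-9)
})

test_that("estimate_parameters errors on insufficient signal", {
  bins <- make_bins(1, 12, bp = 1000)
  st <- identity_structure(bins)
  map <- contact_map(0L, 1L, 1, bins)
  expect_error(estimate_parameters(st, map), "insufficient signal")
})

test_that("the truth structure outscores random permutations", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  tst <- truth_structure(map, sim$truth)
  p <- estimate_parameters(tst, map)
  ll_truth <- log_likelihood(tst, map, p)
  nb <- map$n_bins
  worse <- 0L
  for (s in 1:100) {
    set.seed(s)
    perm <- sample(nb) * sample(c(-1L, 1L), nb, TRUE)
    st <- genome_structure(list(perm), map$bins)
    if (log_likelihood(st, map, p) < ll_truth) worse <- worse + 1L
  }
  expect_gte(worse, 95L)
})
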