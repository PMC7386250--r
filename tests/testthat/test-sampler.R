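test_that("apply_mutation implements each permutation kind", {
  bins <- make_bins(1, 5)
  st <- identity_structure(bins)

  # flip is an involution
  st2 <- apply_mutation(apply_mutation(st, mutation("flip", 2)),
                        mutation("flip", 2))
  expect_equal(st2$scaffolds, st$scaffolds)

  # eject splits off a singleton
  st2 <- apply_mutation(st, mutation("eject", 2))
  expect_equal(sort(lengths(st2$scaffolds)), c(1L, 4L))

  # insert_before with flip: [a+, b+, c+] -> [c-, a+, b+]
  st3 <- genome_structure(list(1:3), make_bins(1, 3))
  st4 <- apply_mutation(st3, mutation("insert_before", 2, anchor = 0,
                                      flipped = TRUE))
  expect_equal(st4$scaffolds[[1]], c(-3L, 1L, 2L))

  # swap exchanges slots, keeping orientations
  st5 <- apply_mutation(st3, mutation("swap", 0, anchor = 2))
  expect_equal(st5$scaffolds[[1]], c(3L, 2L, 1L))

  expect_error(apply_mutation(st, mutation("flip", 99)), "invalid")
  expect_error(mutation("swap", 1, anchor = 1), "differ")
})

test_that("candidate_moves ranks anchors by contact and prunes no-ops", {
  bins <- make_bins(1, 5)
  st <- identity_structure(bins)
  # bin 0 contacts: B=1 strongest, C=2, D=3
  map <- contact_map(c(0L, 0L, 0L), c(1L, 2L, 3L), c(10, 5, 1), bins)
  cands <- candidate_moves(0, st, map, k = 2)
  anchors <- unique(stats::na.omit(vapply(cands, function(m) m$anchor, 1L)))
  expect_equal(sort(anchors), c(1L, 2L))

  # isolated bin: stay, flip, eject only
  map0 <- contact_map(1L, 2L, 5, bins)
  cands <- candidate_moves(0, st, map0, k = 5)
  expect_equal(sort(vapply(cands, function(m) m$kind, "")),
               sort(c("stay", "flip", "eject")))

  # 3 + 5k candidates when no duplicates arise (distant anchors)
  bins9 <- make_bins(1, 9)
  st9 <- identity_structure(bins9)
  map9 <- contact_map(c(0L, 0L), c(4L, 7L), c(5, 4), bins9)
  cands <- candidate_moves(0, st9, map9, k = 2)
  expect_equal(length(cands), 3L + 5L * 2L)
})

test_that("sample_step is deterministic per seed and greedy picks argmax", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  emap <- pyramid_level(sim$pyr, 1)
  st <- structure_from_map(map)
  p <- estimate_parameters(expand_structure(st, map, emap), emap)
  set.seed(5)
  a <- sample_step(st, map, p, bin = 3, eval_map = emap)
  set.seed(5)
  b <- sample_step(st, map, p, bin = 3, eval_map = emap)
  expect_equal(a$mutation, b$mutation)
  expect_equal(a$structure$scaffolds, b$structure$scaffolds)

  g <- sample_step(st, map, p, bin = 3, eval_map = emap, greedy = TRUE)
  expect_true(g$delta >= 0)
})

test_that("run_cycle visits every bin once and conserves the bin multiset", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  emap <- pyramid_level(sim$pyr, 1)
  st <- structure_from_map(map)
  p <- estimate_parameters(expand_structure(st, map, emap), emap)
  set.seed(11)
  res <- run_cycle(st, map, p, eval_map = emap)
  expect_equal(sum(res$stats), map$n_bins)
  expect_setequal(abs(unlist(res$structure$scaffolds)), seq_len(map$n_bins))
  # determinism
  set.seed(11)
  res2 <- run_cycle(st, map, p, eval_map = emap)
  expect_equal(res$structure$scaffolds, res2$structure$scaffolds)
})

test_that("the engine applies mutations exactly like apply_mutation", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  emap <- pyramid_level(sim$pyr, 1)
  st <- structure_from_map(map)
  p <- estimate_parameters(expand_structure(st, map, emap), emap)
  for (s in 1:30) {
    mu <- random_mutation(map$n_bins, 500 + s)
    eng <- scaffoldmc:::build_engine(st, map, emap)
    scaffoldmc:::engine_set_params(eng, p)
    cm <- scaffoldmc:::encode_mutations(list(mu))
    scaffoldmc:::eng_apply(eng$ptr, cm[1, 1], cm[1, 2], cm[1, 3], cm[1, 4])
    st_r <- apply_mutation(st, mu)
    expect_equal(scaffoldmc:::eng_structure(eng$ptr),
                 lapply(st_r$scaffolds, as.integer))
    st <- st_r
  }
})

test_that("run_scaffolder returns the input structure for zero cycles", {
  sim <- make_sim()
  # pyramid truncated at the working level: no coarse pre-pass possible
  pyr2 <- sim$pyr
  res <- run_scaffolder(pyr2, 2, 0, seed = 1, config = list(init = "contigs"))
  expect_equal(res$structure$scaffolds,
               structure_from_map(pyramid_level(pyr2, 2))$scaffolds)
  expect_equal(nrow(res$trajectory), 0L)
})

test_that("run_scaffolder records one trajectory row per cycle", {
  sim <- make_sim()
  res <- run_scaffolder(sim$pyr, 2, 3, seed = 2)
  expect_equal(nrow(res$trajectory), 3L)
  expect_equal(res$trajectory$cycle, 1:3)
  expect_true(all(c("logL", "A", "alpha", "delta", "stay") %in%
                  names(res$trajectory)))
  expect_equal(attr(res$trajectory, "seed"), 2)
})

test_that("the log-likelihood trend over cycles is non-degrading", {
  sim <- make_sim()
  res <- run_scaffolder(sim$pyr, 2, 12, seed = 4)
  ll <- res$trajectory$logL
  expect_gte(stats::median(utils::tail(ll, 2)), ll[1])
})

test_that("a two-bin system samples both arrangements at Gibbs frequencies", {
  # two 2-unit bins on one contig with asymmetric counts between sub-bins;
  # compare the visit ratio of the two merged orders with the likelihood
  # ratio (the exhaustible oracle)
  bins <- data.frame(bin = 0:1, contig = "c", orig = 1:2, length_bp = 2000,
                     n_frag = 2L, frags = I(list(0:1, 2:3)))
  ebins <- data.frame(bin = 0:3, contig = "c", orig = 1:4, length_bp = 1000,
                      n_frag = 1L, frags = I(as.list(0:3)),
                      parent = c(0L, 0L, 1L, 1L))
  emap <- contact_map(c(0L, 1L, 2L, 0L), c(1L, 2L, 3L, 3L),
                      c(3, 2, 3, 1), ebins, level = 1)
  map <- contact_map(c(0L, 0L, 1L), c(0L, 1L, 1L), c(3, 3, 3), bins,
                     level = 2)
  p <- hic_params(A = 3000, alpha = 1, delta = 0.5)
  st <- genome_structure(list(1L, 2L), bins)
  canon <- function(st) {
    paste(vapply(st$scaffolds, function(v) {
      r <- -rev(v)
      a <- paste(v, collapse = ","); b <- paste(r, collapse = ",")
      if (a < b) a else b
    }, ""), collapse = ";")
  }
  keys <- character(0)
  set.seed(42)
  cur <- st
  for (cy in 1:4000) {
    res <- run_cycle(cur, map, p, eval_map = emap)
    cur <- res$structure
    keys <- c(keys, canon(cur))
  }
  tab <- table(keys)
  # restrict to the merged (one-scaffold) arrangements: their candidate
  # sets are mutually symmetric, so visit frequencies follow the Gibbs
  # ratios implied by the likelihoods
  merged <- grepl(",", names(tab))
  expect_gte(sum(merged), 2L)
  mt <- tab[merged]
  ll <- vapply(names(mt), function(k) {
    sc <- lapply(strsplit(strsplit(k, ";")[[1]], ","), as.integer)
    log_likelihood(genome_structure(sc, bins), map, p, emap)
  }, numeric(1))
  top <- order(-as.numeric(mt))[1:2]
  n1 <- as.numeric(mt[top[1]]); n2 <- as.numeric(mt[top[2]])
  expected_ratio <- exp(ll[top[1]] - ll[top[2]])
  se_log <- sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(log(n1 / n2) - log(expected_ratio)), 3 * se_log)
  # both orders of the two bins are visited
  expect_true(any(grepl("1,", names(mt)) | grepl("-2", names(mt))))
})

test_that("convergence_iqr uses interpolated quartiles over the tail", {
  tr <- data.frame(cycle = 1:10, A = 5, alpha = 2, delta = 0.1, logL = 7)
  expect_equal(unname(convergence_iqr(tr, 0.5)), rep(0, 4))

  tr <- data.frame(cycle = 1:4, A = 1:4, alpha = 1:4, delta = 1:4,
                   logL = 1:4)
  iqr <- convergence_iqr(tr, 1.0)
  expect_equal(unname(iqr["alpha"]), 1.5)  # Q1 = 1.75, Q3 = 3.25

  expect_error(convergence_iqr(tr[1, , drop = FALSE], 0.5), "fewer than 2")
})
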