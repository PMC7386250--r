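test_that("reorient rewrites runs to their consensus orientation", {
  bins <- make_bins(1, 3)
  # [b1+, b2+, b3-] -> all forward
  st <- genome_structure(list(c(1L, 2L, -3L)), bins)
  expect_equal(reorient(st)$scaffolds[[1]], c(1L, 2L, 3L))
  # consistent whole-contig reversal is left unchanged
  st <- genome_structure(list(c(-3L, -2L, -1L)), bins)
  expect_equal(reorient(st)$scaffolds[[1]], c(-3L, -2L, -1L))
  # tie -> forward
  bins2 <- make_bins(1, 2)
  st <- genome_structure(list(c(1L, -2L)), bins2)
  expect_equal(reorient(st)$scaffolds[[1]], c(1L, 2L))
  # order scrambles inside a run are healed too
  bins3 <- make_bins(1, 3)
  st <- genome_structure(list(c(2L, 1L, 3L)), bins3)
  expect_equal(reorient(st)$scaffolds[[1]], c(1L, 2L, 3L))
})

test_that("rearrange gathers split contigs at their largest run", {
  bins <- make_bins(2, 9)
  # contig 1 split 7 + 2 across two scaffolds
  st <- genome_structure(list(c(1:7, 10:18), c(8L, 9L)), bins)
  out <- rearrange(st)
  expect_equal(length(out$scaffolds), 1L)
  expect_equal(out$scaffolds[[1]][1:9], 1:9)

  # [a1, x, a2] -> [a1, a2, x]
  bins2 <- rbind(make_bins(1, 2), make_bins(1, 1))
  bins2$contig[3] <- "cx"
  bins2$bin <- 0:2
  st <- genome_structure(list(c(1L, 3L, 2L)), bins2)
  out <- rearrange(st)
  expect_equal(out$scaffolds[[1]], c(1L, 2L, 3L))

  # tie: anchor is the run with the lowest original rank
  bins3 <- make_bins(2, 6)
  st <- genome_structure(list(c(4:6, 7:9), c(1:3, 10:12)), bins3)
  out <- rearrange(st)
  idx <- scaffoldmc:::structure_index(out)
  # contig 1's bins 1..6 end up contiguous where ranks 1-3 sat
  expect_equal(idx$scaf[1], idx$scaf[6])
  run <- out$scaffolds[[idx$scaf[1]]]
  expect_true(all(1:6 %in% abs(run)))
})

test_that("reorient + rearrange are idempotent", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  st <- structure_from_map(map)
  set.seed(31)
  for (z in 1:25) st <- apply_mutation(st, random_mutation(map$n_bins, 700 + z))
  once <- rearrange(reorient(st))
  twice <- rearrange(reorient(once))
  expect_equal(twice$scaffolds, once$scaffolds)
})

test_that("misassembly_report counts inversions, relocations, splits", {
  bins <- make_bins(2, 5)
  st <- identity_structure(bins)
  r <- misassembly_report(st)
  expect_equal(misassembly_total(r), 0L)
  expect_equal(nrow(r$records), 0L)

  r <- misassembly_report(apply_mutation(st, mutation("flip", 2)))
  expect_equal(r$intra_contig_inversions, 1L)

  # contig split across two scaffolds
  st2 <- genome_structure(list(1:3, 4:5, 6:10), bins)
  r <- misassembly_report(st2)
  expect_equal(r$contig_splits, 1L)

  # rank discontinuity within a scaffold
  st3 <- genome_structure(list(c(1L, 2L, 4L, 3L, 5L), 6:10), bins)
  r <- misassembly_report(st3)
  expect_gt(r$intra_contig_relocations, 0L)
})

test_that("correction heals random flip/relocation/split perturbations", {
  bins <- make_bins(8, 8)
  base <- identity_structure(bins)
  n <- nrow(bins)
  for (seed in 1:50) {
    set.seed(seed)
    st <- base
    for (z in seq_len(sample(1:4, 1))) {
      kind <- sample(c("flip", "relocate", "split"), 1)
      b <- sample(0:(n - 1), 1)
      mu <- switch(kind,
        flip = mutation("flip", b),
        relocate = mutation(sample(c("insert_before", "insert_after"), 1), b,
                            anchor = sample(setdiff(0:(n - 1), b), 1),
                            flipped = sample(c(TRUE, FALSE), 1)),
        split = mutation("eject", b))
      st <- apply_mutation(st, mu)
    }
    healed <- rearrange(reorient(st))
    expect_equal(misassembly_total(misassembly_report(healed)), 0L)
  }
})

test_that("correction conserves bins and bp exactly", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  st <- structure_from_map(map)
  set.seed(13)
  for (z in 1:30) st <- apply_mutation(st, random_mutation(map$n_bins, 900 + z))
  out <- rearrange(reorient(st))
  expect_setequal(abs(unlist(out$scaffolds)), seq_len(map$n_bins))
  expect_equal(total_bp(out), total_bp(st))
})

test_that("reinsert_filtered restores every filtered fragment", {
  fr <- data.frame(frag_id = 0:9,
                   contig = rep(c("c1", "c2"), c(8, 2)),
                   start = c((0:7) * 100L, 0L, 100L),
                   end = c((1:8) * 100L, 100L, 200L),
                   length = 100L, coverage = 10, filtered = FALSE)
  # interior fragment 3, tail fragment 7, and all of contig c2 filtered
  filtered_ids <- c(3L, 7L, 8L, 9L)
  fr$filtered[fr$frag_id %in% filtered_ids] <- TRUE
  keep <- fr[!fr$filtered, ]
  bins <- fragment_bins(keep)
  bins$frags <- I(as.list(keep$frag_id))
  st <- genome_structure(list(seq_len(nrow(bins))), bins, fr)
  report <- structure(list(removed_short = integer(0),
                           removed_low_coverage = c(3L, 7L),
                           removed_orphaned = c(8L, 9L),
                           threshold_len = 50L, threshold_cov = 0,
                           threshold_contig_frags = 5L),
                      class = "filter_report")
  out <- reinsert_filtered(st, report, fr)
  expect_equal(total_bp(out), sum(fr$length))
  # interior fragment sits between its original neighbours
  placed <- unlist(lapply(abs(out$scaffolds[[1]]),
                          function(b) out$bins$frags[[b]]))
  expect_equal(placed[1:8], 0:7)
  # fully filtered contig becomes a standalone trailing scaffold
  last <- out$scaffolds[[length(out$scaffolds)]]
  expect_equal(out$bins$frags[[abs(last[1])]], c(8L, 9L))
})

test_that("linkage validation passes on a consistent structure", {
  sim <- make_sim(seed = 13)
  map <- pyramid_level(sim$pyr, 2)
  tst <- truth_structure(map, sim$truth)
  lmap <- simulate_linkage_map(sim$truth)
  pairs <- suppressWarnings(linkage_match(tst, lmap))
  expect_equal(nrow(pairs), length(unique(lmap$linkage_group)))
  v <- suppressWarnings(linkage_apply(tst, lmap, mode = "validate"))
  expect_equal(v$changes, 0L)
})

test_that("linkage correction detects and repairs a translocation", {
  sim <- make_sim(seed = 13)
  map <- pyramid_level(sim$pyr, 2)
  tst <- truth_structure(map, sim$truth)
  lmap <- simulate_linkage_map(sim$truth)
  mk <- suppressWarnings(scaffoldmc:::markers_to_bins(tst, lmap))
  idx <- scaffoldmc:::structure_index(tst)
  b <- mk$bin[1]
  other <- setdiff(seq_along(tst$scaffolds), idx$scaf[b + 1])[1]
  anchor <- abs(tst$scaffolds[[other]][3]) - 1L
  st2 <- apply_mutation(tst, mutation("insert_after", b, anchor = anchor))
  v <- suppressWarnings(linkage_apply(st2, lmap, mode = "validate"))
  expect_gte(v$changes, 1L)
  fixed <- suppressWarnings(linkage_apply(st2, lmap, mode = "correct"))
  v2 <- suppressWarnings(linkage_apply(fixed$structure, lmap,
                                       mode = "validate"))
  expect_equal(v2$changes, 0L)
})

test_that("adjacent marker bins in swapped cM order count as one change", {
  sim <- make_sim(seed = 13)
  map <- pyramid_level(sim$pyr, 2)
  tst <- truth_structure(map, sim$truth)
  lmap <- simulate_linkage_map(sim$truth)
  mk <- suppressWarnings(scaffoldmc:::markers_to_bins(tst, lmap))
  idx <- scaffoldmc:::structure_index(tst)
  # two marker-bearing bins of one group on the same scaffold
  g <- mk[mk$linkage_group == mk$linkage_group[1], ]
  g <- g[!duplicated(g$bin), ]
  b1 <- g$bin[1]; b2 <- g$bin[2]
  st2 <- apply_mutation(tst, mutation("swap", b1, anchor = b2))
  v <- suppressWarnings(linkage_apply(st2, lmap, mode = "validate"))
  expect_gte(v$changes, 1L)
  # bins without markers keep their positions in correct mode
  unmarked <- setdiff(seq_len(nrow(tst$bins)) - 1L, mk$bin)
  fixed <- suppressWarnings(linkage_apply(st2, lmap, mode = "correct"))
  idx0 <- scaffoldmc:::structure_index(st2)
  idx1 <- scaffoldmc:::structure_index(fixed$structure)
  expect_equal(idx1$scaf[unmarked + 1L], idx0$scaf[unmarked + 1L])
})
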