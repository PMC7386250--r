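test_that("the generator is deterministic per seed", {
  spec <- truth_spec(n_chromosomes = 1, chrom_length = 2e4, seed = 5)
  expect_identical(as.character(generate_genome(spec)),
                   as.character(generate_genome(spec)))
  sh1 <- shred(generate_genome(spec), mean_len = 5e3, seed = 5)
  sh2 <- shred(generate_genome(spec), mean_len = 5e3, seed = 5)
  expect_identical(as.character(sh1$contigs), as.character(sh2$contigs))
  fr <- digest_genome(sh1$contigs)
  m1 <- simulate_contacts(sh1$truth, fr, spec, seed = 9)
  m2 <- simulate_contacts(sh1$truth, fr, spec, seed = 9)
  expect_identical(m1$count, m2$count)
})

test_that("fixed-spacing mode plants the site exactly every d bp", {
  spec <- truth_spec(n_chromosomes = 1, chrom_length = 5000, spacing = 500,
                     seed = 2)
  g <- generate_genome(spec)
  fr <- digest_genome(g)
  # 10 planted sites at 0, 500, ..., 4500; the cut at 0 adds no fragment
  expect_equal(nrow(fr), 10L)
  expect_equal(fr$start, seq(0L, 4500L, by = 500L))
})

test_that("random mode has the binomial site density", {
  spec <- truth_spec(n_chromosomes = 1, chrom_length = 1e6,
                     spacing_mode = "random", seed = 7)
  g <- generate_genome(spec)
  fr <- digest_genome(g)
  n_sites <- nrow(fr) - 1L   # cuts, excluding the contig start
  L <- 1e6
  expected <- (L - 3) * 4^-4
  sd <- sqrt((L - 3) * 4^-4 * (1 - 4^-4))
  expect_lt(abs(n_sites - expected), 5 * sd)
})

test_that("shredding conserves the chromosomes exactly", {
  spec <- truth_spec(n_chromosomes = 2, chrom_length = 1e5, seed = 3)
  g <- generate_genome(spec)
  sh <- shred(g, mean_len = 2e4, seed = 3)
  seqs <- as.character(sh$contigs)
  for (ch in names(g)) {
    rows <- sh$truth[sh$truth$chrom == ch, ]
    rows <- rows[order(rows$chrom_start), ]
    parts <- vapply(seq_len(nrow(rows)), function(r) {
      s <- substr(seqs[[rows$contig[r]]], rows$contig_start[r] + 1L,
                  rows$contig_end[r])
      if (rows$strand[r] == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      s
    }, "")
    expect_identical(paste(parts, collapse = ""), as.character(g[[ch]]))
  }
})

test_that("fixed windows of 300 kb cut a 3-Mb chromosome into 10 contigs", {
  spec <- truth_spec(n_chromosomes = 1, chrom_length = 3e6, seed = 1)
  g <- generate_genome(spec)
  sh <- shred(g, mean_len = 3e5, seed = 1, mode = "fixed")
  expect_equal(length(sh$contigs), 10L)
})

test_that("a planted inversion shows up as exactly one misassembly", {
  spec <- truth_spec(n_chromosomes = 1, chrom_length = 2e5, seed = 21)
  g <- generate_genome(spec)
  sh <- shred(g, mean_len = 4e4, seed = 21,
              error_spec = list(inversions = 1))
  multi <- sh$truth$contig %in% names(which(table(sh$truth$contig) > 1))
  expect_equal(sum(multi & sh$truth$strand == "-"), 1L)
  fr <- digest_genome(sh$contigs)
  map0 <- simulate_contacts(sh$truth, fr, spec, seed = 21)
  fr <- compute_coverage(map0, fr)
  flt <- filter_fragments(map0, fr)
  pyr <- build_pyramid(flt$map, 1, 3)
  tst <- truth_structure(pyramid_level(pyr, 1), sh$truth)
  r <- misassembly_report(tst)
  expect_equal(r$intra_contig_inversions, 1L)
})

test_that("simulated counts decay with the prescribed exponent", {
  spec <- truth_spec(n_chromosomes = 1, chrom_length = 3e5, seed = 8,
                     depth = 4)
  g <- generate_genome(spec)
  sh <- shred(g, mean_len = 1e5, seed = 8)
  fr <- digest_genome(sh$contigs)
  map <- simulate_contacts(sh$truth, fr, spec, seed = 8)
  co <- scaffoldmc:::fragment_truth_coords(fr, sh$truth)
  s <- abs(co$pos[map$i + 1] - co$pos[map$j + 1])
  # mean count per log-distance bin over the power-law region
  sel <- s > 0 & s < 5e4
  brk <- seq(min(log(s[sel])), max(log(s[sel])), length.out = 13)
  lg <- cut(log(s[sel]), brk, include.lowest = TRUE)
  ls <- tapply(log(s[sel]), lg, mean)
  # zero cells are absent from the sparse map; divide the per-bin count
  # total by the number of available pairs per bin
  d_all <- abs(outer(co$pos, co$pos, "-"))
  d_all <- d_all[upper.tri(d_all)]
  d_all <- d_all[d_all > 0]
  np_t <- table(cut(log(d_all), brk, include.lowest = TRUE))
  tot <- tapply(map$count[sel], lg, sum)
  mn_all <- as.numeric(tot) / as.numeric(np_t)
  ok <- is.finite(mn_all) & mn_all > 0 & is.finite(ls)
  fit <- lm(log(mn_all[ok]) ~ ls[ok])
  expect_lt(abs(unname(coef(fit)[2]) + spec$alpha), 0.05)
})

test_that("inter-chromosomal cells match the floor level", {
  spec <- truth_spec(n_chromosomes = 2, chrom_length = 1e5, seed = 6)
  g <- generate_genome(spec)
  sh <- shred(g, mean_len = 5e4, seed = 6)
  fr <- digest_genome(sh$contigs)
  map <- simulate_contacts(sh$truth, fr, spec, seed = 6)
  co <- scaffoldmc:::fragment_truth_coords(fr, sh$truth)
  inter <- co$chrom[map$i + 1] != co$chrom[map$j + 1]
  n1 <- sum(co$chrom == "chr_1"); n2 <- sum(co$chrom == "chr_2")
  npairs <- as.numeric(n1) * n2
  mu <- spec$delta * spec$depth
  observed <- sum(map$count[inter]) / npairs
  se <- sqrt(mu / npairs)
  expect_lt(abs(observed - mu), 3 * se)
})

test_that("a zero floor yields no inter-chromosomal cells", {
  spec <- truth_spec(n_chromosomes = 2, chrom_length = 5e4, seed = 4)
  spec$delta <- 0
  g <- generate_genome(spec)
  sh <- shred(g, mean_len = 2e4, seed = 4)
  fr <- digest_genome(sh$contigs)
  map <- simulate_contacts(sh$truth, fr, spec, seed = 4)
  co <- scaffoldmc:::fragment_truth_coords(fr, sh$truth)
  expect_equal(sum(co$chrom[map$i + 1] != co$chrom[map$j + 1]), 0L)
})

test_that("the simulated linkage map is internally consistent", {
  sim <- make_sim(seed = 13)
  lmap <- simulate_linkage_map(sim$truth)
  expect_true(all(lmap$pos >= 0))
  # markers map back to the chromosome position they were planted at
  for (r in sample(nrow(lmap), min(10, nrow(lmap)))) {
    row <- lmap[r, ]
    tr <- sim$truth[sim$truth$contig == row$contig &
                    row$pos >= sim$truth$contig_start &
                    row$pos < sim$truth$contig_end, ][1, ]
    chrom_pos <- if (tr$strand == "+") tr$chrom_start + (row$pos - tr$contig_start)
                 else tr$chrom_end - 1 - (row$pos - tr$contig_start)
    expect_equal(row$cm, chrom_pos / 1e6 * 4, tolerance = 1e-8)
    expect_equal(row$linkage_group, tr$chrom)
  }
})
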