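test_that("read_fasta uppercases, preserves order, and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACgt"), f)
  x <- read_fasta(f)
  expect_equal(as.character(x), c(a = "ACGT"))

  writeLines(c(">a", "AC", ">b", "GT"), f)
  x <- read_fasta(f)
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x), c(a = "AC", b = "GT"))

  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_fasta(f), "duplicate header")
})

test_that("fasta round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(a = strrep("ACGTN", 50), b = "TTTT")
  write_fasta(seqs, f)
  expect_equal(as.character(read_fasta(f)), seqs)
})

test_that("read_pairs parses records, comments, and malformed lines", {
  f <- withr::local_tempfile(fileext = ".pairs")
  writeLines(c("#columns: readID chr1 pos1 strand1 chr2 pos2 strand2 mapq1 mapq2",
               "r1\tc1\t10\t+\tc1\t500\t-\t42\t42"), f)
  p <- read_pairs(f)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pos2, 500L)
  expect_equal(p$strand2, "-")

  writeLines("#only a comment", f)
  expect_equal(nrow(read_pairs(f)), 0L)

  writeLines(c("#h", "r1\tc1\t10\t+\tc1", "r2\tc1\t1\t+\tc1\t2\t-\t60\t60"), f)
  expect_error(read_pairs(f), "line 2")
})

test_that("sparse map round-trips and rejects invalid entries", {
  f <- withr::local_tempfile(fileext = ".tsv")
  bins <- make_bins(1, 4)
  m <- contact_map(c(0L, 1L), c(1L, 1L), c(3, 2), bins)
  write_sparse_map(m, f)
  expect_equal(length(readLines(f)), 3L)  # header + 2 data lines
  m2 <- read_sparse_map(f, bins = bins)
  expect_equal(m2$i, m$i)
  expect_equal(m2$j, m$j)
  expect_equal(m2$count, m$count)

  writeLines(c("id_a\tid_b\tcount", "1\t0\t3"), f)
  expect_error(read_sparse_map(f), "lower-triangle")
  writeLines(c("id_a\tid_b\tcount", "0\t1\t0"), f)
  expect_error(read_sparse_map(f), "count")
  writeLines("id_a\tid_b\tcount", f)
  expect_equal(length(read_sparse_map(f)$i), 0L)
})

test_that("placement tables serialize structures and round-trip", {
  sim <- make_sim()
  st <- structure_from_map(pyramid_level(sim$pyr, 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_placement_table(st, f)
  d <- read_placement_table(f)
  expect_true(all(c("scaffold", "input_contig", "start", "end",
                    "orientation", "rank") %in% names(d)))
  expect_true(all(d$end > d$start))
  # round trip at the table level is lossless
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_placement_table(d, f2)
  expect_equal(read_placement_table(f2), d)

  bad <- d
  bad$end[1] <- bad$start[1]
  expect_error(write_placement_table(bad, f), "end <= start")
})

test_that("placement round-trip holds for randomized structures", {
  sim <- make_sim()
  map <- pyramid_level(sim$pyr, 2)
  st <- structure_from_map(map)
  for (seed in 1:5) {
    set.seed(seed)
    for (z in 1:10) {
      mu <- random_mutation(map$n_bins, seed * 100 + z)
      st <- apply_mutation(st, mu)
    }
    f <- withr::local_tempfile(fileext = ".tsv")
    write_placement_table(st, f)
    d <- read_placement_table(f)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_placement_table(d, f2)
    expect_equal(read_placement_table(f2), d)
  }
})

test_that("write_scaffold_fasta assembles, reverse-complements, and gaps", {
  bins <- data.frame(bin = 0:1, contig = c("c1", "c2"), orig = c(1L, 1L),
                     length_bp = 4, n_frag = 1L, frags = I(list(0L, 1L)))
  frags <- data.frame(frag_id = 0:1, contig = c("c1", "c2"),
                      start = 0L, end = 4L, length = 4L,
                      coverage = 0, filtered = FALSE)
  seqs <- c(c1 = "AACC", c2 = "GGAA")
  st <- genome_structure(list(1L), bins[1, , drop = FALSE], frags)
  expect_equal(as.character(write_scaffold_fasta(st, seqs["c1"], gap_size = 0)),
               c(scaffold_1 = "AACC"))
  st_rev <- genome_structure(list(-1L), bins[1, , drop = FALSE], frags)
  expect_equal(unname(as.character(write_scaffold_fasta(st_rev, seqs["c1"],
                                                        gap_size = 0))[1]),
               "GGTT")  # reverse complement of AACC
  st2 <- genome_structure(list(c(1L, 2L)), bins, frags)
  out <- write_scaffold_fasta(st2, seqs, gap_size = 100)
  expect_equal(unname(Biostrings::width(out)[1]), 108L)
  # non-N base conservation
  expect_equal(sum(Biostrings::letterFrequency(out, "ACGT")), 8)
  # interval beyond contig
  expect_error(write_scaffold_fasta(st2, c(c1 = "AA", c2 = "GGAA")), "beyond")
  # non-integrated contigs appended under their own names
  out3 <- write_scaffold_fasta(st, seqs)
  expect_true("c2" %in% names(out3))
})

test_that("linkage maps round-trip and are sorted by cM within groups", {
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(marker_id = c("m2", "m1"), linkage_group = "LG1",
                  cm = c(5.5, 1.0), contig = "c1", pos = c(100L, 10L))
  write_linkage_map(d, f)
  d2 <- read_linkage_map(f)
  expect_equal(d2$marker_id, c("m1", "m2"))
  expect_equal(d2$cm, c(1.0, 5.5))
})
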