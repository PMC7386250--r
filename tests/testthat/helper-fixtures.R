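# Shared fixture builders. Everything is generated in code, deterministically
# per seed; the heavier simulations are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

# full synthetic study: genome -> contigs -> fragments -> contacts ->
# filtered map -> pyramid
make_sim <- function(seed = 3, n_chrom = 2, chrom_len = 2e5, mean_len = 2e4,
                     levels = 2, ...) {
  key <- paste(seed, n_chrom, chrom_len, mean_len, levels, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- truth_spec(n_chromosomes = n_chrom, chrom_length = chrom_len,
                     seed = seed, ...)
  gen <- generate_genome(spec)
  sh <- shred(gen, mean_len = mean_len, seed = seed)
  frag <- digest_genome(sh$contigs, spec$site)
  map0 <- simulate_contacts(sh$truth, frag, spec, seed = seed)
  frag <- compute_coverage(map0, frag)
  flt <- filter_fragments(map0, frag)
  pyr <- build_pyramid(flt$map, levels, 3L)
  out <- list(spec = spec, genome = gen, contigs = sh$contigs,
              truth = sh$truth, fragments0 = frag, map0 = map0, flt = flt,
              pyr = pyr)
  .fixture_cache[[key]] <- out
  out
}

# small random likelihood instance: random scaffold partition + counts
rand_instance <- function(nb, seed) {
  set.seed(seed)
  bins <- data.frame(bin = 0:(nb - 1),
                     contig = paste0("c", rep(seq_len(max(1, nb %/% 5)),
                                              length.out = nb)),
                     orig = 1L, length_bp = sample(500:1500, nb, TRUE),
                     n_frag = 1L, frags = I(as.list(0:(nb - 1))))
  bins$orig <- as.integer(stats::ave(seq_len(nb), bins$contig, FUN = seq_along))
  ids <- sample(nb)
  k <- sample(seq_len(max(1, nb %/% 3)), 1)
  brk <- sort(sample(seq_len(nb - 1), min(k, nb - 1)))
  sc <- split(ids, findInterval(seq_len(nb), brk + 1))
  sc <- lapply(unname(sc), function(v) v * sample(c(-1L, 1L), length(v), TRUE))
  st <- genome_structure(sc, bins)
  npairs <- sample(seq_len(nb * 3), 1)
  i <- sample(0:(nb - 1), npairs, TRUE)
  j <- sample(0:(nb - 1), npairs, TRUE)
  map <- contact_map(pmin(i, j), pmax(i, j), sample(1:5, npairs, TRUE), bins)
  list(st = st, map = map)
}

# dense brute-force log-likelihood oracle: enumerates every bin pair
dense_loglik <- function(st, map, params) {
  nb <- map$n_bins
  M <- matrix(0, nb, nb)
  for (k in seq_along(map$i))
    M[map$i[k] + 1, map$j[k] + 1] <- M[map$i[k] + 1, map$j[k] + 1] + map$count[k]
  M <- M + t(M) - diag(diag(M))
  idx <- scaffoldmc:::structure_index(st)
  u <- mean(st$bins$length_bp)
  ll <- 0
  for (a in seq_len(nb - 1)) {
    for (b in (a + 1):nb) {
      lam <- if (idx$scaf[a] == idx$scaf[b]) {
        s <- u * abs(idx$rank[a] - idx$rank[b])
        max(params$A * s^(-params$alpha), params$delta)
      } else params$delta
      ll <- ll + M[a, b] * log(lam) - lam
    }
  }
  ll
}

# a clean multi-contig bin table + identity structure for polish tests
make_bins <- function(n_contigs = 5, bins_per_contig = 6, bp = 1000) {
  n <- n_contigs * bins_per_contig
  bins <- data.frame(bin = 0:(n - 1),
                     contig = rep(sprintf("c%02d", seq_len(n_contigs)),
                                  each = bins_per_contig),
                     orig = rep(seq_len(bins_per_contig), n_contigs),
                     length_bp = bp, n_frag = 1L,
                     frags = I(as.list(0:(n - 1))))
  bins
}

identity_structure <- function(bins) {
  contigs <- unique(bins$contig)
  genome_structure(lapply(contigs, function(ct) which(bins$contig == ct)),
                   bins)
}

random_mutation <- function(nb, seed) {
  set.seed(seed)
  t0 <- sample(0:(nb - 1), 1)
  an <- sample(setdiff(0:(nb - 1), t0), 1)
  kind <- sample(MUTATION_KINDS <- c("stay", "flip", "eject", "insert_before",
                                     "insert_after", "swap"), 1)
  mutation(kind, t0,
           anchor = if (kind %in% c("insert_before", "insert_after", "swap"))
             an else NA_integer_,
           flipped = sample(c(TRUE, FALSE), 1))
}
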