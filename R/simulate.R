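# Synthetic-data generator: genomes with controlled restriction-site
# spacing, shredded draft contigs, and Hi-C contact maps drawn from the
# power-law contact model. This is first-class, tested code: it defines the
# study conditions for the end-to-end benchmarks.

#' Specification of a synthetic genome and contact experiment
#'
#' Defaults describe the benchmark conditions used throughout the package:
#' 4 chromosomes of 1 Mb with a restriction site planted every 800 bp
#' (within the typical DpnII site density of one per 600-1000 bp), and a
#' fragment-level contact model `depth * max(A * s^-alpha, delta)` chosen so
#' that adjacent fragments expect ~10 contacts and an inter-chromosomal
#' working-bin pair (81 fragment pairs at level 2) expects ~0.05.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length(s) in bp (recycled).
#' @param site restriction site sequence.
#' @param spacing_mode `"fixed"` (site planted every `spacing` bp, no
#'   background occurrences) or `"random"` (uniform random sequence).
#' @param spacing planted site spacing in bp (fixed mode).
#' @param A,alpha,delta fragment-level contact model (s in bp).
#' @param depth sequencing-depth scale multiplying expected counts.
#' @param seed integer seed; all generator output is deterministic given it.
#' @export
truth_spec <- function(n_chromosomes = 4L, chrom_length = 1e6, site = "GATC",
                       spacing_mode = c("fixed", "random"), spacing = 800L,
                       A = 8000, alpha = 1.0, delta = 6e-4, depth = 1.0,
                       seed = 1L) {
  spacing_mode <- match.arg(spacing_mode)
  if (any(chrom_length <= 0)) stop_("chromosome lengths must be positive")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = rep_len(chrom_length, n_chromosomes),
                 site = site, spacing_mode = spacing_mode,
                 spacing = as.integer(spacing),
                 A = A, alpha = alpha, delta = delta, depth = depth,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

# mutate away site occurrences that are not at planted positions
scrub_sites <- function(v, site, keep = integer(0)) {
  sl <- nchar(site)
  planted <- logical(length(v))
  for (p in keep) planted[(p + 1L):(p + sl)] <- TRUE
  repeat {
    s <- paste(v, collapse = "")
    hits <- gregexpr(paste0("(?=", site, ")"), s, perl = TRUE)[[1]]
    hits <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
    bad <- setdiff(hits, keep)
    if (!length(bad)) return(v)
    for (p in bad) {
      cells <- (p + 1L):(p + sl)
      cells <- cells[!planted[cells]]
      cell <- cells[1]
      v[cell] <- sample(setdiff(c("A", "C", "G", "T"), v[cell]), 1)
    }
  }
}

#' Generate a synthetic genome
#'
#' Random uniform A/C/G/T chromosomes; in fixed-spacing mode the
#' restriction site is planted exactly every `spacing` bp (starting at
#' position 0) and background occurrences are mutated away, so the
#' restriction map is fully controlled.
#'
#' @param spec a [truth_spec()].
#' @return a named `DNAStringSet` (`chr_1`, `chr_2`, ...).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  sl <- nchar(spec$site)
  site_chars <- strsplit(spec$site, "")[[1]]
  seqs <- character(spec$n_chromosomes)
  for (c in seq_len(spec$n_chromosomes)) {
    L <- spec$chrom_length[c]
    v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (spec$spacing_mode == "fixed") {
      plant <- seq(0L, L - sl, by = spec$spacing)
      for (p in plant) v[(p + 1L):(p + sl)] <- site_chars
      v <- scrub_sites(v, spec$site, keep = plant)
    }
    seqs[c] <- paste(v, collapse = "")
  }
  names(seqs) <- sprintf("chr_%d", seq_len(spec$n_chromosomes))
  Biostrings::DNAStringSet(seqs)
}

#' Shred a genome into draft contigs
#'
#' Chromosomes are cut at random positions (or fixed windows), and the
#' resulting contigs are shuffled and randomly strand-flipped, emulating a
#' draft assembly. The returned truth table records each contig piece's
#' true chromosome interval and strand; concatenating the pieces in truth
#' order and orientation reconstructs each chromosome exactly.
#'
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param mean_len target mean contig length in bp.
#' @param seed integer seed.
#' @param mode `"random"` (contig lengths uniform in 0.5-1.5x `mean_len`)
#'   or `"fixed"` (exact windows of `mean_len`).
#' @param error_spec optional list; `inversions = k` plants k segment
#'   inversions inside contigs (boundaries aligned to `align` bp, e.g. the
#'   restriction-site spacing), recorded in the truth table.
#' @param align alignment grid for planted-error boundaries (default 800).
#' @return list with `contigs` (shuffled, oriented `DNAStringSet`) and
#'   `truth` (data frame: contig, contig_start, contig_end, chrom,
#'   chrom_start, chrom_end, strand).
#' @export
shred <- function(genome, mean_len = 4e4, seed = 1L,
                  mode = c("random", "fixed"), error_spec = NULL,
                  align = 800L) {
  mode <- match.arg(mode)
  set.seed(seed)
  seqs <- as.character(genome)
  pieces <- list(); z <- 0L
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    if (mode == "fixed") {
      cuts <- seq(0L, L, by = as.integer(mean_len))
      if (cuts[length(cuts)] != L) cuts <- c(cuts, L)
    } else {
      cuts <- 0L
      while (cuts[length(cuts)] < L) {
        step <- round(stats::runif(1, 0.5, 1.5) * mean_len)
        cuts <- c(cuts, min(cuts[length(cuts)] + step, L))
      }
      # avoid a tiny trailing contig
      if (length(cuts) > 2L && diff(cuts)[length(cuts) - 1L] < mean_len / 4)
        cuts <- cuts[-(length(cuts) - 1L)]
    }
    for (k in seq_len(length(cuts) - 1L)) {
      z <- z + 1L
      pieces[[z]] <- list(chrom = ch, start = cuts[k], end = cuts[k + 1L])
    }
  }
  n <- length(pieces)
  names_in_order <- sprintf("contig_%03d", seq_len(n))
  contig_seq <- character(n)
  truth <- list()
  inverted_in <- integer(0)
  if (!is.null(error_spec) && (error_spec$inversions %||% 0L) > 0L) {
    big <- which(vapply(pieces, function(p) p$end - p$start, 1) >= 6L * align)
    inverted_in <- sample(big, min(error_spec$inversions, length(big)))
  }
  for (k in seq_len(n)) {
    p <- pieces[[k]]
    s <- substr(seqs[[p$chrom]], p$start + 1L, p$end)
    clen <- p$end - p$start
    if (k %in% inverted_in) {
      # invert the middle third, boundaries on the alignment grid relative
      # to chromosome coordinates (i.e., at restriction sites)
      a <- ceiling((p$start + clen / 3) / align) * align - p$start
      b <- floor((p$start + 2 * clen / 3) / align) * align - p$start
      inv <- reverse_complement_chr(substr(s, a + 1L, b))
      s <- paste0(substr(s, 1L, a), inv, substr(s, b + 1L, clen))
      truth[[length(truth) + 1L]] <- data.frame(
        contig = names_in_order[k],
        contig_start = c(0L, a, b), contig_end = c(a, b, clen),
        chrom = p$chrom,
        chrom_start = p$start + c(0L, a, b),
        chrom_end = p$start + c(a, b, clen),
        strand = c("+", "-", "+"), stringsAsFactors = FALSE)
    } else {
      truth[[length(truth) + 1L]] <- data.frame(
        contig = names_in_order[k], contig_start = 0L, contig_end = clen,
        chrom = p$chrom, chrom_start = p$start, chrom_end = p$end,
        strand = "+", stringsAsFactors = FALSE)
    }
    contig_seq[k] <- s
  }
  names(contig_seq) <- names_in_order
  truth <- do.call(rbind, truth)
  # shuffle and strand-flip whole contigs (error contigs stay forward so
  # the planted-error bookkeeping remains one row per event)
  ord <- sample(n)
  flip <- stats::runif(n) < 0.5
  flip[inverted_in] <- FALSE
  for (k in which(flip)) {
    contig_seq[k] <- reverse_complement_chr(contig_seq[k])
    r <- truth$contig == names_in_order[k]
    truth$strand[r] <- ifelse(truth$strand[r] == "+", "-", "+")
    clen <- pieces[[k]]$end - pieces[[k]]$start
    new_start <- clen - truth$contig_end[r]
    truth$contig_end[r] <- clen - truth$contig_start[r]
    truth$contig_start[r] <- new_start
  }
  contigs <- Biostrings::DNAStringSet(contig_seq[ord])
  rownames(truth) <- NULL
  list(contigs = contigs, truth = truth)
}

# true chromosome and coordinate of each fragment center
fragment_truth_coords <- function(fragments, truth) {
  centers <- (fragments$start + fragments$end) / 2
  chrom <- character(nrow(fragments))
  pos <- numeric(nrow(fragments))
  for (r in seq_len(nrow(truth))) {
    sel <- fragments$contig == truth$contig[r] &
      centers >= truth$contig_start[r] & centers < truth$contig_end[r]
    if (!any(sel)) next
    chrom[sel] <- truth$chrom[r]
    off <- centers[sel] - truth$contig_start[r]
    pos[sel] <- if (truth$strand[r] == "+") truth$chrom_start[r] + off
                else truth$chrom_end[r] - off
  }
  if (any(chrom == "")) stop_("fragment not covered by the truth table")
  data.frame(chrom = chrom, pos = pos)
}

#' Simulate a level-0 Hi-C contact map from the truth
#'
#' For every fragment pair, a count is drawn from
#' `Poisson(depth * P(s))` with `s` the true genomic distance between the
#' fragment centers, `P(s) = max(A * s^-alpha, delta)` within a chromosome
#' and `delta` between chromosomes. Zero draws are omitted from the sparse
#' map. Inter-chromosomal (and other floor-level) cells are drawn by first
#' sampling the number of non-zero cells, which keeps the simulation linear
#' in the number of non-zero contacts.
#'
#' @param truth truth table from [shred()].
#' @param fragments fragment table of the shredded contigs
#'   ([digest_genome()]).
#' @param spec a [truth_spec()] supplying `A`, `alpha`, `delta`, `depth`.
#' @param seed integer seed.
#' @return a level-0 [contact_map()] over the contig fragments.
#' @export
simulate_contacts <- function(truth, fragments, spec, seed = 1L) {
  set.seed(seed)
  co <- fragment_truth_coords(fragments, truth)
  A <- spec$A * spec$depth
  delta <- spec$delta * spec$depth
  alpha <- spec$alpha
  ii <- list(); jj <- list(); cc <- list(); z <- 0L
  chroms <- unique(co$chrom)
  for (ch in chroms) {
    f <- which(co$chrom == ch)
    nf <- length(f)
    if (nf < 2L) next
    pr_i <- rep(seq_len(nf - 1L), times = (nf - 1L):1L)
    pr_j <- sequence((nf - 1L):1L) + pr_i
    s <- abs(co$pos[f[pr_i]] - co$pos[f[pr_j]])
    s[s <= 0] <- 1
    mu <- pmax(A * s^(-alpha), delta)
    cnt <- stats::rpois(length(mu), mu)
    keep <- cnt > 0L
    if (any(keep)) {
      z <- z + 1L
      gi <- fragments$frag_id[f[pr_i[keep]]]
      gj <- fragments$frag_id[f[pr_j[keep]]]
      ii[[z]] <- pmin(gi, gj); jj[[z]] <- pmax(gi, gj); cc[[z]] <- cnt[keep]
    }
  }
  # inter-chromosomal cells: constant mean delta
  if (length(chroms) > 1L && delta > 0) {
    p_nz <- 1 - exp(-delta)
    for (a in seq_len(length(chroms) - 1L)) {
      fa <- which(co$chrom == chroms[a])
      for (b in (a + 1L):length(chroms)) {
        fb <- which(co$chrom == chroms[b])
        npairs <- length(fa) * length(fb)
        K <- stats::rbinom(1L, npairs, p_nz)
        if (K == 0L) next
        cells <- sample.int(npairs, K)
        ai <- fa[((cells - 1L) %% length(fa)) + 1L]
        bj <- fb[((cells - 1L) %/% length(fa)) + 1L]
        u <- stats::runif(K, exp(-delta), 1)
        cnt <- stats::qpois(u, delta)
        cnt[cnt < 1L] <- 1L
        gi <- fragments$frag_id[ai]; gj <- fragments$frag_id[bj]
        z <- z + 1L
        ii[[z]] <- pmin(gi, gj); jj[[z]] <- pmax(gi, gj); cc[[z]] <- cnt
      }
    }
  }
  contact_map(unlist(ii), unlist(jj), unlist(cc), fragment_bins(fragments),
              level = 0L, fragments = fragments)
}

#' Emit synthetic read pairs from a level-0 contact map
#'
#' Draws one read pair per contact, uniformly positioned within each
#' fragment, for testing the pair-assignment path.
#'
#' @param map level-0 `contact_map`.
#' @param fragments fragment table.
#' @param seed integer seed.
#' @param mapq mapping quality written on all reads (default 60).
#' @return a pairs data frame (see [read_pairs()]).
#' @export
simulate_pairs <- function(map, fragments, seed = 1L, mapq = 60L) {
  set.seed(seed)
  n <- rep(seq_along(map$i), map$count)
  fi <- map$i[n]; fj <- map$j[n]
  row_i <- match(fi, fragments$frag_id)
  row_j <- match(fj, fragments$frag_id)
  pos1 <- floor(stats::runif(length(fi), fragments$start[row_i],
                             fragments$end[row_i]))
  pos2 <- floor(stats::runif(length(fj), fragments$start[row_j],
                             fragments$end[row_j]))
  data.frame(read_id = sprintf("r%d", seq_along(fi)),
             contig1 = fragments$contig[row_i], pos1 = as.integer(pos1),
             strand1 = sample(c("+", "-"), length(fi), replace = TRUE),
             contig2 = fragments$contig[row_j], pos2 = as.integer(pos2),
             strand2 = sample(c("+", "-"), length(fi), replace = TRUE),
             mapq1 = as.integer(mapq), mapq2 = as.integer(mapq),
             stringsAsFactors = FALSE)
}

#' Simulate a linkage map consistent with the truth
#'
#' Places SNP markers every `marker_every` bp along each chromosome, maps
#' them back to contig coordinates through the truth table, and assigns cM
#' positions proportional to the chromosome position.
#'
#' @param truth truth table from [shred()].
#' @param marker_every marker spacing in chromosome bp (default 5e4).
#' @param cm_per_mb recombination rate in cM per Mb (default 4).
#' @return a linkage map data frame (see [read_linkage_map()]).
#' @export
simulate_linkage_map <- function(truth, marker_every = 5e4, cm_per_mb = 4) {
  out <- list()
  for (ch in unique(truth$chrom)) {
    rows <- truth[truth$chrom == ch, , drop = FALSE]
    L <- max(rows$chrom_end)
    mpos <- seq(marker_every / 2, L - 1, by = marker_every)
    for (k in seq_along(mpos)) {
      p <- mpos[k]
      r <- rows[p >= rows$chrom_start & p < rows$chrom_end, , drop = FALSE][1, ]
      cpos <- if (r$strand == "+") r$contig_start + (p - r$chrom_start)
              else r$contig_start + (r$chrom_end - 1 - p)
      out[[length(out) + 1L]] <- data.frame(
        marker_id = sprintf("m_%s_%d", ch, k), linkage_group = ch,
        cm = p / 1e6 * cm_per_mb, contig = r$contig,
        pos = as.integer(cpos), stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  d[order(d$linkage_group, d$cm), , drop = FALSE]
}

#' Truth genome structure over a map's bins
#'
#' Orders the bins of a (filtered, binned) contact map into the true
#' chromosome arrangement given the shredding truth table: one scaffold per
#' chromosome, contig pieces ordered by true position, bins within a piece
#' in original order (reversed and flipped for `-` pieces).
#'
#' @param map a `contact_map` (any level).
#' @param truth truth table from [shred()].
#' @return a `genome_structure`.
#' @export
truth_structure <- function(map, truth) {
  bins <- map$bins
  frags <- map$fragments
  if (is.null(frags)) stop_("map carries no fragment table")
  centers <- vapply(seq_len(nrow(bins)), function(b) {
    fr <- frags[match(bins$frags[[b]], frags$frag_id), , drop = FALSE]
    (min(fr$start) + max(fr$end)) / 2
  }, numeric(1))
  scaffolds <- list()
  for (ch in unique(truth$chrom)) {
    rows <- truth[truth$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$chrom_start), , drop = FALSE]
    sb <- integer(0)
    for (r in seq_len(nrow(rows))) {
      w <- which(bins$contig == rows$contig[r] &
                 centers >= rows$contig_start[r] &
                 centers < rows$contig_end[r])
      w <- w[order(bins$orig[w])]
      sb <- c(sb, if (rows$strand[r] == "+") w else -rev(w))
    }
    if (length(sb)) scaffolds[[length(scaffolds) + 1L]] <- sb
  }
  genome_structure(scaffolds, bins, frags)
}
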