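# Three-parameter power-law contact model, parameter estimation, and sparse
# Poisson log-likelihood.
#
# The model for the expected contact count between two loci is
#   P(s) = max(A * s^-alpha, delta)   for loci on the same scaffold,
#   P(s) = delta                      for loci on different scaffolds,
# with s the genomic distance. Inside the likelihood, distances are measured
# on a uniform bin grid: s = u * |rank_i - rank_j| with u the mean bin
# length of the map. Bins at a given pyramid level are nearly equal-sized,
# the power law is scale-free, and the grid makes the zero-count term an
# exact function of scaffold sizes, so likelihood differences under bin
# moves are computable incrementally and exactly (see the vignette).

#' Contact-model parameters
#'
#' @param A prefactor: expected count at unit genomic distance.
#' @param alpha decay exponent (> 0).
#' @param delta floor / inter-scaffold expected count per bin pair (> 0).
#' @return an object of class `hic_params`.
#' @export
hic_params <- function(A, alpha, delta) {
  if (!is.numeric(A) || A <= 0) stop_("A must be > 0")
  if (!is.numeric(alpha) || alpha <= 0) stop_("alpha must be > 0")
  if (!is.numeric(delta) || delta <= 0) stop_("delta must be > 0")
  structure(list(A = A, alpha = alpha, delta = delta), class = "hic_params")
}

#' @export
print.hic_params <- function(x, ...) {
  cat(sprintf("hic_params: A = %.6g, alpha = %.4f, delta = %.6g\n",
              x$A, x$alpha, x$delta))
  invisible(x)
}

#' Expected contact count at a genomic distance
#'
#' @param s genomic distance(s) in bp; must be > 0 when `is_intra`.
#' @param params a [hic_params()].
#' @param is_intra whether the two loci lie on the same scaffold.
#' @return expected count(s): `max(A * s^-alpha, delta)` intra, `delta` inter.
#' @export
expected_contact <- function(s, params, is_intra = TRUE) {
  if (!is_intra) return(rep(params$delta, length(s)))
  if (any(s <= 0)) stop_("genomic distance must be > 0 for intra contacts")
  pmax(params$A * s^(-params$alpha), params$delta)
}

#' Genomic distance between two bins of a structure
#'
#' Distance between bin centers from cumulative bin bp lengths along the
#' scaffold (gaps counted as 0 bp). Returns 0 for a bin against itself and
#' `Inf` for bins on different scaffolds ("inter").
#'
#' @param structure a `genome_structure`.
#' @param bin_i,bin_j 0-based bin ids.
#' @export
genomic_distance <- function(structure, bin_i, bin_j) {
  idx <- structure_index(structure)
  bi <- bin_i + 1L; bj <- bin_j + 1L
  if (bi > nrow(structure$bins) || bj > nrow(structure$bins) || bi < 1L || bj < 1L)
    stop_("bin id out of range")
  if (bi == bj) return(0)
  if (idx$scaf[bi] != idx$scaf[bj]) return(Inf)
  sb <- structure$scaffolds[[idx$scaf[bi]]]
  lens <- structure$bins$length_bp[abs(sb)]
  centers <- cumsum(lens) - lens / 2
  abs(centers[idx$rank[bi]] - centers[idx$rank[bj]])
}

# mean bin length used as the grid unit
grid_unit <- function(bins) {
  u <- mean(bins$length_bp)
  if (!is.finite(u) || u <= 0) 1 else u
}

# lambda over grid distances d = 1..maxd
model_lambda <- function(params, u, maxd) {
  if (maxd < 1L) return(numeric(0))
  pmax(params$A * (u * seq_len(maxd))^(-params$alpha), params$delta)
}

# sum of lambda over all intra pairs of a scaffold with S bins:
# F(S) = sum_{d=1}^{S-1} (S-d) * lam[d]
lambda_pair_sums <- function(lam, sizes) {
  if (!length(sizes)) return(0)
  maxS <- max(sizes)
  if (maxS < 2L) return(0)
  c1 <- cumsum(lam[seq_len(maxS - 1L)])
  c2 <- cumsum(seq_len(maxS - 1L) * lam[seq_len(maxS - 1L)])
  s2 <- sizes[sizes >= 2L]
  sum(s2 * c1[s2 - 1L] - c2[s2 - 1L])
}

#' Sparse Poisson log-likelihood of a structure given a contact map
#'
#' Poisson log-likelihood with constant terms dropped:
#' `sum over bin pairs i < j of n_ij * log(lambda_ij) - lambda_ij`, with
#' `lambda_ij` from the contact model at the grid distance between the bins.
#' Self-pairs are excluded. The sum of `lambda` over zero-count pairs is not
#' enumerated: the inter part is `delta` times the number of inter-scaffold
#' pairs and the intra part is an exact function of scaffold sizes.
#'
#' If `eval_map` (the map one pyramid level below, with `parent` links to
#' the bins of `map`) is supplied, the structure is expanded so that each
#' bin is evaluated at sub-bin resolution; a flipped bin then reverses its
#' sub-bin order, which is what makes bin orientation identifiable.
#'
#' @param structure `genome_structure` over the bins of `map`.
#' @param map `contact_map` at the working level.
#' @param params [hic_params()].
#' @param eval_map optional `contact_map` one level below `map`.
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(structure, map, params, eval_map = NULL) {
  if (!is.null(eval_map)) {
    structure <- expand_structure(structure, map, eval_map)
    map <- eval_map
  }
  if (map$n_bins != nrow(structure$bins))
    stop_("map and structure are over different bin sets")
  idx <- structure_index(structure)
  u <- grid_unit(structure$bins)
  N <- map$n_bins
  off <- map$i != map$j
  i1 <- map$i[off] + 1L; j1 <- map$j[off] + 1L; n <- map$count[off]
  intra <- idx$scaf[i1] == idx$scaf[j1]
  d <- abs(idx$rank[i1] - idx$rank[j1])
  sizes <- vapply(structure$scaffolds, length, 1L)
  maxd <- max(c(1L, sizes - 1L))
  lam <- model_lambda(params, u, maxd)
  term_nnz <- sum(n[intra] * log(lam[d[intra]])) +
    sum(n[!intra]) * log(params$delta)
  sum_intra <- lambda_pair_sums(lam, sizes)
  n_inter_pairs <- (N^2 - sum(sizes^2)) / 2
  term_nnz - sum_intra - params$delta * n_inter_pairs
}

#' Expand a structure to sub-bin resolution
#'
#' Replaces each working-level bin by its member bins at the level below
#' (`eval_map`), in order for `+` bins and reversed for `-` bins.
#'
#' @inheritParams log_likelihood
#' @return a `genome_structure` over the bins of `eval_map`.
#' @export
expand_structure <- function(structure, map, eval_map) {
  eb <- eval_map$bins
  if (is.null(eb$parent)) stop_("eval_map carries no parent links")
  if (max(eb$parent) + 1L > nrow(structure$bins))
    stop_("eval_map parents exceed working-level bins")
  children <- split(seq_len(nrow(eb)), eb$parent)  # 1-based rows per parent
  children <- children[as.character(seq_len(nrow(structure$bins)) - 1L)]
  scaffolds <- lapply(structure$scaffolds, function(sb) {
    unlist(lapply(sb, function(x) {
      ch <- children[[abs(x)]]
      if (x > 0) ch else -rev(ch)
    }), use.names = FALSE)
  })
  genome_structure(scaffolds, eb, eval_map$fragments)
}

#' Estimate contact-model parameters from a structure
#'
#' `delta` is the total inter-scaffold count divided by the number of
#' inter-scaffold bin pairs (clamped to >= 1e-9). `A` and `alpha` come from
#' a least-squares fit of `log(mean count)` against `log(s)` over a
#' geometric distance-bin profile built from intra-scaffold pairs of
#' scaffolds with at least `min_scaffold_bins` bins; distance bins whose
#' mean count is not above `2 * delta` (the floor region) are excluded.
#' `alpha` is clamped to (0, 10].
#'
#' @param structure `genome_structure`.
#' @param map `contact_map` over the same bins.
#' @param min_scaffold_bins scaffolds smaller than this are excluded from
#'   the distance profile (default 10).
#' @param n_dist_bins number of geometric distance bins (default 20).
#' @param prev previous `hic_params`, returned unchanged when no scaffold
#'   qualifies.
#' @return a [hic_params()].
#' @export
estimate_parameters <- function(structure, map, min_scaffold_bins = 10L,
                                n_dist_bins = 20L, prev = NULL) {
  if (map$n_bins != nrow(structure$bins))
    stop_("map and structure are over different bin sets")
  idx <- structure_index(structure)
  u <- grid_unit(structure$bins)
  N <- map$n_bins
  sizes <- vapply(structure$scaffolds, length, 1L)

  off <- map$i != map$j
  i1 <- map$i[off] + 1L; j1 <- map$j[off] + 1L; n <- map$count[off]
  intra <- idx$scaf[i1] == idx$scaf[j1]
  n_inter_pairs <- (N^2 - sum(sizes^2)) / 2
  inter_count <- sum(n[!intra])
  # delta is the trans level: the expected count between bins of different
  # chromosomes. While scaffolding is incomplete, many cross-scaffold cells
  # actually join pieces of one chromosome and would inflate a plain mean
  # by orders of magnitude, so delta is estimated from the Poisson zero
  # fraction (P(0) = exp(-delta)) of cross-scaffold cells, iteratively
  # excluding scaffold pairs whose non-zero cell rate reveals them as
  # linked (rate > 5x the current floor estimate).
  delta <- 1e-9
  if (n_inter_pairs > 0) {
    if (sum(!intra) >= n_inter_pairs) {
      delta <- max(inter_count / n_inter_pairs, 1e-9)
    } else {
      ns <- length(sizes)
      key <- function(a, b) pmin(a, b) * (ns + 1L) + pmax(a, b)
      nz <- table(key(idx$scaf[i1][!intra], idx$scaf[j1][!intra]))
      pair_a <- rep(seq_len(ns), times = ns)
      pair_b <- rep(seq_len(ns), each = ns)
      sel <- pair_a < pair_b
      pk <- key(pair_a[sel], pair_b[sel])
      cells <- as.numeric(sizes[pair_a[sel]]) * sizes[pair_b[sel]]
      nzc <- numeric(length(pk))
      hit <- match(as.character(pk), names(nz))
      nzc[!is.na(hit)] <- as.numeric(nz[hit[!is.na(hit)]])
      # seed with the cell-weighted median per-pair rate, which sits in the
      # trans mass as long as most scaffold pairs are cross-chromosome
      rate <- nzc / cells
      o <- order(rate)
      med_rate <- rate[o][which(cumsum(cells[o]) >= sum(cells) / 2)[1]]
      est <- max(-log1p(-min(med_rate, 0.999)), 1e-9)
      for (it in 1:10) {
        keep <- nzc / cells <= 5 * est | cells < 4
        if (!any(keep)) break
        new_est <- max(-log1p(-sum(nzc[keep]) / sum(cells[keep])), 1e-9)
        if (abs(new_est - est) <= 1e-3 * est) { est <- new_est; break }
        est <- new_est
      }
      delta <- est
    }
  }

  qual <- which(sizes >= min_scaffold_bins)
  if (!length(qual)) {
    if (!is.null(prev)) return(prev)
    stop_("no scaffold with >= ", min_scaffold_bins, " bins")
  }
  qs <- sizes[qual]
  maxd <- max(qs) - 1L
  if (maxd < 1L) stop_("insufficient signal: no intra-scaffold pairs")
  # pairs available at each grid distance d, over qualifying scaffolds
  dseq <- seq_len(maxd)
  npairs_d <- vapply(dseq, function(d) sum(pmax(qs - d, 0L)), numeric(1))
  # observed counts at each distance (qualifying scaffolds only)
  qset <- logical(length(sizes)); qset[qual] <- TRUE
  use <- intra & qset[idx$scaf[i1]]
  d <- abs(idx$rank[i1] - idx$rank[j1])[use]
  cnt_d <- numeric(maxd)
  if (length(d)) {
    t <- tapply(n[use], d, sum)
    cnt_d[as.integer(names(t))] <- as.numeric(t)
  }
  # geometric distance bins over s = u * d
  breaks <- exp(seq(log(1), log(maxd + 1), length.out = n_dist_bins + 1L))
  grp <- findInterval(dseq, breaks, rightmost.closed = TRUE)
  np <- rowsum(npairs_d, grp)
  nc <- rowsum(cnt_d, grp)
  ls <- rowsum(npairs_d * log(u * dseq), grp)
  ok <- np[, 1] > 0
  mean_cnt <- nc[ok, 1] / np[ok, 1]
  mean_logs <- ls[ok, 1] / np[ok, 1]
  # exclude the floor region from the power-law fit: below twice the floor
  # level, taken as the larger of the inter-scaffold delta and the level
  # of the most distant part of the profile itself (the latter matters
  # when the map has a single scaffold and delta is unidentified)
  pos <- which(mean_cnt > 0)
  tail_floor <- if (length(pos)) mean_cnt[max(pos)] else 0
  usable <- mean_cnt > 2 * max(delta, tail_floor)
  if (sum(usable) < 2L) stop_("insufficient signal: fewer than 2 usable distance bins")
  fit <- stats::lm(log(mean_cnt[usable]) ~ mean_logs[usable])
  alpha <- -unname(stats::coef(fit)[2])
  alpha <- min(max(alpha, 1e-3), 10)
  A <- exp(unname(stats::coef(fit)[1]))
  hic_params(A = A, alpha = alpha, delta = delta)
}

#' Incremental log-likelihood change under a mutation
#'
#' Computes `log_likelihood(after) - log_likelihood(before)` without a full
#' recomputation: only non-zero pairs involving the moved bin's (sub-)bins
#' and pairs whose grid distance shifts across the removal/insertion cuts
#' are touched; the zero-count term changes analytically with scaffold
#' sizes.
#'
#' @inheritParams log_likelihood
#' @param mutation a [mutation()].
#' @return numeric scalar delta log-likelihood.
#' @export
delta_log_likelihood <- function(structure, map, params, mutation,
                                 eval_map = NULL) {
  eng <- build_engine(structure, map, eval_map)
  engine_set_params(eng, params)
  cand <- encode_mutations(list(mutation))
  eng_deltas(eng$ptr, cand)[1]
}
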