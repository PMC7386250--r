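# Assembly contiguity metrics and truth-based accuracy scoring.

#' Nx / Lx contiguity metrics
#'
#' `Nx` is the length of the scaffold at which the cumulative sum of
#' descending-sorted lengths first reaches x% of the assembly total (of
#' `reference_total` for NGx); `Lx` is the number of scaffolds needed.
#' Ties are inclusive ("first reaches >= x%").
#'
#' @param lengths positive scaffold lengths.
#' @param x percentages (default c(50, 75)).
#' @param reference_total optional reference genome length for NGx/LGx.
#' @return named list: `N50`, `L50`, ... and `NG50`, `LG50`, ... when a
#'   reference total is given.
#' @export
nx_metrics <- function(lengths, x = c(50, 75), reference_total = NULL) {
  if (!length(lengths) || any(lengths <= 0))
    stop_("lengths must be non-empty and positive")
  if (!is.null(reference_total) && reference_total <= 0)
    stop_("reference_total must be positive")
  sl <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(sl)
  one <- function(total, xx) {
    thr <- total * xx / 100
    k <- which(cs >= thr)[1]
    if (is.na(k)) list(N = NA_real_, L = NA_integer_)
    else list(N = sl[k], L = k)
  }
  out <- list()
  for (xx in x) {
    r <- one(sum(sl), xx)
    out[[sprintf("N%d", xx)]] <- r$N
    out[[sprintf("L%d", xx)]] <- r$L
  }
  if (!is.null(reference_total)) {
    for (xx in x) {
      r <- one(reference_total, xx)
      out[[sprintf("NG%d", xx)]] <- r$N
      out[[sprintf("LG%d", xx)]] <- r$L
    }
  }
  out$scaffold_count <- length(lengths)
  out$total_bp <- sum(lengths)
  out
}

# canonical keys of the oriented adjacencies of a structure
adjacency_keys <- function(structure) {
  keys <- character(0)
  for (sb in structure$scaffolds) {
    if (length(sb) < 2L) next
    a <- sb[-length(sb)]; b <- sb[-1L]
    # a pair (a, b) is equivalent to its reversal (-b, -a)
    swap <- abs(b) < abs(a)
    ca <- ifelse(swap, -b, a)
    cb <- ifelse(swap, -a, b)
    keys <- c(keys, paste(ca, cb, sep = "|"))
  }
  keys
}

#' Junction accuracy of a predicted structure against the truth
#'
#' The fraction of adjacent bin pairs of the truth that are adjacent in the
#' prediction with compatible relative orientation. Whole-scaffold
#' reversals and scaffold reordering are ignored by construction.
#'
#' @param predicted,truth `genome_structure`s over the same bins.
#' @return fraction in `[0, 1]`.
#' @export
junction_accuracy <- function(predicted, truth) {
  if (nrow(predicted$bins) != nrow(truth$bins))
    stop_("structures are over different bin sets")
  tk <- adjacency_keys(truth)
  if (!length(tk)) return(1)
  pk <- adjacency_keys(predicted)
  mean(tk %in% pk)
}

#' Scaffold size summary and rank ratio
#'
#' Descending scaffold sizes in bp plus the ratio of the k-th largest to
#' the (k+1)-th: a large ratio at the expected chromosome count indicates
#' that the main scaffolds dominate the residue.
#'
#' @param structure a `genome_structure`.
#' @param rank optional rank at which to report the size ratio.
#' @return list with `sizes` (descending bp) and, when `rank` is given,
#'   `ratio` = sizes[rank] / sizes[rank + 1].
#' @export
scaffold_size_summary <- function(structure, rank = NULL) {
  sizes <- sort(scaffold_lengths(structure), decreasing = TRUE)
  out <- list(sizes = sizes)
  if (!is.null(rank)) {
    if (rank < 1L || rank + 1L > length(sizes))
      stop_("rank out of range: need at least ", rank + 1L, " scaffolds")
    out$ratio <- sizes[rank] / sizes[rank + 1L]
  }
  out
}
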