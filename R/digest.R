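# In-silico restriction digestion and read-pair assignment.

#' Digest contigs at a restriction site
#'
#' Cuts every contig at the start index of each occurrence of `site`
#' (overlapping occurrences included). Fragments are the intervals between
#' consecutive cut positions and the contig ends; a contig without any site
#' yields a single fragment. The cut convention (cut at site start rather
#' than at an enzyme-specific overhang offset) shifts all fragment
#' boundaries by a constant and is irrelevant to the contact model.
#'
#' @param sequences `DNAStringSet` or named character vector of contigs.
#' @param site recognition sequence over A/C/G/T (default `"GATC"`, DpnII).
#' @return a fragment table: `frag_id` (0-based global index), `contig`,
#'   `start`, `end` (0-based, half-open), `length`, `coverage` (0 until
#'   [compute_coverage()]), `filtered`.
#' @export
digest_genome <- function(sequences, site = "GATC") {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_("sequences must be uniquely named")
  if (!nzchar(site) || grepl("[^ACGT]", site)) stop_("invalid restriction site")
  rows <- lapply(names(sequences), function(nm) {
    s <- sequences[[nm]]
    L <- nchar(s)
    if (L == 0L) stop_("empty sequence: ", nm)
    hits <- gregexpr(paste0("(?=", site, ")"), s, perl = TRUE)[[1]]
    cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < L], L))
    data.frame(contig = nm, start = bounds[-length(bounds)],
               end = bounds[-1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start
  out$coverage <- 0
  out$filtered <- FALSE
  out <- cbind(frag_id = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  out
}

#' Assign aligned read pairs to restriction fragments
#'
#' Builds the level-0 contact map: each read pair passing the mapping-quality
#' filter increments the count of the (ordered) pair of fragments containing
#' its two positions. Pairs mapping within one fragment increment the
#' diagonal (the likelihood later excludes self-pairs).
#'
#' @param pairs data frame from [read_pairs()].
#' @param fragments fragment table from [digest_genome()].
#' @param min_mapq minimum mapping quality; pairs with either mate below it
#'   are dropped (default 30).
#' @param dedup drop exact coordinate/strand duplicate pairs (default FALSE;
#'   PCR duplicates are normally removed upstream).
#' @return list with `map` (level-0 [contact_map()]) and `counters`
#'   (`kept`, `dropped_mapq`, `dropped_unknown_contig`,
#'   `dropped_unknown_coordinate`).
#' @export
assign_pairs <- function(pairs, fragments, min_mapq = 30L, dedup = FALSE) {
  assert_fragment_table(fragments)
  n_in <- nrow(pairs)
  if (dedup && n_in) {
    key <- paste(pairs$contig1, pairs$pos1, pairs$strand1,
                 pairs$contig2, pairs$pos2, pairs$strand2)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  n_dup <- n_in - nrow(pairs)
  ok_q <- pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  dropped_mapq <- sum(!ok_q)
  pairs <- pairs[ok_q, , drop = FALSE]

  contigs <- unique(fragments$contig)
  known <- pairs$contig1 %in% contigs & pairs$contig2 %in% contigs
  dropped_ctg <- sum(!known)
  pairs <- pairs[known, , drop = FALSE]

  # fragment containing a position, per contig
  locate <- function(contig, pos) {
    out <- rep(NA_integer_, length(pos))
    for (ct in unique(contig)) {
      sel <- contig == ct
      fr <- fragments[fragments$contig == ct, , drop = FALSE]
      idx <- findInterval(pos[sel], fr$start)
      inside <- idx >= 1L & pos[sel] < fr$end[pmax(idx, 1L)]
      out[sel][inside] <- fr$frag_id[idx[inside]]
    }
    out
  }
  f1 <- locate(pairs$contig1, pairs$pos1)
  f2 <- locate(pairs$contig2, pairs$pos2)
  bad <- is.na(f1) | is.na(f2)
  dropped_coord <- sum(bad)
  f1 <- f1[!bad]; f2 <- f2[!bad]
  i <- pmin(f1, f2); j <- pmax(f1, f2)
  bins <- fragment_bins(fragments)
  map <- if (length(i)) contact_map(i, j, rep(1, length(i)), bins,
                                    level = 0L, fragments = fragments)
         else contact_map(integer(0), integer(0), numeric(0), bins,
                          level = 0L, fragments = fragments)
  list(map = map,
       counters = c(kept = length(i), dropped_mapq = dropped_mapq,
                    dropped_unknown_contig = dropped_ctg,
                    dropped_unknown_coordinate = dropped_coord,
                    dropped_duplicate = n_dup))
}

#' Per-fragment contact coverage
#'
#' Coverage of fragment i is the symmetric row sum of the level-0 contact
#' map, with the diagonal counted once.
#'
#' @param map level-0 `contact_map` over the fragments.
#' @param fragments fragment table.
#' @return the fragment table with its `coverage` column filled in.
#' @export
compute_coverage <- function(map, fragments) {
  assert_fragment_table(fragments)
  if (map$n_bins != nrow(fragments))
    stop_("map and fragment table disagree on fragment count")
  cov <- numeric(nrow(fragments))
  off <- map$i != map$j
  for (side in list(map$i[off], map$j[off])) {
    t <- tapply(map$count[off], side, sum)
    cov[as.integer(names(t)) + 1L] <- cov[as.integer(names(t)) + 1L] + as.numeric(t)
  }
  diag <- !off
  if (any(diag)) {
    t <- tapply(map$count[diag], map$i[diag], sum)
    cov[as.integer(names(t)) + 1L] <- cov[as.integer(names(t)) + 1L] + as.numeric(t)
  }
  fragments$coverage <- cov
  fragments
}
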