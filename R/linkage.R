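# Genetic linkage-map validation and correction of a scaffolded structure.
# Linkage groups provide an independent marker-order oracle: a consistent
# structure needs zero changes (validation); otherwise marker-bearing bins
# are relocated parsimoniously (correction).

# map each marker to the placed bin containing its position; markers on
# filtered fragments are dropped with a warning
markers_to_bins <- function(structure, linkage) {
  frags <- structure$fragments
  if (is.null(frags)) stop_("structure carries no fragment table")
  bins <- structure$bins
  frag2bin <- rep(NA_integer_, max(frags$frag_id) + 1L)
  for (b in seq_len(nrow(bins)))
    frag2bin[bins$frags[[b]] + 1L] <- b
  bin <- rep(NA_integer_, nrow(linkage))
  for (r in seq_len(nrow(linkage))) {
    fr <- frags[frags$contig == linkage$contig[r], , drop = FALSE]
    hit <- fr$frag_id[linkage$pos[r] >= fr$start & linkage$pos[r] < fr$end]
    if (length(hit) == 1L) bin[r] <- frag2bin[hit + 1L]
  }
  if (anyNA(bin))
    warning(sum(is.na(bin)), " marker(s) on filtered or unknown fragments ignored")
  cbind(linkage, bin = bin - 1L)[!is.na(bin), , drop = FALSE]
}

#' Pair linkage groups with scaffolds
#'
#' Each linkage group is paired with the scaffold containing the largest
#' number of its markers (ties toward the larger scaffold); groups or
#' scaffolds with zero overlap stay unpaired and are left untouched
#' downstream.
#'
#' @param structure a `genome_structure` (with its fragment table).
#' @param linkage a linkage map (see [read_linkage_map()]).
#' @return data frame with columns `linkage_group`, `scaffold` (1-based
#'   index), `n_markers`.
#' @export
linkage_match <- function(structure, linkage) {
  mk <- markers_to_bins(structure, linkage)
  idx <- structure_index(structure)
  sizes <- scaffold_lengths(structure)
  out <- list()
  for (lg in unique(mk$linkage_group)) {
    sel <- mk[mk$linkage_group == lg, , drop = FALSE]
    sca <- idx$scaf[sel$bin + 1L]
    tb <- table(sca)
    cand <- as.integer(names(tb))
    best <- cand[order(-as.numeric(tb), -sizes[cand])][1]
    out[[length(out) + 1L]] <-
      data.frame(linkage_group = lg, scaffold = best,
                 n_markers = as.integer(tb[as.character(best)]))
  }
  do.call(rbind, out)
}

# longest non-decreasing (dir > 0) or non-increasing subsequence, O(k^2);
# returns indices of one optimal subsequence
longest_monotone <- function(v, dir) {
  k <- length(v)
  if (k == 0L) return(integer(0))
  best <- rep(1L, k); prev <- rep(0L, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      ok <- if (dir > 0) v[j] <= v[i] else v[j] >= v[i]
      if (ok && best[j] + 1L > best[i]) { best[i] <- best[j] + 1L; prev[i] <- j }
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Validate or correct a structure against a linkage map
#'
#' For every (linkage group, scaffold) pair, the cM order of the markers is
#' projected onto the order of the marker-bearing bins; the longest
#' already-consistent subsequence (in either direction, since the linkage
#' group's orientation is free) is kept, and the remaining marker-bearing
#' bins, including any placed on other scaffolds, count as needed changes.
#' In `correct` mode those bins are relocated to cM-consistent positions in
#' the paired scaffold; bins without markers are never moved. A change
#' count of zero means the structure is fully consistent with the map.
#'
#' @param structure a `genome_structure`.
#' @param linkage a linkage map.
#' @param mode `"validate"` (count only) or `"correct"` (also relocate).
#' @param pairs optional precomputed [linkage_match()] result.
#' @return list with `structure` (corrected in `correct` mode, input
#'   otherwise) and `changes` (total change count).
#' @export
linkage_apply <- function(structure, linkage, mode = c("validate", "correct"),
                          pairs = NULL) {
  mode <- match.arg(mode)
  if (mode == "correct") {
    # iterate to a fixpoint: block reordering can leave a boundary marker
    # one block off; subsequent passes are cheap and strictly reduce the
    # remaining inconsistency. The reported change count is the first
    # pass's (the number of changes the input structure needed).
    first <- linkage_apply_once(structure, linkage, "correct", pairs)
    cur <- first$structure
    for (pass in 2:5) {
      v <- linkage_apply_once(cur, linkage, "validate", NULL)
      if (v$changes == 0L) break
      nxt <- linkage_apply_once(cur, linkage, "correct", NULL)
      if (nxt$changes >= v$changes && pass > 2) break
      cur <- nxt$structure
    }
    return(list(structure = cur, changes = first$changes))
  }
  linkage_apply_once(structure, linkage, mode, pairs)
}

linkage_apply_once <- function(structure, linkage,
                               mode = c("validate", "correct"),
                               pairs = NULL) {
  mode <- match.arg(mode)
  mk <- suppressWarnings(markers_to_bins(structure, linkage))
  pairs_given <- !is.null(pairs)
  if (!pairs_given) pairs <- linkage_match(structure, linkage)
  changes <- 0L
  sc <- structure$scaffolds
  for (r in seq_len(nrow(pairs))) {
    lg <- pairs$linkage_group[r]
    sel <- mk[mk$linkage_group == lg, , drop = FALSE]
    # one cM value per marked bin (median over its markers)
    cm_by_bin <- vapply(split(sel$cm, sel$bin), stats::median, numeric(1))
    marked <- as.integer(names(cm_by_bin))
    idx <- structure_index(genome_structure(sc, structure$bins,
                                            structure$fragments))
    s <- if (pairs_given) pairs$scaffold[r] else {
      # re-derive against the current (possibly already edited) scaffolds
      tb <- table(idx$scaf[marked + 1L])
      as.integer(names(tb))[which.max(tb)]
    }
    inside <- marked[idx$scaf[marked + 1L] == s]
    outside <- marked[idx$scaf[marked + 1L] != s]
    ord <- order(idx$rank[inside + 1L])
    inside <- inside[ord]
    v <- unname(cm_by_bin[as.character(inside)])
    up <- longest_monotone(v, +1L)
    down <- longest_monotone(v, -1L)
    keep <- if (length(up) >= length(down)) up else down
    moved <- length(inside) - length(keep) + length(outside)
    changes <- changes + moved
    if (mode == "correct" && moved > 0L) {
      # work on an ascending target: reverse the scaffold first when the
      # marker order is predominantly descending
      if (length(down) > length(up)) {
        sc[[s]] <- -rev(sc[[s]])
        idx <- structure_index(genome_structure(sc, structure$bins,
                                                structure$fragments))
        inside <- rev(inside)
        v <- rev(v)
      }
      # pull translocated bins out of other scaffolds; they rejoin as
      # singleton blocks
      for (b in outside) {
        sb <- idx$scaf[b + 1L]
        sc[[sb]] <- sc[[sb]][abs(sc[[sb]]) != b + 1L]
      }
      keep_first <- abs(sc[[s]][1])  # re-locate after possible drops
      sc <- sc[lengths(sc) > 0L]
      s_now <- which(vapply(sc, function(x) any(abs(x) == keep_first), TRUE))[1]
      vsc <- sc[[s_now]]
      pos_marked <- match(inside + 1L, abs(vsc))
      # segment the marker sequence into maximal monotone runs; descending
      # runs are whole flipped segments
      k <- length(v)
      blk <- integer(k); dirb <- integer(0)
      cur <- 1L; dcur <- 0L
      blk[1] <- 1L
      for (z in seq_len(k - 1L)) {
        step <- sign(v[z + 1L] - v[z])
        if (dcur == 0L || step == 0L || step == dcur) {
          if (dcur == 0L && step != 0L) dcur <- step
        } else {
          dirb[cur] <- dcur
          cur <- cur + 1L
          dcur <- 0L
        }
        blk[z + 1L] <- cur
      }
      dirb[cur] <- if (dcur == 0L) 1L else dcur
      # bin-position span of each block: from its first marked bin to just
      # before the next block's first marked bin (interstitial unmarked
      # bins travel with the block to their left); the scaffold prefix
      # before the first marker stays in front
      starts <- pos_marked[!duplicated(blk)]
      ends <- c(starts[-1L] - 1L, length(vsc))
      segs <- lapply(seq_len(cur), function(q) {
        seg <- vsc[starts[q]:ends[q]]
        if (dirb[q] < 0L) -rev(seg) else seg
      })
      med_cm <- vapply(split(v, blk), stats::median, numeric(1))
      new_vsc <- c(if (starts[1] > 1L) vsc[1:(starts[1] - 1L)] else integer(0),
                   unlist(segs[order(med_cm)], use.names = FALSE))
      # reinsert translocated bins at their cM-consistent position
      # second stage: blocks fix large flips/rotations; any marker still
      # out of sequence (typically a block-boundary stray) plus the
      # translocated bins are relocated individually to their cM slot
      mp <- match(inside + 1L, abs(new_vsc))
      srt <- order(mp)
      ins_sorted <- inside[srt]; v_sorted <- v[srt]
      lis <- longest_monotone(v_sorted, +1L)
      stray <- ins_sorted[setdiff(seq_along(ins_sorted), lis)]
      pool <- c(stray, outside)
      if (length(pool)) {
        new_vsc <- new_vsc[!abs(new_vsc) %in% (stray + 1L)]
        kept_bins <- setdiff(ins_sorted, stray)
        kept_cm <- unname(cm_by_bin[as.character(kept_bins)])
        pool_cm <- unname(cm_by_bin[as.character(pool)])
        for (z in order(pool_cm)) {
          b <- pool[z]
          mp2 <- match(kept_bins + 1L, abs(new_vsc))
          srt2 <- order(mp2)
          w <- which(kept_cm[srt2] <= pool_cm[z])
          at <- if (length(w)) mp2[srt2][max(w)] else mp2[srt2][1] - 1L
          new_vsc <- append(new_vsc, b + 1L, after = at)
        }
      }
      sc[[s_now]] <- new_vsc
    }
  }
  out_structure <- if (mode == "correct")
    genome_structure(sc, structure$bins, structure$fragments)
  else structure
  list(structure = out_structure, changes = changes)
}
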