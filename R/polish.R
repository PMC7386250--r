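# Post-scaffolding correction: consensus reorientation, rearrangement of
# split contigs, reinsertion of filtered fragments, a misassembly proxy
# report, and genetic linkage-map validation/correction.
#
# The correction trusts the input contigs: single-bin flips and relocations
# introduced by the sampler are treated as mistakes and the original local
# contig structure is reinstated while preserving the scaffold-level
# arrangement.

# maximal runs of same-contig bins: data frame (scaffold, from, to, contig,
# n) with 1-based positions within the scaffold
contig_runs <- function(structure) {
  out <- list(); z <- 0L
  for (s in seq_along(structure$scaffolds)) {
    sb <- structure$scaffolds[[s]]
    ct <- structure$bins$contig[abs(sb)]
    brk <- c(TRUE, ct[-1L] != ct[-length(ct)])
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      w <- which(grp == g)
      z <- z + 1L
      out[[z]] <- data.frame(scaffold = s, from = w[1], to = w[length(w)],
                             contig = ct[w[1]], n = length(w),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# rewrite one run as a clean block: original-rank order, uniform
# orientation; direction = majority of bin orientations, ties forward
clean_block <- function(signed, orig) {
  dir <- if (sum(sign(signed)) < 0) -1L else 1L
  o <- order(orig)
  if (dir > 0) abs(signed)[o] else -rev(abs(signed)[o])
}

#' Reorient bins to their original consensus orientation
#'
#' For each maximal run of same-contig bins within a scaffold, takes a
#' majority vote over the bins' orientations (ties forward) and rewrites
#' the run in original-rank order, all forward for a forward majority or
#' rank-reversed all-reverse for a reverse majority. Single-bin flips and
#' order scrambles inside a run are thereby healed.
#'
#' @param structure a `genome_structure`.
#' @return the corrected `genome_structure`.
#' @export
reorient <- function(structure) {
  sc <- structure$scaffolds
  runs <- contig_runs(structure)
  for (r in seq_len(nrow(runs))) {
    s <- runs$scaffold[r]
    w <- runs$from[r]:runs$to[r]
    signed <- sc[[s]][w]
    orig <- structure$bins$orig[abs(signed)]
    sc[[s]][w] <- clean_block(signed, orig)
  }
  genome_structure(sc, structure$bins, structure$fragments)
}

#' Gather split contigs next to their largest run
#'
#' For every input contig present as more than one maximal run, the largest
#' run (by bin count; ties toward the run containing the lowest original
#' rank) anchors the contig: all other runs are removed and the anchor is
#' rewritten as the full block of the contig's placed bins in original-rank
#' order, oriented with the anchor's majority direction. Emptied scaffolds
#' are deleted.
#'
#' @param structure a `genome_structure`.
#' @return the corrected `genome_structure`.
#' @export
rearrange <- function(structure) {
  repeat {
    runs <- contig_runs(structure)
    split_contigs <- names(which(table(runs$contig) > 1))
    # removing a run from between two runs of another contig makes those
    # adjacent; a final consensus pass keeps the composition with
    # reorient() a fixpoint
    if (!length(split_contigs)) return(reorient(structure))
    ct <- split_contigs[1]
    rr <- runs[runs$contig == ct, , drop = FALSE]
    sc <- structure$scaffolds
    # anchor: most bins; ties -> run containing the lowest original rank
    minrank <- vapply(seq_len(nrow(rr)), function(q) {
      signed <- sc[[rr$scaffold[q]]][rr$from[q]:rr$to[q]]
      min(structure$bins$orig[abs(signed)])
    }, numeric(1))
    a <- order(-rr$n, minrank)[1]
    anchor_signed <- sc[[rr$scaffold[a]]][rr$from[a]:rr$to[a]]
    dir <- if (sum(sign(anchor_signed)) < 0) -1L else 1L
    # gather every placed bin of the contig
    all_signed <- unlist(lapply(seq_len(nrow(rr)), function(q)
      sc[[rr$scaffold[q]]][rr$from[q]:rr$to[q]]))
    orig <- structure$bins$orig[abs(all_signed)]
    block <- if (dir > 0) abs(all_signed)[order(orig)]
             else -rev(abs(all_signed)[order(orig)])
    # drop every run of the contig, keeping a placeholder at the anchor's
    # first position, then splice the gathered block there
    drop <- lapply(sc, function(v) logical(length(v)))
    for (q in seq_len(nrow(rr)))
      drop[[rr$scaffold[q]]][rr$from[q]:rr$to[q]] <- TRUE
    sa <- rr$scaffold[a]
    sc[[sa]][rr$from[a]] <- NA_integer_
    drop[[sa]][rr$from[a]] <- FALSE
    for (s in unique(rr$scaffold)) sc[[s]] <- sc[[s]][!drop[[s]]]
    spos <- which(is.na(sc[[sa]]))
    sc[[sa]] <- append(sc[[sa]][-spos], block, after = spos - 1L)
    sc <- sc[lengths(sc) > 0L]
    structure <- genome_structure(sc, structure$bins, structure$fragments)
  }
}

#' Reinsert filtered fragments into the corrected structure
#'
#' Each run of filtered fragments that was adjacent (in original contig
#' order) to a placed fragment is inserted back at the corresponding
#' junction or scaffold extremity with matching orientation; fragments of
#' fully filtered contigs become standalone single-bin scaffolds appended
#' after all others, in input order.
#'
#' @param structure a corrected `genome_structure` (after [reorient()] and
#'   [rearrange()]).
#' @param filter_report the `filter_report` from [filter_fragments()].
#' @param fragments the full level-0 fragment table (with `filtered` flags).
#' @return a `genome_structure` over an extended bin table.
#' @export
reinsert_filtered <- function(structure, filter_report, fragments) {
  assert_fragment_table(fragments)
  removed <- sort(c(filter_report$removed_short,
                    filter_report$removed_low_coverage,
                    filter_report$removed_orphaned))
  if (!length(removed)) return(structure)
  bins <- structure$bins
  sc <- structure$scaffolds
  # fragment -> placed bin lookup
  frag2bin <- rep(NA_integer_, max(fragments$frag_id) + 1L)
  for (b in seq_len(nrow(bins)))
    frag2bin[bins$frags[[b]] + 1L] <- b
  idx <- structure_index(structure)

  new_rows <- list()
  standalone <- list()
  add_bin <- function(fids, contig) {
    fr <- fragments[match(fids, fragments$frag_id), , drop = FALSE]
    row <- data.frame(bin = NA_integer_, contig = contig, orig = NA_integer_,
                      length_bp = sum(fr$length), n_frag = length(fids),
                      frags = I(list(fids)), stringsAsFactors = FALSE)
    for (extra in setdiff(names(bins), names(row))) row[[extra]] <- NA
    row[names(bins)]
  }

  for (ct in unique(fragments$contig)) {
    fr <- fragments[fragments$contig == ct, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    filt <- fr$filtered
    if (!any(filt)) next
    if (all(filt)) {
      standalone[[length(standalone) + 1L]] <- add_bin(fr$frag_id, ct)
      next
    }
    runs <- rle(filt)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (q in which(runs$values)) {
      fids <- fr$frag_id[starts[q]:ends[q]]
      left <- if (starts[q] > 1L) fr$frag_id[starts[q] - 1L] else NA
      right <- if (ends[q] < nrow(fr)) fr$frag_id[ends[q] + 1L] else NA
      nb <- add_bin(fids, ct)
      # neighbor placed bin: prefer the left one
      nbr <- if (!is.na(left)) frag2bin[left + 1L] else frag2bin[right + 1L]
      use_left <- !is.na(left)
      new_rows[[length(new_rows) + 1L]] <-
        list(row = nb, nbr = nbr, use_left = use_left)
    }
  }

  insert_next_to <- function(sc, bins_n, nbr, use_left, new_id) {
    s <- idx$scaf[nbr]; p0 <- which(abs(sc[[s]]) == nbr)
    ori <- sign(sc[[s]][p0])
    # going rightward on the contig from a '+' neighbor means after it;
    # from a '-' neighbor it means before it (and the new bin is '-')
    after_flag <- (use_left && ori > 0) || (!use_left && ori < 0)
    val <- ori * new_id
    append(sc[[s]], val, after = if (after_flag) p0 else p0 - 1L)
  }

  for (nr in new_rows) {
    new_id <- nrow(bins) + 1L
    row <- nr$row; row$bin <- new_id - 1L
    bins <- rbind(bins, row)
    s <- idx$scaf[nr$nbr]
    sc[[s]] <- insert_next_to(sc, bins, nr$nbr, nr$use_left, new_id)
  }
  for (srow in standalone) {
    new_id <- nrow(bins) + 1L
    srow$bin <- new_id - 1L
    bins <- rbind(bins, srow)
    sc[[length(sc) + 1L]] <- new_id
  }
  rownames(bins) <- NULL
  genome_structure(sc, bins, fragments)
}

#' Misassembly proxy report
#'
#' Compares a structure against its input contigs: an inversion per maximal
#' block of bins whose orientation disagrees with its run's majority
#' direction; a relocation per original-rank discontinuity between
#' consecutive bins of a run; a split per extra maximal run of a contig
#' beyond the first. Zero counts mean the structure preserves every input
#' contig's local order and orientation.
#'
#' @param structure a `genome_structure`.
#' @return object of class `misassembly_report`: counts plus a data frame
#'   of offending (contig, bin) records.
#' @export
misassembly_report <- function(structure) {
  runs <- contig_runs(structure)
  inversions <- 0L; relocations <- 0L; splits <- 0L
  offenders <- list()
  for (r in seq_len(nrow(runs))) {
    sb <- structure$scaffolds[[runs$scaffold[r]]][runs$from[r]:runs$to[r]]
    orig <- structure$bins$orig[abs(sb)]
    dir <- if (sum(sign(sb)) < 0) -1L else 1L
    bad <- sign(sb) != dir
    if (any(bad)) {
      blocks <- sum(diff(c(FALSE, bad)) == 1L)
      inversions <- inversions + blocks
      offenders[[length(offenders) + 1L]] <-
        data.frame(contig = runs$contig[r], bin = abs(sb)[bad] - 1L,
                   type = "inversion", stringsAsFactors = FALSE)
    }
    if (length(sb) > 1L) {
      steps <- diff(orig)
      wrong <- steps != dir
      if (any(wrong)) {
        relocations <- relocations + sum(wrong)
        offenders[[length(offenders) + 1L]] <-
          data.frame(contig = runs$contig[r],
                     bin = abs(sb)[-1L][wrong] - 1L,
                     type = "relocation", stringsAsFactors = FALSE)
      }
    }
  }
  extra <- table(runs$contig) - 1L
  splits <- sum(extra)
  if (splits > 0) {
    for (ct in names(extra)[extra > 0])
      offenders[[length(offenders) + 1L]] <-
        data.frame(contig = ct, bin = NA_integer_, type = "split",
                   stringsAsFactors = FALSE)
  }
  structure(list(intra_contig_inversions = inversions,
                 intra_contig_relocations = relocations,
                 contig_splits = splits,
                 records = if (length(offenders)) do.call(rbind, offenders)
                           else data.frame(contig = character(),
                                           bin = integer(),
                                           type = character())),
            class = "misassembly_report")
}

#' @export
print.misassembly_report <- function(x, ...) {
  cat(sprintf("misassembly_report: %d inversions, %d relocations, %d splits\n",
              x$intra_contig_inversions, x$intra_contig_relocations,
              x$contig_splits))
  invisible(x)
}

#' Total misassembly count of a report
#' @param report a `misassembly_report`.
#' @export
misassembly_total <- function(report) {
  report$intra_contig_inversions + report$intra_contig_relocations +
    report$contig_splits
}
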