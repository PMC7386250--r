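# Fragment filtering and recursive sum-pooling of the contact map.

#' Filter fragments by length and coverage
#'
#' Two-step filter applied once at level 0: (1) fragments shorter than
#' `min_len` bp are removed; (2) the mean and population standard deviation
#' of coverage are computed over the remaining fragments and fragments with
#' coverage strictly below `mean - cov_sd_k * sd` are removed. Survivors are
#' re-indexed densely.
#'
#' @param map0 level-0 `contact_map` over all fragments.
#' @param fragments fragment table with coverage (see [compute_coverage()]).
#' @param min_len minimum fragment length in bp (default 50).
#' @param cov_sd_k number of standard deviations below the mean for the
#'   coverage cutoff (default 1).
#' @param min_contig_frags contigs left with fewer surviving fragments than
#'   this are put aside entirely (default 5): such remnants carry too
#'   little signal for the contact model and would be scattered by the
#'   sampler; they are reinserted after correction like all filtered
#'   sequence ([reinsert_filtered()]).
#' @return list with `map` (filtered, re-indexed `contact_map`), `report`
#'   (a `filter_report`), and `fragments` (table with `filtered` flags set).
#' @export
filter_fragments <- function(map0, fragments, min_len = 50L, cov_sd_k = 1.0,
                             min_contig_frags = 5L) {
  assert_fragment_table(fragments)
  if (map0$n_bins != nrow(fragments))
    stop_("map and fragment table disagree on fragment count")
  short <- fragments$length < min_len
  cov <- fragments$coverage[!short]
  m <- mean(cov)
  s <- sqrt(mean((cov - m)^2))  # population SD
  thr <- m - cov_sd_k * s
  lowcov <- logical(nrow(fragments))
  lowcov[!short] <- fragments$coverage[!short] < thr
  removed <- short | lowcov
  surv_per_contig <- table(fragments$contig[!removed])
  orphan_contigs <- names(surv_per_contig)[surv_per_contig < min_contig_frags]
  orphaned <- !removed & fragments$contig %in% orphan_contigs
  removed <- removed | orphaned
  if (all(removed)) stop_("empty map after filtering")
  fragments$filtered <- removed

  keep_ids <- fragments$frag_id[!removed]
  newid <- rep(NA_integer_, nrow(fragments))
  newid[!removed] <- seq_len(sum(!removed)) - 1L
  sel <- !is.na(newid[map0$i + 1L]) & !is.na(newid[map0$j + 1L])
  bins <- fragment_bins(fragments[!removed, , drop = FALSE])
  bins$frags <- I(as.list(keep_ids))
  map <- contact_map(newid[map0$i[sel] + 1L], newid[map0$j[sel] + 1L],
                     map0$count[sel], bins, level = 0L, fragments = fragments)
  report <- structure(
    list(removed_short = fragments$frag_id[short],
         removed_low_coverage = fragments$frag_id[lowcov],
         removed_orphaned = fragments$frag_id[orphaned],
         threshold_len = min_len, threshold_cov = thr,
         threshold_contig_frags = min_contig_frags),
    class = "filter_report")
  list(map = map, report = report, fragments = fragments)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d short (< %d bp), %d low-coverage (< %.3f), %d on orphaned contigs\n",
              length(x$removed_short), x$threshold_len,
              length(x$removed_low_coverage), x$threshold_cov,
              length(x$removed_orphaned %||% integer(0))))
  invisible(x)
}

#' Build a contact-map pyramid by recursive sum-pooling
#'
#' Starting from a (filtered) level-0 map, groups of `fold` consecutive bins
#' within each input contig are sum-pooled into one bin, recursively, so a
#' level-L interior bin holds `fold^L` fragments; a contig's trailing
#' remainder forms a smaller final bin. Pooling never crosses contig
#' boundaries, so every bin maps to a single source interval. The total
#' contact count is conserved exactly at every level.
#'
#' @param map0 level-0 `contact_map` (typically the output of
#'   [filter_fragments()]).
#' @param n_levels number of pooling levels to build (>= 0).
#' @param fold pooling factor (default 3).
#' @return a `contact_pyramid`: list with `levels` (maps for levels
#'   `0..n_levels`, each carrying a `parent` column linking bins to the next
#'   level) and `fold`.
#' @export
build_pyramid <- function(map0, n_levels, fold = 3L) {
  if (!is_count(n_levels)) stop_("n_levels must be a non-negative integer")
  levels <- vector("list", n_levels + 1L)
  levels[[1]] <- map0
  cur <- map0
  for (L in seq_len(n_levels)) {
    b <- cur$bins
    # group consecutive bins within each contig
    grp_in_contig <- (b$orig - 1L) %/% fold
    key <- paste(b$contig, grp_in_contig, sep = "\r")
    ukey <- unique(key)  # bins are ordered by contig then orig
    parent <- match(key, ukey) - 1L
    cur$bins$parent <- parent
    levels[[L]] <- cur

    first <- !duplicated(key)
    nb <- data.frame(bin = seq_along(ukey) - 1L,
                     contig = b$contig[first],
                     orig = as.integer(grp_in_contig[first] + 1L),
                     length_bp = as.numeric(rowsum(b$length_bp, parent,
                                                   reorder = FALSE)),
                     n_frag = as.integer(rowsum(b$n_frag, parent,
                                                reorder = FALSE)),
                     stringsAsFactors = FALSE)
    nb$frags <- I(lapply(split(seq_len(nrow(b)), parent)[
      as.character(seq_along(ukey) - 1L)],
      function(rows) unlist(b$frags[rows], use.names = FALSE)))
    pi <- parent[cur$i + 1L]
    pj <- parent[cur$j + 1L]
    nmap <- contact_map(pmin(pi, pj), pmax(pi, pj), cur$count, nb,
                        level = L, fragments = cur$fragments)
    levels[[L + 1L]] <- nmap
    cur <- nmap
  }
  structure(list(levels = levels, fold = as.integer(fold)), class = "contact_pyramid")
}

#' @export
print.contact_pyramid <- function(x, ...) {
  cat(sprintf("contact_pyramid: fold %d, levels 0..%d (%s bins)\n",
              x$fold, length(x$levels) - 1L,
              paste(vapply(x$levels, function(m) m$n_bins, 1L), collapse = " > ")))
  invisible(x)
}

#' Extract one level of a pyramid
#' @param pyramid a `contact_pyramid`.
#' @param level level index (0-based).
#' @export
pyramid_level <- function(pyramid, level) {
  if (level < 0L || level > length(pyramid$levels) - 1L)
    stop_("level ", level, " not present in pyramid")
  pyramid$levels[[level + 1L]]
}
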