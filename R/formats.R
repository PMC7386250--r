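# Readers and writers for every on-disk artifact. All coordinates are
# 0-based, half-open; orientation is "+" / "-".

#' Read a FASTA file
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return a [Biostrings::DNAStringSet] with unique names and uppercase
#'   sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop_("duplicate header: ", names(x)[duplicated(names(x))][1])
  if (any(Biostrings::width(x) == 0L))
    stop_("empty sequence for header: ", names(x)[Biostrings::width(x) == 0L][1])
  # store uppercase
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences as FASTA
#'
#' @param seqs a `DNAStringSet` or named character vector.
#' @param path output path.
#' @param width line-wrap width (default 80 columns).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a pairs file of aligned Hi-C read pairs
#'
#' The dialect is a 4DN-pairs-like TSV: lines starting with `#` are header
#' or comments; data lines have nine tab-separated fields
#' `read_id contig1 pos1 strand1 contig2 pos2 strand2 mapq1 mapq2`
#' with 0-based positions.
#'
#' @param path path to the pairs file.
#' @return data frame with one row per pair, in file order.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) {
    return(data.frame(read_id = character(), contig1 = character(),
                      pos1 = integer(), strand1 = character(),
                      contig2 = character(), pos2 = integer(),
                      strand2 = character(), mapq1 = integer(),
                      mapq2 = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(keep)[which(nf != 9L)[1]]
    stop_("malformed pairs line ", bad, ": expected 9 fields, got ",
          nf[which(nf != 9L)[1]])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  out <- data.frame(read_id = m[, 1], contig1 = m[, 2],
                    pos1 = as.integer(m[, 3]), strand1 = m[, 4],
                    contig2 = m[, 5], pos2 = as.integer(m[, 6]),
                    strand2 = m[, 7], mapq1 = as.integer(m[, 8]),
                    mapq2 = as.integer(m[, 9]), stringsAsFactors = FALSE)
  if (anyNA(out$pos1) || anyNA(out$pos2) || anyNA(out$mapq1) || anyNA(out$mapq2))
    stop_("non-numeric position or mapq in pairs file")
  if (any(out$pos1 < 0L) || any(out$pos2 < 0L)) stop_("negative position in pairs file")
  if (any(!out$strand1 %in% c("+", "-")) || any(!out$strand2 %in% c("+", "-")))
    stop_("strand must be '+' or '-'")
  if (any(out$mapq1 < 0L | out$mapq1 > 60L | out$mapq2 < 0L | out$mapq2 > 60L))
    stop_("mapq out of range [0, 60]")
  out
}

#' Write a pairs file
#' @param pairs data frame as returned by [read_pairs()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#columns: readID chr1 pos1 strand1 chr2 pos2 strand2 mapq1 mapq2", con)
  if (nrow(pairs))
    utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a sparse contact map
#'
#' The on-disk dialect is a TSV with header `id_a  id_b  count`, 0-based
#' integer bin ids, upper triangle only (`id_a <= id_b`), counts >= 1.
#'
#' @param path file path.
#' @param fragments optional fragment table; when given, the map is built
#'   with per-fragment bins at level 0.
#' @param bins optional explicit bin table.
#' @param level pyramid level recorded on the map.
#' @return a [contact_map()].
#' @export
read_sparse_map <- function(path, fragments = NULL, bins = NULL, level = 0L) {
  if (!file.exists(path)) stop_("no such file: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "integer", "numeric"),
                         col.names = c("id_a", "id_b", "count"))
  if (nrow(d) && any(d$id_a > d$id_b)) stop_("lower-triangle entry in ", path)
  if (nrow(d) && any(d$count <= 0)) stop_("non-positive count in ", path)
  if (is.null(bins)) {
    if (!is.null(fragments)) {
      bins <- fragment_bins(fragments)
    } else {
      n <- if (nrow(d)) max(d$id_b) + 1L else 0L
      bins <- data.frame(bin = seq_len(n) - 1L,
                         contig = rep(NA_character_, n),
                         orig = seq_len(n), length_bp = rep(NA_real_, n),
                         n_frag = rep(1L, n),
                         frags = I(as.list(seq_len(n) - 1L)))
    }
  }
  contact_map(d$id_a, d$id_b, d$count, bins, level = level, fragments = fragments)
}

#' @rdname read_sparse_map
#' @param map a `contact_map` to serialize.
#' @export
write_sparse_map <- function(map, path) {
  d <- data.frame(id_a = map$i, id_b = map$j, count = map$count)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a fragment table
#'
#' @param fragments fragment table data frame.
#' @param path file path.
#' @export
write_fragment_table <- function(fragments, path) {
  assert_fragment_table(fragments)
  utils::write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  assert_fragment_table(d)
  if (!"coverage" %in% names(d)) d$coverage <- 0
  if (!"filtered" %in% names(d)) d$filtered <- FALSE
  d
}

# ---- placement tables -------------------------------------------------------

# Resolve each bin of a structure to its maximal contiguous bp runs on the
# source contig. Returns a data frame with one row per run.
bin_runs <- function(structure) {
  frags <- structure$fragments
  if (is.null(frags)) stop_("structure carries no fragment table")
  fr_start <- frags$start[match(seq_len(nrow(frags)) - 1L, frags$frag_id)]
  # fragment lookup by id
  id2row <- match(seq(0L, max(frags$frag_id)), frags$frag_id)
  rows <- list()
  n <- 0L
  for (s in seq_along(structure$scaffolds)) {
    sb <- structure$scaffolds[[s]]
    for (r in seq_along(sb)) {
      b <- abs(sb[r]); ori <- if (sb[r] > 0) "+" else "-"
      fids <- structure$bins$frags[[b]]
      fr <- frags[id2row[fids + 1L], , drop = FALSE]
      fr <- fr[order(fr$start), , drop = FALSE]
      brk <- c(TRUE, fr$start[-1L] != fr$end[-nrow(fr)])
      grp <- cumsum(brk)
      st <- tapply(fr$start, grp, min)
      en <- tapply(fr$end, grp, max)
      runs <- data.frame(scaffold = sprintf("scaffold_%d", s),
                         input_contig = structure$bins$contig[b],
                         start = as.integer(st), end = as.integer(en),
                         orientation = ori, rank = r - 1L,
                         stringsAsFactors = FALSE)
      if (ori == "-") runs <- runs[rev(seq_len(nrow(runs))), , drop = FALSE]
      n <- n + 1L
      rows[[n]] <- runs
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a placement table
#'
#' A placement table records, for each scaffold, the ordered and oriented
#' intervals of the input contigs it is built from. Columns: `scaffold`,
#' `input_contig`, `start` (0-based), `end` (half-open), `orientation`
#' (`+`/`-`), `rank` (0-based rank of the bin within its scaffold).
#'
#' @param x a `genome_structure` (with its fragment table) or a placement
#'   data frame.
#' @param path file path.
#' @export
write_placement_table <- function(x, path) {
  d <- if (inherits(x, "genome_structure")) bin_runs(x) else validate_placement(x)
  d <- d[order(d$scaffold, d$rank), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_placement <- function(d) {
  need <- c("scaffold", "input_contig", "start", "end", "orientation", "rank")
  if (!all(need %in% names(d))) stop_("placement table must have columns ",
                                      paste(need, collapse = ", "))
  if (any(d$end <= d$start)) stop_("placement interval with end <= start")
  if (any(!d$orientation %in% c("+", "-"))) stop_("orientation must be '+' or '-'")
  for (ct in unique(d$input_contig)) {
    iv <- d[d$input_contig == ct, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop_("overlapping placement intervals on contig ", ct)
  }
  d
}

#' @rdname write_placement_table
#' @export
read_placement_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d <- validate_placement(d)
  d[order(d$scaffold, d$rank), , drop = FALSE]
}

#' Emit scaffold sequences from a structure
#'
#' Concatenates, per scaffold, the placed contig intervals in rank order
#' (reverse-complementing `-` segments), separating consecutive segments by
#' `gap_size` `N` characters. Input contigs that were not integrated at all
#' are appended under their original names.
#'
#' @param structure a `genome_structure` (or placement data frame).
#' @param sequences the input contigs as a `DNAStringSet` or named character.
#' @param gap_size number of `N`s between joined segments (default 100).
#' @param path optional output FASTA path.
#' @return a `DNAStringSet` of scaffold (plus leftover contig) sequences.
#' @export
write_scaffold_fasta <- function(structure, sequences, gap_size = 100L, path = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  d <- if (inherits(structure, "genome_structure")) bin_runs(structure)
       else validate_placement(structure)
  d <- d[order(d$scaffold, d$rank), , drop = FALSE]
  seqs <- as.character(sequences)
  lens <- nchar(seqs)
  if (nrow(d)) {
    unknown <- setdiff(d$input_contig, names(seqs))
    if (length(unknown)) stop_("placement refers to unknown contig: ", unknown[1])
    if (any(d$end > lens[d$input_contig]))
      stop_("placement interval beyond contig length")
  }
  gap <- strrep("N", gap_size)
  out <- character(0)
  for (sc in unique(d$scaffold)) {
    rows <- d[d$scaffold == sc, , drop = FALSE]
    segs <- substr(rep(seqs[rows$input_contig], 1L), rows$start + 1L, rows$end)
    rev <- rows$orientation == "-"
    if (any(rev)) segs[rev] <- reverse_complement_chr(segs[rev])
    out[sc] <- paste(segs, collapse = gap)
  }
  leftover <- setdiff(names(seqs), unique(d$input_contig))
  out <- c(out, seqs[leftover])
  res <- Biostrings::DNAStringSet(out)
  if (!is.null(path)) write_fasta(res, path)
  res
}

#' Read / write a linkage map
#'
#' TSV columns: `marker_id`, `linkage_group`, `cm` (centimorgan position),
#' `contig`, `pos` (0-based bp on the input contig). Within a linkage group
#' rows are kept sorted by cM.
#'
#' @param path file path.
#' @export
read_linkage_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("marker_id", "linkage_group", "cm", "contig", "pos")
  if (!all(need %in% names(d))) stop_("linkage map must have columns ",
                                      paste(need, collapse = ", "))
  d[order(d$linkage_group, d$cm), , drop = FALSE]
}

#' @rdname read_linkage_map
#' @param linkage linkage map data frame.
#' @export
write_linkage_map <- function(linkage, path) {
  linkage <- linkage[order(linkage$linkage_group, linkage$cm), , drop = FALSE]
  utils::write.table(linkage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
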