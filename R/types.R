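#' Construct a sparse contact map
#'
#' A contact map stores symmetric contact counts between bins in
#' coordinate-list (upper triangle) form, together with a bin table mapping
#' each bin to its member restriction fragments. At level 0 every bin is a
#' single restriction fragment; higher levels hold sum-pooled groups of
#' fragments (see [build_pyramid()]).
#'
#' @param i,j integer vectors of 0-based bin ids with `i <= j` elementwise.
#' @param count numeric vector of positive contact counts.
#' @param bins data frame with one row per bin: `bin` (0-based id), `contig`,
#'   `orig` (1-based rank of the bin among its contig's bins), `length_bp`
#'   (total bp of member fragments), `n_frag`, and a list column `frags` of
#'   0-based member fragment ids. An optional `parent` column links each bin
#'   to its bin at the level above.
#' @param level non-negative integer pyramid level.
#' @param fragments the level-0 fragment table the bins refer to (optional
#'   but required for placement/FASTA output).
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(i, j, count, bins, level = 0L, fragments = NULL) {
  i <- as.integer(i); j <- as.integer(j); count <- as.numeric(count)
  if (length(i) != length(j) || length(i) != length(count))
    stop_("i, j, count must have equal length")
  if (any(i > j)) stop_("lower-triangle entry: all entries must satisfy i <= j")
  if (any(count <= 0)) stop_("contact counts must be >= 1")
  if (any(i < 0)) stop_("bin ids must be >= 0")
  n <- nrow(bins)
  if (length(i) && max(j) >= n) stop_("bin id exceeds bin table")
  # sort and collapse duplicate cells
  o <- order(i, j)
  i <- i[o]; j <- j[o]; count <- count[o]
  if (length(i) > 1L) {
    same <- c(FALSE, i[-1L] == i[-length(i)] & j[-1L] == j[-length(j)])
    if (any(same)) {
      grp <- cumsum(!same)
      count <- as.numeric(rowsum(count, grp, reorder = FALSE))
      i <- i[!same]; j <- j[!same]
    }
  }
  structure(
    list(level = as.integer(level), n_bins = n,
         i = i, j = j, count = count,
         bins = bins, fragments = fragments),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: level %d, %d bins, %d non-zero cells, total count %g\n",
              x$level, x$n_bins, length(x$i), sum(x$count)))
  invisible(x)
}

#' Total contact count of a map
#' @param map a `contact_map`.
#' @export
total_count <- function(map) sum(map$count)

# bin table for per-fragment (level 0) bins
fragment_bins <- function(fragments) {
  assert_fragment_table(fragments)
  orig <- stats::ave(seq_len(nrow(fragments)), fragments$contig,
                     FUN = seq_along)
  data.frame(bin = seq_len(nrow(fragments)) - 1L,
             contig = fragments$contig,
             orig = as.integer(orig),
             length_bp = fragments$length,
             n_frag = 1L,
             frags = I(as.list(fragments$frag_id)),
             stringsAsFactors = FALSE)
}

#' Construct a genome structure
#'
#' A genome structure is an ordered list of scaffolds, each an ordered,
#' oriented chain of bins; it is the object the MCMC sampler permutes and the
#' correction module edits. Bins are represented as signed 1-based indices
#' into the bin table (`+b` forward, `-b` reverse).
#'
#' @param scaffolds list of integer vectors of signed 1-based bin indices.
#' @param bins bin table (as in [contact_map()]).
#' @param fragments level-0 fragment table (optional).
#' @return an object of class `genome_structure`.
#' @export
genome_structure <- function(scaffolds, bins, fragments = NULL) {
  scaffolds <- lapply(scaffolds, as.integer)
  if (any(vapply(scaffolds, length, 1L) == 0L)) stop_("empty scaffold")
  ids <- abs(unlist(scaffolds, use.names = FALSE))
  if (length(ids) && (any(ids < 1L) | any(ids > nrow(bins))))
    stop_("bin index out of range")
  if (anyDuplicated(ids)) stop_("a bin appears in more than one position")
  structure(list(scaffolds = scaffolds, bins = bins, fragments = fragments),
            class = "genome_structure")
}

#' Identity structure from a contact map
#'
#' Builds the initial genome structure in which every input contig is one
#' scaffold with its bins in original order, all oriented forward.
#'
#' @param map a `contact_map`.
#' @return a `genome_structure`.
#' @export
structure_from_map <- function(map) {
  b <- map$bins
  contigs <- unique(b$contig)
  scaffolds <- lapply(contigs, function(ct) {
    idx <- which(b$contig == ct)
    idx[order(b$orig[idx])]
  })
  genome_structure(scaffolds, b, map$fragments)
}

#' @export
print.genome_structure <- function(x, ...) {
  sizes <- vapply(x$scaffolds, length, 1L)
  cat(sprintf("genome_structure: %d scaffolds over %d bins (largest %d bins)\n",
              length(sizes), nrow(x$bins), if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Total placed base pairs of a structure
#' @param structure a `genome_structure`.
#' @export
total_bp <- function(structure) {
  idx <- abs(unlist(structure$scaffolds, use.names = FALSE))
  sum(structure$bins$length_bp[idx])
}

#' Scaffold lengths in bp
#' @param structure a `genome_structure`.
#' @return numeric vector of per-scaffold bp totals (bin lengths, no gaps).
#' @export
scaffold_lengths <- function(structure) {
  vapply(structure$scaffolds,
         function(s) sum(structure$bins$length_bp[abs(s)]), numeric(1))
}
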