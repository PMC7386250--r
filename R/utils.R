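# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' @keywords internal
assert_fragment_table <- function(fragments) {
  need <- c("frag_id", "contig", "start", "end", "length")
  if (!is.data.frame(fragments) || !all(need %in% names(fragments)))
    stop_("'fragments' must be a fragment table with columns ",
          paste(need, collapse = ", "))
  invisible(fragments)
}

# bin rank / scaffold lookup arrays from a genome_structure
# (1-based bin indices; rank is the 1-based position within the scaffold)
structure_index <- function(structure) {
  n <- nrow(structure$bins)
  scaf <- integer(n)
  rank <- integer(n)
  orient <- integer(n)
  for (s in seq_along(structure$scaffolds)) {
    sb <- structure$scaffolds[[s]]
    idx <- abs(sb)
    scaf[idx] <- s
    rank[idx] <- seq_along(sb)
    orient[idx] <- sign(sb)
  }
  list(scaf = scaf, rank = rank, orient = orient)
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
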