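# Mutations of a genome structure and candidate-move generation.

MUTATION_KINDS <- c("stay", "flip", "eject", "insert_before", "insert_after", "swap")

#' Construct a mutation
#'
#' @param kind one of `stay`, `flip`, `eject`, `insert_before`,
#'   `insert_after`, `swap`.
#' @param target 0-based id of the bin being moved.
#' @param anchor 0-based id of the anchor bin (insert/swap only).
#' @param flipped for inserts: whether the target's orientation is toggled.
#' @export
mutation <- function(kind, target, anchor = NA_integer_, flipped = FALSE) {
  kind <- match.arg(kind, MUTATION_KINDS)
  if (kind %in% c("insert_before", "insert_after", "swap")) {
    if (is.na(anchor)) stop_("mutation '", kind, "' requires an anchor")
    if (anchor == target) stop_("anchor must differ from target")
  }
  structure(list(kind = kind, target = as.integer(target),
                 anchor = as.integer(anchor), flipped = isTRUE(flipped)),
            class = "mutation")
}

#' @export
print.mutation <- function(x, ...) {
  cat(sprintf("mutation: %s target=%d%s%s\n", x$kind, x$target,
              if (!is.na(x$anchor)) sprintf(" anchor=%d", x$anchor) else "",
              if (x$flipped) " (flipped)" else ""))
  invisible(x)
}

# integer encoding used by the C++ engine: kind, target, anchor, flipped
encode_mutations <- function(mutations) {
  m <- matrix(0L, nrow = length(mutations), ncol = 4L)
  for (r in seq_along(mutations)) {
    mu <- mutations[[r]]
    m[r, ] <- c(match(mu$kind, MUTATION_KINDS) - 1L, mu$target,
                if (is.na(mu$anchor)) -1L else mu$anchor,
                as.integer(mu$flipped))
  }
  m
}

#' Apply a mutation to a genome structure
#'
#' `flip` toggles the target's orientation in place; `eject` removes the
#' target into a new singleton scaffold appended at the end (dropping its
#' source scaffold if emptied); `insert_before`/`insert_after` place the
#' target adjacent to the anchor (optionally with toggled orientation);
#' `swap` exchanges the two bins' slots. All other bins keep their relative
#' order.
#'
#' @param structure a `genome_structure`.
#' @param mutation a [mutation()].
#' @return a new `genome_structure`.
#' @export
apply_mutation <- function(structure, mutation) {
  sc <- structure$scaffolds
  n <- nrow(structure$bins)
  t1 <- mutation$target + 1L
  if (t1 < 1L || t1 > n) stop_("invalid target bin id")
  idx <- structure_index(structure)
  st <- idx$scaf[t1]; pt <- idx$rank[t1]
  if (st == 0L) stop_("target bin not present in structure")
  signed_t <- sc[[st]][pt]

  if (mutation$kind == "stay") return(structure)
  if (mutation$kind == "flip") {
    sc[[st]][pt] <- -signed_t
    return(genome_structure(sc, structure$bins, structure$fragments))
  }
  if (mutation$kind == "eject") {
    sc[[st]] <- sc[[st]][-pt]
    sc[[length(sc) + 1L]] <- signed_t
    sc <- sc[lengths(sc) > 0L]
    return(genome_structure(sc, structure$bins, structure$fragments))
  }
  a1 <- mutation$anchor + 1L
  if (a1 < 1L || a1 > n) stop_("invalid anchor bin id")
  sa <- idx$scaf[a1]; pa <- idx$rank[a1]
  if (mutation$kind == "swap") {
    signed_a <- sc[[sa]][pa]
    sc[[st]][pt] <- signed_a
    sc[[sa]][pa] <- signed_t
    return(genome_structure(sc, structure$bins, structure$fragments))
  }
  # inserts: remove target first
  sc[[st]] <- sc[[st]][-pt]
  if (sa == st && pa > pt) pa <- pa - 1L
  val <- if (mutation$flipped) -signed_t else signed_t
  at <- if (mutation$kind == "insert_before") pa - 1L else pa
  sc[[sa]] <- append(sc[[sa]], val, after = at)
  sc <- sc[lengths(sc) > 0L]
  genome_structure(sc, structure$bins, structure$fragments)
}

#' Candidate moves for one bin
#'
#' Anchors are the `k` bins with the highest total contact with the target
#' (ties broken toward the lower bin id). The candidate set is `stay`,
#' `flip`, `eject`, insertion before/after each anchor in either
#' orientation, and a swap with each anchor; no-ops (moves recreating the
#' current arrangement) and duplicates are removed.
#'
#' @param bin 0-based target bin id.
#' @param structure a `genome_structure`.
#' @param map `contact_map` at the structure's level.
#' @param k number of anchors (default 5).
#' @return list of [mutation()]s.
#' @export
candidate_moves <- function(bin, structure, map, k = 5L) {
  if (k < 1L) stop_("k must be >= 1")
  b1 <- bin + 1L
  sel <- (map$i == bin | map$j == bin) & map$i != map$j
  partner <- ifelse(map$i[sel] == bin, map$j[sel], map$i[sel])
  anchors <- integer(0)
  if (length(partner)) {
    tot <- tapply(map$count[sel], partner, sum)
    ids <- as.integer(names(tot))
    o <- order(-as.numeric(tot), ids)
    anchors <- ids[o][seq_len(min(k, length(ids)))]
  }
  idx <- structure_index(structure)
  singleton <- length(structure$scaffolds[[idx$scaf[b1]]]) == 1L
  out <- list(mutation("stay", bin), mutation("flip", bin))
  if (!singleton) out[[length(out) + 1L]] <- mutation("eject", bin)
  seen <- character(0)
  for (a in anchors) {
    a1 <- a + 1L
    # post-removal slot of the anchor, for no-op/duplicate detection
    pa <- idx$rank[a1]
    if (idx$scaf[a1] == idx$scaf[b1] && pa > idx$rank[b1]) pa <- pa - 1L
    for (side in c("insert_before", "insert_after")) {
      slot <- if (side == "insert_before") pa - 1L else pa
      for (fl in c(FALSE, TRUE)) {
        ori <- sign(structure$scaffolds[[idx$scaf[b1]]][idx$rank[b1]])
        if (fl) ori <- -ori
        key <- paste(idx$scaf[a1], slot, ori)
        noop <- !fl && idx$scaf[a1] == idx$scaf[b1] &&
          ((side == "insert_before" && idx$rank[a1] == idx$rank[b1] + 1L) ||
           (side == "insert_after" && idx$rank[a1] == idx$rank[b1] - 1L))
        if (!noop && !(key %in% seen)) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- mutation(side, bin, a, fl)
        }
      }
    }
    out[[length(out) + 1L]] <- mutation("swap", bin, a)
  }
  out
}
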