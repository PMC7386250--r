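# R-side wrappers around the C++ sampler engine.
#
# The engine evaluates the likelihood over "units": the bins of `eval_map`
# (one level below the working map) when given, otherwise the working bins
# themselves (each bin one unit, in which case flips carry no signal).

build_engine <- function(structure, map, eval_map = NULL) {
  if (map$n_bins != nrow(structure$bins))
    stop_("map and structure are over different bin sets")
  B <- map$n_bins
  if (is.null(eval_map)) {
    umap <- map
    bin_units <- as.list(seq_len(B) - 1L)
  } else {
    eb <- eval_map$bins
    if (is.null(eb$parent)) stop_("eval_map carries no parent links")
    ch <- split(seq_len(nrow(eb)) - 1L, eb$parent)
    bin_units <- ch[as.character(seq_len(B) - 1L)]
    if (any(vapply(bin_units, is.null, TRUE)))
      stop_("eval_map does not cover every working bin")
    umap <- eval_map
  }
  bptr <- c(0L, cumsum(lengths(bin_units)))
  ptr <- eng_new(umap$i, umap$j, umap$count, umap$n_bins,
                 as.integer(bptr), as.integer(unlist(bin_units)),
                 structure$scaffolds)
  list(ptr = ptr, U = umap$n_bins, u = grid_unit(umap$bins))
}

engine_set_params <- function(eng, params) {
  lam <- model_lambda(params, eng$u, eng$U)
  eng_set_model(eng$ptr, lam, log(params$delta), params$delta)
  invisible(eng)
}

engine_structure <- function(eng, bins, fragments = NULL) {
  genome_structure(eng_structure(eng$ptr), bins, fragments)
}
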