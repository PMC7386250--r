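# The MCMC scaffolder: Gibbs sampling among candidate moves, cycles, and
# convergence monitoring.

# Gibbs choice among candidate deltas; stay has delta 0 so rejection is
# always possible. temperature -> 0 (greedy) picks the argmax, ties -> stay.
choose_candidate <- function(deltas, temperature, greedy = FALSE) {
  if (greedy || temperature <= 0) {
    best <- max(deltas)
    if (best <= 0) return(1L)  # stay (always first)
    return(which.max(deltas))
  }
  w <- exp((deltas - max(deltas)) / temperature)
  pr <- w / sum(w)
  min(findInterval(stats::runif(1), cumsum(pr), rightmost.closed = TRUE) + 1L,
      length(deltas))
}

#' One sampling step for one bin
#'
#' Computes the log-likelihood change of every candidate move of `bin`
#' (see [candidate_moves()]) and samples one with probability proportional
#' to `exp(delta / temperature)`, then applies it.
#'
#' @param structure `genome_structure` at the working level.
#' @param map working-level `contact_map`.
#' @param params [hic_params()].
#' @param bin 0-based target bin.
#' @param temperature Gibbs temperature (> 0, default 1).
#' @param k number of contact anchors (default 5).
#' @param eval_map optional map one level below for sub-bin evaluation.
#' @param greedy take the argmax candidate deterministically (ties -> stay).
#' @return list with the new `structure`, the chosen `mutation`, and its
#'   `delta` log-likelihood.
#' @export
sample_step <- function(structure, map, params, bin, temperature = 1.0,
                        k = 5L, eval_map = NULL, greedy = FALSE) {
  cands <- candidate_moves(bin, structure, map, k = k)
  eng <- build_engine(structure, map, eval_map)
  engine_set_params(eng, params)
  deltas <- eng_deltas(eng$ptr, encode_mutations(cands))
  pick <- choose_candidate(deltas, temperature, greedy)
  list(structure = apply_mutation(structure, cands[[pick]]),
       mutation = cands[[pick]], delta = deltas[pick])
}

#' One full sampler cycle
#'
#' Visits every bin exactly once in a randomly shuffled order, applying
#' [sample_step()] logic with a single persistent engine.
#'
#' @inheritParams sample_step
#' @return list with the new `structure` and `stats`, a named count of
#'   accepted mutations per kind (`stay` counts rejections).
#' @export
run_cycle <- function(structure, map, params, temperature = 1.0, k = 5L,
                      eval_map = NULL, greedy = FALSE) {
  eng <- build_engine(structure, map, eval_map)
  engine_set_params(eng, params)
  B <- map$n_bins
  stats <- stats::setNames(integer(length(MUTATION_KINDS)), MUTATION_KINDS)
  for (b0 in sample.int(B) - 1L) {
    cands <- eng_candidates(eng$ptr, b0, as.integer(k))
    deltas <- eng_deltas(eng$ptr, cands)
    pick <- choose_candidate(deltas, temperature, greedy)
    kind <- cands[pick, 1] + 1L
    stats[kind] <- stats[kind] + 1L
    if (cands[pick, 1] != 0L)
      eng_apply(eng$ptr, cands[pick, 1], cands[pick, 2], cands[pick, 3],
                cands[pick, 4])
  }
  list(structure = engine_structure(eng, structure$bins, structure$fragments),
       stats = stats)
}

# rescale fragment-pair-mass: expected counts between units f-fold bigger
# scale by f^2 at equal bp distance
rescale_params <- function(params, f) {
  hic_params(params$A * f^2, params$alpha, params$delta * f^2)
}

# estimate params for a structure at `level`, evaluated one level below;
# falls back to the level-0 intra-contig profile (rescaled to the
# evaluation level) when no scaffold at `level` is large enough yet
init_params_for <- function(pyramid, level, structure, cfg) {
  map <- pyramid_level(pyramid, level)
  eval_map <- if (level > 0L) pyramid_level(pyramid, level - 1L) else NULL
  direct <- tryCatch({
    s <- structure; m <- map
    if (!is.null(eval_map)) {
      s <- expand_structure(structure, map, eval_map)
      m <- eval_map
    }
    estimate_parameters(s, m, cfg$min_scaffold_bins, cfg$n_dist_bins)
  }, error = function(e) NULL)
  if (!is.null(direct)) return(direct)
  map0 <- pyramid_level(pyramid, 0L)
  st0 <- structure_from_map(map0)
  p0 <- estimate_parameters(st0, map0, cfg$min_scaffold_bins, cfg$n_dist_bins)
  rescale_params(p0, pyramid$fold^max(level - 1L, 0L))
}

#' Run the MCMC scaffolder on a contact-map pyramid
#'
#' Scaffolds coarse-to-fine: when the pyramid provides levels above the
#' working one, a short pre-pass at the coarsest level (where a whole input
#' contig is typically a single bin, so scaffold joins are single high-signal
#' moves) orders and orients the contigs, and its structure is projected
#' down to initialize the working level; otherwise the structure starts as
#' the input contigs in input order and the working-level chain anneals
#' from `anneal_T0` down to `temperature` to let single-bin moves cross
#' junction barriers. The likelihood is always evaluated one level below
#' the working level when available, so bin orientation carries signal.
#' The contact model is re-estimated after every cycle from scaffolds with
#' at least `min_scaffold_bins` (sub-)bins.
#'
#' @param pyramid a `contact_pyramid` from [build_pyramid()].
#' @param level working level (bins of `fold^level` fragments).
#' @param n_cycles number of cycles; every bin is visited once per cycle.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param config optional list overriding `temperature` (1.0), `k_anchors`
#'   (5), `min_scaffold_bins` (10), `n_dist_bins` (20), `init` ("auto":
#'   coarse pre-pass when possible; "coarse"; "contigs"), `pre_cycles`
#'   (15), `pre_anneal_T0` (8), `anneal_T0` (32, used for contig
#'   initialization; 1 disables), `anneal_frac` (0.5), `greedy_final`
#'   (FALSE), `verbose` (FALSE).
#' @return list with `structure`, `trajectory` (one row per cycle: cycle,
#'   iterations, logL, A, alpha, delta, and acceptance counts per mutation
#'   kind), and final `params`. The seed is recorded as an attribute of the
#'   trajectory.
#' @export
run_scaffolder <- function(pyramid, level, n_cycles, seed = 1L,
                           config = list()) {
  cfg <- utils::modifyList(list(temperature = 1.0, k_anchors = 5L,
                                min_scaffold_bins = 10L, n_dist_bins = 20L,
                                init = "auto", pre_cycles = 24L,
                                anneal_T0 = "auto", anneal_frac = 0.4,
                                greedy_final = FALSE, verbose = FALSE),
                           config)
  map <- pyramid_level(pyramid, level)
  eval_map <- if (level > 0L) pyramid_level(pyramid, level - 1L) else NULL
  top <- length(pyramid$levels) - 1L
  use_coarse <- switch(cfg$init,
                       auto = top > level,
                       coarse = TRUE,
                       contigs = FALSE,
                       stop_("unknown init mode: ", cfg$init))
  set.seed(seed)

  if (use_coarse) {
    if (top <= level) stop_("no pyramid level above the working level")
    pre_cfg <- cfg
    pre_cfg$init <- "contigs"
    pre <- run_scaffolder(pyramid, top, cfg$pre_cycles, seed = seed,
                          config = pre_cfg)
    st <- pre$structure
    for (L in seq(top, level + 1L))
      st <- expand_structure(st, pyramid_level(pyramid, L),
                             pyramid_level(pyramid, L - 1L))
    structure <- st
  } else {
    structure <- structure_from_map(map)
  }

  est <- function(structure, prev = NULL) {
    s <- structure; m <- map
    if (!is.null(eval_map)) {
      s <- expand_structure(structure, map, eval_map)
      m <- eval_map
    }
    tryCatch(estimate_parameters(s, m, cfg$min_scaffold_bins,
                                 cfg$n_dist_bins, prev = prev),
             error = function(e) {
               if (is.null(prev)) stop(e)
               prev
             })
  }
  params <- init_params_for(pyramid, level, structure, cfg)

  # annealing start temperature: junction-crossing barriers scale with the
  # counting noise of one bin's contacts, ~ sqrt(lambda_adjacent) *
  # log(lambda_adjacent / delta), while destroying a good junction costs
  # ~ lambda * log(lambda / delta) -- an order of magnitude more. "auto"
  # places T0 at twice the barrier scale: hot enough to cross, far too
  # cold to melt correct structure. A coarse-initialized chain starts from
  # an already-ordered structure and is only gently reheated.
  anneal_T0 <- cfg$anneal_T0
  if (identical(anneal_T0, "auto")) {
    u_eval <- grid_unit(if (is.null(eval_map)) map$bins else eval_map$bins)
    lam1 <- max(params$A * u_eval^(-params$alpha), params$delta)
    barrier <- sqrt(lam1) * log(lam1 / params$delta + 1)
    # a coarse-initialized chain starts from an already-ordered structure:
    # run it cold rather than melt the initialization
    anneal_T0 <- if (use_coarse) cfg$temperature else max(1, 2 * barrier)
  }

  # annealing: a train of pulses, each holding at anneal_T0 for several
  # cycles before cooling back to the base temperature. Single-bin moves
  # across a scaffold junction face a likelihood barrier of the order of
  # the counting noise of one bin's contacts even when the merged
  # arrangement is vastly better, and joins proceed bin by bin, so the hot
  # phases must be sustained; the cold intervals let clean chunks form so
  # that later pulses can fuse them. The final 1 - 2*anneal_frac of the
  # cycles run cold to refine local order. anneal_T0 = 1 disables the
  # schedule.
  n_anneal <- floor(2 * cfg$anneal_frac * n_cycles)
  pulse_len <- 8L
  temp_at <- function(cy) {
    if (anneal_T0 <= cfg$temperature || cy > n_anneal)
      return(cfg$temperature)
    ph <- (cy - 1L) %% pulse_len
    if (ph < 4L) return(anneal_T0)
    if (ph < 7L)
      return(cfg$temperature *
             (anneal_T0 / cfg$temperature)^(1 - (ph - 3L) / 3))
    cfg$temperature
  }
  traj <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    res <- run_cycle(structure, map, params, temperature = temp_at(cy),
                     k = cfg$k_anchors, eval_map = eval_map)
    structure <- res$structure
    params <- est(structure, prev = params)
    ll <- log_likelihood(structure, map, params, eval_map)
    traj[[cy]] <- c(cycle = cy, iterations = cy * map$n_bins, logL = ll,
                    A = params$A, alpha = params$alpha, delta = params$delta,
                    res$stats)
    if (isTRUE(cfg$verbose))
      message(sprintf("cycle %d: logL=%.2f A=%.3g alpha=%.3f delta=%.3g scaffolds=%d",
                      cy, ll, params$A, params$alpha, params$delta,
                      length(structure$scaffolds)))
  }
  if (isTRUE(cfg$greedy_final) && n_cycles > 0) {
    res <- run_cycle(structure, map, params, temperature = cfg$temperature,
                     k = cfg$k_anchors, eval_map = eval_map, greedy = TRUE)
    structure <- res$structure
  }
  trajectory <- as.data.frame(do.call(rbind, traj))
  attr(trajectory, "seed") <- seed
  list(structure = structure, trajectory = trajectory, params = params)
}

#' Tail interquartile ranges of a sampler trajectory
#'
#' IQR of each model parameter and of the log-likelihood over the last
#' `ceil(tail_fraction * n)` cycles; near-zero values indicate that the
#' structure has stabilized. Quartiles use linear interpolation on the
#' sorted values at positions `p = (k - 1) / (n - 1)`.
#'
#' @param trace trajectory data frame from [run_scaffolder()].
#' @param tail_fraction fraction of trailing cycles to use (default 0.2).
#' @return named numeric vector of IQRs for `A`, `alpha`, `delta`, `logL`.
#' @export
convergence_iqr <- function(trace, tail_fraction = 0.2) {
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop_("tail_fraction must be in (0, 1]")
  n <- nrow(trace)
  tn <- ceiling(tail_fraction * n)
  if (tn < 2L) stop_("fewer than 2 trailing records")
  tail_rows <- trace[(n - tn + 1L):n, , drop = FALSE]
  vapply(c("A", "alpha", "delta", "logL"), function(col) {
    q <- stats::quantile(tail_rows[[col]], c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  }, numeric(1))
}
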