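# Independent reference implementation of the rank-driven process: at every
# step the pool is explicitly re-sorted by count with random tie order.
# O(steps * pool log pool); used only at tiny sizes to cross-check the
# bucket-index implementation.
naive_rank_process <- function(alpha, steps, pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prob <- seq_len(pool)^(-alpha)
  prob <- prob / sum(prob)
  cnt <- integer(pool)
  out <- integer(steps)
  for (s in seq_len(steps)) {
    ord <- order(cnt, runif(pool), decreasing = TRUE)
    r <- sample.int(pool, 1, prob = prob)
    el <- ord[r]
    cnt[el] <- cnt[el] + 1L
    out[s] <- el
  }
  out
}

# log-spaced checkpoint Heaps fit of a simulation, the package's standard
# way of fitting simulated growth curves
sim_heaps_fit <- function(sim, checkpoints = 1000) {
  fit_heaps_lsq(growth_curve_from_stream(sim$stream, checkpoints = checkpoints))
}
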