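# Seeded differential evolution (rand/1/bin) with box constraints.
# Small, deterministic given the RNG state; callers seed before use.
de_optim <- function(fn, lower, upper, np = NULL, maxiter = 200,
                     f_weight = 0.7, crossover = 0.9, tol = 1e-8,
                     patience = 25) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  if (is.null(np)) np <- max(15L * n, 20L)
  span <- upper - lower
  pop <- sweep(matrix(stats::runif(np * n), np, n), 2, span, "*")
  pop <- sweep(pop, 2, lower, "+")
  cost <- apply(pop, 1, fn)
  best_prev <- min(cost)
  stall <- 0L
  iters <- 0L
  for (g in seq_len(maxiter)) {
    iters <- g
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 3)
      mutant <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      jrand <- sample.int(n, 1)
      mask <- stats::runif(n) < crossover
      mask[jrand] <- TRUE
      trial <- ifelse(mask, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
    best <- min(cost)
    if ((best_prev - best) <= tol * max(abs(best), 1e-12)) {
      stall <- stall + 1L
      if (stall >= patience) break
    } else stall <- 0L
    best_prev <- best
  }
  i <- which.min(cost)
  list(par = pop[i, ], value = cost[i], iterations = iters,
       converged = stall >= patience)
}
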