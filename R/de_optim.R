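#' Box-constrained differential evolution
#'
#' A compact rand/1/bin differential-evolution minimizer over a box. The
#' objective is evaluated population-wise: `fn` receives a numeric matrix
#' (one candidate per row, within the box) and returns a numeric vector of
#' objective values, which keeps the optimizer fast when the objective is
#' vectorized (as the session log-posterior is).
#'
#' @param fn Objective: `matrix[np x d] -> numeric[np]`, to be minimized.
#' @param lower,upper Numeric bound vectors of length `d`.
#' @param control List of settings, see [de_control()].
#' @param seed Integer seed; identical seeds give identical runs.
#' @return List: `par` (best candidate), `value`, `iterations`, `converged`
#'   (`TRUE` when stopped by the stall rule rather than the iteration cap),
#'   `n_eval`.
#' @export
de_optim <- function(fn, lower, upper, control = de_control(), seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  np <- if (is.null(control$np)) 10L * d else control$np
  np <- max(np, 6L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  pop <- matrix(runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  val <- fn(pop)
  n_eval <- np
  best_val <- min(val)
  stall <- 0L
  iter <- 0L
  converged <- FALSE

  for (iter in seq_len(control$maxiter)) {
    # distinct donor indices r1, r2, r3, all different from the target row
    idx <- seq_len(np)
    r1 <- sample.int(np, np, replace = TRUE)
    r2 <- sample.int(np, np, replace = TRUE)
    r3 <- sample.int(np, np, replace = TRUE)
    for (k in 1:10) {
      bad <- r1 == idx | r2 == idx | r3 == idx | r1 == r2 | r1 == r3 | r2 == r3
      if (!any(bad)) break
      r1[bad] <- sample.int(np, sum(bad), replace = TRUE)
      r2[bad] <- sample.int(np, sum(bad), replace = TRUE)
      r3[bad] <- sample.int(np, sum(bad), replace = TRUE)
    }
    mutant <- pop[r1, , drop = FALSE] +
      control$F * (pop[r2, , drop = FALSE] - pop[r3, , drop = FALSE])
    # binomial crossover with a guaranteed mutant coordinate per row
    cross <- matrix(runif(np * d) < control$CR, np, d)
    jrand <- cbind(seq_len(np), sample.int(d, np, replace = TRUE))
    cross[jrand] <- TRUE
    trial <- pop
    trial[cross] <- mutant[cross]
    # reflect out-of-box coordinates back inside, then clip
    lo <- matrix(lower, np, d, byrow = TRUE)
    hi <- matrix(upper, np, d, byrow = TRUE)
    below <- trial < lo
    trial[below] <- (2 * lo - trial)[below]
    above <- trial > hi
    trial[above] <- (2 * hi - trial)[above]
    trial <- pmin(pmax(trial, lo), hi)

    tval <- fn(trial)
    n_eval <- n_eval + np
    improve <- tval < val
    pop[improve, ] <- trial[improve, , drop = FALSE]
    val[improve] <- tval[improve]

    new_best <- min(val)
    if (best_val - new_best > control$reltol * (abs(best_val) + 1e-10)) {
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    best_val <- new_best
    if (stall >= control$stall) { converged <- TRUE; break }
  }
  b <- which.min(val)
  list(par = pop[b, ], value = val[b], iterations = iter,
       converged = converged, n_eval = n_eval)
}

#' Differential-evolution settings
#'
#' @param np Population size (default `10 * d`, chosen per problem).
#' @param maxiter Maximum generations (default 250).
#' @param stall Stop when the best value has not improved for this many
#'   generations (default 50).
#' @param F Mutation weight (default 0.8).
#' @param CR Crossover probability (default 0.9).
#' @param reltol Relative improvement below which a generation counts as
#'   stalled (default 1e-8).
#' @return A list of control settings.
#' @export
de_control <- function(np = NULL, maxiter = 250L, stall = 50L, F = 0.8,
                       CR = 0.9, reltol = 1e-8) {
  list(np = np, maxiter = as.integer(maxiter), stall = as.integer(stall),
       F = F, CR = CR, reltol = reltol)
}
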