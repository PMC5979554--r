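# The hybrid driver: each generation the population is randomly split by the
# partition rate PR, subpopulation 1 evolves under ABC and subpopulation 2
# under DE, the subpopulations are merged, and PR is updated from the elite
# probabilities O_z (fraction of global elites residing in each
# subpopulation) and the evolution rates v_z:
#     PR = O1*v1 / (O1*v1 + O2*v2),  clamped to [PR_min, PR_max].

#' Per-generation evolution rate of a subpopulation
#'
#' Slot-paired relative improvement summed over the subpopulation,
#' `sum((before - after) / (|after| + eps_denom))`, floored at a small
#' positive `eps_floor` so that the partition-rate update is always well
#' defined. Improvement (energy decrease) contributes positively.
#'
#' @param before,after Slot-paired energy vectors from the start and end of
#'   the generation, kcal/mol.
#' @param eps_floor Positive floor of the rate.
#' @param eps_denom Denominator regulariser.
#' @return Scalar rate, `>= eps_floor`.
#' @export
evolution_rate <- function(before, after, eps_floor = 1e-12,
                           eps_denom = 1e-12) {
  if (length(before) != length(after)) {
    stop("energy vectors must have equal length")
  }
  v <- sum((before - after) / (abs(after) + eps_denom))
  max(eps_floor, v)
}

#' Partition-rate update of the adaptive controller
#'
#' `PR = O1*v1 / (O1*v1 + O2*v2)`, clamped to `bounds`; a zero denominator
#' falls back to an even split (0.5).
#'
#' @param o1,o2 Elite probabilities of the two subpopulations, in `[0, 1]`.
#' @param v1,v2 Evolution rates, `>= 0`.
#' @param bounds Lower and upper clamp for the partition rate.
#' @return Partition rate in `bounds`.
#' @export
update_partition_rate <- function(o1, v1, o2, v2, bounds = c(0.1, 0.9)) {
  stopifnot(o1 >= 0, o2 >= 0, v1 >= 0, v2 >= 0)
  den <- o1 * v1 + o2 * v2
  if (den <= 0) return(0.5)
  clamp(o1 * v1 / den, bounds[1], bounds[2])
}

#' Randomly partition population indices between the two engines
#'
#' Indices are shuffled; the first `M1 = round(M * PR)` (half away from
#' zero, with `PR` first clamped to `bounds`) go to the ABC subpopulation
#' and the rest to DE, with both sizes then forced to at least `min_size`.
#'
#' @param m Population size, `>= 2 * min_size`.
#' @param pr Partition rate.
#' @param bounds Partition-rate clamp.
#' @param min_size Minimum subpopulation size (DE needs 4).
#' @return List with integer index vectors `abc` and `de`.
#' @export
partition_indices <- function(m, pr, bounds = c(0.1, 0.9), min_size = 4L) {
  if (m < 2L * min_size) {
    stop("population must have at least ", 2L * min_size, " individuals")
  }
  idx <- sample.int(m)
  m1 <- round_half_away(m * clamp(pr, bounds[1], bounds[2]))
  m1 <- max(min_size, min(m - min_size, m1))
  list(abc = idx[seq_len(m1)], de = idx[(m1 + 1L):m])
}

#' Flag the elite individuals of a population
#'
#' The `E = round(elite_fraction * M)` lowest-energy individuals (half
#' away from zero); ties at the boundary are broken by stable population
#' order.
#'
#' @param energies Population energies.
#' @param elite_fraction Fraction of the population that counts as elite.
#' @return Logical elite flags.
#' @export
find_elites <- function(energies, elite_fraction = 0.2) {
  m <- length(energies)
  e <- min(m, max(0L, round_half_away(elite_fraction * m)))
  flags <- logical(m)
  if (e > 0L) flags[order(energies)[seq_len(e)]] <- TRUE
  flags
}

#' Elite probability of a subpopulation
#'
#' The number of global elites residing in the subpopulation divided by its
#' size.
#'
#' @param elite_flags Logical elite flags over the whole population.
#' @param idx Indices of the subpopulation's members.
#' @return Probability in `[0, 1]`.
#' @export
elite_probability <- function(elite_flags, idx) {
  if (length(idx) == 0L) stop("empty subpopulation")
  sum(elite_flags[idx]) / length(idx)
}

# ---- generic search driver -------------------------------------------------
#
# Operates on raw gene vectors through three callbacks (score, init, repair),
# so the same driver runs docking problems and analytic test landscapes.
# Uses R's global RNG stream; callers seed it for reproducibility.
search_run <- function(score, init, repair,
                       algorithm = c("hybrid", "abc", "de", "random"),
                       pop_size = 100L, budget = 27000L,
                       abc = abc_config(), de = de_config(),
                       pr_init = 0.5, pr_bounds = c(0.1, 0.9),
                       elite_fraction = 0.2, eps_floor = 1e-12) {
  algorithm <- match.arg(algorithm)
  m <- as.integer(pop_size)
  if (budget < m) stop("evaluation budget must be at least the population size")
  if (algorithm %in% c("hybrid") && m < 8L) {
    stop("hybrid search needs a population of at least 8")
  }
  if (algorithm %in% c("abc", "de") && m < 4L) {
    stop(algorithm, " needs a population of at least 4")
  }

  x0 <- init()
  d <- length(x0)
  X <- matrix(0, m, d)
  X[1, ] <- x0
  for (i in seq_len(m)[-1]) X[i, ] <- init()
  energy <- vapply(seq_len(m), function(i) score(X[i, ]), 0)
  trials <- integer(m)
  evals <- m
  ib <- which.min(energy)
  best_energy <- energy[ib]
  best_x <- X[ib, ]
  note_best <- function(e, x) {
    if (e < best_energy) {
      best_energy <<- e
      best_x <<- x
    }
  }

  pr <- pr_init
  trace <- list()
  gen <- 0L
  while (evals < budget) {
    gen <- gen + 1L
    pr_used <- pr
    m1 <- NA_integer_; m2 <- NA_integer_
    o1 <- NA_real_; o2 <- NA_real_; v1 <- NA_real_; v2 <- NA_real_

    if (algorithm == "hybrid") {
      part <- partition_indices(m, pr, pr_bounds)
      i1 <- part$abc; i2 <- part$de
      m1 <- length(i1); m2 <- length(i2)
      g1 <- abc_generation(list(X = X[i1, , drop = FALSE],
                                energy = energy[i1], trials = trials[i1]),
                           score, init, repair, abc, budget - evals)
      evals <- evals + g1$evals
      g2 <- de_generation(list(X = X[i2, , drop = FALSE],
                               energy = energy[i2], trials = trials[i2]),
                          score, repair, de, budget - evals)
      evals <- evals + g2$evals
      X[i1, ] <- g1$pop$X; energy[i1] <- g1$pop$energy
      trials[i1] <- g1$pop$trials
      X[i2, ] <- g2$pop$X; energy[i2] <- g2$pop$energy
      trials[i2] <- g2$pop$trials
      note_best(g1$best_pre_scout$energy, g1$best_pre_scout$x)
      note_best(g2$best_pre_scout$energy, g2$best_pre_scout$x)
      v1 <- g1$rate; v2 <- g2$rate
      flags <- find_elites(energy, elite_fraction)
      o1 <- elite_probability(flags, i1)
      o2 <- elite_probability(flags, i2)
      # no improvement signal anywhere -> reset to an even split
      pr <- if (v1 <= eps_floor && v2 <= eps_floor) 0.5 else
        update_partition_rate(o1, v1, o2, v2, pr_bounds)
    } else if (algorithm == "abc") {
      g <- abc_generation(list(X = X, energy = energy, trials = trials),
                          score, init, repair, abc, budget - evals)
      evals <- evals + g$evals
      X <- g$pop$X; energy <- g$pop$energy; trials <- g$pop$trials
      note_best(g$best_pre_scout$energy, g$best_pre_scout$x)
    } else if (algorithm == "de") {
      g <- de_generation(list(X = X, energy = energy, trials = trials),
                         score, repair, de, budget - evals)
      evals <- evals + g$evals
      X <- g$pop$X; energy <- g$pop$energy; trials <- g$pop$trials
      note_best(g$best_pre_scout$energy, g$best_pre_scout$x)
    } else { # random search: best-so-far over i.i.d. samples
      k <- min(m, budget - evals)
      for (s in seq_len(k)) {
        v <- init()
        e <- score(v)
        note_best(e, v)
      }
      evals <- evals + k
    }
    ibg <- which.min(energy)
    note_best(energy[ibg], X[ibg, ])
    trace[[gen]] <- c(generation = gen, evaluations = evals,
                      best_energy = best_energy, pr = pr_used,
                      m1 = m1, m2 = m2, o1 = o1, o2 = o2, v1 = v1, v2 = v2)
  }
  trace <- as.data.frame(do.call(rbind, trace))
  list(best_energy = best_energy, best_x = best_x, trace = trace,
       evaluations = evals,
       population = list(X = X, energy = energy, trials = trials))
}
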