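# Artificial bee colony engine: employed, onlooker and scout phases over a
# set of food sources (candidate genotypes with cached energies and a
# stagnation counter). Energy is the fitness, minimised.

#' ABC engine settings
#'
#' @param limit Stagnation limit: a food source that fails to improve in
#'   more than `limit` attempts becomes eligible for scout replacement.
#' @param phi_range Interval the perturbation factor `phi` is drawn from,
#'   symmetric about 0.
#' @param food_source_fraction Fraction of the subpopulation that are food
#'   sources (employed bees); the remainder act as onlooker bees.
#' @param per_gene_phi Draw an independent `phi` per gene instead of one
#'   scalar per candidate.
#' @return List of class `abc_config`.
#' @export
abc_config <- function(limit = 100, phi_range = c(-1, 1),
                       food_source_fraction = 0.5, per_gene_phi = FALSE) {
  stopifnot(limit >= 1, length(phi_range) == 2L,
            isTRUE(all.equal(phi_range[1], -phi_range[2])),
            food_source_fraction > 0, food_source_fraction <= 1)
  structure(list(limit = limit, phi_range = phi_range,
                 food_source_fraction = food_source_fraction,
                 per_gene_phi = per_gene_phi),
            class = "abc_config")
}

#' Candidate food source near an existing one
#'
#' Implements the bee perturbation `v = x_i + phi * (x_i - x_k)` on the raw
#' gene vector with a single `phi` drawn uniformly from `phi_range`
#' (or one per gene), followed by repair.
#'
#' @param x_i,x_k Raw gene vectors (the existing source and a distinct
#'   randomly chosen one); their population indices must differ, equal gene
#'   values are allowed.
#' @param box A [search_box()] used for repair.
#' @param n_torsions Torsion gene count.
#' @param phi Optional fixed `phi` (otherwise drawn from `phi_range`).
#' @param phi_range Interval for `phi`.
#' @param i,k Optional population indices, checked to differ when given.
#' @return Repaired candidate gene vector.
#' @export
neighbor_candidate <- function(x_i, x_k, box, n_torsions = length(x_i) - 7L,
                               phi = NULL, phi_range = c(-1, 1),
                               i = NULL, k = NULL) {
  if (!is.null(i) && !is.null(k) && i == k) stop("neighbor must differ")
  if (is.null(phi)) phi <- runif(1, phi_range[1], phi_range[2])
  repair_vec(x_i + phi * (x_i - x_k), box$half_extent, n_torsions)
}

#' Greedy one-to-one selection
#'
#' The candidate replaces the current solution iff its energy is less than
#' or equal to the current energy (ties go to the candidate).
#'
#' @param current_energy,candidate_energy Energies, kcal/mol.
#' @return `TRUE` if the candidate survives.
#' @export
greedy_select <- function(current_energy, candidate_energy) {
  candidate_energy <= current_energy
}

#' Onlooker selection probabilities
#'
#' Maps food-source energies to a fitness-proportional distribution. Raw
#' binding energies are negative, so the standard ABC transform is applied
#' first: `F = 1/(1+E)` for `E >= 0`, `F = 1 + |E|` otherwise; then
#' `p_i = F_i / sum(F)`. Lower energy always gets strictly higher
#' probability.
#'
#' @param energies Food-source energies, kcal/mol.
#' @return Probability vector summing to 1.
#' @export
selection_probabilities <- function(energies) {
  if (length(energies) == 0L) stop("no food sources")
  f <- ifelse(energies >= 0, 1 / (1 + energies), 1 + abs(energies))
  f / sum(f)
}

# One ABC generation over a subpopulation.
# pop: list(X = n x d matrix, energy, trials). Returns the updated pop,
# evaluations used, the evolution rate of the food-source slots, and the
# best (energy, vector) observed before any scout replacement.
abc_generation <- function(pop, score, init, repair, config = abc_config(),
                           budget = Inf) {
  X <- pop$X
  energy <- pop$energy
  trials <- pop$trials
  n <- nrow(X)
  if (n < 4L) stop("ABC requires at least 4 individuals")
  n_food <- max(2L, floor(n * config$food_source_fraction))
  e_before <- energy[seq_len(n_food)]
  evals <- 0L
  lo <- config$phi_range[1]; hi <- config$phi_range[2]

  try_update <- function(i) {
    k <- seq_len(n_food)[-i][sample.int(n_food - 1L, 1L)]
    phi <- if (config$per_gene_phi) runif(ncol(X), lo, hi) else runif(1, lo, hi)
    v <- repair(X[i, ] + phi * (X[i, ] - X[k, ]))
    e <- score(v)
    if (e <= energy[i]) {
      X[i, ] <<- v
      energy[i] <<- e
      trials[i] <<- 0L
    } else {
      trials[i] <<- trials[i] + 1L
    }
  }

  # employed bees: one local probe per food source
  for (i in seq_len(n_food)) {
    if (evals >= budget) break
    try_update(i)
    evals <- evals + 1L
  }
  # onlooker bees: fitness-proportional reinforcement
  if (evals < budget && n > n_food) {
    p <- selection_probabilities(energy[seq_len(n_food)])
    for (o in seq_len(n - n_food)) {
      if (evals >= budget) break
      try_update(sample.int(n_food, 1L, prob = p))
      evals <- evals + 1L
    }
  }
  best_pre_scout <- local({
    i <- which.min(energy)
    list(energy = energy[i], x = X[i, ])
  })
  # scout: at most one exhausted source (the worst such) restarts at random
  over <- which(trials[seq_len(n_food)] > config$limit)
  if (length(over) && evals < budget) {
    i <- over[which.max(energy[over])]
    v <- init()
    X[i, ] <- v
    energy[i] <- score(v)
    trials[i] <- 0L
    evals <- evals + 1L
  }
  list(pop = list(X = X, energy = energy, trials = trials),
       evals = evals,
       rate = evolution_rate(e_before, energy[seq_len(n_food)]),
       best_pre_scout = best_pre_scout)
}
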