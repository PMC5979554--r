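# Differential evolution engine (rand/1/bin): mutation from three random
# donors, binomial crossover with a forced gene, one-to-one greedy survival.

#' DE engine settings
#'
#' @param f Differential weight multiplying the donor difference vector.
#' @param cr Crossover probability in `[0, 1]`.
#' @return List of class `de_config`.
#' @export
de_config <- function(f = 0.9, cr = 0.8) {
  stopifnot(f > 0, cr >= 0, cr <= 1)
  structure(list(f = f, cr = cr), class = "de_config")
}

#' DE mutation (rand/1)
#'
#' `v = x_r1 + f * (x_r2 - x_r3)` on raw gene vectors; the caller guarantees
#' the three donor indices and the target index are pairwise distinct.
#'
#' @param x_r1,x_r2,x_r3 Donor gene vectors.
#' @param f Differential weight.
#' @param box Optional [search_box()]; when given the mutant is repaired.
#' @param n_torsions Torsion gene count (for repair).
#' @param r1,r2,r3,target Optional indices, checked pairwise distinct when
#'   given.
#' @return Mutant gene vector.
#' @export
de_mutate <- function(x_r1, x_r2, x_r3, f = 0.9, box = NULL,
                      n_torsions = length(x_r1) - 7L,
                      r1 = NULL, r2 = NULL, r3 = NULL, target = NULL) {
  idx <- c(r1, r2, r3, target)
  if (length(idx) && anyDuplicated(idx)) {
    stop("donor and target indices must be pairwise distinct")
  }
  v <- x_r1 + f * (x_r2 - x_r3)
  if (!is.null(box)) v <- repair_vec(v, box$half_extent, n_torsions)
  v
}

#' Binomial crossover with one forced mutant gene
#'
#' Per gene the trial takes the mutant's value with probability `cr`,
#' otherwise the target's; one uniformly chosen gene index always comes from
#' the mutant so that the trial can differ from the target even at
#' `cr = 0`.
#'
#' @param target,mutant Gene vectors of equal length.
#' @param cr Crossover probability.
#' @param j_rand Optional forced gene index (drawn uniformly when `NULL`).
#' @return Trial gene vector.
#' @export
de_crossover <- function(target, mutant, cr = 0.8, j_rand = NULL) {
  stopifnot(length(target) == length(mutant))
  d <- length(target)
  if (is.null(j_rand)) j_rand <- sample.int(d, 1L)
  take <- runif(d) < cr
  take[j_rand] <- TRUE
  ifelse(take, mutant, target)
}

#' DE survivor selection
#'
#' The trial replaces the target iff its energy is less than or equal to the
#' target's (ties go to the trial).
#'
#' @param target_energy,trial_energy Energies, kcal/mol.
#' @return `TRUE` if the trial survives.
#' @export
de_select <- function(target_energy, trial_energy) {
  trial_energy <= target_energy
}

# One DE generation over a subpopulation. Donors and targets are taken from
# the generation-start snapshot; survivors form the next generation.
de_generation <- function(pop, score, repair, config = de_config(),
                          budget = Inf) {
  X0 <- pop$X
  e0 <- pop$energy
  n <- nrow(X0)
  if (n < 4L) stop("DE requires at least 4 individuals")
  d <- ncol(X0)
  X <- X0
  energy <- e0
  evals <- 0L
  for (i in seq_len(n)) {
    if (evals >= budget) break
    donors <- seq_len(n)[-i][sample.int(n - 1L, 3L)]
    v <- repair(X0[donors[1], ] + config$f * (X0[donors[2], ] - X0[donors[3], ]))
    u <- de_crossover(X0[i, ], v, config$cr)
    u <- repair(u)
    e <- score(u)
    evals <- evals + 1L
    if (e <= e0[i]) {
      X[i, ] <- u
      energy[i] <- e
    }
  }
  list(pop = list(X = X, energy = energy, trials = pop$trials),
       evals = evals,
       rate = evolution_rate(e0, energy),
       best_pre_scout = local({
         i <- which.min(energy)
         list(energy = energy[i], x = X[i, ])
       }))
}
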