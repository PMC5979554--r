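#' Search settings for [dock()]
#'
#' Defaults follow the reference parameterisation of the hybrid search:
#' population 100, evaluation budget 27,000, ABC stagnation limit 100 with
#' food sources at half the subpopulation, DE weight 0.9 and crossover rate
#' 0.8, initial partition rate 0.5 clamped to `[0.1, 0.9]`, elites at 20% of
#' the population.
#'
#' @param pop_size Population size `M` (`>= 8` for the hybrid).
#' @param budget Total score-function evaluation budget (`>= pop_size`).
#' @param limit ABC stagnation limit.
#' @param food_source_fraction Fraction of the ABC subpopulation that are
#'   food sources.
#' @param phi_range ABC perturbation interval, symmetric about 0.
#' @param f DE differential weight.
#' @param cr DE crossover probability.
#' @param pr_init Initial partition rate (ABC share).
#' @param pr_bounds Partition-rate clamp.
#' @param elite_fraction Elite share of the population.
#' @return List of class `dock_control`.
#' @export
dock_control <- function(pop_size = 100L, budget = 27000L,
                         limit = 100L, food_source_fraction = 0.5,
                         phi_range = c(-1, 1), f = 0.9, cr = 0.8,
                         pr_init = 0.5, pr_bounds = c(0.1, 0.9),
                         elite_fraction = 0.2) {
  stopifnot(pop_size >= 4L, budget >= pop_size,
            pr_init >= 0, pr_init <= 1,
            length(pr_bounds) == 2L, pr_bounds[1] <= pr_bounds[2],
            elite_fraction > 0, elite_fraction <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 budget = as.integer(budget),
                 abc = abc_config(limit = limit,
                                  phi_range = phi_range,
                                  food_source_fraction = food_source_fraction),
                 de = de_config(f = f, cr = cr),
                 pr_init = pr_init, pr_bounds = pr_bounds,
                 elite_fraction = elite_fraction),
            class = "dock_control")
}

#' Dock a flexible ligand into a rigid receptor
#'
#' Minimises the semi-empirical binding free energy over the ligand's
#' translation + orientation + torsion space inside the search box, using
#' the adaptive hybrid of the bee-colony and differential-evolution engines
#' (or one of the single-engine / random-sampling baselines).
#'
#' @param receptor A `receptor` from [read_pdbqt_receptor()].
#' @param ligand A `ligand` from [read_pdbqt_ligand()].
#' @param box A [search_box()].
#' @param algorithm `"hybrid"` (ABC + DE under the adaptive partition
#'   controller), `"abc"`, `"de"`, or `"random"`.
#' @param control A [dock_control()].
#' @param forcefield A [load_forcefield()] table.
#' @param seed Optional integer seed; with a fixed seed the full run
#'   (trace included) is reproducible bit for bit.
#' @return An object of class `dock_result`: the best genotype and pose,
#'   its [binding_energy()] breakdown, the per-generation convergence and
#'   partition trace, and the exact number of evaluations used.
#' @seealso [make_toy_complex()] for ready-made synthetic systems,
#'   [run_bench()] for batch evaluation.
#' @export
#' @examples
#' toy <- make_toy_complex(seed = 7, n_torsions = 1)
#' fit <- dock(toy$receptor, toy$ligand, toy$box,
#'             control = dock_control(pop_size = 20, budget = 600), seed = 1)
#' fit
#' rmsd(predict(fit), build_pose(toy$ligand, toy$planted, toy$box),
#'      heavy_only = TRUE, types = toy$ligand$atoms$type)
dock <- function(receptor, ligand, box,
                 algorithm = c("hybrid", "abc", "de", "random"),
                 control = dock_control(), forcefield = load_forcefield(),
                 seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(control, "dock_control"))
  if (!is.null(seed)) set.seed(seed)
  sc <- make_scorer(receptor, ligand, box, forcefield)
  nt <- ligand$n_torsions
  half <- box$half_extent
  res <- search_run(score = sc$score_vec,
                    init = function() random_gvec(nt, half),
                    repair = function(v) repair_vec(v, half, nt),
                    algorithm = algorithm,
                    pop_size = control$pop_size, budget = control$budget,
                    abc = control$abc, de = control$de,
                    pr_init = control$pr_init, pr_bounds = control$pr_bounds,
                    elite_fraction = control$elite_fraction)
  structure(list(algorithm = algorithm,
                 energy = sc$breakdown_vec(res$best_x),
                 genotype = vec_to_genotype(res$best_x),
                 pose = build_pose_vec(ligand, res$best_x, box),
                 trace = res$trace,
                 evaluations = res$evaluations,
                 control = control, seed = seed,
                 receptor = receptor, ligand = ligand, box = box,
                 call = match.call()),
            class = "dock_result")
}
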