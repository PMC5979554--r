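# Batch evaluation: success rates, box-plot statistics, rank tests, and the
# benchmark runner over fixture suites.

#' Docking success rate at an RMSD threshold
#'
#' A run counts as successful when its RMSD to the reference pose is
#' strictly smaller than the threshold (default 2.0 A).
#'
#' @param rmsds RMSD values, Angstrom.
#' @param threshold Success threshold, Angstrom, > 0.
#' @return List with `count` and `fraction`.
#' @export
success_rate <- function(rmsds, threshold = 2.0) {
  if (length(rmsds) == 0L) stop("no RMSD values")
  stopifnot(threshold > 0)
  n <- sum(rmsds < threshold)
  list(count = n, fraction = n / length(rmsds))
}

#' Five-number box-plot statistics
#'
#' Median and quartiles by the linear-interpolation convention
#' ([stats::quantile()] type 7), Tukey whiskers (most extreme observations
#' within 1.5 IQR of the quartiles) and the outliers beyond them.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return List of class `box_stats`: `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `outliers`.
#' @export
box_stats <- function(values) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(values[inside]),
                 whisker_hi = max(values[inside]),
                 outliers = values[!inside]),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("median %.3f [Q1 %.3f, Q3 %.3f], whiskers [%.3f, %.3f], %d outlier(s)\n",
              x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
              length(x$outliers)))
  invisible(x)
}

#' Rank-based comparison of two algorithms' best energies
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the two samples, the
#' usual protocol being the n = 10 best values per algorithm per complex.
#' Fully tied samples give p = 1 (no evidence of a difference).
#'
#' @param samples_a,samples_b Best-energy samples, `n >= 5` each.
#' @param alpha Significance level.
#' @return List with `statistic` (Mann-Whitney U of sample A), `p_value`,
#'   and the logical `significant` (`p < alpha`).
#' @export
compare_algorithms <- function(samples_a, samples_b, alpha = 0.05) {
  stopifnot(length(samples_a) >= 5L, length(samples_b) >= 5L)
  pooled <- c(samples_a, samples_b)
  if (max(pooled) == min(pooled)) {
    return(list(statistic = NA_real_, p_value = 1, significant = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(samples_a, samples_b,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha)
}

#' Run a docking benchmark over complexes, algorithms and seeds
#'
#' Docks every complex with every algorithm and seed under the same budget
#' and records the best energy, the heavy-atom RMSD to the planted reference
#' pose, and the evaluations used.
#'
#' @param complexes A `toy_complex` or (named) list of them.
#' @param algorithms Subset of `c("hybrid", "abc", "de", "random")`.
#' @param seeds Integer seeds; each (complex, algorithm, seed) triple is one
#'   independent run.
#' @param control A [dock_control()].
#' @param forcefield A [load_forcefield()] table.
#' @param verbose Print one line per run.
#' @return Data frame of run records: `complex`, `algorithm`, `seed`,
#'   `n_torsions`, `best_energy`, `best_rmsd`, `evaluations`.
#' @export
run_bench <- function(complexes, algorithms = c("hybrid", "abc", "de"),
                      seeds = 1:10, control = dock_control(),
                      forcefield = load_forcefield(), verbose = FALSE) {
  if (inherits(complexes, "toy_complex")) complexes <- list(complexes)
  if (is.null(names(complexes))) {
    names(complexes) <- paste0("complex", seq_along(complexes))
  }
  algorithms <- match.arg(algorithms, c("hybrid", "abc", "de", "random"),
                          several.ok = TRUE)
  rows <- list()
  for (cx_name in names(complexes)) {
    cx <- complexes[[cx_name]]
    ref_pose <- build_pose(cx$ligand, cx$planted, cx$box)
    types <- cx$ligand$atoms$type
    for (alg in algorithms) {
      for (s in seeds) {
        fit <- dock(cx$receptor, cx$ligand, cx$box, algorithm = alg,
                    control = control, forcefield = forcefield, seed = s)
        r <- rmsd(fit$pose, ref_pose, heavy_only = TRUE, types = types)
        rows[[length(rows) + 1L]] <-
          data.frame(complex = cx_name, algorithm = alg, seed = s,
                     n_torsions = cx$ligand$n_torsions,
                     best_energy = fit$energy$total, best_rmsd = r,
                     evaluations = fit$evaluations,
                     stringsAsFactors = FALSE)
        if (verbose) {
          cat(sprintf("%s %-6s seed %3d: %8.3f kcal/mol, rmsd %5.2f A\n",
                      cx_name, alg, s, fit$energy$total, r))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise benchmark records
#'
#' Per-algorithm medians/quartiles of the best energies, success counts at
#' the 2 A RMSD threshold, and pairwise two-sided rank tests between all
#' algorithm pairs on the pooled best energies.
#'
#' @param records Data frame from [run_bench()].
#' @param alpha Significance level for the rank tests.
#' @return List of class `bench_summary` with data frames `by_algorithm` and
#'   `pairwise`.
#' @export
bench_summary <- function(records, alpha = 0.05) {
  algs <- unique(records$algorithm)
  by_alg <- do.call(rbind, lapply(algs, function(a) {
    e <- records$best_energy[records$algorithm == a]
    r <- records$best_rmsd[records$algorithm == a]
    bs <- box_stats(e)
    sr <- success_rate(r)
    data.frame(algorithm = a, n = length(e),
               median_energy = bs$median, q1_energy = bs$q1,
               q3_energy = bs$q3, mean_rmsd = mean(r),
               successes = sr$count, success_fraction = sr$fraction,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(algs, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    ct <- compare_algorithms(records$best_energy[records$algorithm == p[1]],
                             records$best_energy[records$algorithm == p[2]],
                             alpha)
    data.frame(algorithm_a = p[1], algorithm_b = p[2],
               statistic = ct$statistic, p_value = ct$p_value,
               significant = ct$significant, stringsAsFactors = FALSE)
  }))
  structure(list(by_algorithm = by_alg, pairwise = pairwise, alpha = alpha),
            class = "bench_summary")
}

#' @export
print.bench_summary <- function(x, ...) {
  cat("Benchmark summary (energies in kcal/mol; success = RMSD < 2 A):\n")
  print(x$by_algorithm, row.names = FALSE, digits = 4)
  cat("\nPairwise rank tests (alpha =", x$alpha, "):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
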