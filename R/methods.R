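# S3 methods for dock_result

#' @export
print.dock_result <- function(x, ...) {
  cat("Docking run (", x$algorithm, "), ", x$evaluations,
      " energy evaluations\n", sep = "")
  cat(sprintf("  best binding energy: %.3f kcal/mol\n", x$energy$total))
  cat("  ligand:", nrow(x$ligand$atoms), "atoms,",
      x$ligand$n_torsions, "torsions\n")
  invisible(x)
}

#' @export
summary.dock_result <- function(object, ...) {
  structure(list(result = object), class = "summary.dock_result")
}

#' @export
print.summary.dock_result <- function(x, ...) {
  r <- x$result
  print(r)
  cat("\nEnergy breakdown:\n")
  print(r$energy)
  tr <- r$trace
  if (nrow(tr)) {
    cat("\nConvergence: ", nrow(tr), " generations; best energy ",
        sprintf("%.3f", tr$best_energy[1]), " -> ",
        sprintf("%.3f", tr$best_energy[nrow(tr)]), " kcal/mol\n", sep = "")
    if (r$algorithm == "hybrid") {
      cat(sprintf("Partition rate: start %.2f, final %.2f, mean %.2f\n",
                  tr$pr[1], tr$pr[nrow(tr)], mean(tr$pr)))
    }
  }
  invisible(x)
}

#' Best genotype of a docking run as a named gene vector
#' @param object A `dock_result`.
#' @param ... Unused.
#' @export
coef.dock_result <- function(object, ...) {
  g <- object$genotype
  nt <- length(g$torsions)
  stats::setNames(c(g$translation, g$orientation, g$torsions),
                  c("tx", "ty", "tz", "qw", "qx", "qy", "qz",
                    if (nt) paste0("tor", seq_len(nt))))
}

#' Ligand pose coordinates predicted by a docking run
#'
#' Without `newdata`, the best pose found; with `newdata` (a `genotype` or
#' raw gene vector), the pose that genotype encodes under the run's ligand
#' and box.
#'
#' @param object A `dock_result`.
#' @param newdata Optional genotype.
#' @param ... Unused.
#' @return N x 3 coordinate matrix, Angstrom.
#' @export
predict.dock_result <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$pose)
  build_pose(object$ligand, newdata, object$box)
}

#' Convergence (and partition) trace plot of a docking run
#'
#' Top panel: best-so-far binding energy against evaluations used. For
#' hybrid runs a second panel shows the partition rate (ABC share of the
#' population) per generation.
#'
#' @param x A `dock_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dock_result <- function(x, ...) {
  tr <- x$trace
  if (!nrow(tr)) return(invisible(x))
  two <- x$algorithm == "hybrid"
  if (two) {
    op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(par(op))
  }
  plot(tr$evaluations, tr$best_energy, type = "s",
       xlab = "energy evaluations", ylab = "best energy (kcal/mol)",
       main = paste("convergence:", x$algorithm), ...)
  if (two) {
    plot(tr$evaluations, tr$pr, type = "s", ylim = c(0, 1),
         xlab = "energy evaluations", ylab = "partition rate (ABC share)")
    abline(h = 0.5, lty = 3)
  }
  invisible(x)
}
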