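#' Load a pairwise force-field parameter table
#'
#' Reads the per-atom-type parameters that drive the semi-empirical binding
#' free-energy score: Lennard-Jones 12-6 well depths and radii, 12-10
#' hydrogen-bond parameters, atomic solvation parameters and volumes, plus the
#' global term weights, the desolvation Gaussian width and the dielectric
#' model. The packaged default table carries the published AutoDock 4.2
#' free-energy-model constants.
#'
#' Pairwise coefficients are combined from the per-type entries as
#' \deqn{A_{ij} = \epsilon_{ij} R_{ij}^{12}, \quad B_{ij} = 2 \epsilon_{ij} R_{ij}^6}
#' with \eqn{R_{ij} = (R_{ii}+R_{jj})/2} and
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_{ii}\epsilon_{jj}}}, so the 12-6 curve
#' has its minimum at \eqn{r = (2A/B)^{1/6} = R_{ij}} with depth
#' \eqn{-B^2/(4A) = -\epsilon_{ij}}. Donor-acceptor pairs instead use the
#' 12-10 coefficients \eqn{C = 5\epsilon_{hb}R_{hb}^{12}},
#' \eqn{D = 6\epsilon_{hb}R_{hb}^{10}} (minimum at \eqn{R_{hb}}, depth
#' \eqn{-\epsilon_{hb}}), taken from the acceptor's entry.
#'
#' @param path Path to a whitespace-delimited parameter file with columns
#'   `type radius well solpar volume hbond rhb epshb` (`#` comments allowed),
#'   or `NULL` for the packaged default table.
#' @param weights Named numeric vector of global term weights
#'   (`vdw`, `hbond`, `elec`, `sol`, `conf`).
#' @param sigma Desolvation Gaussian width, Angstrom.
#' @param dielectric Either `"mehler-solmajer"` for the sigmoidal
#'   distance-dependent screening function, or a single positive number for a
#'   constant dielectric.
#' @return An object of class `forcefield`.
#' @export
#' @examples
#' ff <- load_forcefield()
#' ff_pair_params(ff, "C", "OA")
load_forcefield <- function(path = NULL,
                            weights = c(vdw = 0.1662, hbond = 0.1209,
                                        elec = 0.1406, sol = 0.1322,
                                        conf = 0.2983),
                            sigma = 3.5,
                            dielectric = "mehler-solmajer") {
  if (is.null(path)) {
    path <- system.file("extdata", "ad4_types.txt", package = "hivedock",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("force-field file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("type", "radius", "well", "solpar",
                                         "volume", "hbond", "rhb", "epshb"),
                           colClasses = c("character", rep("numeric", 7)),
                           na.strings = character(0), # "NA" is a real type
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$type)) stop("duplicated atom types in parameter file")
  if (any(tab$radius <= 0) || any(tab$well <= 0)) {
    stop("radii and well depths must be positive")
  }
  stopifnot(sigma > 0)
  req <- c("vdw", "hbond", "elec", "sol", "conf")
  if (!all(req %in% names(weights))) {
    stop("weights must name: ", paste(req, collapse = ", "))
  }
  if (is.numeric(dielectric)) {
    stopifnot(length(dielectric) == 1L, dielectric > 0)
  } else if (!identical(dielectric, "mehler-solmajer")) {
    stop("dielectric must be \"mehler-solmajer\" or a positive number")
  }
  structure(list(types = tab,
                 weights = weights[req],
                 sigma = sigma,
                 coulomb = 332.06363,   # kcal*A/(mol*e^2)
                 qsolpar = 0.01097,     # charge-dependent solvation increment
                 dielectric = dielectric),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("<forcefield>", nrow(x$types), "atom types:",
      paste(x$types$type, collapse = " "), "\n")
  cat("  weights:", paste(sprintf("%s=%.4f", names(x$weights), x$weights),
                          collapse = " "), "\n")
  cat("  sigma:", x$sigma, "A; dielectric:",
      if (is.numeric(x$dielectric)) paste("constant", x$dielectric)
      else x$dielectric, "\n")
  invisible(x)
}

ff_type_row <- function(ff, type) {
  i <- match(type, ff$types$type)
  if (is.na(i)) {
    stop("unknown atom type \"", type, "\"; known types: ",
         paste(ff$types$type, collapse = ", "))
  }
  ff$types[i, ]
}

ff_is_hbond_pair <- function(ri, rj) {
  (ri$hbond == 1 && rj$hbond == 2) || (ri$hbond == 2 && rj$hbond == 1)
}

#' Pairwise interaction coefficients for two atom types
#'
#' @param ff A `forcefield` object.
#' @param type_i,type_j AutoDock atom type tokens.
#' @return List with `A`, `B` (12-6 coefficients), `C`, `D` (12-10
#'   hydrogen-bond coefficients, 0 unless the pair is donor-acceptor) and the
#'   logical `hbond`. Symmetric in its type arguments.
#' @export
ff_pair_params <- function(ff, type_i, type_j) {
  ri <- ff_type_row(ff, type_i)
  rj <- ff_type_row(ff, type_j)
  rij <- (ri$radius + rj$radius) / 2
  eij <- sqrt(ri$well * rj$well)
  hb <- ff_is_hbond_pair(ri, rj)
  if (hb) {
    acc <- if (ri$hbond == 2) ri else rj
    list(A = eij * rij^12, B = 2 * eij * rij^6,
         C = 5 * acc$epshb * acc$rhb^12, D = 6 * acc$epshb * acc$rhb^10,
         hbond = TRUE)
  } else {
    list(A = eij * rij^12, B = 2 * eij * rij^6, C = 0, D = 0, hbond = FALSE)
  }
}

# screening dielectric e(r); vectorised over r
ff_dielectric <- function(ff, r) {
  if (is.numeric(ff$dielectric)) {
    rep_len(ff$dielectric, length(r))
  } else {
    # Mehler-Solmajer sigmoidal screening
    A <- -8.5525
    B <- 78.4 - A
    k <- 7.7839
    lam <- 0.003627
    A + B / (1 + k * exp(-lam * B * r))
  }
}

# per-atom solvation parameter including the |q| increment
ff_atom_solpar <- function(ff, types, charges) {
  idx <- match(types, ff$types$type)
  ff$types$solpar[idx] + ff$qsolpar * abs(charges)
}

ff_atom_volume <- function(ff, types) {
  ff$types$volume[match(types, ff$types$type)]
}
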