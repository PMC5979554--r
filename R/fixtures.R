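# Synthetic receptor-ligand systems with planted poses, analytic test
# landscapes, and a brute-force translation-grid oracle. Everything here is
# deterministic given its seed and scores through the production scoring
# path -- no special-cased physics.

#' Generate a synthetic receptor-ligand complex with a planted pose
#'
#' The ligand is a zigzag chain with `n_torsions` nested rotatable bonds and
#' a charge gradient along its axis. The receptor pocket is moulded around
#' the planted pose (the centered chain, zero torsions, identity
#' orientation): every receptor atom is anchored to one ligand atom at the
#' anchored pair's own energy-optimal distance (the 12-6 minimum, or the
#' 12-10 hydrogen-bond minimum for donor-acceptor pairs), placed in a
#' clash-checked direction that leaves an entry channel open towards +z,
#' and given a charge complementary to its anchor. The planted pose
#' therefore sits at the bottom of a genuine binding funnel.
#'
#' With the same seed the same complex (and, when `dir` is given, byte-for-
#' byte identical PDBQT files) is produced; the caller's RNG stream is left
#' untouched.
#'
#' @param seed Integer seed for the jitter in the receptor geometry.
#' @param n_rec Number of receptor atoms, `>= 6`.
#' @param n_lig Number of ligand atoms, `>= 3`.
#' @param n_torsions Rotatable bond count `T`, `0 <= T <= n_lig - 3`.
#' @param dir Optional directory; when given, `receptor.pdbqt` and
#'   `ligand.pdbqt` are written there.
#' @return An object of class `toy_complex`: `receptor`, `ligand`, `box`
#'   ([search_box()] of half extent 3.5 A), the `planted` [genotype()], and
#'   file `paths` when written.
#' @export
make_toy_complex <- function(seed = 1L, n_rec = 60L, n_lig = 8L,
                             n_torsions = 2L, dir = NULL) {
  stopifnot(n_rec >= 6L, n_lig >= 3L, n_torsions >= 0L)
  # the terminal branch owns two atoms so every torsion moves something
  if (n_torsions > 0L && n_lig - n_torsions - 1L < 3L) {
    stop("ligand needs at least 3 rigid-root atoms: ",
         "n_lig - n_torsions - 1 >= 3 for flexible ligands")
  }
  with_local_seed(seed, {
    # ---- ligand: zigzag chain, bond length ~1.55 A --------------------
    k <- seq_len(n_lig)
    lx <- (k - 1) * 1.26
    ly <- 0.45 * (-1)^k
    # aperiodic helical twist makes the chain chiral with no screw
    # self-symmetry, so flipped or shifted poses cannot fit the pocket
    # moulded around the planted pose
    lz <- 0.45 * sin(1.7 * (k - 1) + 0.4)
    lig_xyz <- cbind(lx - mean(lx), ly - mean(ly), lz - mean(lz))
    lig_type <- rep("C", n_lig)
    lig_type[1] <- "N"       # non-acceptor amine-like end (positive)
    lig_type[n_lig] <- "OA"  # acceptor end (negative)
    if (n_lig >= 6L) lig_type[3L] <- "A"
    lig_q <- -0.45 * lig_xyz[, 1] / max(abs(lig_xyz[, 1]))
    # nested chain of branches; the terminal branch owns the last two atoms
    # so its torsion moves an off-axis atom
    n_root <- if (n_torsions > 0L) n_lig - n_torsions - 1L else n_lig
    groups <- integer(n_lig)
    branches <- lapply(seq_len(n_torsions), function(j) {
      own <- if (j < n_torsions) n_root + j else c(n_root + j, n_lig)
      list(axis_from_serial = n_root + j - 1L, axis_to_serial = n_root + j,
           parent = j - 1L,
           axis_from = n_root + j - 1L, axis_to = n_root + j,
           atoms = own, subtree = (n_root + j):n_lig)
    })
    for (j in seq_len(n_torsions)) groups[branches[[j]]$atoms] <- j
    ligand <- structure(list(
      atoms = data.frame(serial = k, name = paste0("L", k), type = lig_type,
                         charge = round(lig_q, 3), stringsAsFactors = FALSE),
      coords = unname(lig_xyz),
      root = seq_len(n_root), groups = groups, branches = branches,
      n_torsions = n_torsions, torsdof = n_torsions), class = "ligand")

    # ---- receptor: pocket moulded around the planted ligand -----------
    ff <- load_forcefield()
    # pair-optimal distance (12-6 minimum, or 12-10 for donor-acceptor)
    opt_dist <- function(ti, tj) {
      pp <- ff_pair_params(ff, ti, tj)
      if (pp$hbond) (6 * pp$C / (5 * pp$D))^0.5 else (2 * pp$A / pp$B)^(1 / 6)
    }
    # receptor types chosen per anchored ligand atom: acceptors get
    # alternating hydrogen-bond donors (steep 12-10 wells that pin the
    # planted pose), other atoms a mix of apolar/polar types
    anchor <- (seq_len(n_rec) - 1L) %% n_lig + 1L
    cyc_plain <- c("C", "N", "C", "A", "OA", "C", "SA", "C")
    seen <- integer(n_lig)
    rec_type <- character(n_rec)
    for (a in seq_len(n_rec)) {
      seen[anchor[a]] <- seen[anchor[a]] + 1L
      rec_type[a] <- if (lig_type[anchor[a]] %in% c("OA", "NA")) {
        "HD" # every acceptor anchor is a donor: steep, unambiguous pinning
      } else {
        cyc_plain[(seen[anchor[a]] - 1L) %% 8L + 1L]
      }
    }
    rec_xyz <- matrix(0, n_rec, 3)
    for (a in seq_len(n_rec)) {
      ropt <- vapply(lig_type, function(t) opt_dist(rec_type[a], t), 0)
      placed <- FALSE
      for (try in 1:400) {
        dirv <- rnorm(3)
        dirv <- dirv / sqrt(sum(dirv * dirv))
        if (dirv[3] > 0.75) next # keep a +z entry channel open
        p <- lig_xyz[anchor[a], ] + ropt[anchor[a]] * dirv
        d <- sqrt(rowSums(sweep(lig_xyz, 2, p)^2))
        if (all(d >= 0.97 * ropt)) {
          rec_xyz[a, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { # fall back to straight below the anchor
        rec_xyz[a, ] <- lig_xyz[anchor[a], ] + c(0, 0, -ropt[anchor[a]])
      }
    }
    # charges complementary to the anchored ligand atom, with a small
    # alternating residual where the anchor is nearly neutral
    rec_q <- clamp(-1.2 * lig_q[anchor], -0.7, 0.7) +
      0.05 * rep_len(c(1, -1), n_rec)
    receptor <- structure(list(
      atoms = data.frame(serial = seq_len(n_rec),
                         name = paste0("R", seq_len(n_rec)),
                         type = rec_type, charge = round(unname(rec_q), 3),
                         stringsAsFactors = FALSE),
      coords = unname(rec_xyz)), class = "receptor")

    box <- search_box(c(0, 0, 0), c(3.5, 3.5, 3.5))
    # pose = (coords - root_centroid) + center + translation, so the
    # centered chain is reproduced by translation = root centroid
    planted <- genotype(translation = colMeans(lig_xyz[seq_len(n_root), ,
                                                       drop = FALSE]),
                        orientation = c(1, 0, 0, 0),
                        torsions = rep(0, n_torsions))
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(receptor = file.path(dir, "receptor.pdbqt"),
                    ligand = file.path(dir, "ligand.pdbqt"))
      write_pdbqt(receptor, paths$receptor)
      write_pdbqt(ligand, paths$ligand)
    }
    structure(list(receptor = receptor, ligand = ligand, box = box,
                   planted = planted, seed = seed, paths = paths),
              class = "toy_complex")
  })
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("<toy_complex> seed", x$seed, "-", nrow(x$receptor$atoms),
      "receptor atoms,", nrow(x$ligand$atoms), "ligand atoms,",
      x$ligand$n_torsions, "torsions\n")
  invisible(x)
}

#' The standard five-complex benchmark suite
#'
#' Five synthetic complexes of increasing flexibility (0 to 4 rotatable
#' bonds) built by [make_toy_complex()] with fixed seeds.
#'
#' @return Named list of `toy_complex` objects.
#' @export
toy_suite <- function() {
  spec <- list(T0 = list(seed = 101L, n_lig = 6L, nt = 0L),
               T1 = list(seed = 102L, n_lig = 7L, nt = 1L),
               T2 = list(seed = 103L, n_lig = 8L, nt = 2L),
               T3 = list(seed = 104L, n_lig = 8L, nt = 3L),
               T4 = list(seed = 105L, n_lig = 8L, nt = 4L))
  lapply(spec, function(s) {
    make_toy_complex(seed = s$seed, n_rec = 60L, n_lig = s$n_lig,
                     n_torsions = s$nt)
  })
}

#' Minimal hand-checkable complex
#'
#' One receptor atom (`OA`, charge -0.30) at the origin and a rigid two-atom
#' ligand (`C` +0.20 at the root, `HD` +0.05 at 1.0 A): small enough that
#' every energy term can be summed by hand from the pairwise formulas.
#'
#' @return A `toy_complex`-like list (receptor, ligand, box, planted).
#' @export
make_hand_complex <- function() {
  receptor <- structure(list(
    atoms = data.frame(serial = 1L, name = "R1", type = "OA", charge = -0.30,
                       stringsAsFactors = FALSE),
    coords = matrix(0, 1, 3)), class = "receptor")
  ligand <- structure(list(
    atoms = data.frame(serial = 1:2, name = c("L1", "L2"),
                       type = c("C", "HD"), charge = c(0.20, 0.05),
                       stringsAsFactors = FALSE),
    coords = rbind(c(0, 0, 0), c(1, 0, 0)),
    root = 1:2, groups = c(0L, 0L), branches = list(),
    n_torsions = 0L, torsdof = 0L), class = "ligand")
  list(receptor = receptor, ligand = ligand,
       box = search_box(c(0, 0, 0), c(5, 5, 5)),
       planted = genotype(c(3.5, 0, 0)))
}

#' Exhaustive translation-grid oracle
#'
#' Brute-force reference optimum for acceptance testing: evaluates the full
#' binding energy on every point of a regular translation lattice spanning
#' the search box, holding orientation and torsions fixed at the planted
#' genotype. Independent of the stochastic search path.
#'
#' @param toy A `toy_complex`.
#' @param spacing Lattice spacing, Angstrom, `<= 0.5`.
#' @param forcefield A [load_forcefield()] table.
#' @return List with `min_energy` (kcal/mol), `argmin` (translation vector),
#'   `n_points` and `spacing`.
#' @export
translation_grid_oracle <- function(toy, spacing = 0.5,
                                    forcefield = load_forcefield()) {
  stopifnot(inherits(toy, "toy_complex") || is.list(toy))
  if (spacing > 0.5) stop("spacing must be <= 0.5 Angstrom")
  h <- toy$box$half_extent
  xs <- seq(-h[1], h[1], by = spacing)
  ys <- seq(-h[2], h[2], by = spacing)
  zs <- seq(-h[3], h[3], by = spacing)
  n_points <- length(xs) * length(ys) * length(zs)
  if (n_points > 1e6) stop("grid too large: ", n_points, " points")
  sc <- make_scorer(toy$receptor, toy$ligand, toy$box, forcefield)
  nt <- toy$ligand$n_torsions
  base_vec <- c(0, 0, 0, toy$planted$orientation, toy$planted$torsions)
  base <- build_pose_vec(toy$ligand, base_vec, toy$box)
  best <- Inf
  arg <- c(NA_real_, NA_real_, NA_real_)
  n <- nrow(base)
  for (z in zs) {
    for (y in ys) {
      for (x in xs) {
        L <- base + matrix(c(x, y, z), n, 3, byrow = TRUE)
        e <- sc$score_coords(L)
        if (e < best) {
          best <- e
          arg <- c(x, y, z)
        }
      }
    }
  }
  list(min_energy = best, argmin = arg, n_points = n_points,
       spacing = spacing)
}

#' Analytic benchmark landscapes for the search engines
#'
#' Closed-form objectives over raw gene vectors, decoupled from the docking
#' score, with global minimum 0 at the origin: `"sphere"` (`sum(x^2)`) and
#' `"rastrigin"` (`10 d + sum(x^2 - 10 cos(2 pi x))`), on `[-5.12, 5.12]^d`.
#'
#' @param name Landscape name.
#' @param dim Dimension, `>= 1`.
#' @return List with `score`, `init` and `repair` callbacks (as consumed by
#'   the internal search driver), `dim` and the known `optimum`.
#' @export
analytic_landscape <- function(name = c("sphere", "rastrigin"), dim = 2L) {
  name <- match.arg(name)
  stopifnot(dim >= 1L)
  score <- switch(name,
    sphere = function(v) sum(v * v),
    rastrigin = function(v) 10 * length(v) + sum(v * v - 10 * cos(2 * pi * v)))
  list(score = score,
       init = function() runif(dim, -5.12, 5.12),
       repair = function(v) clamp(v, -5.12, 5.12),
       dim = dim, optimum = 0)
}
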