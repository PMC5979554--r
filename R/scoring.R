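# The semi-empirical pairwise binding free-energy score (kcal/mol).
#
# Total:  dG = (V_LL_bound - V_LL_unbound) + (V_PP_bound - V_PP_unbound)
#             + (V_PL_bound - V_PL_unbound + dS_conf)
# With a rigid receptor the P-P difference is identically zero, the unbound
# P-L term is zero (infinite separation), the unbound ligand reference is the
# input-file conformation, and dS_conf = W_conf * T.
#
# Each pairwise V sums four terms over atom pairs (Angstrom, electrons):
#   vdw    = W_vdw  * (A/r^12 - B/r^6)             (non H-bonding pairs)
#   hbond  = W_hb   * (C/r^12 - D/r^10)            (donor-acceptor pairs)
#   elec   = W_elec * 332.06363 * qi*qj / (e(r) r)
#   desolv = W_sol  * (Si*Vj + Sj*Vi) * exp(-r^2 / (2 sigma^2))
# e(r) is the Mehler-Solmajer sigmoidal dielectric (or a constant).

#' Pairwise interaction energy of two atoms at distance r
#'
#' Returns the four weighted energy terms for one atom pair. Donor-acceptor
#' pairs (`HD` vs an acceptor type) are evaluated with the 12-10
#' hydrogen-bond potential instead of the 12-6 dispersion term; the angular
#' weight of the hydrogen bond is taken as 1 (distance-only form).
#'
#' @param atom_i,atom_j Lists (or single data-frame rows) with fields `type`
#'   and `charge`.
#' @param r Interatomic distance, Angstrom, > 0.
#' @param ff A [load_forcefield()] table.
#' @return Named numeric vector `c(vdw, hbond, elec, desolv)`, kcal/mol.
#' @export
#' @examples
#' ff <- load_forcefield()
#' pair_energy(list(type = "C", charge = 0.1),
#'             list(type = "OA", charge = -0.3), 3.5, ff)
pair_energy <- function(atom_i, atom_j, r, ff) {
  stopifnot(length(r) == 1L, is.finite(r))
  if (r <= 0) stop("coincident atoms: r must be > 0")
  pp <- ff_pair_params(ff, atom_i$type, atom_j$type)
  w <- ff$weights
  r2 <- r * r; r6 <- r2^3; r12 <- r6^2
  if (pp$hbond) {
    vdw <- 0
    hb <- w[["hbond"]] * (pp$C / r12 - pp$D / (r12 / r2))
  } else {
    vdw <- w[["vdw"]] * (pp$A / r12 - pp$B / r6)
    hb <- 0
  }
  elec <- w[["elec"]] * ff$coulomb * atom_i$charge * atom_j$charge /
    (ff_dielectric(ff, r) * r)
  si <- ff_atom_solpar(ff, atom_i$type, atom_i$charge)
  sj <- ff_atom_solpar(ff, atom_j$type, atom_j$charge)
  vi <- ff_atom_volume(ff, atom_i$type)
  vj <- ff_atom_volume(ff, atom_j$type)
  des <- w[["sol"]] * (si * vj + sj * vi) * exp(-r2 / (2 * ff$sigma^2))
  c(vdw = unname(vdw), hbond = unname(hb), elec = unname(elec),
    desolv = unname(des))
}

# ---- ligand topology for the internal energy ------------------------------

# bonds inferred from reference coordinates by covalent distance cutoff
# (PDBQT has no CONECT records): 1.9 A, 2.42 A when sulfur is involved
infer_bonds <- function(ligand) {
  xyz <- ligand$coords
  n <- nrow(xyz)
  ty <- ligand$atoms$type
  out <- matrix(integer(0), ncol = 2)
  if (n < 2L) return(out)
  cut <- ifelse(ty %in% c("S", "SA"), 2.42, 1.9)
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(xyz[(i + 1L):n, , drop = FALSE]) - xyz[i, ])^2))
    cij <- pmax(cut[i], cut[(i + 1L):n])
    hit <- which(d < cij)
    if (length(hit)) out <- rbind(out, cbind(i, i + hit))
  }
  out
}

# all-pairs bond-graph distances by BFS (ligands are small)
bond_graph_distances <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(D[s, nxt])]
      if (length(nxt)) D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' Moving atom pairs of a flexible ligand
#'
#' The ligand-internal energy sums over "moving pairs": atom pairs that lie
#' in different rigid groups of the torsion tree and are more than three
#' bonds apart in the bond graph (bonds inferred from the reference
#' coordinates by a covalent distance cutoff). The pair list depends only on
#' topology, never on the genotype.
#'
#' @param ligand A `ligand`.
#' @return Two-column integer matrix of atom index pairs (each pair once,
#'   `i < j`); zero rows for a rigid ligand.
#' @export
moving_pairs <- function(ligand) {
  stopifnot(inherits(ligand, "ligand"))
  n <- nrow(ligand$atoms)
  if (ligand$n_torsions == 0L || n < 2L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  D <- bond_graph_distances(n, infer_bonds(ligand))
  grp <- ligand$groups
  out <- which(upper.tri(D) & D > 3 &
                 outer(grp, grp, "!=") , arr.ind = TRUE)
  colnames(out) <- c("i", "j")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# ---- precomputed fast scorer ----------------------------------------------

# Precomputes pairwise coefficient matrices for one receptor/ligand pair so
# that a pose evaluation is a handful of vectorised operations. All global
# weights are folded into the coefficients.
make_scorer <- function(receptor, ligand, box, ff = load_forcefield(),
                        cutoff = NULL) {
  stopifnot(inherits(receptor, "receptor"), inherits(ligand, "ligand"),
            inherits(box, "search_box"), inherits(ff, "forcefield"))
  check_atom_types(receptor$atoms$type, ff)
  check_atom_types(ligand$atoms$type, ff)
  w <- ff$weights
  pair_mats <- function(ti, qi, tj, qj) {
    ni <- length(ti); nj <- length(tj)
    A <- B <- C <- D <- matrix(0, ni, nj)
    for (a in seq_len(ni)) {
      for (b in seq_len(nj)) {
        pp <- ff_pair_params(ff, ti[a], tj[b])
        if (pp$hbond) {
          C[a, b] <- w[["hbond"]] * pp$C
          D[a, b] <- w[["hbond"]] * pp$D
        } else {
          A[a, b] <- w[["vdw"]] * pp$A
          B[a, b] <- w[["vdw"]] * pp$B
        }
      }
    }
    Si <- ff_atom_solpar(ff, ti, qi); Vi <- ff_atom_volume(ff, ti)
    Sj <- ff_atom_solpar(ff, tj, qj); Vj <- ff_atom_volume(ff, tj)
    list(A = A, B = B, C = C, D = D,
         QQ = w[["elec"]] * ff$coulomb * outer(qi, qj),
         SV = w[["sol"]] * (outer(Si, Vj) + outer(Vi, Sj)))
  }

  rt <- receptor$atoms$type; rq <- receptor$atoms$charge
  lt <- ligand$atoms$type;   lq <- ligand$atoms$charge
  PM <- pair_mats(rt, rq, lt, lq)
  Rc <- receptor$coords
  n_rec <- nrow(Rc); n_lig <- nrow(ligand$coords)
  # flattened (receptor x ligand) coefficient vectors; column-major order
  # matches as.vector(tcrossprod(Rc, L))
  cA <- as.vector(PM$A); cB <- as.vector(PM$B)
  cC <- as.vector(PM$C); cD <- as.vector(PM$D)
  cQQ <- as.vector(PM$QQ); cSV <- as.vector(PM$SV)
  inv2sig2 <- 1 / (2 * ff$sigma^2)
  const_diel <- if (is.numeric(ff$dielectric)) ff$dielectric else NULL
  cut2 <- if (is.null(cutoff)) Inf else cutoff^2

  diel_arg <- if (is.null(const_diel)) -1 else const_diel

  # intermolecular terms for a pose coordinate matrix (compiled pair sums)
  inter_terms <- function(L) {
    cpp_inter_terms(Rc, L, cA, cB, cC, cD, cQQ, cSV,
                    diel_arg, inv2sig2, cut2)
  }

  # internal (ligand-ligand) energy over moving pairs
  mp <- moving_pairs(ligand)
  has_mp <- nrow(mp) > 0L
  if (has_mp) {
    ip <- mp[, 1]; jp <- mp[, 2]
    mpc <- list(A = numeric(nrow(mp)), B = numeric(nrow(mp)),
                C = numeric(nrow(mp)), D = numeric(nrow(mp)))
    for (k in seq_len(nrow(mp))) {
      pp <- ff_pair_params(ff, lt[ip[k]], lt[jp[k]])
      if (pp$hbond) {
        mpc$C[k] <- w[["hbond"]] * pp$C
        mpc$D[k] <- w[["hbond"]] * pp$D
      } else {
        mpc$A[k] <- w[["vdw"]] * pp$A
        mpc$B[k] <- w[["vdw"]] * pp$B
      }
    }
    Sl <- ff_atom_solpar(ff, lt, lq); Vl <- ff_atom_volume(ff, lt)
    mpc$QQ <- w[["elec"]] * ff$coulomb * lq[ip] * lq[jp]
    mpc$SV <- w[["sol"]] * (Sl[ip] * Vl[jp] + Vl[ip] * Sl[jp])
  }
  internal_of <- function(L) {
    if (!has_mp) return(0)
    cpp_internal_energy(L, ip, jp, mpc$A, mpc$B, mpc$C, mpc$D,
                        mpc$QQ, mpc$SV, diel_arg, inv2sig2)
  }

  internal_unbound <- internal_of(ligand$coords)
  entropy <- w[["conf"]] * ligand$n_torsions

  score_coords <- function(L) {
    it <- inter_terms(L)
    sum(it) + (internal_of(L) - internal_unbound) + entropy
  }
  score_vec <- function(v) score_coords(build_pose_vec(ligand, v, box))
  breakdown_vec <- function(v) {
    L <- build_pose_vec(ligand, v, box)
    it <- inter_terms(L)
    ib <- internal_of(L)
    structure(list(vdw = it[["vdw"]], hbond = it[["hbond"]],
                   elec = it[["elec"]], desolv = it[["desolv"]],
                   internal_bound = ib, internal_unbound = internal_unbound,
                   entropy = entropy,
                   total = sum(it) + (ib - internal_unbound) + entropy),
              class = "energy_breakdown")
  }
  list(score_coords = score_coords, score_vec = score_vec,
       breakdown_vec = breakdown_vec, inter_terms = inter_terms,
       internal_of = internal_of, internal_unbound = internal_unbound,
       entropy = entropy)
}

#' Intermolecular (receptor-ligand) energy terms of a pose
#'
#' Sums [pair_energy()] over all receptor-ligand atom pairs (no distance
#' cutoff by default).
#'
#' @param receptor A `receptor`.
#' @param pose N x 3 ligand coordinates in the ligand's atom order.
#' @param ligand The `ligand` the pose belongs to.
#' @param ff A [load_forcefield()] table.
#' @param cutoff Optional pair distance cutoff, Angstrom.
#' @return Named numeric vector `c(vdw, hbond, elec, desolv)`, kcal/mol.
#' @export
intermolecular_energy <- function(receptor, pose, ligand,
                                  ff = load_forcefield(), cutoff = NULL) {
  stopifnot(nrow(pose) == nrow(ligand$atoms))
  sc <- make_scorer(receptor, ligand, search_box(), ff, cutoff = cutoff)
  sc$inter_terms(as.matrix(pose))
}

#' Ligand internal (intramolecular) energy of a pose
#'
#' [pair_energy()] summed over the ligand's [moving_pairs()]; identically 0
#' for a rigid ligand.
#'
#' @inheritParams intermolecular_energy
#' @return Scalar energy, kcal/mol.
#' @export
internal_energy <- function(pose, ligand, ff = load_forcefield()) {
  stopifnot(nrow(pose) == nrow(ligand$atoms))
  mp <- moving_pairs(ligand)
  if (nrow(mp) == 0L) return(0)
  tot <- 0
  for (k in seq_len(nrow(mp))) {
    i <- mp[k, 1]; j <- mp[k, 2]
    r <- sqrt(sum((pose[i, ] - pose[j, ])^2))
    tot <- tot + sum(pair_energy(list(type = ligand$atoms$type[i],
                                      charge = ligand$atoms$charge[i]),
                                 list(type = ligand$atoms$type[j],
                                      charge = ligand$atoms$charge[j]),
                                 r, ff))
  }
  tot
}

#' Binding free energy of a genotype
#'
#' Builds the pose and assembles the full score: intermolecular terms plus
#' the internal-energy difference between the docked pose and the input-file
#' (unbound reference) conformation plus the torsional entropy penalty
#' `W_conf * T`. The rigid-receptor P-P difference and the unbound P-L term
#' are identically zero.
#'
#' @param receptor A `receptor`.
#' @param ligand A `ligand`.
#' @param g A `genotype` (or raw gene vector).
#' @param box A [search_box()].
#' @param ff A [load_forcefield()] table.
#' @return An `energy_breakdown` object: per-term energies and `total`
#'   (kcal/mol, lower is better).
#' @export
binding_energy <- function(receptor, ligand, g, box, ff = load_forcefield()) {
  sc <- make_scorer(receptor, ligand, box, ff)
  sc$breakdown_vec(as_gvec(g, ligand$n_torsions))
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("binding energy: %8.3f kcal/mol\n", x$total))
  cat(sprintf("  vdw %8.3f  hbond %8.3f  elec %8.3f  desolv %8.3f\n",
              x$vdw, x$hbond, x$elec, x$desolv))
  cat(sprintf("  internal (bound - unbound) %8.3f  entropy %8.3f\n",
              x$internal_bound - x$internal_unbound, x$entropy))
  invisible(x)
}

#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  data.frame(vdw = x$vdw, hbond = x$hbond, elec = x$elec, desolv = x$desolv,
             internal_bound = x$internal_bound,
             internal_unbound = x$internal_unbound,
             entropy = x$entropy, total = x$total)
}
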