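# Independently coded naive reference implementations used as oracles.
# These deliberately avoid the package's scoring internals: parameters are
# combined and summed from first principles, pair by pair, in plain loops.

# read the per-type parameter table straight from the packaged text file
oracle_param_table <- function() {
  path <- system.file("extdata", "ad4_types.txt", package = "hivedock")
  tab <- read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = character(0),
                    col.names = c("type", "radius", "well", "solpar",
                                  "volume", "hbond", "rhb", "epshb"))
  rownames(tab) <- tab$type
  tab
}

oracle_dielectric <- function(r) {
  -8.5525 + (78.4 + 8.5525) / (1 + 7.7839 * exp(-0.003627 * (78.4 + 8.5525) * r))
}

# all four weighted terms for one atom pair at distance r
oracle_pair <- function(ti, qi, tj, qj, r, tab,
                        w = c(vdw = 0.1662, hbond = 0.1209, elec = 0.1406,
                              sol = 0.1322)) {
  a <- tab[ti, ]; b <- tab[tj, ]
  rij <- (a$radius + b$radius) / 2
  eij <- sqrt(a$well * b$well)
  is_hb <- (a$hbond == 1 && b$hbond == 2) || (a$hbond == 2 && b$hbond == 1)
  if (is_hb) {
    acc <- if (a$hbond == 2) a else b
    vdw <- 0
    hb <- w[["hbond"]] *
      (5 * acc$epshb * acc$rhb^12 / r^12 - 6 * acc$epshb * acc$rhb^10 / r^10)
  } else {
    vdw <- w[["vdw"]] * (eij * rij^12 / r^12 - 2 * eij * rij^6 / r^6)
    hb <- 0
  }
  elec <- w[["elec"]] * 332.06363 * qi * qj / (oracle_dielectric(r) * r)
  si <- a$solpar + 0.01097 * abs(qi)
  sj <- b$solpar + 0.01097 * abs(qj)
  des <- w[["sol"]] * (si * b$volume + sj * a$volume) * exp(-r^2 / (2 * 3.5^2))
  c(vdw = vdw, hbond = hb, elec = elec, desolv = des)
}

# naive bond graph: covalent distance cutoff on the reference coordinates
oracle_bonds <- function(coords, types) {
  n <- nrow(coords)
  cut <- ifelse(types %in% c("S", "SA"), 2.42, 1.9)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < max(cut[i], cut[j])) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# naive shortest bond-path lengths (Floyd-Warshall)
oracle_graph_dist <- function(n, bonds) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(NROW(bonds))) {
    D[bonds[k, 1], bonds[k, 2]] <- 1
    D[bonds[k, 2], bonds[k, 1]] <- 1
  }
  for (via in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, via] + D[via, j] < D[i, j]) D[i, j] <- D[i, via] + D[via, j]
      }
    }
  }
  D
}

# naive moving-pair list: different rigid groups and > 3 bonds apart
oracle_moving_pairs <- function(ligand) {
  n <- nrow(ligand$atoms)
  D <- oracle_graph_dist(n, oracle_bonds(ligand$coords, ligand$atoms$type))
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ligand$groups[i] != ligand$groups[j] && D[i, j] > 3) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# full naive binding energy: double loop over all pairs, fixed order
oracle_binding_energy <- function(receptor, ligand, gvec, box) {
  tab <- oracle_param_table()
  pose <- build_pose(ligand, gvec, box)
  inter <- c(vdw = 0, hbond = 0, elec = 0, desolv = 0)
  for (i in seq_len(nrow(receptor$atoms))) {
    for (j in seq_len(nrow(ligand$atoms))) {
      r <- sqrt(sum((receptor$coords[i, ] - pose[j, ])^2))
      r <- max(r, 0.01)
      inter <- inter + oracle_pair(receptor$atoms$type[i],
                                   receptor$atoms$charge[i],
                                   ligand$atoms$type[j],
                                   ligand$atoms$charge[j], r, tab)
    }
  }
  internal_of <- function(xyz) {
    mp <- oracle_moving_pairs(ligand)
    tot <- 0
    for (k in seq_len(NROW(mp))) {
      i <- mp[k, 1]; j <- mp[k, 2]
      r <- max(sqrt(sum((xyz[i, ] - xyz[j, ])^2)), 0.01)
      tot <- tot + sum(oracle_pair(ligand$atoms$type[i],
                                   ligand$atoms$charge[i],
                                   ligand$atoms$type[j],
                                   ligand$atoms$charge[j], r, tab))
    }
    tot
  }
  sum(inter) + internal_of(pose) - internal_of(ligand$coords) +
    0.2983 * ligand$n_torsions
}

# small random receptor/ligand systems for oracle-equivalence checks
random_oracle_fixture <- function(seed, n_rec = 12, n_lig = 6, n_torsions = 1) {
  make_toy_complex(seed = seed, n_rec = n_rec, n_lig = n_lig,
                   n_torsions = n_torsions)
}

# random raw gene vector valid for a toy complex (uses the caller's RNG)
random_gvec_for <- function(toy) {
  g <- random_genotype(toy$ligand, toy$box)
  c(g$translation, g$orientation, g$torsions)
}
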