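simple_ff <- function() {
  # single type "X": A = 1, B = 2 (12-6 minimum at r = 1, depth -1),
  # unit weights, constant dielectric, S = 1, V = 1
  f <- tempfile(fileext = ".txt")
  writeLines("X 1.0 1.0 1.0 1.0 0 0 0", f)
  ff <- load_forcefield(f, weights = c(vdw = 1, hbond = 1, elec = 1,
                                       sol = 1, conf = 1), dielectric = 1)
  ff$qsolpar <- 0 # keep S_i exactly at the table value for hand checks
  ff
}

test_that("pair energy terms match their closed forms", {
  ff <- simple_ff()
  at <- function(q) list(type = "X", charge = q)
  # vdw minimum of the A=1, B=2 pair: r = 1, value -1
  pe <- pair_energy(at(0), at(0), 1, ff)
  expect_equal(pe[["vdw"]], -1)
  expect_equal(pe[["hbond"]], 0)
  expect_equal(pe[["elec"]], 0)              # zero charge kills elec exactly
  expect_equal(pair_energy(at(0.7), at(0), 2, ff)[["elec"]], 0)
  # desolvation Gaussian at r = sigma: (S1*V2 + S2*V1) * exp(-1/2)
  pe2 <- pair_energy(at(0), at(0), ff$sigma, ff)
  expect_equal(pe2[["desolv"]], 2 * exp(-0.5))
  # coulomb term with constant dielectric
  pe3 <- pair_energy(at(0.5), at(-0.4), 2, ff)
  expect_equal(pe3[["elec"]], 332.06363 * 0.5 * -0.4 / 2)
  expect_error(pair_energy(at(0), at(0), 0, ff), "coincident")
})

test_that("pair energy is symmetric in its atoms", {
  ff <- load_forcefield()
  set.seed(31)
  types <- ff$types$type
  for (i in 1:30) {
    a <- list(type = sample(types, 1), charge = runif(1, -0.7, 0.7))
    b <- list(type = sample(types, 1), charge = runif(1, -0.7, 0.7))
    r <- runif(1, 1, 9)
    expect_equal(pair_energy(a, b, r, ff), pair_energy(b, a, r, ff),
                 tolerance = 1e-12)
  }
})

test_that("all intermolecular terms vanish far from the receptor", {
  toy <- make_toy_complex(seed = 41, n_lig = 6, n_torsions = 0)
  far <- toy$ligand$coords +
    matrix(c(150, 0, 0), nrow(toy$ligand$coords), 3, byrow = TRUE)
  it <- intermolecular_energy(toy$receptor, far, toy$ligand)
  expect_true(all(abs(it) < 1e-3))
})

test_that("intermolecular energy equals the naive fixed-order double loop", {
  toy <- make_toy_complex(seed = 42, n_rec = 15, n_lig = 6, n_torsions = 1)
  pose <- build_pose(toy$ligand, toy$planted, toy$box)
  it <- intermolecular_energy(toy$receptor, pose, toy$ligand)
  tab <- oracle_param_table()
  ref <- c(vdw = 0, hbond = 0, elec = 0, desolv = 0)
  for (i in seq_len(nrow(toy$receptor$atoms))) {
    for (j in seq_len(nrow(toy$ligand$atoms))) {
      r <- sqrt(sum((toy$receptor$coords[i, ] - pose[j, ])^2))
      ref <- ref + oracle_pair(toy$receptor$atoms$type[i],
                               toy$receptor$atoms$charge[i],
                               toy$ligand$atoms$type[j],
                               toy$ligand$atoms$charge[j], r, tab)
    }
  }
  expect_equal(it, ref, tolerance = 1e-9)
})

test_that("electrostatics is linear in the ligand charges", {
  toy <- make_toy_complex(seed = 43, n_lig = 6, n_torsions = 0)
  ff <- load_forcefield()
  ff$qsolpar <- 0 # remove the |q| coupling so only elec can change
  pose <- build_pose(toy$ligand, toy$planted, toy$box)
  it1 <- intermolecular_energy(toy$receptor, pose, toy$ligand, ff)
  lig2 <- toy$ligand
  lig2$atoms$charge <- 2 * lig2$atoms$charge
  it2 <- intermolecular_energy(toy$receptor, pose, lig2, ff)
  expect_equal(it2[["elec"]], 2 * it1[["elec"]], tolerance = 1e-9)
  expect_equal(it2[c("vdw", "hbond", "desolv")],
               it1[c("vdw", "hbond", "desolv")], tolerance = 1e-12)
})

test_that("zeroing each term's knob zeroes exactly that term", {
  toy <- make_toy_complex(seed = 44, n_lig = 6, n_torsions = 0)
  pose <- build_pose(toy$ligand, toy$planted, toy$box)
  ff <- load_forcefield()
  # all charges zero -> elec identically zero
  rec0 <- toy$receptor
  rec0$atoms$charge <- rep(0, nrow(rec0$atoms))
  expect_identical(intermolecular_energy(rec0, pose, toy$ligand, ff)[["elec"]],
                   0)
  # all S and V zero -> desolvation identically zero
  ff0 <- ff
  ff0$types$solpar <- 0
  ff0$types$volume <- 0
  ff0$qsolpar <- 0
  expect_identical(
    intermolecular_energy(toy$receptor, pose, toy$ligand, ff0)[["desolv"]], 0)
})

test_that("moving pairs: topology only, rigid ligands give the empty set", {
  toy0 <- make_toy_complex(seed = 45, n_lig = 6, n_torsions = 0)
  expect_equal(nrow(moving_pairs(toy0$ligand)), 0)
  expect_identical(internal_energy(toy0$ligand$coords, toy0$ligand), 0)

  toy <- make_toy_complex(seed = 46, n_lig = 10, n_torsions = 4)
  mp <- moving_pairs(toy$ligand)
  expect_gt(nrow(mp), 0)
  # independent graph-distance oracle on the 10-atom ligand
  ref <- oracle_moving_pairs(toy$ligand)
  expect_equal(unname(as.matrix(mp)), unname(ref))
  # pair list is a function of topology alone: any pose gives the same list
  expect_equal(moving_pairs(toy$ligand), mp)
})

test_that("binding energy assembles its parts per the breakdown identity", {
  toy <- make_toy_complex(seed = 47, n_lig = 8, n_torsions = 2)
  be <- binding_energy(toy$receptor, toy$ligand, toy$planted, toy$box)
  expect_equal(be$total,
               (be$internal_bound - be$internal_unbound) +
                 be$vdw + be$hbond + be$elec + be$desolv + be$entropy,
               tolerance = 1e-9)
  # identity genotype: bound conformation equals the unbound reference
  expect_equal(be$internal_bound, be$internal_unbound, tolerance = 1e-9)
  # rigid ligand: no internal terms and no entropy penalty
  toy0 <- make_toy_complex(seed = 47, n_lig = 6, n_torsions = 0)
  be0 <- binding_energy(toy0$receptor, toy0$ligand, toy0$planted, toy0$box)
  expect_identical(be0$entropy, 0)
  expect_identical(be0$internal_bound, 0)
})

test_that("the two-atom hand fixture matches a hand-summed pair table", {
  hc <- make_hand_complex()
  ff <- load_forcefield()
  # planted genotype (3.5, 0, 0): root centroid (0.5,0,0) lands at 3.5
  pose <- build_pose(hc$ligand, hc$planted, hc$box)
  expect_equal(pose, rbind(c(3, 0, 0), c(4, 0, 0)), tolerance = 1e-12)
  # hand-assembled total: C at r = 3, HD at r = 4 from the OA receptor atom
  tab <- oracle_param_table()
  hand <- sum(oracle_pair("OA", -0.30, "C", 0.20, 3, tab)) +
    sum(oracle_pair("OA", -0.30, "HD", 0.05, 4, tab))
  be <- binding_energy(hc$receptor, hc$ligand, hc$planted, hc$box, ff)
  expect_equal(be$total, hand, tolerance = 1e-9)
})

test_that("scoring is invariant under a global rigid motion of the system", {
  toy <- make_toy_complex(seed = 48, n_lig = 7, n_torsions = 1)
  pose <- build_pose(toy$ligand, toy$planted, toy$box)
  it <- intermolecular_energy(toy$receptor, pose, toy$ligand)
  set.seed(48)
  q <- rnorm(4)
  R <- hivedock:::quat_rotation_matrix(q / sqrt(sum(q * q)))
  shift <- c(3, -7, 11)
  rec2 <- toy$receptor
  rec2$coords <- toy$receptor$coords %*% t(R) +
    matrix(shift, nrow(toy$receptor$coords), 3, byrow = TRUE)
  pose2 <- pose %*% t(R) + matrix(shift, nrow(pose), 3, byrow = TRUE)
  it2 <- intermolecular_energy(rec2, pose2, toy$ligand)
  expect_equal(it2, it, tolerance = 1e-9)
})

test_that("binding energy matches the naive oracle on 20 random systems", {
  set.seed(49)
  for (i in 1:20) {
    n_lig <- sample(5:9, 1)
    toy <- random_oracle_fixture(seed = 1000 + i,
                                 n_rec = sample(8:20, 1),
                                 n_lig = n_lig,
                                 n_torsions = sample(0:min(2, n_lig - 4), 1))
    g <- random_gvec_for(toy)
    be <- binding_energy(toy$receptor, toy$ligand, g, toy$box)
    expect_equal(be$total,
                 oracle_binding_energy(toy$receptor, toy$ligand, g, toy$box),
                 tolerance = 1e-9)
  }
})
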