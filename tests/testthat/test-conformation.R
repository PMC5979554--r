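test_that("orientation normalisation preserves direction and unit norm", {
  expect_equal(normalize_orientation(genotype(orientation = c(1, 0, 0, 0)))$orientation,
               c(1, 0, 0, 0))
  expect_equal(normalize_orientation(genotype(orientation = c(2, 0, 0, 0)))$orientation,
               c(1, 0, 0, 0))
  set.seed(42)
  for (i in 1:20) {
    q <- rnorm(4) * 10^runif(1, -3, 3)
    n <- sqrt(sum(normalize_orientation(genotype(orientation = q))$orientation^2))
    expect_equal(n, 1, tolerance = 1e-12)
  }
  expect_error(normalize_orientation(genotype(orientation = c(0, 0, 0, 0))),
               "degenerate orientation")
})

test_that("identity genotype recenters the rigid root at the box center", {
  toy <- make_toy_complex(seed = 5, n_lig = 6, n_torsions = 0)
  box <- search_box(c(1, -2, 3), c(5, 5, 5))
  pose <- build_pose(toy$ligand, genotype(), box)
  rc <- colMeans(pose[toy$ligand$root, ])
  expect_equal(rc, box$center, tolerance = 1e-9)
  # pure recentring: all interatomic vectors unchanged
  d0 <- dist(toy$ligand$coords)
  expect_equal(as.numeric(dist(pose)), as.numeric(d0), tolerance = 1e-9)
})

test_that("translation gene shifts every atom by exactly that vector", {
  toy <- make_toy_complex(seed = 5, n_lig = 7, n_torsions = 2)
  g0 <- genotype(torsions = c(0.3, -0.7))
  g1 <- genotype(translation = c(1, 0, 0), torsions = c(0.3, -0.7))
  p0 <- build_pose(toy$ligand, g0, toy$box)
  p1 <- build_pose(toy$ligand, g1, toy$box)
  expect_equal(p1 - p0, matrix(c(1, 0, 0), nrow(p0), 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("a half-turn about z maps centroid-relative (1,0,0) to (-1,0,0)", {
  # quaternion (0,0,0,1) is a 180-degree rotation about the z axis
  lig <- structure(list(
    atoms = data.frame(serial = 1:2, name = c("L1", "L2"),
                       type = c("C", "C"), charge = c(0, 0)),
    coords = rbind(c(0, 0, 0), c(2, 0, 0)),
    root = 1:2, groups = c(0L, 0L), branches = list(),
    n_torsions = 0L, torsdof = 0L), class = "ligand")
  box <- search_box(c(0, 0, 0), c(5, 5, 5))
  pose <- build_pose(lig, genotype(orientation = c(0, 0, 0, 1)), box)
  # centroid at origin; atom 2 was at +1 relative to centroid
  expect_equal(pose[2, ], c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(pose[1, ], c(1, 0, 0), tolerance = 1e-12)
})

test_that("perturbing torsion k moves exactly branch k's subtree", {
  toy <- make_toy_complex(seed = 9, n_lig = 8, n_torsions = 3)
  lig <- toy$ligand
  base <- build_pose(lig, genotype(torsions = rep(0, 3)), toy$box)
  for (k in 1:3) {
    tors <- rep(0, 3)
    tors[k] <- 0.8
    pose <- build_pose(lig, genotype(torsions = tors), toy$box)
    moved <- which(sqrt(rowSums((pose - base)^2)) > 1e-9)
    expect_true(all(moved %in% lig$branches[[k]]$subtree))
    # at least one off-axis atom of the subtree actually moves
    expect_gt(length(moved), 0)
  }
})

test_that("rigid-group internal distances survive any rigid genotype", {
  toy <- make_toy_complex(seed = 13, n_lig = 8, n_torsions = 2)
  lig <- toy$ligand
  set.seed(99)
  for (i in 1:10) {
    g <- random_genotype(lig, toy$box)
    g$torsions <- rep(0, 2) # zero torsions: whole ligand moves rigidly
    pose <- build_pose(lig, g, toy$box)
    expect_equal(as.numeric(dist(pose)), as.numeric(dist(lig$coords)),
                 tolerance = 1e-9)
  }
})

test_that("rmsd matches its definition and is a pseudometric", {
  a <- matrix(rnorm(30), 10, 3)
  expect_identical(rmsd(a, a), 0)
  expect_equal(rmsd(a, a + matrix(c(3, 4, 0), 10, 3, byrow = TRUE)), 5)
  b2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  b2_shift <- rbind(c(0, 0, 2), c(1, 0, 0))
  expect_equal(rmsd(b2, b2_shift), sqrt(2), tolerance = 1e-12)
  expect_error(rmsd(a, a[1:5, ]), "differ")
  set.seed(7)
  for (i in 1:25) {
    x <- matrix(rnorm(15), 5, 3)
    y <- matrix(rnorm(15), 5, 3)
    z <- matrix(rnorm(15), 5, 3)
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z) + 1e-12)
  }
})

test_that("heavy-only rmsd excludes hydrogens", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(9, 0, 0))
  expect_equal(rmsd(a, b, heavy_only = TRUE, types = c("C", "HD")), 0)
  expect_error(rmsd(a, b, heavy_only = TRUE), "types")
})

test_that("repair clamps, wraps and renormalises; and is idempotent", {
  box <- search_box(c(0, 0, 0), c(2, 2, 2))
  ok <- genotype(c(1, -1, 0), c(1, 0, 0, 0), c(0.5))
  expect_equal(repair_genotype(ok, box), ok)
  g <- genotype(c(3, 0, 0), c(2, 0, 0, 0), c(3 * pi))
  r <- repair_genotype(g, box)
  expect_equal(r$translation, c(2, 0, 0))          # clamped to the face
  expect_equal(r$orientation, c(1, 0, 0, 0))
  expect_equal(r$torsions, pi)                     # 3*pi wraps to +pi
  expect_equal(repair_genotype(r, box), r)         # idempotent
  # the wrap boundary maps -pi to +pi
  expect_equal(repair_genotype(genotype(torsions = -pi), box)$torsions, pi)
})

test_that("random genotypes are uniform in the box and on the 3-sphere", {
  box <- search_box(c(1, 2, 3), c(2, 3, 4))
  set.seed(123)
  n <- 10000
  tr <- matrix(0, n, 3)
  qs <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    g <- random_genotype(2L, box)
    tr[i, ] <- g$translation
    qs[i, ] <- g$orientation
  }
  expect_true(all(abs(tr) <= rep(box$half_extent, each = n)))
  expect_true(all(abs(sqrt(rowSums(qs^2)) - 1) < 1e-9))
  # each component mean within 4 sigma of 0 under the uniform-sphere null
  # (component variance 1/4 -> se = 1/(2*sqrt(n)))
  se <- 1 / (2 * sqrt(n))
  expect_true(all(abs(colMeans(qs)) < 4 * se))
})
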