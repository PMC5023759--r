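test_that("SASA of an isolated sphere matches the closed form within 2%", {
  st <- toy_structure(matrix(0, 1, 3), elem = "X")
  a <- sasa(st, probe = 1.4, n_points = 92, radii = c(X = 1.9))
  exact <- 4 * pi * (1.9 + 1.4)^2
  expect_equal(as.numeric(a), exact, tolerance = 0.02)
  # two far-apart atoms: additive
  st2 <- toy_structure(rbind(c(0, 0, 0), c(100, 0, 0)),
                       names = c("CA", "CA"), resno = 1:2, elem = "X")
  a2 <- sasa(st2, probe = 1.4, n_points = 92, radii = c(X = 1.9))
  expect_equal(sum(a2), 2 * exact, tolerance = 0.02)
  expect_error(sasa(st, n_points = 16), "n_points")
  expect_error(sasa(toy_structure(matrix(0, 1, 3), elem = "Q")), "radius")
})

test_that("two-atom overlap SASA matches a dense numeric oracle within 2%", {
  # oracle: brute-force spherical quadrature with 1e6 points per atom,
  # independent of the package's neighbour-culled implementation
  r1 <- 1.7 + 1.4; r2 <- 1.52 + 1.4; sep <- 2.0
  dense_sphere <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    th <- pi * (3 - sqrt(5)) * i
    r <- sqrt(pmax(0, 1 - z^2))
    # rotate the spiral so the poles do not align with the inter-atom axis
    m <- cbind(r * cos(th), r * sin(th), z)
    ang <- 0.7
    m %*% t(matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0,
                     sin(ang), 0, cos(ang)), 3))
  }
  n <- 1e6
  pts <- dense_sphere(n)
  # atom 1 at origin, atom 2 at (sep, 0, 0)
  p1 <- pts * r1
  free1 <- mean((p1[, 1] - sep)^2 + p1[, 2]^2 + p1[, 3]^2 >= r2^2)
  p2 <- sweep(pts * r2, 2, c(sep, 0, 0), "+")
  free2 <- mean(p2[, 1]^2 + p2[, 2]^2 + p2[, 3]^2 >= r1^2)
  oracle <- c(4 * pi * r1^2 * free1, 4 * pi * r2^2 * free2)

  st <- toy_structure(rbind(c(0, 0, 0), c(sep, 0, 0)),
                      names = c("C1", "O1"), resno = 1:2, elem = c("C", "O"))
  got <- as.numeric(sasa(st, probe = 1.4, n_points = 92))
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("interface area is zero for separated protomers and symmetric", {
  mono <- fixture_monomer()
  at <- mono$atoms
  far <- at; far$chain <- "B"; far$x <- far$x + 100
  dimer_far <- pdb_structure(rbind(at, far), segments = mono$segments,
                             bw_refs = mono$bw_refs)
  dimer_far$atoms$serial <- seq_len(nrow(dimer_far$atoms))
  expect_equal(interface_area(dimer_far), 0, tolerance = 1e-9)
  ir <- interface_residues(dimer_far)
  expect_equal(nrow(ir$A), 0L)
  expect_equal(nrow(ir$B), 0L)
  expect_equal(classify_interface(dimer_far), "none")

  # contact pose: swapping chain labels leaves the area unchanged
  pose <- enumerate_dimer_poses(mono, 4, 4)[[6]]
  dim2 <- realize_pose(pose)
  ab <- interface_area(dim2)
  swapped <- dim2
  swapped$atoms$chain <- ifelse(dim2$atoms$chain == "A", "B", "A")
  expect_equal(interface_area(swapped), ab, tolerance = 1e-9)
  expect_gt(ab, 0)
  # subadditivity: buried area cannot exceed either monomer's full SASA
  s_mono <- sum(sasa(mono))
  expect_lte(ab, s_mono)
})

test_that("interface area equals an independently recomputed three-term difference", {
  mono <- fixture_monomer()
  pose <- enumerate_dimer_poses(mono, 4, 4)[[6]]
  dim2 <- realize_pose(pose)
  ia <- select_atoms(dim2, "A")
  ib <- select_atoms(dim2, "B")
  # independent settings: different quadrature density
  recompute <- function(npts) {
    r <- energy_params()$radii[dim2$atoms$elem]
    sA <- sum(sasa(coords(dim2, ia), n_points = npts, atom_radii = r[ia]))
    sB <- sum(sasa(coords(dim2, ib), n_points = npts, atom_radii = r[ib]))
    sAB <- sum(sasa(coords(dim2), n_points = npts, atom_radii = r))
    sA + sB - sAB
  }
  got <- interface_area(dim2)
  expect_equal(got, recompute(92), tolerance = 1e-9)
  expect_equal(got, recompute(492), tolerance = 0.12)
})

test_that("interface residue lists respect the burial threshold exactly", {
  mono <- fixture_monomer()
  pose <- enumerate_dimer_poses(mono, 4, 4)[[6]]
  dim2 <- realize_pose(pose)
  b <- dimerscan:::per_atom_burial(dim2)
  for (thr in c(0.1, 10)) {
    ir <- interface_residues(dim2, burial_threshold = thr)
    per_res <- tapply(b$burial_a, b$parts$atoms_a$resno, sum)
    listed <- as.integer(names(per_res)[per_res > thr])
    expect_equal(ir$A$resno, sort(listed))
  }
  # monotonicity: larger threshold gives a subset
  r_small <- interface_residues(dim2, 0.1)
  r_big <- interface_residues(dim2, 10)
  expect_true(all(r_big$A$resno %in% r_small$A$resno))
  expect_true(all(r_big$B$resno %in% r_small$B$resno))
})

test_that("hydrogen-bond detection follows the geometric criteria", {
  # collinear CA-N donor pointing at a backbone O acceptor at d_opt
  at <- data.frame(
    name = c("CA", "N", "O"), resname = "ALA", resno = c(1, 1, 2),
    chain = c("A", "A", "B"),
    x = c(-1.46, 0, 2.9), y = 0, z = 0, charge = 0,
    stringsAsFactors = FALSE)
  st <- pdb_structure(at)
  bonds <- detect_hbonds(st)
  expect_equal(nrow(bonds), 1L)
  expect_equal(bonds$energy, -hbond_params()$eps_hb, tolerance = 1e-9)
  expect_equal(bonds$distance, 2.9)
  expect_equal(bonds$angle, 180)
  # beyond d_max: nothing
  at2 <- at; at2$x[3] <- 5.0
  expect_equal(nrow(detect_hbonds(pdb_structure(at2))), 0L)
  # bad alignment (90 degrees): nothing
  at3 <- at; at3$x[3] <- 0; at3$y[3] <- 2.9
  expect_equal(nrow(detect_hbonds(pdb_structure(at3))), 0L)
  # hbond energy within [-eps, 0] and ramp decreasing with distance
  at4 <- at; at4$x[3] <- 3.3
  b4 <- detect_hbonds(pdb_structure(at4))
  expect_true(b4$energy > -hbond_params()$eps_hb && b4$energy < 0)
})

test_that("binding energy vanishes at separation and is rigid-motion invariant", {
  mono <- fixture_patched()
  at <- mono$atoms
  far <- at; far$chain <- "B"; far$x <- far$x + 500
  dimer_far <- pdb_structure(rbind(at, far))
  be <- binding_energy(dimer_far)
  expect_equal(be$dg_bind, 0)
  expect_equal(be$interface_score, 0)
  expect_equal(be$hbond_energy, 0)

  pose <- enumerate_dimer_poses(mono, 4, 4)[[6]]
  dim2 <- realize_pose(pose)
  be0 <- binding_energy(dim2)
  expect_equal(be0$dg_bind, be0$interface_score + be0$hbond_energy)
  expect_equal(be0$hbond_energy, sum(detect_hbonds(dim2)$energy))
  set.seed(21)
  for (k in 1:3) {
    tr <- random_rigid()
    moved <- set_coords(dim2, apply_rigid(coords(dim2), tr))
    be1 <- binding_energy(moved)
    expect_equal(be1$dg_bind, be0$dg_bind, tolerance = 1e-6)
    expect_equal(be1$interface_score, be0$interface_score, tolerance = 1e-6)
    expect_equal(be1$hbond_energy, be0$hbond_energy, tolerance = 1e-6)
  }
})

test_that("close contacts raise the clash flag with capped energy", {
  at <- data.frame(name = c("CA", "CA"), resname = "ALA", resno = 1:2,
                   chain = c("A", "B"), x = c(0, 0.3), y = 0, z = 0,
                   charge = 0, stringsAsFactors = FALSE)
  be <- binding_energy(pdb_structure(at))
  expect_true(be$clash)
  expect_lte(be$interface_score, energy_params()$clash_cap + 1e-9)
})

test_that("interface classification identifies constructed TM contacts", {
  mono <- fixture_monomer()
  poses <- enumerate_dimer_poses(mono, 12, 12)
  # symmetric TM4/TM5 groove contact
  p45 <- Filter(function(p) p$rot_a == 180 && p$rot_b == 0, poses)[[1]]
  expect_equal(classify_interface(p45), "45_45")
  # the class label is canonical: protomer order never matters
  d <- realize_pose(p45)
  sw <- d; sw$atoms$chain <- ifelse(d$atoms$chain == "A", "B", "A")
  expect_equal(classify_interface(sw), "45_45")
})

test_that("the interface-class alphabet has exactly 28 canonical labels", {
  cls <- interface_classes()
  expect_length(cls, 28L)
  expect_false(anyDuplicated(cls) > 0)
  parts <- strsplit(cls, "_")
  expect_true(all(vapply(parts, function(p) p[1] <= p[2], TRUE)))
  pairs <- c("12", "23", "34", "45", "56", "67", "71")
  expect_true(all(unlist(parts) %in% pairs))
})
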