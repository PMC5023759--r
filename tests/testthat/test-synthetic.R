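test_that("helices have ideal alpha-helical CA geometry", {
  st <- fixture_monomer()
  tmpl <- bundle_template()
  for (h in paste0("TM", 1:7)) {
    idx <- which(st$atoms$segment == h & st$atoms$name == "CA")
    m <- coords(st, idx)
    d1 <- sqrt(rowSums((m[-1, ] - m[-nrow(m), ])^2))
    expect_true(all(abs(d1 - 3.80) <= 0.05),
                label = paste(h, "consecutive CA-CA within 3.80 +/- 0.05"))
    d3 <- sqrt(rowSums((m[-(1:3), ] - m[1:(nrow(m) - 3), ])^2))
    expect_true(all(d3 >= 4.9 & d3 <= 5.4),
                label = paste(h, "CA(i)-CA(i+3) alpha-helix signature"))
    # axial rise per residue along the helix axis
    hn <- as.integer(sub("TM", "", h))
    fit <- prcomp(m)$rotation[, 1]
    rises <- abs(diff(m %*% fit))
    expect_true(all(abs(rises - tmpl$rise_per_residue) <= 0.05),
                label = paste(h, "axial rise 1.5 +/- 0.05"))
  }
})

test_that("degenerate templates are rejected", {
  tmpl <- bundle_template()
  tmpl$helix_lengths[3] <- 0L
  expect_error(build_ideal_tm_bundle(tmpl,
                                     annotations = default_annotations(tmpl)),
               "helix length")
  expect_error(bundle_template(bundle_radius = 2), "6 Angstrom")
  expect_error(bundle_template(rise_per_residue = 0), "rise")
})

test_that("functional residues carry their interaction sites", {
  st <- fixture_monomer()
  expect_length(select_atoms(st, "A:3.50:NE,NH1,NH2"), 3L)
  expect_length(select_atoms(st, "A:6.30:OE1,OE2"), 2L)
  expect_length(select_atoms(st, "A:3.49:OD1,OD2"), 2L)
  expect_length(select_atoms(st, "A:5.42:OH"), 1L)
  # planted ionic lock: minimum guanidinium-carboxylate distance = lock gap
  g <- coords(st, select_atoms(st, "A:3.50:NE,NH1,NH2"))
  e <- coords(st, select_atoms(st, "A:6.30:OE1,OE2"))
  dmin <- min(sqrt(outer(rowSums(g^2), rep(1, 2)) +
                     outer(rep(1, 3), rowSums(e^2)) - 2 * g %*% t(e)))
  expect_equal(dmin, 3.5, tolerance = 1e-6)
  # pocket residues face the bundle axis
  for (gn in c("3.32", "6.48", "6.55")) {
    ca <- coords(st, select_atoms(st, paste0("A:", gn, ":CA")))[1, ]
    cb <- coords(st, select_atoms(st, paste0("A:", gn, ":CB")))[1, ]
    v <- cb - ca; v[3] <- 0
    inward <- -ca; inward[3] <- 0
    cosang <- sum(v * inward) / sqrt(sum(v^2) * sum(inward^2))
    expect_gt(cosang, 0.7)
  }
})

test_that("interface patch decorates only the named faces", {
  mono <- fixture_monomer()
  patched <- fixture_patched()
  extra <- setdiff(patched$atoms$name, mono$atoms$name)
  expect_true(all(grepl("^P[DA][0-9]+$", extra)))
  pd <- patched$atoms[grepl("^PD", patched$atoms$name), ]
  pa <- patched$atoms[grepl("^PA", patched$atoms$name), ]
  expect_equal(nrow(pd), 8L)
  expect_equal(nrow(pa), 8L)
  expect_true(all(pd$segment == "TM4") && all(pa$segment == "TM5"))
  expect_true(all(pd$charge > 0) && all(pa$charge < 0))
  # undecorated atoms unchanged
  key <- function(a) paste(a$resno, a$name)
  common <- match(key(mono$atoms), key(patched$atoms))
  expect_equal(coords(patched)[common, ], coords(mono),
               ignore_attr = TRUE)
  # no-op and error cases
  expect_identical(plant_interface_patch(mono, patch_spec(donor_count = 0,
                                                          acceptor_count = 0)),
                   mono)
  expect_error(patch_spec(helix_pair = c("TM9", "TM5")), "TM1")
})

test_that("decorated matched-face pose binds tighter than an undecorated face", {
  patched <- fixture_patched()
  poses <- enumerate_dimer_poses(patched, 12, 12, 4.0)
  # TM4/TM5 faces meet at rotations (180, 0); TM1/TM2 faces near (330, 150)
  sym45 <- Filter(function(p) p$rot_a == 180 && p$rot_b == 0, poses)[[1]]
  sym12 <- Filter(function(p) p$rot_a == 330 && p$rot_b == 150, poses)[[1]]
  e45 <- binding_energy(sym45)
  e12 <- binding_energy(sym12)
  expect_lt(e45$dg_bind, e12$dg_bind)
  # and strictly lower than the same pose without decoration
  mono <- fixture_monomer()
  undec <- enumerate_dimer_poses(mono, 12, 12, 4.0)
  u45 <- Filter(function(p) p$rot_a == 180 && p$rot_b == 0, undec)[[1]]
  expect_lt(e45$dg_bind, binding_energy(u45)$dg_bind)
})

test_that("stronger planted charges never weaken the matched-face pose", {
  mono <- fixture_monomer()
  energies <- vapply(c(0.2, 0.4, 0.6, 0.8), function(q) {
    p <- plant_interface_patch(mono, patch_spec(charge_magnitude = q))
    pose <- enumerate_dimer_poses(p, 12, 12, 4.0)[[73]]  # rot_a 180, rot_b 0
    stopifnot(pose$rot_a == 180, pose$rot_b == 0)
    binding_energy(pose)$dg_bind
  }, 0)
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("synthetic trajectories are deterministic with planted events", {
  st <- fixture_monomer()
  # identity: one frame, no jitter, no events
  tr <- simulate_trajectory(st, trajectory_spec(n_frames = 1))
  expect_equal(frame_coords(tr, 1), unname(coords(st)), ignore_attr = TRUE)
  # determinism: same seed -> identical arrays
  spec <- trajectory_spec(n_frames = 20, jitter_sd = 0.3, seed = 99)
  expect_identical(simulate_trajectory(st, spec)$coords,
                   simulate_trajectory(st, spec)$coords)
  # planted event: displacing the Glu 6.30 side chain by 6 Angstrom along
  # the lock axis increases the minimum lock distance by about 6 from the
  # event frame onward
  g <- coords(st, select_atoms(st, "A:3.50:NH1"))[1, ]
  e630 <- coords(st, select_atoms(st, "A:6.30:OE1"))[1, ]
  u <- (e630 - g) / sqrt(sum((e630 - g)^2))
  ev <- list(list(frame = 11, selector = "A:6.30:OE1,OE2", d = 6 * u))
  spec2 <- trajectory_spec(n_frames = 20, jitter_sd = 0, events = ev)
  tr2 <- simulate_trajectory(st, spec2)
  ds <- ionic_lock_series(tr2, "A")
  expect_equal(ds$values[1], 3.5, tolerance = 1e-6)
  expect_true(all(abs(ds$values[1:10] - 3.5) < 1e-9))
  expect_equal(ds$values[11:20], rep(9.5, 10), tolerance = 0.05)
  # unknown atom group errors
  bad <- trajectory_spec(n_frames = 2,
                         events = list(list(frame = 1, selector = "A:9.99",
                                            d = c(1, 0, 0))))
  expect_error(simulate_trajectory(st, bad))
  expect_error(trajectory_spec(n_frames = 2,
                               events = list(list(frame = 5, selector = "A",
                                                  d = c(1, 0, 0)))),
               "outside")
})

test_that("trajectory RMSD grows monotonically with jitter amplitude", {
  st <- fixture_monomer()
  mean_rmsd <- vapply(c(0.1, 0.3, 0.6), function(sd) {
    tr <- simulate_trajectory(st, trajectory_spec(n_frames = 6,
                                                  jitter_sd = sd, seed = 5))
    mean(rmsd_series(tr, 1)$values[-1])
  }, 0)
  expect_true(all(diff(mean_rmsd) > 0))
})
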