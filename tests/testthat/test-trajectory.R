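test_that("distance series reduce static and degenerate cases correctly", {
  st <- fixture_monomer()
  tr <- simulate_trajectory(st, trajectory_spec(n_frames = 5))
  ds <- distance_series(tr, "A:3.50:NH1", "A:6.30:OE1", "min")
  expect_equal(ds$values, rep(ds$values[1], 5))
  # identical selections with min reduction: all zeros
  ds0 <- distance_series(tr, "A:TM4", "A:TM4", "min")
  expect_equal(ds0$values, rep(0, 5))
  expect_error(distance_series(tr, "A:9.99", "A:TM4"), "9.99")
  # centroid reduction equals the hand-computed centroid distance
  dc <- distance_series(tr, "A:3.50:NH1,NH2,NE", "A:6.30:OE1,OE2", "centroid")
  c1 <- colMeans(coords(st, select_atoms(st, "A:3.50:NH1,NH2,NE")))
  c2 <- colMeans(coords(st, select_atoms(st, "A:6.30:OE1,OE2")))
  expect_equal(dc$values[1], sqrt(sum((c1 - c2)^2)), tolerance = 1e-9)
})

test_that("a locked trajectory stays below the lock threshold", {
  st <- fixture_monomer()
  tr <- simulate_trajectory(st, trajectory_spec(n_frames = 100,
                                                jitter_sd = 0.2, seed = 31))
  ds <- ionic_lock_series(tr, "A")
  # lock planted at 3.5 with 0.2 jitter: crossing 4.5 needs a >3.5 sigma
  # excursion of the pair distance
  expect_gte(ds$fraction_below, 0.99)
})

test_that("a planted lock break is detected at the right frame", {
  st <- fixture_monomer()
  g <- coords(st, select_atoms(st, "A:3.50:NH1"))[1, ]
  e630 <- coords(st, select_atoms(st, "A:6.30:OE1"))[1, ]
  u <- (e630 - g) / sqrt(sum((e630 - g)^2))
  k <- 60L; n <- 100L
  ev <- list(list(frame = k, selector = "A:6.30:OE1,OE2", d = 6 * u))
  tr <- simulate_trajectory(st, trajectory_spec(n_frames = n, jitter_sd = 0.2,
                                                events = ev, seed = 37))
  ds <- ionic_lock_series(tr, "A")
  expect_equal(ds$fraction_below, (k - 1) / n, tolerance = 0.02)
  break_frame <- which(ds$values > ds$threshold)[1]
  expect_true(abs(break_frame - k) <= 1)
  # missing annotation errors name the residue
  st2 <- st; st2$bw_refs <- st$bw_refs[names(st$bw_refs) != "TM6"]
  tr2 <- simulate_trajectory(st2, trajectory_spec(n_frames = 2))
  expect_error(ionic_lock_series(tr2, "A"), "6.30")
})

test_that("hydrogen-bond occupancy recovers a planted fraction", {
  # donor (backbone N with CA antecedent) on chain A, acceptor O on chain B
  at <- data.frame(name = c("CA", "N", "O"), resname = "ALA",
                   resno = c(1, 1, 2), chain = c("A", "A", "B"),
                   x = c(-1.46, 0, 2.9), y = 0, z = 0, charge = 0,
                   stringsAsFactors = FALSE)
  topo <- pdb_structure(at)
  n <- 500L; p <- 0.6
  set.seed(41)
  present <- runif(n) < p
  co <- array(rep(coords(topo), each = n), dim = c(n, 3, 3))
  co[!present, 3, 1] <- 6.0   # move the acceptor out of range
  tr <- trajectory(topo, co)
  rep_ <- hbond_persistence(tr, "A:1:N", "B:2:O")
  expect_equal(rep_$present, present)
  expect_lt(abs(rep_$occupancy - p), 3 * sqrt(p * (1 - p) / n))
  # all / none
  expect_equal(hbond_persistence(trajectory(topo, co[present, , , drop = FALSE]),
                                 "A:1:N", "B:2:O")$occupancy, 1.0)
  expect_equal(hbond_persistence(trajectory(topo, co[!present, , , drop = FALSE]),
                                 "A:1:N", "B:2:O")$occupancy, 0.0)
  expect_error(hbond_persistence(tr, "A:5:N", "B:2:O"), "empty|no residue")
})

test_that("occupancy estimates tighten as the trajectory grows", {
  at <- data.frame(name = c("CA", "N", "O"), resname = "ALA",
                   resno = c(1, 1, 2), chain = c("A", "A", "B"),
                   x = c(-1.46, 0, 2.9), y = 0, z = 0, charge = 0,
                   stringsAsFactors = FALSE)
  topo <- pdb_structure(at)
  p <- 0.3
  err <- vapply(c(50L, 1000L), function(n) {
    set.seed(43)
    errs <- vapply(1:8, function(rep) {
      present <- runif(n) < p
      co <- array(rep(coords(topo), each = n), dim = c(n, 3, 3))
      co[!present, 3, 1] <- 6.0
      abs(hbond_persistence(trajectory(topo, co), "A:1:N", "B:2:O")$occupancy - p)
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("water bridges count only waters touching both partners", {
  at <- data.frame(
    name = c("CA", "CA", "O", "O"),
    resname = c("ALA", "ALA", "HOH", "HOH"),
    resno = c(1, 2, 3, 4), chain = c("A", "B", "W", "W"),
    x = c(0, 5, 2.5, 10), y = c(0, 0, 0, 10), z = 0, charge = 0,
    stringsAsFactors = FALSE)
  topo <- pdb_structure(at)
  co <- array(rep(coords(topo), each = 3), dim = c(3, 4, 3))
  tr <- trajectory(topo, co)
  # one water midway between atoms 5 apart (2.5 to each), one water far away
  expect_equal(water_bridges(tr, "A:1", "B:2", d_max = 3.5), rep(1L, 3))
  expect_equal(water_bridges(tr, "A:1", "B:2", d_max = 2.0), rep(0L, 3))
  # topology without waters: all zeros
  dry <- pdb_structure(at[1:2, ])
  tr_dry <- trajectory(dry, co[, 1:2, , drop = FALSE])
  expect_equal(water_bridges(tr_dry, "A:1", "B:2"), rep(0L, 3))
})

test_that("RMSD series give stability verdicts and are reference-zero", {
  st <- fixture_monomer()
  tr <- simulate_trajectory(st, trajectory_spec(n_frames = 50,
                                                jitter_sd = 0.3, seed = 47))
  rs <- rmsd_series(tr, 1)
  expect_equal(rs$values[1], 0, tolerance = 1e-9)
  expect_true(rs$stable)      # 0.3 A jitter never approaches 4 A
  expect_lt(rs$max, 1.0)
  # an event displacing half the atoms by 12 A breaks stability
  half <- paste0("A:1-", floor(max(st$atoms$resno) / 2))
  ev <- list(list(frame = 25, selector = half, d = c(12, 0, 0)))
  tr2 <- simulate_trajectory(st, trajectory_spec(n_frames = 50,
                                                 jitter_sd = 0.3, events = ev,
                                                 seed = 47))
  rs2 <- rmsd_series(tr2, 1)
  expect_false(rs2$stable)
})

test_that("series are invariant under a uniform global rigid motion", {
  st <- fixture_monomer()
  tr <- simulate_trajectory(st, trajectory_spec(n_frames = 10,
                                                jitter_sd = 0.2, seed = 53))
  set.seed(59)
  rig <- random_rigid()
  co2 <- tr$coords
  for (f in 1:10) co2[f, , ] <- apply_rigid(frame_coords(tr, f), rig)
  tr2 <- trajectory(st, co2)
  d1 <- ionic_lock_series(tr, "A")$values
  d2 <- ionic_lock_series(tr2, "A")$values
  expect_equal(d1, d2, tolerance = 1e-9)
  r1 <- rmsd_series(tr, 1)$values
  r2 <- rmsd_series(tr2, 1)$values
  expect_equal(r1, r2, tolerance = 1e-6)
})
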