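#' Enumerate membrane-compatible dimer starting poses
#'
#' Builds the exhaustive rotational grid of dimer interfaces: for each pair
#' of grid angles (alpha_i = 360 i / steps_a, beta_j = 360 j / steps_b) copy
#' A is rotated by alpha_i and copy B by beta_j about their own membrane
#' normals (z-axes through each protomer's centroid), and B is slid along the
#' inter-axis (+x) direction until the minimum inter-protomer heavy-atom
#' distance equals `d_contact`. Both protomers keep the +z membrane normal,
#' so every pose is compatible with membrane integration. Poses are ordered
#' by (i, j). The default 12 x 12 grid yields 144 starting dimers.
#'
#' @param monomer annotated `Structure` (needs at least two labeled helices)
#' @param steps_a,steps_b rotational grid steps per protomer
#' @param d_contact closest heavy-atom contact distance at placement
#'   (Angstrom)
#' @return list of `DimerPose` objects (length `steps_a * steps_b`)
#' @export
enumerate_dimer_poses <- function(monomer, steps_a = 12L, steps_b = 12L,
                                  d_contact = 4.0) {
  if (steps_a < 1 || steps_b < 1) stop("steps must be >= 1")
  if (d_contact <= 0) stop("d_contact must be > 0")
  nhel <- sum(helix_names() %in% unique(monomer$atoms$segment))
  if (nhel < 2) stop("monomer needs at least 2 labeled helices")
  M <- coords(monomer)
  ctr <- colMeans(M)
  M <- sweep(M, 2, c(ctr[1], ctr[2], 0))  # own z-axis through the origin
  poses <- vector("list", steps_a * steps_b)
  k <- 0L
  for (i in 0:(steps_a - 1L)) {
    alpha <- 360 * i / steps_a
    A <- M %*% t(rotz(alpha))
    for (j in 0:(steps_b - 1L)) {
      beta <- 360 * j / steps_b
      B0 <- M %*% t(rotz(beta))
      s <- cpp_contact_shift(A, B0, d_contact)
      if (!is.finite(s)) stop("no contact possible for pose (", i, ",", j, ")")
      k <- k + 1L
      p <- list(monomer = monomer, template_xyz = M,
                rot_a = alpha, rot_b = beta, separation = c(s, 0),
                d_contact = d_contact, grid_index = c(i, j),
                refinement = NULL)
      class(p) <- "DimerPose"
      poses[[k]] <- p
    }
  }
  poses
}

#' @export
print.DimerPose <- function(x, ...) {
  cat(sprintf("DimerPose grid (%d,%d): rot A %.1f deg, rot B %.1f deg, shift %.2f A",
              x$grid_index[1], x$grid_index[2], x$rot_a, x$rot_b,
              x$separation[1]))
  if (!is.null(x$refinement))
    cat(sprintf(" | refined: replicate %d, E = %.3f", x$refinement$replicate,
                x$refinement$energy))
  cat("\n")
  invisible(x)
}

#' Protomer coordinates of a dimer pose
#'
#' Fast path used by the scoring loop: returns the placed coordinate
#' matrices of both protomers without materializing a full `Structure`.
#' The refinement transform, when present, is applied to protomer B
#' (rotation about B's own z-axis, in-plane translation, bounded z-shift).
#'
#' @param pose a `DimerPose`
#' @return list with matrices `A` and `B`
#' @export
pose_coords <- function(pose) {
  A <- pose$template_xyz %*% t(rotz(pose$rot_a))
  B <- pose$template_xyz %*% t(rotz(pose$rot_b))
  B[, 1] <- B[, 1] + pose$separation[1]
  B[, 2] <- B[, 2] + pose$separation[2]
  rf <- pose$refinement
  if (!is.null(rf)) {
    cB <- colMeans(B)
    B <- sweep(B, 2, cB) %*% t(rotz(rf$state[1]))
    B <- sweep(B, 2, cB + rf$state[2:4], "+")
  }
  list(A = A, B = B)
}

#' Materialize a dimer pose as a two-chain Structure
#'
#' @param pose a `DimerPose`
#' @return `Structure` with chains A and B (protomer copies sharing residue
#'   numbering and annotations)
#' @export
realize_pose <- function(pose) {
  xy <- pose_coords(pose)
  at <- pose$monomer$atoms
  a <- at; a$chain <- "A"; a$x <- xy$A[, 1]; a$y <- xy$A[, 2]; a$z <- xy$A[, 3]
  b <- at; b$chain <- "B"; b$x <- xy$B[, 1]; b$y <- xy$B[, 2]; b$z <- xy$B[, 3]
  m <- rbind(a, b)
  m$serial <- seq_len(nrow(m))
  pdb_structure(m, segments = pose$monomer$segments,
                bw_refs = pose$monomer$bw_refs)
}

#' Monte Carlo refinement control parameters
#'
#' Proposal standard deviations for the rigid-body Metropolis chains:
#' in-plane translation, z-shift (bounded by `zmax` to keep membrane
#' register), rotation of protomer B about its own z-axis; `temperature` is
#' in energy units (1.0 accepts a +1 move with probability exp(-1) ~ 0.37).
#' Initial chain states are drawn with the same standard deviations. The
#' stage's role is local sampling around a fixed enumerated interface, so
#' chains are confined to `rot_max` degrees of rotation and `trans_max`
#' Angstrom of in-plane drift around the parent pose (the rotation bound
#' defaults to half the default 30-degree enumeration step, keeping each
#' refined population attached to its starting interface).
#'
#' @param trans_sd in-plane translation proposal sd (Angstrom)
#' @param z_sd z-shift proposal sd (Angstrom)
#' @param rot_sd rotation proposal sd (degrees)
#' @param temperature Metropolis temperature (energy units)
#' @param zmax maximum absolute z-shift (Angstrom)
#' @param rot_max maximum rotation away from the parent pose (degrees)
#' @param trans_max maximum in-plane drift from the parent pose (Angstrom;
#'   the conventional local-perturbation magnitude); `NULL` derives it per
#'   pose as `separation * tan(rot_max)` for an angularly isotropic bound
#' @return list of control parameters
#' @export
refine_control <- function(trans_sd = 1.0, z_sd = 0.25, rot_sd = 5.0,
                           temperature = 1.0, zmax = 2.0, rot_max = 15.0,
                           trans_max = 3.0) {
  list(trans_sd = trans_sd, z_sd = z_sd, rot_sd = rot_sd,
       temperature = temperature, zmax = zmax, rot_max = rot_max,
       trans_max = trans_max)
}

#' Refine a dimer pose by rigid-body Monte Carlo
#'
#' Runs `n_outputs` independent Metropolis chains over the membrane-
#' compatible rigid-body degrees of freedom of protomer B (rotation about
#' its own z-axis, in-plane translation, bounded z-shift), minimizing the
#' surrogate cross-protomer interaction energy (6-12 Lennard-Jones plus
#' Coulomb with distance-dependent dielectric). Each chain starts from a
#' small random perturbation of the parent pose and reports its best-visited
#' transform and energy. A fixed seed gives bit-identical output.
#'
#' @param pose a `DimerPose` from [enumerate_dimer_poses()]
#' @param n_outputs number of refined poses (independent chains)
#' @param mc_steps Metropolis steps per chain
#' @param seed RNG seed
#' @param control a [refine_control()]
#' @param params an [energy_params()]
#' @return list of `n_outputs` refined `DimerPose` objects, each with a
#'   `refinement` field (`state`, `energy`, `replicate`, `seed`)
#' @export
refine_pose <- function(pose, n_outputs = 10L, mc_steps = 200L, seed = 1L,
                        control = refine_control(), params = energy_params()) {
  if (n_outputs < 1) stop("n_outputs must be >= 1")
  if (mc_steps < 0) stop("mc_steps must be >= 0")
  ff <- atom_ff(pose$monomer, params)
  A <- pose$template_xyz %*% t(rotz(pose$rot_a))
  B0 <- pose$template_xyz %*% t(rotz(pose$rot_b))
  B0[, 1] <- B0[, 1] + pose$separation[1]
  B0[, 2] <- B0[, 2] + pose$separation[2]
  trans_max <- control$trans_max
  if (is.null(trans_max))
    trans_max <- sqrt(sum(pose$separation^2)) *
      tan(control$rot_max * pi / 180)
  sds <- c(control$rot_sd, control$trans_sd, control$trans_sd, control$z_sd)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  out <- vector("list", n_outputs)
  for (r in seq_len(n_outputs)) {
    start <- rnorm(4, sd = sds)
    start[1] <- max(min(start[1], control$rot_max), -control$rot_max)
    start[4] <- max(min(start[4], control$zmax), -control$zmax)
    tn <- sqrt(start[2]^2 + start[3]^2)
    if (tn > trans_max) start[2:3] <- start[2:3] * trans_max / tn
    props <- matrix(rnorm(4 * mc_steps, sd = rep(sds, each = mc_steps)),
                    ncol = 4)
    unifs <- runif(mc_steps)
    res <- cpp_mc_refine(A, B0, ff$charge, ff$charge, ff$rmin, ff$rmin,
                         ff$eps, ff$eps, start, props, unifs,
                         control$temperature, control$zmax, control$rot_max,
                         trans_max, params$cutoff,
                         params$clash_dist, params$clash_cap,
                         params$coulomb_k)
    p <- pose
    p$refinement <- list(state = res$best_state, energy = res$best_energy,
                         final_state = res$final_state,
                         final_energy = res$final_energy,
                         replicate = r, seed = seed)
    out[[r]] <- p
  }
  out
}

#' Refine every pose of an enumeration
#'
#' Applies [refine_pose()] to each pose with a per-pose seed derived as
#' `seed + pose index - 1`; a 144-pose grid with 10 replicates yields the
#' full population of 1440 refined dimers.
#'
#' @inheritParams refine_pose
#' @param poses list of `DimerPose`
#' @return flat list of refined poses, ordered by (grid i, grid j, replicate)
#' @export
refine_poses <- function(poses, n_outputs = 10L, mc_steps = 200L, seed = 1L,
                         control = refine_control(),
                         params = energy_params()) {
  out <- vector("list", length(poses) * n_outputs)
  k <- 0L
  for (ip in seq_along(poses)) {
    rp <- refine_pose(poses[[ip]], n_outputs = n_outputs, mc_steps = mc_steps,
                      seed = seed + ip - 1L, control = control,
                      params = params)
    for (p in rp) { k <- k + 1L; out[[k]] <- p }
  }
  out
}
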