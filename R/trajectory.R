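#' Trajectory over a fixed topology
#'
#' @param topology a `Structure` giving the frame-invariant atom identities
#' @param coords numeric array `n_frames x n_atoms x 3`
#' @param frame_interval time per frame (arbitrary units)
#' @return object of class `Trajectory`
#' @export
trajectory <- function(topology, coords, frame_interval = 1) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("frame atom count (", dim(coords)[2],
         ") does not match topology (", nrow(topology$atoms), ")")
  if (dim(coords)[1] < 1L) stop("need at least one frame")
  x <- list(topology = topology, coords = coords,
            frame_interval = frame_interval)
  class(x) <- "Trajectory"
  x
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2], "atoms\n")
  invisible(x)
}

#' Number of frames of a trajectory
#' @param traj a `Trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a `Trajectory`
#' @param f frame index (1-based)
#' @return n x 3 matrix
#' @export
frame_coords <- function(traj, f) {
  m <- traj$coords[f, , , drop = TRUE]
  dim(m) <- c(dim(traj$coords)[2], 3)
  m
}

new_distance_series <- function(values, sel1, sel2, reduction,
                                threshold = NULL) {
  x <- list(values = values, sel1 = sel1, sel2 = sel2, reduction = reduction,
            mean = mean(values), min = min(values), max = max(values),
            threshold = threshold,
            fraction_below = if (is.null(threshold)) NULL
                             else mean(values < threshold))
  class(x) <- "DistanceSeries"
  x
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("DistanceSeries (%s): %d frames, mean %.2f, min %.2f, max %.2f A\n",
              x$reduction, length(x$values), x$mean, x$min, x$max))
  if (!is.null(x$threshold))
    cat(sprintf("  fraction below %.2f A: %.3f\n", x$threshold,
                x$fraction_below))
  invisible(x)
}

#' Per-frame distance between two atom selections
#'
#' @param traj a `Trajectory`
#' @param sel1,sel2 selector strings on the topology
#' @param reduction "min" (minimum pairwise distance) or "centroid"
#'   (centroid-centroid distance)
#' @param threshold optional distance threshold; when given the fraction of
#'   frames below it is reported
#' @return a `DistanceSeries`
#' @export
distance_series <- function(traj, sel1, sel2, reduction = c("min", "centroid"),
                            threshold = NULL) {
  reduction <- match.arg(reduction)
  i1 <- select_atoms(traj$topology, sel1)
  i2 <- select_atoms(traj$topology, sel2)
  if (length(i1) == 0L) stop("empty selection: ", sel1)
  if (length(i2) == 0L) stop("empty selection: ", sel2)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    a <- m[i1, , drop = FALSE]; b <- m[i2, , drop = FALSE]
    if (reduction == "centroid") {
      sqrt(sum((colMeans(a) - colMeans(b))^2))
    } else {
      d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
      sqrt(max(0, min(d2)))
    }
  }, 0)
  new_distance_series(vals, sel1, sel2, reduction, threshold)
}

#' Ionic-lock distance series (Arg 3.50 - Glu 6.30)
#'
#' The inactive-state diagnostic of class-A GPCRs: per frame, the minimum
#' distance between the Arg 3.50 guanidinium nitrogens (NE, NH1, NH2) and
#' the Glu 6.30 carboxylate oxygens (OE1, OE2) on one chain, plus the
#' fraction of frames below the lock-formed threshold (default 4.5
#' Angstrom, the salt-bridge convention).
#'
#' @param traj a `Trajectory` with generic-number annotations
#' @param chain chain id
#' @param threshold lock-formed distance threshold (Angstrom)
#' @return a `DistanceSeries` with `fraction_below`
#' @export
ionic_lock_series <- function(traj, chain = "A", threshold = 4.5) {
  topo <- traj$topology
  need <- list(c("3.50", "NE,NH1,NH2", 3L), c("6.30", "OE1,OE2", 2L))
  sels <- character(2)
  for (k in 1:2) {
    gn <- need[[k]][1]
    sel <- paste0(chain, ":", gn, ":", need[[k]][2])
    idx <- tryCatch(select_atoms(topo, sel),
                    error = function(e) stop("cannot resolve residue ", gn,
                                             " on chain ", chain, ": ",
                                             conditionMessage(e)))
    if (length(idx) < as.integer(need[[k]][3]))
      stop("residue ", gn, " on chain ", chain,
           " is missing side-chain atoms (", need[[k]][2], ")")
    sels[k] <- sel
  }
  distance_series(traj, sels[1], sels[2], reduction = "min",
                  threshold = threshold)
}

#' Hydrogen-bond persistence over a trajectory
#'
#' Per frame, the bond is present iff any donor-acceptor pair between the
#' two selections satisfies the geometric criteria of [detect_hbonds()]
#' (heavy-atom variant). Occupancy is the fraction of frames with the bond
#' present.
#'
#' @param traj a `Trajectory`
#' @param donor_sel selector for candidate donor atoms
#' @param acceptor_sel selector for candidate acceptor atoms
#' @param d_max,theta_min geometric criteria (see [hbond_params()])
#' @return object of class `OccupancyReport`: `pair`, per-frame logical
#'   `present`, `occupancy`
#' @export
hbond_persistence <- function(traj, donor_sel, acceptor_sel, d_max = 3.5,
                              theta_min = 120) {
  topo <- traj$topology
  di <- select_atoms(topo, donor_sel)
  ai <- select_atoms(topo, acceptor_sel)
  if (length(di) == 0L) stop("empty selection: ", donor_sel)
  if (length(ai) == 0L) stop("empty selection: ", acceptor_sel)
  hb <- hbond_params(d_max = d_max, theta_min = theta_min)
  typ <- hbond_typing(topo$atoms)
  keep <- typ$donors %in% di
  don <- typ$donors[keep]; base <- typ$base[keep]
  if (length(don) == 0L) { don <- di; base <- rep(NA_integer_, length(di)) }
  present <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    for (k in seq_along(don)) {
      bxyz <- if (is.na(base[k])) NULL else m[base[k], ]
      for (j in ai) {
        if (!is.null(hbond_geometry(m[don[k], ], m[j, ], bxyz, hb)))
          return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  x <- list(pair = paste(donor_sel, "-", acceptor_sel), present = present,
            occupancy = mean(present))
  class(x) <- "OccupancyReport"
  x
}

#' @export
print.OccupancyReport <- function(x, ...) {
  cat(sprintf("OccupancyReport %s: occupancy %.3f over %d frames\n", x$pair,
              x$occupancy, length(x$present)))
  invisible(x)
}

#' Water-mediated bridges between two selections
#'
#' Per frame, the number of water molecules (residue name HOH or WAT) whose
#' oxygen lies within `d_max` of at least one atom of each selection.
#'
#' @param traj a `Trajectory`
#' @param sel1,sel2 selector strings
#' @param d_max bridging distance (Angstrom)
#' @return integer vector, one count per frame (all zero without waters)
#' @export
water_bridges <- function(traj, sel1, sel2, d_max = 3.5) {
  topo <- traj$topology
  i1 <- select_atoms(topo, sel1)
  i2 <- select_atoms(topo, sel2)
  wi <- which(topo$atoms$resname %in% c("HOH", "WAT") &
                topo$atoms$name == "O")
  nf <- n_frames(traj)
  if (length(wi) == 0L) return(rep(0L, nf))
  vapply(seq_len(nf), function(f) {
    m <- frame_coords(traj, f)
    w <- m[wi, , drop = FALSE]
    near <- function(idx) {
      t2 <- m[idx, , drop = FALSE]
      d2 <- outer(rowSums(w^2), rep(1, nrow(t2))) +
        outer(rep(1, nrow(w)), rowSums(t2^2)) - 2 * w %*% t(t2)
      apply(d2 <= d_max^2, 1, any)
    }
    sum(near(i1) & near(i2))
  }, 0L)
}

#' Superposed RMSD series and stability verdict
#'
#' Per frame, the Kabsch-superposed RMSD to a reference frame; the
#' trajectory is called stable iff the maximum RMSD stays at or below
#' `threshold` (default 4 Angstrom, the usual complex-stability criterion).
#'
#' @param traj a `Trajectory`
#' @param reference_frame reference frame index (default 1)
#' @param selection optional selector restricting the compared atoms
#' @param threshold stability threshold (Angstrom)
#' @return a `DistanceSeries` with an extra `stable` logical field
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL,
                        threshold = 4.0) {
  idx <- if (is.null(selection)) seq_len(dim(traj$coords)[2])
         else select_atoms(traj$topology, selection)
  if (length(idx) < 3L) stop("selection must resolve at least 3 atoms")
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch(frame_coords(traj, f)[idx, , drop = FALSE], ref)$rmsd
  }, 0)
  out <- new_distance_series(vals, selection %||% "all",
                             sprintf("frame %d", reference_frame), "rmsd")
  out$threshold <- threshold
  out$stable <- max(vals) <= threshold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
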