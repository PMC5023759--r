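#' Surrogate force-field and SASA parameters
#'
#' Per-element Lennard-Jones radii (rmin/2, Angstrom) and well depths
#' (kcal/mol), Coulomb constant with distance-dependent dielectric
#' eps(r) = 4r, 10 Angstrom cutoff, clash handling, and Shrake-Rupley
#' quadrature defaults (probe 1.4 Angstrom, 92 sphere points).
#'
#' @param radii named vector of per-element LJ radii
#' @param eps named vector of per-element LJ well depths
#' @param cutoff pair-interaction cutoff (Angstrom)
#' @param coulomb_k Coulomb prefactor (kcal mol-1 Angstrom e-2)
#' @param clash_dist distance below which a pair is flagged as a clash
#' @param clash_cap cap on a single pair's repulsive LJ term
#' @param probe solvent probe radius (Angstrom)
#' @param n_points Shrake-Rupley sphere points per atom
#' @return list of parameters
#' @export
energy_params <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                    H = 1.20, P = 1.80),
                          eps = c(C = 0.10, N = 0.16, O = 0.21, S = 0.25,
                                  H = 0.02, P = 0.20),
                          cutoff = 10, coulomb_k = 332.06, clash_dist = 0.5,
                          clash_cap = 100, probe = 1.4, n_points = 92L) {
  list(radii = radii, eps = eps, cutoff = cutoff, coulomb_k = coulomb_k,
       clash_dist = clash_dist, clash_cap = clash_cap, probe = probe,
       n_points = as.integer(n_points))
}

#' Hydrogen-bond geometric criteria and energy parameters
#'
#' Heavy-atom criteria (the structures carry no hydrogens): donor-acceptor
#' distance at most `d_max`, alignment angle (donor antecedent - donor -
#' acceptor) at least `theta_min`. Bond energy is
#' -eps_hb * cos^2(180 - theta) * ramp(d) with ramp falling linearly from 1
#' to 0 over \[d_opt, d_max\].
#'
#' @param d_opt optimal donor-acceptor distance (Angstrom)
#' @param d_max maximum donor-acceptor distance (Angstrom)
#' @param theta_min minimum alignment angle (degrees)
#' @param eps_hb well depth (energy units, > 0)
#' @return list of parameters
#' @export
hbond_params <- function(d_opt = 2.9, d_max = 3.5, theta_min = 120,
                         eps_hb = 2.0) {
  list(d_opt = d_opt, d_max = d_max, theta_min = theta_min, eps_hb = eps_hb)
}

# Per-atom force-field assignment (radius, well depth, charge).
atom_ff <- function(structure, params = energy_params()) {
  el <- structure$atoms$elem
  unknown <- setdiff(unique(el), names(params$radii))
  if (length(unknown))
    stop("no configured radius for element(s): ", paste(unknown, collapse = ", "))
  list(rmin = unname(params$radii[el]), eps = unname(params$eps[el]),
       charge = structure$atoms$charge)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from a deterministic spherical quadrature
#' (golden-section spiral points), neighbour-culled. The sum over atoms is
#' attached as attribute `total`.
#'
#' @param x a `Structure` or an n x 3 coordinate matrix
#' @param probe probe radius (Angstrom)
#' @param n_points quadrature points per atom (>= 32)
#' @param radii per-element radius table (used when `x` is a `Structure`)
#' @param atom_radii explicit per-atom radii (required when `x` is a matrix)
#' @return numeric vector of per-atom areas (Angstrom^2)
#' @export
sasa <- function(x, probe = 1.4, n_points = 92L,
                 radii = energy_params()$radii, atom_radii = NULL) {
  if (n_points < 32) stop("n_points must be >= 32")
  if (inherits(x, "Structure")) {
    el <- x$atoms$elem
    unknown <- setdiff(unique(el), names(radii))
    if (length(unknown))
      stop("no configured radius for element(s): ",
           paste(unknown, collapse = ", "))
    atom_radii <- unname(radii[el])
    x <- coords(x)
  }
  if (is.null(atom_radii)) stop("atom_radii required for matrix input")
  a <- cpp_sasa(x, atom_radii, probe, as.integer(n_points))
  attr(a, "total") <- sum(a)
  a
}

# Accept a DimerPose or a two-chain Structure; return list with coordinate
# matrices A/B, the shared atom table(s), and per-chain atom indices.
dimer_parts <- function(dimer) {
  if (inherits(dimer, "DimerPose")) {
    xy <- pose_coords(dimer)
    at <- dimer$monomer$atoms
    list(A = xy$A, B = xy$B, atoms_a = at, atoms_b = at,
         structure = NULL, mono = dimer$monomer)
  } else if (inherits(dimer, "Structure")) {
    ch <- unique(dimer$atoms$chain)
    if (length(ch) != 2L) stop("dimer structure must have exactly 2 chains")
    ia <- which(dimer$atoms$chain == ch[1])
    ib <- which(dimer$atoms$chain == ch[2])
    list(A = coords(dimer, ia), B = coords(dimer, ib),
         atoms_a = dimer$atoms[ia, ], atoms_b = dimer$atoms[ib, ],
         structure = dimer, mono = NULL)
  } else stop("dimer must be a DimerPose or a two-chain Structure")
}

elem_radii <- function(atoms, radii) {
  unknown <- setdiff(unique(atoms$elem), names(radii))
  if (length(unknown))
    stop("no configured radius for element(s): ", paste(unknown, collapse = ", "))
  unname(radii[atoms$elem])
}

#' Interface area buried upon dimerization
#'
#' SASA(A alone) + SASA(B alone) - SASA(AB); tiny negative quadrature noise
#' is clamped to zero.
#'
#' @param dimer a `DimerPose` or two-chain `Structure`
#' @param params an [energy_params()] (probe, n_points, radii)
#' @return buried area (Angstrom^2)
#' @export
interface_area <- function(dimer, params = energy_params()) {
  b <- per_atom_burial(dimer, params)
  max(0, sum(b$burial_a) + sum(b$burial_b))
}

# Per-atom SASA loss upon complexation, per chain.
per_atom_burial <- function(dimer, params = energy_params()) {
  dp <- dimer_parts(dimer)
  ra <- elem_radii(dp$atoms_a, params$radii)
  rb <- elem_radii(dp$atoms_b, params$radii)
  sa <- cpp_sasa(dp$A, ra, params$probe, params$n_points)
  sb <- cpp_sasa(dp$B, rb, params$probe, params$n_points)
  sab <- cpp_sasa(rbind(dp$A, dp$B), c(ra, rb), params$probe, params$n_points)
  na <- nrow(dp$A)
  list(burial_a = sa - sab[seq_len(na)],
       burial_b = sb - sab[na + seq_len(nrow(dp$B))],
       parts = dp)
}

#' Interface residues by SASA burial
#'
#' A residue is interfacial iff its summed per-atom SASA loss upon
#' complexation exceeds `burial_threshold` (default 0.1 Angstrom^2: any
#' burial counts, in the spirit of PISA's permissive interface listing).
#'
#' @param dimer a `DimerPose` or two-chain `Structure`
#' @param burial_threshold minimum buried area per residue (Angstrom^2)
#' @param params an [energy_params()]
#' @return list with per-chain data.frames (`resno`, `buried`), ordered by
#'   residue number
#' @export
interface_residues <- function(dimer, burial_threshold = 0.1,
                               params = energy_params()) {
  b <- per_atom_burial(dimer, params)
  per_chain <- function(burial, atoms) {
    agg <- tapply(burial, atoms$resno, sum)
    out <- data.frame(resno = as.integer(names(agg)), buried = as.numeric(agg))
    out <- out[out$buried > burial_threshold, , drop = FALSE]
    out[order(out$resno), , drop = FALSE]
  }
  list(A = per_chain(b$burial_a, b$parts$atoms_a),
       B = per_chain(b$burial_b, b$parts$atoms_b))
}

# Hydrogen-bond donor/acceptor typing from residue templates (heavy-atom
# variant; base = antecedent used for the alignment angle at the donor).
hbond_typing <- function(atoms) {
  nm <- atoms$name
  donors <- which((nm == "N" & atoms$resname != "PRO") |
                    nm %in% c("NE", "NH1", "NH2", "NE1", "OG1", "OH") |
                    grepl("^PD[0-9]+$", nm))
  acceptors <- which(nm %in% c("O", "OD1", "OD2", "OE1", "OE2", "OG1", "OH",
                               "NE2") | grepl("^PA[0-9]+$", nm))
  base_name <- c(N = "CA", NE = "CB", NH1 = "NE", NH2 = "NE", NE1 = "CB",
                 OG1 = "CB", OH = "CB")
  base <- integer(length(donors))
  for (k in seq_along(donors)) {
    i <- donors[k]
    bn <- if (grepl("^PD", nm[i])) "CB" else unname(base_name[nm[i]])
    j <- which(atoms$resno == atoms$resno[i] & atoms$chain == atoms$chain[i] &
                 nm == bn)
    base[k] <- if (length(j) == 1L) j else NA_integer_
  }
  list(donors = donors, base = base, acceptors = acceptors)
}

hbond_geometry <- function(dxyz, axyz, bxyz, hb) {
  d <- sqrt(sum((axyz - dxyz)^2))
  if (d > hb$d_max) return(NULL)
  if (is.null(bxyz)) {
    theta <- 180
  } else {
    v1 <- dxyz - bxyz; v2 <- axyz - dxyz
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    # alignment angle at the donor: 180 deg when base-donor-acceptor are
    # collinear in extension
    theta <- 180 - acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  }
  if (theta < hb$theta_min) return(NULL)
  ramp <- if (d <= hb$d_opt) 1 else (hb$d_max - d) / (hb$d_max - hb$d_opt)
  energy <- -hb$eps_hb * cos((180 - theta) * pi / 180)^2 * ramp
  c(d = d, theta = theta, energy = energy)
}

# Cross-protomer H-bonds from precomputed typing and coordinate matrices.
# Distances are prefiltered with one vectorized donor x acceptor matrix;
# angles are evaluated only for pairs inside d_max.
hbonds_cross <- function(typA, typB, A, B, atoms_a, atoms_b, hb) {
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor = character(0), acceptor_chain = character(0),
                      acceptor_resno = integer(0), acceptor = character(0),
                      distance = numeric(0), angle = numeric(0),
                      energy = numeric(0))
  scan <- function(typD, typA2, D, Acc, lbl_d, lbl_a, atd, ata) {
    di <- typD$donors; ai <- typA2$acceptors
    if (length(di) == 0L || length(ai) == 0L) return(NULL)
    Dm <- D[di, , drop = FALSE]; Am <- Acc[ai, , drop = FALSE]
    d2 <- outer(rowSums(Dm^2), rep(1, nrow(Am))) +
      outer(rep(1, nrow(Dm)), rowSums(Am^2)) - 2 * Dm %*% t(Am)
    hits <- which(d2 <= hb$d_max^2, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(NULL)
    nh <- nrow(hits)
    ii <- jj <- integer(nh); dd <- th <- en <- numeric(nh)
    nkeep <- 0L
    for (h in seq_len(nh)) {
      k <- hits[h, 1]; j <- ai[hits[h, 2]]
      i <- di[k]
      bxyz <- if (is.na(typD$base[k])) NULL else D[typD$base[k], ]
      g <- hbond_geometry(D[i, ], Acc[j, ], bxyz, hb)
      if (is.null(g)) next
      nkeep <- nkeep + 1L
      ii[nkeep] <- i; jj[nkeep] <- j
      dd[nkeep] <- g[["d"]]; th[nkeep] <- g[["theta"]]; en[nkeep] <- g[["energy"]]
    }
    if (nkeep == 0L) return(NULL)
    s <- seq_len(nkeep)
    data.frame(donor_chain = lbl_d, donor_resno = atd$resno[ii[s]],
               donor = atd$name[ii[s]], acceptor_chain = lbl_a,
               acceptor_resno = ata$resno[jj[s]], acceptor = ata$name[jj[s]],
               distance = dd[s], angle = th[s], energy = en[s],
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan(typA, typB, A, B, "A", "B", atoms_a, atoms_b),
               scan(typB, typA, B, A, "B", "A", atoms_b, atoms_a))
  if (is.null(out)) empty else out
}

#' Detect cross-protomer hydrogen bonds
#'
#' Heavy-atom geometric criteria: donor-acceptor distance <= `d_max` and
#' alignment angle (donor antecedent - donor - acceptor, 180 = collinear)
#' >= `theta_min`. Donors/acceptors are typed from residue templates
#' (backbone N/O, pseudo-side-chain polar atoms, planted patch sites).
#' Donors with no resolvable antecedent are angle-unconstrained.
#'
#' @param dimer a `DimerPose` or two-chain `Structure`
#' @param hb an [hbond_params()]
#' @return data.frame of bonds (donor, acceptor, distance, angle, energy)
#' @export
detect_hbonds <- function(dimer, hb = hbond_params()) {
  dp <- dimer_parts(dimer)
  # distance prefilter: only consider atoms near the other protomer
  typA <- hbond_typing(dp$atoms_a)
  typB <- hbond_typing(dp$atoms_b)
  hbonds_cross(typA, typB, dp$A, dp$B, dp$atoms_a, dp$atoms_b, hb)
}

#' Binding-energy surrogate of a dimer pose
#'
#' E(X) is a sum over atom pairs of 6-12 Lennard-Jones plus Coulomb with
#' distance-dependent dielectric eps(r) = 4r, plus hydrogen-bond energies.
#' Because the protomers are rigid, the intramolecular terms of
#' E(AB) - E(A) - E(B) cancel exactly, and the surrogate binding free energy
#' equals the cross-protomer pair energy plus the cross-protomer H-bond
#' energy; the implementation computes those cross terms directly. All three
#' values are invariant under global rigid motion of the dimer. Atom pairs
#' closer than the configured clash distance set the clash flag and have
#' their repulsive terms capped.
#'
#' @param dimer a `DimerPose` or two-chain `Structure`
#' @param params an [energy_params()]
#' @param hb an [hbond_params()]
#' @return list with `dg_bind`, `interface_score` (cross pair terms only),
#'   `hbond_energy`, `hbonds` (data.frame), and `clash`
#' @export
binding_energy <- function(dimer, params = energy_params(),
                           hb = hbond_params()) {
  dp <- dimer_parts(dimer)
  ffa <- list(rmin = elem_radii(dp$atoms_a, params$radii),
              eps = unname(params$eps[dp$atoms_a$elem]),
              charge = dp$atoms_a$charge)
  ffb <- list(rmin = elem_radii(dp$atoms_b, params$radii),
              eps = unname(params$eps[dp$atoms_b$elem]),
              charge = dp$atoms_b$charge)
  ce <- cpp_cross_energy(dp$A, dp$B, ffa$charge, ffb$charge, ffa$rmin,
                         ffb$rmin, ffa$eps, ffb$eps, params$cutoff,
                         params$clash_dist, params$clash_cap,
                         params$coulomb_k)
  bonds <- hbonds_cross(hbond_typing(dp$atoms_a), hbond_typing(dp$atoms_b),
                        dp$A, dp$B, dp$atoms_a, dp$atoms_b, hb)
  hbe <- sum(bonds$energy)
  list(dg_bind = ce$energy + hbe, interface_score = ce$energy,
       hbond_energy = hbe, hbonds = bonds, clash = ce$clash)
}

adjacent_tm_pairs <- function() {
  data.frame(label = c("12", "23", "34", "45", "56", "67", "71"),
             h1 = c(1:7), h2 = c(2:7, 1), stringsAsFactors = FALSE)
}

#' The canonical interface-class alphabet
#'
#' All unordered pairs (with repetition) of the seven adjacent-TM pair
#' labels 12, 23, 34, 45, 56, 67, 71 — exactly 28 classes.
#'
#' @return character vector of 28 labels such as "45_71"
#' @export
interface_classes <- function() {
  p <- adjacent_tm_pairs()$label
  out <- character(0)
  for (i in seq_along(p)) for (j in i:length(p))
    out <- c(out, paste(p[i], p[j], sep = "_"))
  out
}

#' Classify the interface of a dimer pose by transmembrane helices
#'
#' Per protomer, each TM helix gets the summed buried area of its atoms; the
#' dominant pair is the adjacent-TM pair (12, 23, 34, 45, 56, 67, 71)
#' maximizing the buried area of its two helices, ties broken toward the
#' lower TM index. The class label is the canonical (lexicographically
#' sorted) combination of the two protomers' dominant pairs; poses with zero
#' buried area are "none". Interfaces dominated by non-adjacent helices are
#' assigned the best-covering adjacent pair by the same rule.
#'
#' @param dimer a `DimerPose` or two-chain `Structure`
#' @param params an [energy_params()]
#' @return class label string (e.g. "45_45", "45_71", or "none")
#' @export
classify_interface <- function(dimer, params = energy_params()) {
  b <- per_atom_burial(dimer, params)
  classify_from_burial(b$burial_a, b$parts$atoms_a$segment,
                       b$burial_b, b$parts$atoms_b$segment)
}

classify_from_burial <- function(burial_a, seg_a, burial_b, seg_b,
                                 tol = 1e-6) {
  pairs <- adjacent_tm_pairs()
  dominant <- function(burial, seg) {
    per_tm <- vapply(1:7, function(h) {
      sum(burial[!is.na(seg) & seg == paste0("TM", h)])
    }, 0)
    score <- per_tm[pairs$h1] + per_tm[pairs$h2]
    if (max(score) <= tol) return(NA_character_)
    pairs$label[which.max(score)]  # first max = lower TM index on ties
  }
  da <- dominant(burial_a, seg_a)
  db <- dominant(burial_b, seg_b)
  if (is.na(da) || is.na(db)) return("none")
  paste(sort(c(da, db)), sep = "", collapse = "_")
}

#' Score a refined dimer population
#'
#' Computes the four scoring parameters (cross-protomer interface score,
#' buried interface area, binding-energy surrogate, hydrogen-bond energy)
#' and the TM-pair interface class for every pose. Monomer SASA and
#' force-field assignments are computed once and reused, since every pose
#' places rigid copies of the same protomer.
#'
#' @param poses list of `DimerPose` (typically from [refine_poses()])
#' @param params an [energy_params()]
#' @param hb an [hbond_params()]
#' @return data.frame with one row per pose: `pose_id`, `grid_i`, `grid_j`,
#'   `replicate`, `class`, `interface_score`, `interface_area`, `dg_bind`,
#'   `hbond_energy`, `clash`
#' @export
score_poses <- function(poses, params = energy_params(),
                        hb = hbond_params()) {
  stopifnot(length(poses) >= 1L)
  mono <- poses[[1]]$monomer
  at <- mono$atoms
  ff <- atom_ff(mono, params)
  radii <- elem_radii(at, params$radii)
  typ <- hbond_typing(at)
  sasa_mono <- cpp_sasa(coords(mono), radii, params$probe, params$n_points)
  n <- nrow(at)
  rows <- vector("list", length(poses))
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    xy <- pose_coords(p)
    # Each chain's burial is evaluated in its own template frame (the dimer
    # is rotated so the chain coincides with the monomer used for the
    # reference SASA): the isolated-protomer baseline then cancels exactly
    # for non-interface atoms, and only interface atoms are re-evaluated.
    rot_b_total <- p$rot_b + if (is.null(p$refinement)) 0 else p$refinement$state[1]
    Ra <- rotz(-p$rot_a); Rb <- rotz(-rot_b_total)
    ba <- cpp_sasa_burial(xy$A %*% t(Ra), xy$B %*% t(Ra), radii, radii,
                          params$probe, params$n_points, sasa_mono,
                          sasa_mono)$burial_a
    bb <- cpp_sasa_burial(xy$B %*% t(Rb), xy$A %*% t(Rb), radii, radii,
                          params$probe, params$n_points, sasa_mono,
                          sasa_mono)$burial_a
    cls <- classify_from_burial(ba, at$segment, bb, at$segment)
    ce <- cpp_cross_energy(xy$A, xy$B, ff$charge, ff$charge, ff$rmin,
                           ff$rmin, ff$eps, ff$eps, params$cutoff,
                           params$clash_dist, params$clash_cap,
                           params$coulomb_k)
    bonds <- hbonds_cross(typ, typ, xy$A, xy$B, at, at, hb)
    hbe <- sum(bonds$energy)
    rep_i <- if (is.null(p$refinement)) NA_integer_ else p$refinement$replicate
    rows[[k]] <- data.frame(
      pose_id = sprintf("p%03d_%03d_r%02d", p$grid_index[1], p$grid_index[2],
                        ifelse(is.na(rep_i), 0L, rep_i)),
      grid_i = p$grid_index[1], grid_j = p$grid_index[2],
      replicate = rep_i, class = cls,
      interface_score = ce$energy,
      interface_area = max(0, sum(ba) + sum(bb)),
      dg_bind = ce$energy + hbe, hbond_energy = hbe,
      clash = ce$clash, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
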