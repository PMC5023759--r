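#' Template for an idealized 7-TM helical bundle
#'
#' Describes the geometry of a synthetic class-A GPCR-like monomer: seven
#' helix axes placed on a circle in the membrane plane, alternating up/down
#' orientation along +z (extracellular side up), per-helix tilts, ideal
#' alpha-helix parameters, and short loops and tails. All dimensions are
#' artifact conventions for a schematic receptor, not a model of any real
#' structure.
#'
#' @param bundle_radius radius (Angstrom) of the circle carrying the helix
#'   axes
#' @param helix_lengths integer vector of 7 helix lengths (residues)
#' @param loop_lengths integer vector of 6 loop lengths
#' @param tail_lengths N-/C-terminal tail lengths, length 2
#' @param tilt_deg helix tilt magnitude (degrees); sign alternates per helix
#' @param rise_per_residue axial rise (Angstrom/residue), ideal value 1.5
#' @param twist_per_residue helical twist (degrees/residue), ideal value 100
#' @param calpha_radius CA distance from the helix axis (Angstrom)
#' @return object of class `BundleTemplate`
#' @export
bundle_template <- function(bundle_radius = 12,
                            helix_lengths = rep(26L, 7),
                            loop_lengths = rep(4L, 6),
                            tail_lengths = c(4L, 4L),
                            tilt_deg = 10,
                            rise_per_residue = 1.5,
                            twist_per_residue = 100,
                            calpha_radius = 2.3) {
  if (length(helix_lengths) != 7L) stop("need 7 helix lengths")
  if (rise_per_residue <= 0) stop("rise_per_residue must be > 0")
  az <- (0:6) * 2 * pi / 7
  pos <- cbind(bundle_radius * cos(az), bundle_radius * sin(az))
  d <- as.matrix(dist(pos))
  if (any(d[upper.tri(d)] < 6)) stop("helix axes closer than 6 Angstrom")
  tmpl <- list(
    helix_axis_positions = pos,
    helix_azimuths = az * 180 / pi,
    helix_tilts = data.frame(tilt = tilt_deg * (-1)^(0:6),
                             azimuth = az * 180 / pi + 180),
    # odd helices (TM1, TM3, ...) run extracellular -> intracellular
    helix_directions = ifelse(seq_len(7) %% 2 == 1, -1, 1),
    helix_lengths = as.integer(helix_lengths),
    loop_lengths = as.integer(loop_lengths),
    tail_lengths = as.integer(tail_lengths),
    rise_per_residue = rise_per_residue,
    twist_per_residue = twist_per_residue,
    calpha_radius = calpha_radius)
  class(tmpl) <- "BundleTemplate"
  tmpl
}

#' Default annotations for a bundle template
#'
#' Sequential residue numbering from 1 (N-tail, TM1, ICL1, TM2, ECL1, ...,
#' TM7, C-tail) with generic numbers attached so each helix of length L spans
#' positions (56-L)..55; for the default 26-residue helices that is x.30 to
#' x.55, which covers every functional position used by the generator (3.32,
#' 3.49, 3.50, 5.42, 6.30, 6.34, 6.48, 6.55).
#'
#' @param template a [bundle_template()]
#' @return list with `segments` data.frame and `bw_refs` named vector
#' @export
default_annotations <- function(template = bundle_template()) {
  hl <- template$helix_lengths
  ll <- template$loop_lengths
  tl <- template$tail_lengths
  loop_labels <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  labels <- c("N-term", rbind(paste0("TM", 1:6), loop_labels), "TM7", "C-term")
  lens <- c(tl[1], rbind(hl[1:6], ll), hl[7], tl[2])
  end <- cumsum(lens)
  start <- end - lens + 1L
  segments <- data.frame(label = labels, start = start, end = end,
                         stringsAsFactors = FALSE)
  hstart <- start[match(paste0("TM", 1:7), labels)]
  bw <- setNames(as.integer(hstart + (50L - (56L - hl))), paste0("TM", 1:7))
  list(segments = segments, bw_refs = bw)
}

rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

unitv <- function(v) v / sqrt(sum(v^2))

# Residue pseudo-side-chain recipes: functional positions get minimal
# interaction sites; everything else is poly-alanine (backbone + CB).
default_functional_residues <- function() {
  list("3.32" = "ASP", "3.49" = "ASP", "3.50" = "ARG", "5.42" = "TYR",
       "6.30" = "GLU", "6.34" = "THR", "6.48" = "TRP", "6.55" = "HIS")
}

#' Build an idealized 7-TM monomer
#'
#' Generates backbone (N, CA, C, O) plus CB on ideal alpha-helical geometry
#' for seven membrane-spanning helices, schematic loops and N-/C-terminal
#' tails, chain A, membrane normal +z. Designated functional residues carry
#' minimal pseudo-side-chain interaction sites: carboxylate-like oxygen pairs
#' (Asp 3.32, Asp 3.49, Glu 6.30), a guanidinium-like nitrogen triplet
#' (Arg 3.50), and single polar atoms for Thr 6.34 (OG1), Trp 6.48 (NE1),
#' His 6.55 (NE2), Tyr 5.42 (OH) and the N-terminal tyrosine (OH). The
#' orthosteric-pocket positions 3.32/6.48/6.55 face the bundle axis; the
#' Arg 3.50 / Glu 6.30 ionic-lock termini are placed schematically along the
#' line joining their CB atoms with a planted minimum N-O gap of `lock_gap`,
#' so the inactive-state lock is formed by construction.
#'
#' Backbone partial charges: N +0.2, O -0.2; carboxylate oxygens -0.5 each;
#' guanidinium nitrogens +0.33 each (all configurable post hoc via the atom
#' table).
#'
#' @param template a [bundle_template()]
#' @param annotations segment/numbering config (default
#'   [default_annotations()])
#' @param lock_gap planted Arg3.50-Glu6.30 minimum N-O distance (Angstrom)
#' @param functional named list mapping generic numbers to residue types
#' @return a `Structure` (chain A)
#' @export
build_ideal_tm_bundle <- function(template = bundle_template(),
                                  annotations = default_annotations(template),
                                  lock_gap = 3.5,
                                  functional = default_functional_residues()) {
  hl <- template$helix_lengths
  if (any(hl < 4)) stop("helix length < 4 residues")
  segs <- annotations$segments
  bw <- annotations$bw_refs
  rise <- template$rise_per_residue
  twist <- template$twist_per_residue
  rca <- template$calpha_radius

  # generic-number bookkeeping before atoms exist
  gn_tab <- list()
  for (h in 1:7) {
    row <- segs[segs$label == paste0("TM", h), ]
    rs <- row$start:row$end
    gn_tab[[h]] <- data.frame(resno = rs, helix = h,
                              pos = 50L + rs - bw[[paste0("TM", h)]])
  }
  gn_tab <- do.call(rbind, gn_tab)
  gn_of <- function(lbl) {
    pp <- as.numeric(strsplit(lbl, ".", fixed = TRUE)[[1]])
    gn_tab$resno[gn_tab$helix == pp[1] & gn_tab$pos == pp[2]]
  }

  res <- list()   # per residue: resno, resname, list of atoms (name, xyz, charge, elem)
  add_res <- function(resno, resname, atoms) {
    res[[length(res) + 1]] <<- list(resno = resno, resname = resname,
                                    atoms = atoms)
  }
  bb <- function(nm, xyz, q = 0) list(name = nm, xyz = xyz, charge = q)

  # helix frames and CA anchors, kept for loop/tail/patch construction
  helix_geo <- vector("list", 7)
  for (h in 1:7) {
    p0 <- c(template$helix_axis_positions[h, ], 0)
    s <- template$helix_directions[h]
    tilt <- template$helix_tilts$tilt[h] * pi / 180
    taz <- template$helix_tilts$azimuth[h] * pi / 180
    d <- unitv(c(sin(tilt) * cos(taz), sin(tilt) * sin(taz), s * cos(abs(tilt))))
    u <- unitv(c(1, 0, 0) - sum(c(1, 0, 0) * d) * d)
    v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    # phase: make a chosen residue's CB face the bundle centre
    L <- hl[h]
    first_pos <- 56L - L
    face_pos <- if (h == 3) 32L else if (h == 6) 48L else 50L
    j_face <- face_pos - first_pos
    tgt <- unitv(c(-p0[1], -p0[2], 0))
    phase <- atan2(sum(tgt * v), sum(tgt * u)) * 180 / pi - j_face * twist
    helix_geo[[h]] <- list(p0 = p0, d = d, u = u, v = v, phase = phase, L = L)
  }

  helix_atom <- function(h, j, r, dth, dt) {
    g <- helix_geo[[h]]
    th <- (g$phase + j * template$twist_per_residue + dth) * pi / 180
    t <- (j - (g$L - 1) / 2) * rise + dt
    g$p0 + t * g$d + r * (cos(th) * g$u + sin(th) * g$v)
  }

  for (h in 1:7) {
    g <- helix_geo[[h]]
    row <- segs[segs$label == paste0("TM", h), ]
    for (j in 0:(g$L - 1)) {
      resno <- row$start + j
      ca <- helix_atom(h, j, rca, 0, 0)
      n <- helix_atom(h, j, 1.56, -27.5, -0.95)
      cc <- helix_atom(h, j, 1.64, 25.5, 1.05)
      o <- cc + 1.23 * g$d
      radial <- unitv(helix_atom(h, j, rca + 1, 0, 0) - helix_atom(h, j, rca, 0, 0))
      cb <- ca + 1.53 * unitv(radial - 0.35 * g$d)
      add_res(resno, "ALA",
              list(bb("N", n, 0.2), bb("CA", ca), bb("C", cc), bb("O", o, -0.2),
                   bb("CB", cb)))
    }
  }

  # schematic loops and tails along interpolated paths
  path_res <- function(resno, ca, tdir) {
    perp <- c(tdir[2], -tdir[1], 0)
    if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
    perp <- unitv(perp)
    perp2 <- unitv(c(tdir[2] * perp[3] - tdir[3] * perp[2],
                     tdir[3] * perp[1] - tdir[1] * perp[3],
                     tdir[1] * perp[2] - tdir[2] * perp[1]))
    list(bb("N", ca - 1.46 * unitv(tdir * 0.94 + perp * 0.34), 0.2),
         bb("CA", ca), bb("C", ca + 1.52 * unitv(tdir * 0.94 - perp * 0.34)),
         bb("O", ca + 1.52 * unitv(tdir * 0.94 - perp * 0.34) + 1.23 * perp2,
            -0.2),
         bb("CB", ca + 1.53 * perp))
  }
  helix_end_ca <- function(h, which_end) {
    g <- helix_geo[[h]]
    j <- if (which_end == "first") 0 else g$L - 1
    helix_atom(h, j, rca, 0, 0)
  }
  loop_labels <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  for (k in 1:6) {
    row <- segs[segs$label == loop_labels[k], ]
    if (nrow(row) == 0 || row$end < row$start) next
    a <- helix_end_ca(k, "last")
    b <- helix_end_ca(k + 1, "first")
    M <- row$end - row$start + 1L
    zsign <- if (startsWith(loop_labels[k], "ICL")) -1 else 1
    for (m in seq_len(M)) {
      fr <- m / (M + 1)
      ca <- a + fr * (b - a) + c(0, 0, zsign * 2.5 * sin(pi * fr))
      add_res(row$start + m - 1L, "ALA", path_res(row$start + m - 1L, ca,
                                                  unitv(b - a)))
    }
  }
  # N tail above TM1 start (extracellular), C tail below TM7 end
  nt <- segs[segs$label == "N-term", ]
  if (nrow(nt) == 1 && nt$end >= nt$start) {
    anchor <- helix_end_ca(1, "first")
    dirv <- unitv(c(0.3, 0.3, 1))
    M <- nt$end - nt$start + 1L
    for (m in seq_len(M)) {
      ca <- anchor + (M - m + 1L) * 3.0 * dirv
      add_res(nt$start + m - 1L, "ALA", path_res(nt$start + m - 1L, ca, -dirv))
    }
  }
  ct <- segs[segs$label == "C-term", ]
  if (nrow(ct) == 1 && ct$end >= ct$start) {
    anchor <- helix_end_ca(7, "last")
    dirv <- unitv(c(0.3, -0.3, -1))
    M <- ct$end - ct$start + 1L
    for (m in seq_len(M)) {
      ca <- anchor + m * 3.0 * dirv
      add_res(ct$start + m - 1L, "ALA", path_res(ct$start + m - 1L, ca, dirv))
    }
  }

  # functional residue decorations
  names(res) <- vapply(res, function(r) as.character(r$resno), "")
  get_atom <- function(resno, nm) {
    r <- res[[as.character(resno)]]
    for (a in r$atoms) if (a$name == nm) return(a$xyz)
    stop("internal: atom ", nm, " missing in residue ", resno)
  }
  add_sites <- function(resno, resname, sites) {
    r <- res[[as.character(resno)]]
    r$resname <- resname
    r$atoms <- c(r$atoms, sites)
    res[[as.character(resno)]] <<- r
  }
  branch <- function(resno) {
    ca <- get_atom(resno, "CA"); cb <- get_atom(resno, "CB")
    b <- unitv(cb - ca)
    p <- c(b[2], -b[1], 0)
    if (sqrt(sum(p^2)) < 1e-6) p <- c(1, 0, 0)
    list(cb = cb, b = b, p = unitv(p))
  }
  for (lbl in names(functional)) {
    resno <- gn_of(lbl)
    if (length(resno) != 1L) next
    type <- functional[[lbl]]
    br <- branch(resno)
    if (type == "ASP") {
      add_sites(resno, "ASP",
                list(bb("OD1", br$cb + 1.5 * br$b + 0.9 * br$p, -0.5),
                     bb("OD2", br$cb + 1.5 * br$b - 0.9 * br$p, -0.5)))
    } else if (type == "THR") {
      add_sites(resno, "THR", list(bb("OG1", br$cb + 1.43 * br$b)))
    } else if (type == "TYR") {
      add_sites(resno, "TYR", list(bb("OH", br$cb + 2.8 * br$b)))
    } else if (type == "TRP") {
      add_sites(resno, "TRP", list(bb("NE1", br$cb + 2.2 * br$b)))
    } else if (type == "HIS") {
      add_sites(resno, "HIS", list(bb("NE2", br$cb + 2.2 * br$b)))
    }
    # ARG 3.50 / GLU 6.30 handled jointly below
  }
  if (!is.null(functional[["3.50"]]) && !is.null(functional[["6.30"]])) {
    r350 <- gn_of("3.50"); r630 <- gn_of("6.30")
    cb1 <- get_atom(r350, "CB"); cb2 <- get_atom(r630, "CB")
    v <- cb2 - cb1; L <- sqrt(sum(v^2)); u <- v / L
    p <- c(u[2], -u[1], 0)
    if (sqrt(sum(p^2)) < 1e-6) p <- c(1, 0, 0)
    p <- unitv(p)
    m <- (L - lock_gap) / 2
    add_sites(r350, "ARG",
              list(bb("NE", cb1 + (m - 1.8) * u + 0.6 * p, 0.33),
                   bb("NH2", cb1 + (m - 0.6) * u + 1.1 * p, 0.33),
                   bb("NH1", cb1 + m * u, 0.33)))
    add_sites(r630, "GLU",
              list(bb("OE1", cb1 + (m + lock_gap) * u, -0.5),
                   bb("OE2", cb1 + (m + lock_gap + 0.9) * u + 0.8 * p, -0.5)))
  }
  # N-terminal tyrosine analog (first residue)
  if (nrow(nt) == 1 && nt$end >= nt$start) {
    br <- branch(nt$start)
    add_sites(nt$start, "TYR", list(bb("OH", br$cb + 2.8 * br$b)))
  }

  # assemble table in residue order
  ord <- order(vapply(res, function(r) r$resno, 0))
  rows <- list()
  for (r in res[ord]) {
    for (a in r$atoms) {
      rows[[length(rows) + 1]] <- data.frame(
        name = a$name, resname = r$resname, resno = r$resno, chain = "A",
        x = a$xyz[1], y = a$xyz[2], z = a$xyz[3], charge = a$charge,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  st <- pdb_structure(atoms, segments = segs, bw_refs = bw)
  st$template <- template
  st
}

#' Specification of a plantable interface decoration
#'
#' @param helix_pair two helix identifiers from TM1..TM7; hydrogen-bond donor
#'   / positive sites go on the first, acceptor / negative sites on the
#'   second, so a symmetric dimer pairing the first helix of one protomer
#'   with the second of the other is electrostatically complementary.
#' @param face_azimuth optional outward direction override (degrees in the
#'   membrane plane); default: the shared outward bisector of the pair.
#' @param donor_count,acceptor_count number of decoration sites per helix
#' @param charge_magnitude absolute charge per site; the default 1.0 makes
#'   each complementary site pair a salt-bridge-like ionized contact, so the
#'   planted double-contact interface dominates any undecorated packing
#' @return object of class `PatchSpec`
#' @export
patch_spec <- function(helix_pair = c("TM4", "TM5"), face_azimuth = NULL,
                       donor_count = 8L, acceptor_count = 8L,
                       charge_magnitude = 1.0) {
  if (length(helix_pair) != 2L || !all(helix_pair %in% helix_names()))
    stop("helix_pair must be two of ", paste(helix_names(), collapse = ", "))
  if (donor_count < 0 || acceptor_count < 0) stop("counts must be >= 0")
  x <- list(helix_pair = helix_pair, face_azimuth = face_azimuth,
            donor_count = as.integer(donor_count),
            acceptor_count = as.integer(acceptor_count),
            charge_magnitude = charge_magnitude)
  class(x) <- "PatchSpec"
  x
}

#' Plant complementary interaction sites on the outward faces of two helices
#'
#' Adds pseudo-atom hydrogen-bond donors (`PD1`, `PD2`, ..., nitrogen,
#' charge +q) on the outward face of the first helix of `patch$helix_pair`
#' and acceptors (`PA1`, ..., oxygen, charge -q) on the second. Sites sit
#' 1.8 Angstrom beyond the CB of the most outward-facing residues. All other
#' atoms are unchanged; with both counts zero the structure is returned
#' atom-identical.
#'
#' @param structure a monomer `Structure` from [build_ideal_tm_bundle()]
#' @param patch a [patch_spec()]
#' @return decorated `Structure`
#' @export
plant_interface_patch <- function(structure, patch = patch_spec()) {
  if (!all(patch$helix_pair %in% helix_names()))
    stop("unknown helix id: ", paste(setdiff(patch$helix_pair, helix_names()),
                                     collapse = ", "))
  if (patch$donor_count == 0L && patch$acceptor_count == 0L) return(structure)
  at <- structure$atoms
  if (!all(patch$helix_pair %in% at$segment))
    stop("unknown helix id (not present in structure): ",
         paste(setdiff(patch$helix_pair, unique(at$segment)), collapse = ", "))

  # shared outward direction: the bisector of the two helices' outward
  # azimuths (or the user-specified azimuth), so that both decorated faces
  # point at the same interface region and the symmetric double-contact
  # arrangement of the planted class is the energetic optimum
  if (is.null(patch$face_azimuth)) {
    ctrs <- lapply(patch$helix_pair, function(h) {
      idx <- which(at$segment == h & at$name == "CB")
      colMeans(cbind(at$x[idx], at$y[idx]))
    })
    outv <- unitv(c(unitv(c(ctrs[[1]], 0)) + unitv(c(ctrs[[2]], 0))))
  } else {
    azr <- patch$face_azimuth * pi / 180
    outv <- c(cos(azr), sin(azr), 0)
  }

  place <- function(helix, count, start_sign) {
    if (count == 0L) return(NULL)
    idx <- which(at$segment == helix & at$name == "CB")
    ca_idx <- which(at$segment == helix & at$name == "CA")
    resnos <- at$resno[idx]
    cb <- cbind(at$x[idx], at$y[idx], at$z[idx])
    ca <- cbind(at$x[ca_idx], at$y[ca_idx], at$z[ca_idx])[match(resnos, at$resno[ca_idx]), , drop = FALSE]
    bdir <- cb - ca
    horiz <- cbind(bdir[, 1], bdir[, 2], 0)
    hn <- sqrt(rowSums(horiz^2))
    cosdev <- (horiz[, 1] * outv[1] + horiz[, 2] * outv[2]) / pmax(hn, 1e-9)
    pick <- order(-cosdev)[seq_len(min(count, length(idx)))]
    pick <- pick[order(cb[pick, 3])]
    # idealized site lattice: all sites of a face lie on the contact plane
    # (normal to the face direction, 1.8 A beyond the most protruding CB)
    # on one vertical line at the helix's transverse position, equally
    # spaced in z and centred at the membrane midplane. The two faces'
    # lattices then coincide site-for-site under the two-fold symmetry of
    # the in-register dimer. Arms connecting each site to its residue's CB
    # are schematic (varying length, like mixed-length ionized side chains).
    depth <- max(cb[pick, 1] * outv[1] + cb[pick, 2] * outv[2]) + 1.8
    perp <- c(-outv[2], outv[1], 0)
    tface <- mean(cb[pick, 1] * perp[1] + cb[pick, 2] * perp[2])
    nk <- length(pick)
    zk <- (seq_len(nk) - (nk + 1) / 2) * 3.0
    lapply(seq_len(nk), function(k) {
      i <- pick[k]
      site <- depth * outv + tface * perp + c(0, 0, zk[k])
      data.frame(name = sprintf("%s%d", if (start_sign > 0) "PD" else "PA", k),
                 resname = at$resname[idx[i]], resno = resnos[i], chain = "A",
                 x = site[1], y = site[2], z = site[3],
                 charge = start_sign * patch$charge_magnitude,
                 elem = if (start_sign > 0) "N" else "O",
                 segment = helix, stringsAsFactors = FALSE)
    })
  }
  extra <- c(place(patch$helix_pair[1], patch$donor_count, +1),
             place(patch$helix_pair[2], patch$acceptor_count, -1))
  extra <- do.call(rbind, extra)
  at$elem <- at$elem  # keep column order stable
  merged <- rbind(at[, names(at) != "serial"], extra[, names(at)[names(at) != "serial"]])
  merged <- merged[order(match(merged$resno, sort(unique(merged$resno)))), ]
  merged$serial <- seq_len(nrow(merged))
  st <- pdb_structure(merged, segments = structure$segments,
                      bw_refs = structure$bw_refs)
  st$template <- structure$template
  st
}

#' Specification of a synthetic trajectory
#'
#' @param n_frames number of frames (>= 1)
#' @param jitter_sd per-atom isotropic Gaussian jitter (Angstrom)
#' @param events list of planted perturbations, each
#'   `list(frame =, selector =, d = c(dx, dy, dz))`; the displacement applies
#'   to the selected atom group from its frame onward (cumulatively with any
#'   other events)
#' @param seed RNG seed for reproducible jitter
#' @return object of class `TrajectorySpec`
#' @export
trajectory_spec <- function(n_frames, jitter_sd = 0, events = list(),
                            seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  for (ev in events) {
    if (ev$frame < 1 || ev$frame > n_frames)
      stop("event frame ", ev$frame, " outside 1..", n_frames)
  }
  x <- list(n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
            events = events, seed = as.integer(seed))
  class(x) <- "TrajectorySpec"
  x
}

#' Simulate a synthetic trajectory around a reference structure
#'
#' Each frame is the reference plus i.i.d. per-atom Gaussian jitter plus the
#' planted event displacements, applied from each event's frame onward. With
#' a fixed seed the output is bit-identical across runs. This is a schematic
#' stand-in for a molecular-dynamics production trajectory: it reproduces
#' known-truth displacements and noise, not physical dynamics.
#'
#' @param structure reference `Structure` (becomes the topology)
#' @param spec a [trajectory_spec()]
#' @return a `Trajectory`
#' @export
simulate_trajectory <- function(structure, spec) {
  base <- coords(structure)
  n <- nrow(base)
  ev_idx <- lapply(spec$events, function(ev) {
    idx <- select_atoms(structure, ev$selector)
    if (length(idx) == 0L) stop("event selector '", ev$selector,
                                "' matches no atoms")
    idx
  })
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  co <- array(0, dim = c(spec$n_frames, n, 3))
  for (f in seq_len(spec$n_frames)) {
    fr <- base
    for (k in seq_along(spec$events)) {
      ev <- spec$events[[k]]
      if (f >= ev$frame)
        fr[ev_idx[[k]], ] <- sweep(fr[ev_idx[[k]], , drop = FALSE], 2, ev$d, "+")
    }
    if (spec$jitter_sd > 0)
      fr <- fr + matrix(rnorm(3 * n, sd = spec$jitter_sd), n, 3)
    co[f, , ] <- fr
  }
  trajectory(structure, co)
}
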