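#' Binding-site specification
#'
#' Defines a site by residues on one chain; residues may be generic numbers
#' ("3.32") or residue numbers. The default orthosteric site is the CA
#' centroid of positions 3.32, 6.48 and 6.55 (the aminergic pocket anchors).
#'
#' @param name site name
#' @param residues character/numeric vector of generic numbers or residue
#'   numbers
#' @param chain chain id
#' @param atoms "CA" (default) or "all"
#' @return object of class `SiteSpec`
#' @export
site_spec <- function(name = "orthosteric",
                      residues = c("3.32", "6.48", "6.55"), chain = "A",
                      atoms = c("CA", "all")) {
  if (length(residues) < 1) stop("need at least one residue")
  x <- list(name = name, residues = as.character(residues), chain = chain,
            atoms = match.arg(atoms))
  class(x) <- "SiteSpec"
  x
}

site_atom_indices <- function(structure, site) {
  idx <- integer(0)
  for (r in site$residues) {
    sel <- if (site$atoms == "CA") paste0(site$chain, ":", r, ":CA")
           else paste0(site$chain, ":", r)
    hit <- tryCatch(select_atoms(structure, sel), error = function(e) integer(0))
    idx <- c(idx, hit)
  }
  sort(unique(idx))
}

#' Centroid of a binding site
#'
#' Unweighted centroid of the site's CA atoms (or all atoms, per the
#' `SiteSpec`).
#'
#' @param structure a `Structure`
#' @param site a [site_spec()]
#' @return numeric length-3 point (Angstrom)
#' @export
site_centroid <- function(structure, site) {
  idx <- site_atom_indices(structure, site)
  if (length(idx) == 0L)
    stop("site '", site$name, "' resolves no atoms on chain ", site$chain)
  colMeans(coords(structure, idx))
}

#' Distance between two binding sites of a dimer
#'
#' `direct` is the Euclidean centroid distance ("through the membrane
#' region"). `extracellular_path` is the length of the two-segment path via
#' a waypoint on the dimer z-axis at z = max(structure z) + 5 Angstrom — a
#' stated surrogate for a route around the extracellular surface; it is
#' always at least the direct distance.
#'
#' @param dimer a two-chain `Structure` (or any `Structure`)
#' @param site1,site2 [site_spec()] objects
#' @param mode "direct" or "extracellular_path"
#' @return distance (Angstrom)
#' @export
site_distance <- function(dimer, site1, site2,
                          mode = c("direct", "extracellular_path")) {
  mode <- match.arg(mode)
  c1 <- site_centroid(dimer, site1)
  c2 <- site_centroid(dimer, site2)
  direct <- sqrt(sum((c1 - c2)^2))
  if (mode == "direct" || direct < 1e-9) return(direct)
  w <- c(0, 0, max(dimer$atoms$z) + 5)
  sqrt(sum((c1 - w)^2)) + sqrt(sum((w - c2)^2))
}

#' Kabsch optimal rigid superposition
#'
#' Least-squares rotation (proper, via SVD with determinant correction) and
#' translation mapping `P` onto `Q`.
#'
#' @param P,Q n x 3 coordinate matrices in consistent atom order (n >= 3)
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd`;
#'   the superposed copy of `P` is `P %*% t(R) + t` (rows).
#' @export
kabsch <- function(P, Q) {
  if (nrow(P) != nrow(Q)) stop("mismatched atom counts")
  if (nrow(P) < 3) stop("need at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(R = R, t = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' RMSD after optimal superposition
#'
#' @param struct1,struct2 `Structure` objects (or n x 3 matrices) with equal
#'   selected atom counts in consistent order
#' @param selection optional selector string applied to both structures
#' @return list with `rmsd` (Angstrom), rotation `R` and translation `t`
#' @export
superpose_rmsd <- function(struct1, struct2, selection = NULL) {
  get_xyz <- function(s) {
    if (inherits(s, "Structure")) {
      idx <- if (is.null(selection)) NULL else select_atoms(s, selection)
      coords(s, idx)
    } else as.matrix(s)
  }
  P <- get_xyz(struct1); Q <- get_xyz(struct2)
  k <- kabsch(P, Q)
  list(rmsd = k$rmsd, R = k$R, t = k$t)
}
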