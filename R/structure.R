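#' Annotated atomic structure
#'
#' The central data container: an ordered atom table plus segment annotations
#' (N-term, TM1..TM7, ICL1..ICL3, ECL1..ECL3, H8, C-term) and per-helix
#' Ballesteros-Weinstein reference residues. The membrane normal is the +z
#' axis by convention; z > 0 is the extracellular side.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resno`,
#'   `chain`, `x`, `y`, `z`, and optionally `elem` (derived from the atom name
#'   when absent), `charge` (partial charge, defaults to 0) and `segment`.
#' @param segments optional data.frame with columns `label`, `start`, `end`
#'   giving residue-number ranges per segment; ranges apply to every chain
#'   (chains are protomer copies sharing one numbering).
#' @param bw_refs optional named integer vector, e.g. `c(TM1 = 25, ...)`,
#'   giving the residue number assigned generic position x.50 in each helix.
#' @return An object of class `Structure`.
#' @export
pdb_structure <- function(atoms, segments = NULL, bw_refs = NULL) {
  req <- c("name", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure has zero atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$elem)) atoms$elem <- guess_element(atoms$name)
  if (is.null(atoms$charge)) atoms$charge <- 0
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name): ", key[anyDuplicated(key)][1])
  atoms$segment <- segment_labels(atoms$resno, segments)
  x <- list(atoms = atoms, segments = segments, bw_refs = bw_refs)
  class(x) <- "Structure"
  x
}

segment_labels <- function(resno, segments) {
  lab <- rep(NA_character_, length(resno))
  if (is.null(segments)) return(lab)
  for (k in seq_len(nrow(segments))) {
    hit <- resno >= segments$start[k] & resno <= segments$end[k]
    lab[hit] <- segments$label[k]
  }
  lab
}

guess_element <- function(name) {
  e <- substr(gsub("^[0-9]", "", name), 1, 1)
  toupper(e)
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  if (!is.null(x$segments))
    cat("  segments:", paste(x$segments$label, collapse = " "), "\n")
  if (!is.null(x$bw_refs))
    cat("  x.50 refs:", paste(names(x$bw_refs), x$bw_refs, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param x a `Structure`
#' @param idx optional integer atom indices
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x, idx = NULL) {
  m <- cbind(x$atoms$x, x$atoms$y, x$atoms$z)
  colnames(m) <- c("x", "y", "z")
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#' @param x a `Structure`
#' @param m numeric n x 3 matrix
#' @return the modified `Structure`
#' @export
set_coords <- function(x, m) {
  stopifnot(nrow(m) == nrow(x$atoms))
  x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
  x
}

helix_names <- function() paste0("TM", 1:7)

#' Ballesteros-Weinstein generic numbering map
#'
#' Builds the residue-number to generic-number map. Residue r in helix H with
#' reference residue ref (the x.50 position) gets generic position
#' 50 + r - ref, so numbering is consecutive with residue numbers within each
#' helix. Residues outside helix segments carry no generic number.
#'
#' @param structure a `Structure` with TM segment annotations
#' @param refs named integer vector of x.50 residue numbers per helix
#'   (default: the structure's own `bw_refs`)
#' @return data.frame with columns `resno`, `helix`, `pos`, `gn` (e.g. "3.32").
#' @export
assign_generic_numbers <- function(structure, refs = structure$bw_refs) {
  if (is.null(refs)) stop("no x.50 reference residues supplied")
  segs <- structure$segments
  if (is.null(segs)) stop("structure has no segment annotations")
  out <- list()
  for (h in intersect(helix_names(), names(refs))) {
    row <- segs[segs$label == h, , drop = FALSE]
    if (nrow(row) == 0L) next
    if (refs[[h]] < row$start || refs[[h]] > row$end)
      stop("reference residue ", refs[[h]], " lies outside ", h,
           " range [", row$start, ", ", row$end, "]")
    rs <- row$start:row$end
    hn <- as.integer(sub("TM", "", h))
    pos <- 50L + rs - refs[[h]]
    out[[h]] <- data.frame(resno = rs, helix = hn, pos = pos,
                           gn = sprintf("%d.%d", hn, pos),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Resolve a generic number to a residue number
#' @param structure a `Structure`
#' @param gn generic number string such as "3.50"
#' @return integer residue number
#' @export
resolve_generic <- function(structure, gn) {
  map <- assign_generic_numbers(structure)
  hit <- map$resno[map$gn == gn]
  if (length(hit) != 1L) stop("no residue with generic number ", gn)
  hit
}

#' Select atoms of a structure
#'
#' Selector grammar: `CHAINS[:RESIDUES[:ATOMS]]`, colon-separated.
#' `CHAINS` is a comma list of chain ids or `*`. `RESIDUES` is a generic
#' number (`3.50`), a residue number (`141`), a range (`10-20`), a segment
#' label (`TM4`, `N-term`, ...), or `*`. `ATOMS` is a comma list of atom
#' names. A two-part selector whose second token is not a residue spec is
#' read as chain plus atom names (e.g. `"A:CA"`, `"A,B:CA"`).
#'
#' @param structure a `Structure`
#' @param selector selector string
#' @return integer vector of atom indices in table order (possibly empty).
#' @export
select_atoms <- function(structure, selector) {
  if (!is.character(selector) || length(selector) != 1L || !nzchar(selector))
    stop("malformed selector: must be a single non-empty string")
  at <- structure$atoms
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 3L)
    stop("malformed selector: ", selector)
  keep <- rep(TRUE, nrow(at))
  chains <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  if (!identical(chains, "*")) {
    if (any(!nzchar(chains))) stop("malformed selector: ", selector)
    keep <- keep & at$chain %in% chains
  }
  seg_set <- c("N-term", helix_names(), paste0("ICL", 1:3), paste0("ECL", 1:3),
               "H8", "C-term")
  atom_tok <- NULL
  if (length(parts) >= 2L) {
    tok <- parts[2]
    if (tok == "*") {
      # all residues
    } else if (grepl("^[0-9]+\\.[0-9]+$", tok)) {
      map <- assign_generic_numbers(structure)
      rn <- map$resno[map$gn == tok]
      if (length(rn) != 1L) stop("no residue with generic number ", tok)
      keep <- keep & at$resno == rn
    } else if (grepl("^[0-9]+$", tok)) {
      keep <- keep & at$resno == as.integer(tok)
    } else if (grepl("^[0-9]+-[0-9]+$", tok)) {
      rr <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      keep <- keep & at$resno >= rr[1] & at$resno <= rr[2]
    } else if (tok %in% seg_set) {
      keep <- keep & !is.na(at$segment) & at$segment == tok
    } else if (length(parts) == 2L && grepl("^[A-Za-z][A-Za-z0-9',]*$", tok)) {
      atom_tok <- tok
    } else {
      stop("malformed selector token: ", tok)
    }
  }
  if (length(parts) == 3L) atom_tok <- parts[3]
  if (!is.null(atom_tok)) {
    nm <- strsplit(atom_tok, ",", fixed = TRUE)[[1]]
    if (any(!nzchar(nm))) stop("malformed selector: ", selector)
    keep <- keep & at$name %in% nm
  }
  which(keep)
}
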