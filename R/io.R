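#' Read a PDB file as a Structure or Trajectory
#'
#' Single-model files give a [pdb_structure()]; files with MODEL/ENDMDL
#' records give a [trajectory()] whose topology is the first model. Partial
#' charges are carried in the occupancy column (the synthetic generator's
#' convention, see [write_structure()]). If a sidecar annotation file
#' `<path>.annot.yaml` exists (or `annotations` is given) segment ranges and
#' x.50 references are attached; otherwise residues are unlabeled.
#'
#' @param path PDB file path
#' @param annotations optional annotation list (`segments`, `bw_refs`) or a
#'   YAML file path; overrides the sidecar.
#' @return `Structure` or `Trajectory`
#' @export
read_structure <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ann <- resolve_annotations(path, annotations)

  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM records in ", path)

  parse_block <- function(idx) {
    ln <- lines[idx]
    num <- function(s, what, digits = TRUE) {
      v <- suppressWarnings(as.numeric(s))
      bad <- is.na(v) & nzchar(trimws(s))
      bad <- bad | !nzchar(trimws(s))
      if (any(bad))
        stop("unparseable ", what, " in ATOM record at line ", idx[which(bad)[1]])
      v
    }
    data.frame(
      serial = as.integer(num(substr(ln, 7, 11), "serial")),
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      resno = as.integer(num(substr(ln, 23, 26), "residue number")),
      x = num(substr(ln, 31, 38), "x coordinate"),
      y = num(substr(ln, 39, 46), "y coordinate"),
      z = num(substr(ln, 47, 54), "z coordinate"),
      charge = {
        occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
        ifelse(is.na(occ), 0, occ)
      },
      elem = {
        e <- trimws(substr(ln, 77, 78))
        ifelse(nzchar(e), e, guess_element(trimws(substr(ln, 13, 16))))
      },
      stringsAsFactors = FALSE)
  }

  if (!any(is_model)) {
    return(pdb_structure(parse_block(which(is_atom)),
                         segments = ann$segments, bw_refs = ann$bw_refs))
  }
  # multi-model file -> trajectory
  model_id <- cumsum(is_model)
  blocks <- split(which(is_atom), model_id[is_atom])
  tabs <- lapply(blocks, parse_block)
  n0 <- nrow(tabs[[1]])
  sizes <- vapply(tabs, nrow, 0L)
  if (any(sizes != n0))
    stop("models differ in atom count (", paste(unique(sizes), collapse = ", "), ")")
  topo <- pdb_structure(tabs[[1]], segments = ann$segments, bw_refs = ann$bw_refs)
  co <- array(0, dim = c(length(tabs), n0, 3))
  for (f in seq_along(tabs)) co[f, , ] <- cbind(tabs[[f]]$x, tabs[[f]]$y, tabs[[f]]$z)
  trajectory(topo, co)
}

resolve_annotations <- function(path, annotations) {
  if (is.character(annotations)) return(read_annotations(annotations))
  if (is.list(annotations)) return(annotations)
  sidecar <- paste0(path, ".annot.yaml")
  if (file.exists(sidecar)) return(read_annotations(sidecar))
  list(segments = NULL, bw_refs = NULL)
}

#' Read an annotation config (segment ranges and x.50 references)
#' @param path YAML file with top-level keys `segments` (label: \[start, end\])
#'   and `bw_refs` (TMk: resno)
#' @return list with `segments` data.frame and `bw_refs` named integer vector
#' @export
read_annotations <- function(path) {
  y <- yaml::read_yaml(path)
  segments <- NULL
  if (!is.null(y$segments)) {
    segments <- data.frame(
      label = names(y$segments),
      start = vapply(y$segments, function(v) as.integer(v[[1]]), 0L),
      end = vapply(y$segments, function(v) as.integer(v[[2]]), 0L),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  bw <- NULL
  if (!is.null(y$bw_refs)) bw <- vapply(y$bw_refs, as.integer, 0L)
  list(segments = segments, bw_refs = bw)
}

#' Write an annotation config next to a structure
#' @param structure a `Structure`
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_annotations <- function(structure, path) {
  y <- list()
  if (!is.null(structure$segments)) {
    s <- structure$segments
    y$segments <- setNames(lapply(seq_len(nrow(s)),
                                  function(k) c(s$start[k], s$end[k])), s$label)
  }
  if (!is.null(structure$bw_refs)) y$bw_refs <- as.list(structure$bw_refs)
  yaml::write_yaml(y, path)
  invisible(path)
}

format_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                             charge, elem) {
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, chain, resno, x, y, z, charge, 0,
          elem)
}

#' Write a Structure or Trajectory as PDB
#'
#' Structures become single-model PDB files (ATOM/TER/END); trajectories
#' multi-model files (MODEL/ENDMDL). Partial charges are written into the
#' occupancy column so pseudo-atom decorations survive a round trip. Segment
#' and numbering annotations go to a `<path>.annot.yaml` sidecar.
#'
#' @param x `Structure` or `Trajectory`
#' @param path output file
#' @param sidecar write the annotation sidecar when annotations exist
#'   (default TRUE)
#' @return `path`, invisibly
#' @export
write_structure <- function(x, path, sidecar = TRUE) {
  if (inherits(x, "Trajectory")) {
    at <- x$topology$atoms
    out <- character(0)
    for (f in seq_len(dim(x$coords)[1])) {
      body <- format_atom_line(at$serial, at$name, at$resname, at$chain,
                               at$resno, x$coords[f, , 1], x$coords[f, , 2],
                               x$coords[f, , 3], at$charge, at$elem)
      out <- c(out, sprintf("MODEL %8d", f), body, "ENDMDL")
    }
    writeLines(c(out, "END"), path)
    topo <- x$topology
  } else {
    at <- x$atoms
    body <- format_atom_line(at$serial, at$name, at$resname, at$chain,
                             at$resno, at$x, at$y, at$z, at$charge, at$elem)
    # TER after each chain
    out <- character(0)
    for (ch in unique(at$chain)) out <- c(out, body[at$chain == ch], "TER")
    writeLines(c(out, "END"), path)
    topo <- x
  }
  if (sidecar && (!is.null(topo$segments) || !is.null(topo$bw_refs)))
    write_annotations(topo, paste0(path, ".annot.yaml"))
  invisible(path)
}
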