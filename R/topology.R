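#' @title Atom topology and selections
#' @description Internal containers describing the atoms of a structure and a
#'   small selection language used by every analysis module.
#' @name topology
NULL

# Bondi-style van der Waals radii (Angstrom). Unknown elements fall back to
# 1.70 A (carbon-like) with a warning.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom. Unknown elements get 1.70 A
#'   with a single warning.
#' @export
vdw_radius <- function(element) {
  key <- toupper(element)
  r <- .vdw_table[key]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; using default vdW radius 1.70 A")
    r[unknown] <- 1.70
  }
  unname(r)
}

#' Build a topology
#'
#' A topology is the static atom table shared by every frame of an ensemble.
#' Internal indices are 1-based; author residue numbers from PDB files are
#' preserved in `resseq` but never used for indexing.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `vdw`,
#'   `resindex`, `resname`, `resseq`, `chain`, `icode`, `heavy`.
#' @param residues data.frame with columns `chain`, `resseq`, `icode`,
#'   `resname`, `key` (one row per residue, in atom order).
#' @return object of class `"topology"`.
#' @export
topology <- function(atoms, residues) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  need <- c("serial", "name", "element", "vdw", "resindex", "resname",
            "resseq", "chain", "icode", "heavy")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$vdw <= 0)) stop("all vdW radii must be positive")
  if (any(atoms$element == "")) stop("all elements must be non-empty")
  if (any(atoms$resindex < 1L | atoms$resindex > nrow(residues)))
    stop("atom resindex out of range of residue table")
  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), nrow(x$residues),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Residue key strings
#'
#' @param chain,resseq,icode vectors of chain id, author residue number and
#'   insertion code.
#' @return character keys of the form `"H:100"` (insertion code appended).
#' @export
residue_key <- function(chain, resseq, icode = "") {
  ic <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resseq, ic)
}

#' Build an ensemble
#'
#' An ensemble couples a topology with F frames of Cartesian coordinates.
#'
#' @param topology a [topology()] object.
#' @param coords numeric array of dimension N x 3 x F (Angstrom), or an N x 3
#'   matrix for a single frame.
#' @param frame_ids optional character labels, one per frame.
#' @return object of class `"ensemble"` with elements `topology`, `coords`
#'   (N x 3 x F array) and `frame_ids`.
#' @export
ensemble <- function(topology, coords, frame_ids = NULL) {
  if (!inherits(topology, "topology")) stop("topology must be a topology object")
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) stop("coords must be an N x 3 x F array")
  if (d[1] != nrow(topology$atoms))
    stop("coords has ", d[1], " atoms but topology has ", nrow(topology$atoms))
  if (d[3] < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (is.null(frame_ids)) frame_ids <- as.character(seq_len(d[3]))
  if (length(frame_ids) != d[3]) stop("frame_ids length must equal frame count")
  structure(list(topology = topology, coords = coords,
                 frame_ids = as.character(frame_ids)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Ensemble: %d frames x %d atoms (%d residues)\n",
              d[3], d[1], nrow(x$topology$residues)))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param x an ensemble.
#' @return integer count.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(x) dim(x$coords)[1]

#' Extract one frame as an N x 3 matrix
#' @param x an ensemble.
#' @param i frame index.
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(x, i) {
  m <- x$coords[, , i, drop = FALSE]
  dim(m) <- dim(x$coords)[1:2]
  m
}

#' Resolve an atom selection expression
#'
#' Grammar: `chain <id> [resid <a>-<b>] [name <n1,n2,...]`; clauses are
#' AND-combined. `resid` matches author residue numbers; a single number is
#' shorthand for a one-residue range.
#'
#' @param topology a [topology()] object.
#' @param expression selection string, e.g. `"chain H resid 95-102 name CA"`.
#' @return object of class `"selection"`: list with `expression` and
#'   `indices` (strictly increasing 1-based atom indices).
#' @export
resolve_selection <- function(topology, expression) {
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  tok <- strsplit(trimws(expression), "\\s+")[[1]]
  if (!length(tok)) stop("empty selection expression")
  i <- 1L
  while (i <= length(tok)) {
    kw <- tok[i]
    if (i == length(tok)) stop("selection clause '", kw, "' lacks an argument")
    arg <- tok[i + 1L]
    if (kw == "chain") {
      keep <- keep & at$chain %in% strsplit(arg, ",")[[1]]
    } else if (kw == "resid") {
      parts <- strsplit(arg, "-")[[1]]
      a <- suppressWarnings(as.integer(parts[1]))
      b <- if (length(parts) > 1) suppressWarnings(as.integer(parts[2])) else a
      if (is.na(a) || is.na(b)) stop("bad resid range: '", arg, "'")
      keep <- keep & at$resseq >= a & at$resseq <= b
    } else if (kw == "name") {
      keep <- keep & at$name %in% strsplit(arg, ",")[[1]]
    } else {
      stop("unknown selection keyword: '", kw, "'")
    }
    i <- i + 2L
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection matched no atoms: '", expression, "'")
  structure(list(expression = expression, indices = idx), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("Selection '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

# Accept either a selection object, an expression string, or raw indices.
as_selection <- function(topology, sel) {
  if (inherits(sel, "selection")) return(sel)
  if (is.character(sel) && length(sel) == 1L) return(resolve_selection(topology, sel))
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > nrow(topology$atoms))) stop("selection index out of range")
    return(structure(list(expression = "<indices>", indices = sort(unique(idx))),
                     class = "selection"))
  }
  stop("cannot interpret selection")
}
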