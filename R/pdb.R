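#' Read a multi-model PDB file as an ensemble
#'
#' Each `MODEL` block becomes one frame; a file without `MODEL` records is a
#' single-frame ensemble. All frames must present the same atoms (matched by
#' serial and name) as the first model. Elements are taken from columns 77-78
#' when present, otherwise inferred from the atom name; van der Waals radii
#' come from a fixed Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80 A; default 1.70). Waters (HOH/WAT) are excluded by default.
#' For alternate locations only the highest-occupancy conformer is kept
#' (ties: blank or 'A' first); insertion codes are appended to the residue key.
#'
#' @param path path to a PDB file.
#' @param keep_waters logical; keep HOH/WAT residues (default FALSE).
#' @return an [ensemble()].
#' @export
read_pdb_ensemble <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # frame id per atom line: 1 until first MODEL, then the running MODEL count
  model_no <- cumsum(is_model)
  frame_of_line <- ifelse(model_no == 0L, 1L, model_no)
  atom_lines <- which(is_atom)
  frames <- frame_of_line[atom_lines]

  fields <- .parse_atom_lines(lines[atom_lines], atom_lines)
  if (!keep_waters) {
    w <- fields$resname %in% c("HOH", "WAT")
    fields <- fields[!w, , drop = FALSE]
    frames <- frames[!w]
  }
  if (!nrow(fields)) stop("no atoms left after water removal in ", path)

  f_ids <- sort(unique(frames))
  first <- fields[frames == f_ids[1], , drop = FALSE]
  first <- .dedupe_altloc(first)
  key1 <- paste(first$serial, first$name)
  n <- nrow(first)

  coords <- array(NA_real_, dim = c(n, 3L, length(f_ids)))
  for (fi in seq_along(f_ids)) {
    blk <- fields[frames == f_ids[fi], , drop = FALSE]
    blk <- .dedupe_altloc(blk)
    if (nrow(blk) != n)
      stop(sprintf("model %d: expected %d atoms, found %d", f_ids[fi], n, nrow(blk)))
    ord <- match(key1, paste(blk$serial, blk$name))
    if (anyNA(ord))
      stop(sprintf("model %d: atom list does not match model %d", f_ids[fi], f_ids[1]))
    coords[, , fi] <- cbind(blk$x[ord], blk$y[ord], blk$z[ord])
  }

  top <- .topology_from_fields(first)
  ensemble(top, coords, frame_ids = as.character(f_ids))
}

# Parse fixed-width ATOM/HETATM lines into a data.frame.
.parse_atom_lines <- function(ln, line_no) {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & trimws(s) != "")
    bad <- union(bad, which(trimws(s) == ""))
    if (length(bad))
      stop("unreadable ", what, " at line ", line_no[bad[1]])
    v
  }
  serial <- suppressWarnings(as.integer(trimws(substr(ln, 7, 11))))
  if (anyNA(serial)) stop("unreadable atom serial at line ",
                          line_no[which(is.na(serial))[1]])
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resseq <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
  if (anyNA(resseq)) stop("unreadable residue number at line ",
                          line_no[which(is.na(resseq))[1]])
  icode <- substr(ln, 27, 27)
  x <- num(substr(ln, 31, 38), "x coordinate")
  y <- num(substr(ln, 39, 46), "y coordinate")
  z <- num(substr(ln, 47, 54), "z coordinate")
  occ_s <- trimws(substr(ln, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_s))
  occ[is.na(occ)] <- 1.0
  elem <- toupper(trimws(substr(ln, 77, 78)))
  infer <- elem == ""
  if (any(infer)) elem[infer] <- .element_from_name(name[infer])
  data.frame(serial = serial, name = name, altloc = altloc, resname = resname,
             chain = chain, resseq = resseq, icode = icode,
             x = x, y = y, z = z, occ = occ, element = elem,
             stringsAsFactors = FALSE)
}

# PDB atom-name heuristic: leading digits are hydrogen-position prefixes
# ("1HB"); otherwise the first letter names the element, with two-letter
# halogens/metals left to the element column which real files provide.
.element_from_name <- function(name) {
  n <- sub("^[0-9']+", "", name)
  first <- toupper(substr(n, 1, 1))
  ifelse(first == "", "C", first)
}

# Keep one conformer per (chain,resseq,icode,name): highest occupancy, ties
# broken in favour of blank/'A' altloc, then input order.
.dedupe_altloc <- function(df) {
  if (all(df$altloc %in% c(" ", ""))) return(df)
  key <- paste(df$chain, df$resseq, df$icode, df$name)
  alt_rank <- ifelse(df$altloc %in% c(" ", ""), 0L,
                     ifelse(df$altloc == "A", 1L, 2L))
  ord <- order(key, -df$occ, alt_rank, seq_len(nrow(df)))
  df2 <- df[ord, , drop = FALSE]
  df2 <- df2[!duplicated(paste(df2$chain, df2$resseq, df2$icode, df2$name)), ,
             drop = FALSE]
  df2[order(match(paste(df2$chain, df2$resseq, df2$icode, df2$name),
                  unique(key))), , drop = FALSE]
}

.topology_from_fields <- function(df) {
  rkey <- residue_key(df$chain, df$resseq, df$icode)
  ukey <- unique(rkey)
  residues <- df[match(ukey, rkey), c("chain", "resseq", "icode", "resname")]
  residues$icode <- ifelse(residues$icode == " ", "", residues$icode)
  residues$key <- ukey
  rownames(residues) <- NULL
  atoms <- data.frame(
    serial = df$serial, name = df$name, element = df$element,
    vdw = suppressWarnings(vdw_radius(df$element)),
    resindex = match(rkey, ukey), resname = df$resname,
    resseq = df$resseq, chain = df$chain,
    icode = ifelse(df$icode == " ", "", df$icode),
    heavy = df$element != "H",
    stringsAsFactors = FALSE)
  topology(atoms, residues)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens an [ensemble()].
#' @param path output path.
#' @param bfactor optional numeric vector (one per atom) for the B-factor
#'   column; default 0.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path, bfactor = NULL) {
  at <- ens$topology$atoms
  n <- nrow(at)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  bfactor <- pmin(pmax(bfactor, 0), 999.99)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(ens) > 1L
  for (f in seq_len(n_frames(ens))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ens, f)
    writeLines(.format_atom_lines(at, xyz, bfactor), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.format_atom_lines <- function(at, xyz, bfactor) {
  # atom names shorter than 4 chars start in column 14 (PDB convention)
  nm <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          at$serial, nm, at$resname, at$chain, at$resseq,
          ifelse(at$icode == "", " ", at$icode),
          xyz[, 1], xyz[, 2], xyz[, 3], 1.0, bfactor, at$element)
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Maps residue-level scores (e.g. localized plasticity) onto every atom of
#' the residue so the structure can be colour-coded in a molecular viewer.
#' Scores are clipped to [0, 999.99] (the PDB field range) with a warning;
#' atoms of unscored residues get 0.00.
#'
#' @param ens an [ensemble()]; its first frame is written.
#' @param per_residue named numeric vector, names are residue keys as produced
#'   by [residue_key()] (`"H:100"`).
#' @param path output path.
#' @param frame frame index to write (default 1).
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(ens, per_residue, path, frame = 1L) {
  if (any(!is.finite(per_residue))) stop("per-residue scores must be finite")
  top <- ens$topology
  score <- per_residue[top$residues$key[top$atoms$resindex]]
  score[is.na(score)] <- 0
  if (any(score < 0 | score > 999.99)) {
    warning("B-factor scores outside [0, 999.99] clipped")
    score <- pmin(pmax(score, 0), 999.99)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.format_atom_lines(top$atoms, frame_coords(ens, frame), score), con)
  writeLines("END", con)
  invisible(path)
}
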