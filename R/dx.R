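#' OpenDX grid I/O
#'
#' Reads and writes scalar grids in the OpenDX "gridpositions counts" dialect
#' used by APBS/PyMOL-style tools. Data are stored z-fastest (standard DX
#' ordering). Grid positions in the DX header are voxel centers; the grid's
#' corner origin, kind and frame count are carried in comment lines at full
#' precision so that a write/read round-trip reproduces the metadata exactly.
#'
#' @param grid an [occupancy_grid()].
#' @param path file path.
#' @return `write_dx_grid` returns `path` invisibly; `read_dx_grid` returns an
#'   [occupancy_grid()].
#' @name dx_io
NULL

#' @rdname dx_io
#' @export
write_dx_grid <- function(grid, path) {
  stopifnot(inherits(grid, "occupancy_grid"))
  sp <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    sprintf("# corner_origin %s %s %s", fmt(sp$origin[1]), fmt(sp$origin[2]), fmt(sp$origin[3])),
    sprintf("# kind %s", grid$kind),
    sprintf("# n_frames %d", grid$n_frames),
    sprintf("object 1 class gridpositions counts %d %d %d",
            sp$dims[1], sp$dims[2], sp$dims[3]),
    sprintf("origin %s %s %s",
            fmt(sp$origin[1] + sp$spacing / 2),
            fmt(sp$origin[2] + sp$spacing / 2),
            fmt(sp$origin[3] + sp$spacing / 2)),
    sprintf("delta %s 0 0", fmt(sp$spacing)),
    sprintf("delta 0 %s 0", fmt(sp$spacing)),
    sprintf("delta 0 0 %s", fmt(sp$spacing)),
    sprintf("object 2 class gridconnections counts %d %d %d",
            sp$dims[1], sp$dims[2], sp$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(sp$dims))
  ), con)
  # DX order: z varies fastest. R arrays vary the first index fastest, so
  # permute to (z, y, x) before flattening.
  v <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))
  pad <- (-length(v)) %% 3L
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(sprintf("%.9g", v), nrow = 3L)
  rows <- apply(m, 2L, function(r) paste(r[!grepl("NA", r)], collapse = " "))
  writeLines(rows, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
  invisible(path)
}

#' @rdname dx_io
#' @export
read_dx_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  corner <- NULL; kind <- "mean"; nfr <- 0L
  for (cl in grep("^#", lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^#", "", cl)), "\\s+")[[1]]
    if (length(tok) >= 4 && tok[1] == "corner_origin") corner <- as.numeric(tok[2:4])
    if (length(tok) >= 2 && tok[1] == "kind") kind <- tok[2]
    if (length(tok) >= 2 && tok[1] == "n_frames") nfr <- as.integer(tok[2])
  }
  lines <- lines[!grepl("^#", lines)]
  hdr <- grep("gridpositions", lines, value = TRUE)
  if (!length(hdr)) stop("malformed DX header: no 'gridpositions' object")
  tok <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
  dims <- suppressWarnings(as.integer(tok[(length(tok) - 2):length(tok)]))
  if (anyNA(dims) || any(dims < 1L))
    stop("malformed DX header: bad counts token '",
         paste(tok[(length(tok) - 2):length(tok)], collapse = " "), "'")
  oline <- grep("^origin", trimws(lines), value = TRUE)
  if (!length(oline)) stop("malformed DX header: missing 'origin'")
  otok <- strsplit(trimws(oline[1]), "\\s+")[[1]]
  center0 <- suppressWarnings(as.numeric(otok[2:4]))
  if (anyNA(center0)) stop("malformed DX header: bad origin token '", oline[1], "'")
  dlines <- grep("^delta", trimws(lines), value = TRUE)
  if (length(dlines) < 3) stop("malformed DX header: expected 3 'delta' lines")
  dmat <- t(vapply(dlines[1:3], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]))
    if (anyNA(v)) stop("malformed DX header: bad delta token '", l, "'")
    v
  }, numeric(3)))
  spacing <- dmat[1, 1]
  if (abs(dmat[2, 2] - spacing) > 1e-9 || abs(dmat[3, 3] - spacing) > 1e-9 ||
      any(abs(dmat[row(dmat) != col(dmat)]) > 1e-12))
    stop("only isotropic axis-aligned DX grids are supported")
  i_data <- grep("data follows", lines)
  if (!length(i_data)) stop("malformed DX header: no 'data follows' marker")
  itok <- strsplit(trimws(lines[i_data[1]]), "\\s+")[[1]]
  n_items <- suppressWarnings(as.integer(itok[which(itok == "items") + 1L]))
  body <- lines[(i_data[1] + 1L):length(lines)]
  body <- body[!grepl("^(attribute|object|component)", trimws(body))]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop("DX data mismatch: counts ", paste(dims, collapse = " "),
         " imply ", prod(dims), " values but found ", length(vals))
  if (!is.na(n_items) && n_items != prod(dims))
    stop("DX data mismatch: items ", n_items, " but counts imply ", prod(dims))
  arr <- aperm(array(vals, dim = rev(dims)), c(3L, 2L, 1L))
  if (is.null(corner)) corner <- center0 - spacing / 2
  spec <- grid_spec(origin = corner, spacing = spacing, dims = dims)
  occupancy_grid(spec, arr, kind = kind, n_frames = nfr)
}
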