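#' Pairwise frame-to-frame RMSD matrix (2D-RMSD)
#'
#' Computes the F x F matrix of pairwise RMSD values over a selection,
#' conventionally the C-alpha atoms of the analysed loop. With `fit = TRUE`
#' (the default) each pair is refitted by Kabsch superposition on the
#' selection before measuring; with `fit = FALSE` the ensemble is assumed
#' pre-aligned and raw coordinate RMSD is used.
#'
#' @param ens an [ensemble()].
#' @param selection selection object or expression.
#' @param fit logical; pairwise refit (default TRUE).
#' @return object of class `"rmsd_matrix"`: list with `values` (symmetric
#'   F x F, zero diagonal), `selection`, `fit`.
#' @export
rmsd_matrix <- function(ens, selection, fit = TRUE) {
  sel <- as_selection(ens$topology, selection)
  f <- n_frames(ens)
  xyz <- ens$coords[sel$indices, , , drop = FALSE]
  n <- length(sel$indices)
  # pre-center every frame once; pairwise fitted rmsd then needs only the
  # 3x3 cross-covariance SVD per pair
  centered <- vector("list", f)
  g <- numeric(f)          # squared norms, for the singular-value rmsd formula
  for (i in seq_len(f)) {
    m <- xyz[, , i]
    m <- sweep(m, 2, colMeans(m))
    centered[[i]] <- m
    g[i] <- sum(m^2)
  }
  v <- matrix(0, f, f)
  for (i in seq_len(f - 1L)) {
    mi <- centered[[i]]
    for (j in (i + 1L):f) {
      if (fit) {
        H <- crossprod(mi, centered[[j]])
        sv <- svd(H)
        d3 <- sign(det(sv$u) * det(sv$v))
        s3 <- if (d3 < 0) -sv$d[3] else sv$d[3]
        msd <- (g[i] + g[j] - 2 * (sv$d[1] + sv$d[2] + s3)) / n
        if (msd < 1e-8) {
          # the singular-value form cancels catastrophically near zero;
          # recompute explicitly with the optimal rotation
          R <- sv$v %*% diag(c(1, 1, if (d3 == 0) 1 else d3)) %*% t(sv$u)
          msd <- sum((mi %*% t(R) - centered[[j]])^2) / n
        }
        v[i, j] <- sqrt(max(msd, 0))
      } else {
        v[i, j] <- coord_rmsd(xyz[, , i], xyz[, , j])
      }
      v[j, i] <- v[i, j]
    }
  }
  structure(list(values = v, selection = sel, fit = fit), class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("2D-RMSD matrix: %d frames, %d atoms (%s), max %.3f A\n",
              nrow(x$values), length(x$selection$indices),
              if (x$fit) "pairwise-fitted" else "pre-aligned", max(x$values)))
  invisible(x)
}

#' Per-atom RMSF and crystallographic B-factors
#'
#' Root-mean-square fluctuation of each selected atom about its mean position
#' over a pre-aligned ensemble, with the isotropic Debye-Waller conversion
#' B = (8 pi^2 / 3) RMSF^2.
#'
#' @param ens a pre-aligned [ensemble()].
#' @param selection selection object or expression.
#' @return object of class `"flexibility_profile"`: data.frame with columns
#'   `serial`, `name`, `residue`, `rmsf` (A), `bfactor` (A^2).
#' @export
rmsf <- function(ens, selection) {
  sel <- as_selection(ens$topology, selection)
  f <- n_frames(ens)
  if (f == 1L) warning("single-frame ensemble: RMSF is identically zero")
  xyz <- ens$coords[sel$indices, , , drop = FALSE]
  mean_xyz <- apply(xyz, c(1, 2), mean)
  dev2 <- sweep(xyz, c(1, 2), mean_xyz)^2
  # per-atom mean over frames of the squared displacement from the mean
  na <- length(sel$indices)
  msf <- numeric(na)
  for (k in seq_len(f)) msf <- msf + rowSums(matrix(dev2[, , k], ncol = 3L))
  msf <- msf / f
  at <- ens$topology$atoms[sel$indices, ]
  out <- data.frame(serial = at$serial, name = at$name,
                    residue = ens$topology$residues$key[at$resindex],
                    rmsf = sqrt(msf),
                    bfactor = (8 * pi^2 / 3) * msf,
                    stringsAsFactors = FALSE)
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' Backbone psi torsion features
#'
#' Computes the psi dihedral (N-CA-C-N' of the next residue, IUPAC sign
#' convention via the atan2 form) for every residue of the selection that has
#' a complete quadruple within one chain, for every frame, and expands it to
#' the (sin psi, cos psi) feature pairs used as collective-variable inputs.
#' Chain-terminal residues lacking the following N are dropped with a message.
#'
#' @param ens an [ensemble()].
#' @param residue_selection selection expression choosing the residues (any
#'   atom match includes its residue), e.g. `"chain H"`.
#' @return object of class `"torsion_features"`: list with `psi` (F x R
#'   radians in (-pi, pi]), `features` (F x 2R, columns interleaved
#'   sin/cos per residue), `residues` (keys), `colnames`.
#' @export
psi_features <- function(ens, residue_selection) {
  top <- ens$topology
  sel <- as_selection(top, residue_selection)
  res_idx <- sort(unique(top$atoms$resindex[sel$indices]))
  at <- top$atoms
  find_atom <- function(ri, nm) {
    w <- which(at$resindex == ri & at$name == nm)
    if (length(w)) w[1] else NA_integer_
  }
  quads <- list(); keys <- character(0)
  for (ri in res_idx) {
    iN <- find_atom(ri, "N"); iCA <- find_atom(ri, "CA"); iC <- find_atom(ri, "C")
    # next residue in the same chain, by residue-table order
    nxt <- ri + 1L
    ok_next <- nxt <= nrow(top$residues) &&
      top$residues$chain[nxt] == top$residues$chain[ri]
    iN2 <- if (ok_next) find_atom(nxt, "N") else NA_integer_
    if (anyNA(c(iN, iCA, iC, iN2))) next
    quads[[length(quads) + 1L]] <- c(iN, iCA, iC, iN2)
    keys <- c(keys, top$residues$key[ri])
  }
  dropped <- length(res_idx) - length(quads)
  if (dropped > 0)
    message(dropped, " residue(s) without a complete psi quadruple dropped")
  if (!length(quads)) stop("no residue in the selection has a complete psi quadruple")
  f <- n_frames(ens); r <- length(quads)
  psi <- matrix(NA_real_, f, r)
  for (fr in seq_len(f)) {
    xyz <- frame_coords(ens, fr)
    for (k in seq_len(r)) {
      q <- quads[[k]]
      psi[fr, k] <- dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    }
  }
  feats <- matrix(NA_real_, f, 2L * r)
  feats[, seq(1L, 2L * r, by = 2L)] <- sin(psi)
  feats[, seq(2L, 2L * r, by = 2L)] <- cos(psi)
  cn <- as.vector(rbind(paste0("sin_psi_", keys), paste0("cos_psi_", keys)))
  colnames(feats) <- cn
  colnames(psi) <- keys
  structure(list(psi = psi, features = feats, residues = keys, colnames = cn),
            class = "torsion_features")
}

#' @export
print.torsion_features <- function(x, ...) {
  cat(sprintf("Torsion features: %d frames x %d residues (psi sin/cos)\n",
              nrow(x$psi), ncol(x$psi)))
  invisible(x)
}

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in radians in (-pi, pi], IUPAC sign convention.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(cr * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

#' Linear collective variable over torsion features
#'
#' Per-frame dot product of the (sin, cos) psi features with a coefficient
#' vector — the scalar descriptor a metadynamics run would bias (no biasing
#' is performed here). Coefficients default to all ones (plain sum).
#'
#' @param features a [psi_features()] result.
#' @param coefficients numeric vector of length 2R (default all 1).
#' @return numeric vector, one CV value per frame.
#' @export
metadynamics_cv <- function(features, coefficients = NULL) {
  stopifnot(inherits(features, "torsion_features"))
  d <- ncol(features$features)
  if (is.null(coefficients)) coefficients <- rep(1, d)
  if (length(coefficients) != d)
    stop("coefficients length ", length(coefficients), " but features have ", d,
         " columns")
  as.vector(features$features %*% coefficients)
}
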