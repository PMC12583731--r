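#' Construct a periodic ensemble frame
#'
#' A frame holds the atoms of one snapshot, grouped into whole (unwrapped)
#' molecules, plus an optional periodic cell. Coordinates are Angstrom.
#'
#' @param atoms data.frame with columns `molecule` (integer index),
#'   `atom_label`, `element`, `x`, `y`, `z`.
#' @param cell optional 3x3 matrix of lattice vectors (rows), Angstrom.
#' @param run_id,frame_index provenance used to address environments.
#' @return an `ens_frame` object.
#' @export
new_frame <- function(atoms, cell = NULL, run_id = "run", frame_index = 0L) {
  stopifnot(is.data.frame(atoms),
            all(c("molecule", "atom_label", "element", "x", "y", "z")
                %in% names(atoms)))
  key <- paste(atoms$molecule, atoms$atom_label)
  if (anyDuplicated(key)) {
    stop("atom labels must be unique within a molecule")
  }
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3, 3)) || abs(det(cell)) < 1e-10) {
      stop("cell must be a non-singular 3x3 matrix")
    }
  }
  structure(list(atoms = atoms, cell = cell, run_id = run_id,
                 frame_index = as.integer(frame_index)),
            class = "ens_frame")
}

#' @export
print.ens_frame <- function(x, ...) {
  cat("frame", x$frame_index, "of", x$run_id, "-",
      length(unique(x$atoms$molecule)), "molecules,",
      nrow(x$atoms), "atoms,",
      if (is.null(x$cell)) "non-periodic" else "periodic", "\n")
  invisible(x)
}

#' Enumerate the environments of an ensemble
#'
#' One environment per molecule per frame, addressed as
#' `run_frame_molecule`.
#'
#' @param frames list of [new_frame()] objects.
#' @return data.frame with columns `env_id`, `run_id`, `frame`, `molecule`.
#' @export
environments <- function(frames) {
  do.call(rbind, lapply(frames, function(fr) {
    mols <- sort(unique(fr$atoms$molecule))
    data.frame(env_id = paste(fr$run_id, fr$frame_index, mols, sep = "_"),
               run_id = fr$run_id, frame = fr$frame_index, molecule = mols,
               stringsAsFactors = FALSE)
  }))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Shortest cell height: V / max cross-section area, per axis.
min_cell_height <- function(cell) {
  v <- abs(det(cell))
  areas <- c(sqrt(sum(cross3(cell[2, ], cell[3, ])^2)),
             sqrt(sum(cross3(cell[1, ], cell[3, ])^2)),
             sqrt(sum(cross3(cell[1, ], cell[2, ])^2)))
  min(v / areas)
}

# Minimum-image displacement for a matrix of row displacement vectors.
# Fractional wrap followed by a 27-neighbour-image refinement, so the
# result is the true minimum for general triclinic cells (exact below
# half the shortest cell height, and for all the neighbour shells the
# wrap can miss in skewed cells).
min_image_disp <- function(d, cell) {
  d <- matrix(d, ncol = 3)
  if (is.null(cell)) return(d)
  inv <- tryCatch(solve(cell), error = function(e)
    stop("singular cell"))
  f <- d %*% inv
  f <- f - round(f)
  # orthorhombic cells: the fractional wrap is already the minimum image
  if (all(abs(cell[lower.tri(cell) | upper.tri(cell)]) < 1e-12)) {
    return(f %*% cell)
  }
  base <- f %*% cell
  best <- base
  bestn <- rowSums(best^2)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    shift <- as.vector(c(i, j, k) %*% cell)
    cand <- sweep(base, 2, shift, "+")
    n <- rowSums(cand^2)
    upd <- n < bestn
    if (any(upd)) {
      best[upd, ] <- cand[upd, , drop = FALSE]
      bestn[upd] <- n[upd]
    }
  }
  best
}

#' Minimum-image distance between two points
#'
#' Shortest distance between `a` and any periodic image of `b` under a
#' (possibly triclinic) cell; plain Euclidean distance when `cell` is NULL.
#'
#' @param a,b numeric xyz coordinates, Angstrom.
#' @param cell optional 3x3 lattice-vector matrix (rows).
#' @return distance in Angstrom.
#' @export
#' @examples
#' min_image_distance(c(0.5, 0, 0), c(9.5, 0, 0), diag(10))  # 1.0
min_image_distance <- function(a, b, cell = NULL) {
  d <- min_image_disp(rbind(b - a), cell)
  sqrt(sum(d^2))
}

# Vectorized dihedral over matrices of points (one row per case).
dihedral_vec <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m <- cr(n1, b2n)
  ang <- atan2(rowSums(m * n2), rowSums(n1 * n2)) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking along the 2->3 bond, a clockwise rotation
#' of the 3-4 bond relative to the 1-2 bond is positive; cis (syn-
#' periplanar) is 0 and trans is 180. Range (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz coordinates, Angstrom.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b <- rbind(p2 - p1, p3 - p2, p4 - p3)
  if (any(rowSums(b^2) < 1e-12)) stop("degenerate geometry: coincident points")
  c12 <- cross3(b[1, ], b[2, ]); c23 <- cross3(b[2, ], b[3, ])
  if (sum(c12^2) < 1e-12 || sum(c23^2) < 1e-12) {
    stop("degenerate geometry: collinear points")
  }
  dihedral_vec(rbind(p1), rbind(p2), rbind(p3), rbind(p4))
}

#' Geometric hydrogen-bond criterion
#'
#' A donor-H forms a hydrogen bond to acceptor A when the H...A distance is
#' at most `max_ha_distance` and the D-H...A angle is at least
#' `min_dha_angle`. Published occurrence censuses rarely print a
#' criterion; these defaults are the standard geometric definition.
#'
#' @param max_ha_distance Angstrom, default 2.5.
#' @param min_dha_angle degrees, default 120.
#' @param acceptor_elements element symbols accepted as acceptors.
#' @return an `hbond_criterion` list.
#' @export
hbond_criterion <- function(max_ha_distance = 2.5, min_dha_angle = 120,
                            acceptor_elements = c("N", "O")) {
  stopifnot(max_ha_distance > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_ha_distance = max_ha_distance,
                 min_dha_angle = min_dha_angle,
                 acceptor_elements = acceptor_elements),
            class = "hbond_criterion")
}

# Vectorized H-bond classification for every molecule of one frame.
# Returns a data.frame (molecule, class, acceptor, scope, distance, angle);
# class is "none" when no acceptor passes. Intermolecular H...A vectors use
# the minimum image; the acceptor with the shortest H...A wins.
hbond_classes_frame <- function(frame, donor_h, donor_heavy,
                                criterion = hbond_criterion(),
                                class_map = NULL, scope = "both") {
  A <- frame$atoms
  mols <- sort(unique(A$molecule))
  hi <- match(paste(mols, donor_h), paste(A$molecule, A$atom_label))
  di <- match(paste(mols, donor_heavy), paste(A$molecule, A$atom_label))
  # only molecules that carry the donor are classified
  has_donor <- !is.na(hi) & !is.na(di)
  if (!any(has_donor)) {
    stop("missing donor atom label(s) ", donor_h, "/", donor_heavy)
  }
  mols <- mols[has_donor]
  H <- as.matrix(A[hi[has_donor], c("x", "y", "z")])
  D <- as.matrix(A[di[has_donor], c("x", "y", "z")])
  if (any(sqrt(rowSums((H - D)^2)) > 1.3)) {
    stop("donor H and heavy atom are not covalently associated (> 1.3 A)")
  }
  acc <- which(A$element %in% criterion$acceptor_elements)
  out <- data.frame(molecule = mols, class = "none",
                    acceptor = NA_character_, scope = NA_character_,
                    distance = NA_real_, angle = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(acc)) return(out)
  accA <- A[acc, , drop = FALSE]
  for (m in seq_along(mols)) {
    keep <- !(accA$molecule == mols[m] & accA$atom_label == donor_heavy)
    same <- accA$molecule == mols[m]
    if (scope == "intra") keep <- keep & same
    if (scope == "inter") keep <- keep & !same
    if (!any(keep)) next
    P <- as.matrix(accA[keep, c("x", "y", "z")])
    disp <- min_image_disp(sweep(P, 2, H[m, ]), frame$cell)
    r <- sqrt(rowSums(disp^2))
    # D-H...A angle at H, between the H->D and H->A vectors
    u <- D[m, ] - H[m, ]
    v <- as.vector(disp %*% u) / (r * sqrt(sum(u^2)))
    ang <- acos(pmin(pmax(v, -1), 1)) * 180 / pi
    pass <- r <= criterion$max_ha_distance & ang >= criterion$min_dha_angle
    if (!any(pass)) next
    j <- which(pass)[which.min(r[pass])]
    lab <- accA$atom_label[keep][j]
    sc <- if (accA$molecule[keep][j] == mols[m]) "intra" else "inter"
    cls <- lab
    if (sc == "inter" && !is.null(class_map) && lab %in% names(class_map)) {
      cls <- class_map[[lab]]
    }
    out$class[m] <- paste0(cls, "|", sc)
    out$acceptor[m] <- lab
    out$scope[m] <- sc
    out$distance[m] <- r[j]
    out$angle[m] <- ang[j]
  }
  out
}

#' Detect the hydrogen bond of one donor in one molecule
#'
#' Among all acceptor-element atoms of the frame (excluding the donor's own
#' heavy atom) that satisfy the geometric criterion, returns the class of
#' the acceptor with the shortest H...A distance; `"none"` if no candidate
#' passes. Intramolecular acceptors are reported by their atom label;
#' intermolecular acceptors can be grouped into chemical classes through
#' `class_map`.
#'
#' @param frame an [new_frame()] object.
#' @param molecule molecule index of the donor.
#' @param donor_h,donor_heavy atom labels of the donor hydrogen and its
#'   heavy atom (must be within 1.3 Angstrom of each other).
#' @param criterion an [hbond_criterion()].
#' @param class_map optional named character map label -> chemical class,
#'   applied to intermolecular acceptors.
#' @param scope `"both"`, `"intra"` or `"inter"`.
#' @return list with `class` (e.g. `"N7|intra"` or `"none"`), `acceptor`,
#'   `scope`, `distance`, `angle`.
#' @export
detect_hbond <- function(frame, molecule, donor_h, donor_heavy,
                         criterion = hbond_criterion(), class_map = NULL,
                         scope = "both") {
  res <- hbond_classes_frame(frame, donor_h, donor_heavy, criterion,
                             class_map, scope)
  row <- res[res$molecule == molecule, ]
  if (nrow(row) == 0) stop("molecule ", molecule, " not in frame")
  as.list(row[1, c("class", "acceptor", "scope", "distance", "angle")])
}

#' Define a geometric feature
#'
#' @param kind `"dihedral"` (4 labels), `"distance"` (2 labels) or
#'   `"hbond"` (donor-H label and donor heavy-atom label).
#' @param atom_labels character vector of atom labels, length per `kind`.
#' @param scope acceptor scope for `"hbond"` features.
#' @param name optional display name; defaults to the joined labels.
#' @return a `feature_spec` list.
#' @export
#' @examples
#' feature_spec("dihedral", c("O1", "C2", "C3", "C4"))
feature_spec <- function(kind = c("dihedral", "distance", "hbond"),
                         atom_labels, scope = "both", name = NULL) {
  kind <- match.arg(kind)
  need <- c(dihedral = 4L, distance = 2L, hbond = 2L)[kind]
  if (length(atom_labels) != need) {
    stop(kind, " feature needs ", need, " atom labels")
  }
  structure(list(kind = kind, atom_labels = atom_labels, scope = scope,
                 name = name %||% paste(atom_labels, collapse = "-")),
            class = "feature_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a feature over every environment of an ensemble
#'
#' One value per molecule per frame, in [environments()] order: dihedral
#' angle (degrees), intramolecular distance (Angstrom), or H-bond acceptor
#' class (character).
#'
#' @param frames list of [new_frame()] objects.
#' @param spec a [feature_spec()].
#' @param criterion,class_map H-bond settings (used for `"hbond"` only).
#' @return named vector (names = `env_id`).
#' @export
feature_values <- function(frames, spec, criterion = hbond_criterion(),
                           class_map = NULL) {
  vals <- lapply(frames, function(fr) {
    A <- fr$atoms
    mols <- sort(unique(A$molecule))
    ids <- paste(fr$run_id, fr$frame_index, mols, sep = "_")
    if (spec$kind == "hbond") {
      res <- hbond_classes_frame(fr, spec$atom_labels[1],
                                 spec$atom_labels[2], criterion, class_map,
                                 spec$scope)
      return(stats::setNames(res$class[match(mols, res$molecule)], ids))
    }
    key <- paste(A$molecule, A$atom_label)
    P <- lapply(spec$atom_labels, function(lab) {
      i <- match(paste(mols, lab), key)
      if (anyNA(i)) stop("missing atom label ", lab)
      as.matrix(A[i, c("x", "y", "z")])
    })
    v <- if (spec$kind == "dihedral") {
      dihedral_vec(P[[1]], P[[2]], P[[3]], P[[4]])
    } else {
      sqrt(rowSums((P[[1]] - P[[2]])^2))
    }
    stats::setNames(v, ids)
  })
  do.call(c, vals)
}
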