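# Shared in-code fixtures for the test suite. Everything is generated at
# test time; no binary data.

# A frame with two 3-atom "molecules" whose closest atoms are `gap` apart
# along x. Optionally periodic in a cubic box.
two_molecule_frame <- function(gap = 6, box = NULL) {
  a1 <- data.frame(molecule = 1L,
                   atom_label = c("O1", "H1", "C2"),
                   element = c("O", "H", "C"),
                   x = c(0, 0.97, 1.5), y = c(0, 0, 1.2), z = 0,
                   stringsAsFactors = FALSE)
  a2 <- data.frame(molecule = 2L,
                   atom_label = c("N1", "C1", "C3"),
                   element = c("N", "C", "C"),
                   x = c(1.5 + gap, 2.5 + gap, 3.5 + gap),
                   y = c(1.2, 1.2, 1.2), z = 0,
                   stringsAsFactors = FALSE)
  new_frame(rbind(a1, a2), cell = if (is.null(box)) NULL else diag(rep(box, 3)))
}

# A frame containing one toy molecule at given torsions (no box).
toy_frame <- function(tau, run_id = "run1", frame_index = 0L) {
  tm <- toy_molecule()
  X <- build_toy_geometry(tau)
  new_frame(data.frame(molecule = 1L, atom_label = tm$atom_label,
                       element = tm$element,
                       x = X[, 1], y = X[, 2], z = X[, 3],
                       stringsAsFactors = FALSE),
            run_id = run_id, frame_index = frame_index)
}

# Random non-degenerate triclinic cell with all heights >= min_height.
random_triclinic_cell <- function(min_height = 14) {
  repeat {
    cell <- diag(stats::runif(3, 18, 26))
    cell[2, 1] <- stats::runif(1, -4, 4)
    cell[3, 1] <- stats::runif(1, -4, 4)
    cell[3, 2] <- stats::runif(1, -4, 4)
    h <- shiftsel:::min_cell_height(cell)
    if (h >= min_height) return(cell)
  }
}

# Random periodic frame of n_mol rigid 3-atom molecules.
random_frame <- function(n_mol = 8, cell = random_triclinic_cell(),
                         run_id = "rnd", frame_index = 0L) {
  atoms <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    base <- stats::runif(3) %*% cell
    offs <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.2, 0))
    data.frame(molecule = m,
               atom_label = c("A1", "A2", "A3"),
               element = c("C", "N", "O"),
               x = base[1] + offs[, 1], y = base[2] + offs[, 2],
               z = base[3] + offs[, 3], stringsAsFactors = FALSE)
  }))
  new_frame(atoms, cell, run_id, frame_index)
}

# Brute-force minimum-image distance: exhaustive search over lattice
# images n in {-3..3}^3 (independent of the package's wrap+refine path).
brute_min_image <- function(a, b, cell) {
  best <- Inf
  for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    img <- b + as.vector(c(i, j, k) %*% cell)
    best <- min(best, sqrt(sum((img - a)^2)))
  }
  best
}

# Brute-force cluster membership: all atom pairs against all 27
# neighbour images (independent of the package's wrap+refine path).
brute_members <- function(frame, central, cutoff) {
  A <- frame$atoms
  C <- as.matrix(A[A$molecule == central, c("x", "y", "z")])
  grid <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pd2 <- function(P, Q) {
    outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  }
  out <- integer(0)
  for (m in setdiff(sort(unique(A$molecule)), central)) {
    P0 <- as.matrix(A[A$molecule == m, c("x", "y", "z")])
    # wrap the molecule near the central one first, then search images
    if (!is.null(frame$cell)) {
      f <- (colMeans(P0) - colMeans(C)) %*% solve(frame$cell)
      P0 <- sweep(P0, 2, as.vector(round(f) %*% frame$cell))
      dmin <- min(vapply(seq_len(nrow(grid)), function(g) {
        s <- as.vector(grid[g, ] %*% frame$cell)
        min(pd2(sweep(P0, 2, s, "+"), C))
      }, 0))
    } else {
      dmin <- min(pd2(P0, C))
    }
    if (sqrt(max(dmin, 0)) <= cutoff) out <- c(out, m)
  }
  out
}

# Independent arithmetic for the toy pair potential (mirrors the
# documented formula; kept separate from the package implementation).
# LJ only between heavy atoms; the donor-acceptor well only for H-(N,O).
analytic_pair_energy <- function(r, el1, el2, epsilon = 0.4,
                                 sigma_lj = 3.0, r_cut = 10, r_cap = 2.5,
                                 hb_depth = 10, hb_r = 1.9, hb_w = 0.3) {
  lj <- function(x) 4 * epsilon * ((sigma_lj / x)^12 - (sigma_lj / x)^6)
  e <- 0
  if (el1 != "H" && el2 != "H" && r <= r_cut) {
    e <- lj(max(r, r_cap)) - lj(r_cut)
  }
  if ((el1 == "H" && el2 %in% c("N", "O")) ||
      (el2 == "H" && el1 %in% c("N", "O"))) {
    e <- e - hb_depth * exp(-(r - hb_r)^2 / (2 * hb_w^2))
  }
  e
}

# Small benchmark case shared by several test files (400 environments).
small_case <- function(preset = "planted_hbond", seed = 7, ...) {
  make_benchmark_case(preset, seed = seed, n_runs = 2, n_frames = 10,
                      molecules_per_frame = 20, nmr_set_size = 40, ...)
}
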