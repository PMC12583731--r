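#' Extract the local molecular cluster around a central molecule
#'
#' Members are all molecules with at least one atom within `cutoff` of any
#' atom of the central molecule (boundary inclusive), with member
#' coordinates shifted to the periodic image nearest the central molecule,
#' so the returned cluster is whole and unwrapped.
#'
#' @param frame an [new_frame()] object.
#' @param central molecule index of the central molecule.
#' @param cutoff neighbour cutoff in Angstrom (default 7).
#' @return a `mol_cluster` list: `env_id`, `central`, `members` (indices),
#'   `atoms` (data.frame, central molecule first, minimum-image
#'   coordinates, non-periodic).
#' @export
extract_cluster <- function(frame, central, cutoff = 7.0) {
  stopifnot(cutoff > 0)
  A <- frame$atoms
  if (!central %in% A$molecule) stop("molecule ", central, " not in frame")
  if (!is.null(frame$cell)) {
    h <- min_cell_height(frame$cell)
    if (cutoff >= h / 2) {
      stop("cutoff ", cutoff, " A exceeds half the shortest cell height (",
           round(h / 2, 2), " A); periodic neighbour search is ambiguous")
    }
  }
  C <- as.matrix(A[A$molecule == central, c("x", "y", "z")])
  members <- integer(0)
  member_atoms <- list()
  for (m in setdiff(sort(unique(A$molecule)), central)) {
    Mi <- A[A$molecule == m, , drop = FALSE]
    P <- as.matrix(Mi[, c("x", "y", "z")])
    # one lattice translation for the whole molecule (molecules are whole):
    # pick the image of the molecule's centroid displacement, then refine
    # over neighbour images of that choice using the closest atom pair.
    best <- NULL; bestd <- Inf
    if (is.null(frame$cell)) {
      shifts <- matrix(0, 1, 3)
    } else {
      d0 <- colMeans(P) - colMeans(C)
      f <- d0 %*% solve(frame$cell)
      base <- -round(as.vector(f))
      grid <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      shifts <- (sweep(grid, 2, base, "+")) %*% frame$cell
    }
    for (s in seq_len(nrow(shifts))) {
      Ps <- sweep(P, 2, shifts[s, ], "+")
      d <- min(proxy_dist(Ps, C))
      if (d < bestd) { bestd <- d; best <- Ps }
    }
    if (bestd <= cutoff) {
      members <- c(members, m)
      Mi[, c("x", "y", "z")] <- best
      member_atoms[[length(member_atoms) + 1]] <- Mi
    }
  }
  atoms <- rbind(A[A$molecule == central, , drop = FALSE],
                 do.call(rbind, member_atoms))
  rownames(atoms) <- NULL
  structure(list(env_id = paste(frame$run_id, frame$frame_index, central,
                                sep = "_"),
                 central = central, members = members, atoms = atoms),
            class = "mol_cluster")
}

# All-pairs Euclidean distances between two coordinate matrices.
proxy_dist <- function(P, Q) {
  p2 <- rowSums(P^2); q2 <- rowSums(Q^2)
  d2 <- outer(p2, q2, "+") - 2 * P %*% t(Q)
  sqrt(pmax(d2, 0))
}

#' @export
print.mol_cluster <- function(x, ...) {
  cat("cluster", x$env_id, "- central molecule", x$central, "+",
      length(x$members), "neighbours (", nrow(x$atoms), "atoms )\n")
  invisible(x)
}

#' Toy pairwise intermolecular energy backend
#'
#' A deterministic stand-in for a quantum-chemistry engine. United-atom
#' style pairwise sum over intermolecular atom pairs: heavy-atom pairs
#' interact through a truncated-and-shifted Lennard-Jones term
#' \deqn{E_{LJ}(r) = 4\epsilon[(\sigma/r')^{12} - (\sigma/r')^6] -
#'   E_{LJ,raw}(r_{cut}), \quad r' = \max(r, r_{cap})}
#' for `r <= r_cut` (0 beyond), and hydrogens interact solely through a
#' Gaussian donor-acceptor well with N/O partners,
#' \deqn{E_{HB}(r) = -D \exp(-(r - r_0)^2 / 2w^2)}
#' so that a 1.9 Angstrom H-bond contact is net stabilizing. Strictly
#' intermolecular, so the formation energy of a cluster decomposes
#' exactly into central-member pair sums.
#'
#' @param epsilon LJ well depth, kJ/mol.
#' @param sigma_lj LJ diameter for heavy-atom pairs, Angstrom.
#' @param r_cut truncation radius, Angstrom.
#' @param r_cap short-range cap (the LJ term is frozen below it).
#' @param hb_depth,hb_r,hb_w donor-acceptor well depth (kJ/mol), position
#'   and width (Angstrom).
#' @return an `energy_backend` function taking an atom data.frame
#'   (`molecule`, `element`, `x`, `y`, `z`) and returning kJ/mol.
#' @export
toy_backend <- function(epsilon = 0.4, sigma_lj = 3.0, r_cut = 10,
                        r_cap = 2.5, hb_depth = 10, hb_r = 1.9,
                        hb_w = 0.3) {
  pair_e <- function(r, heavy, hb) {
    e <- numeric(length(r))
    lj <- heavy & r <= r_cut
    rr <- pmax(r[lj], r_cap)
    sr6 <- (sigma_lj / rr)^6
    sr6c <- (sigma_lj / r_cut)^6
    e[lj] <- 4 * epsilon * (sr6^2 - sr6) - 4 * epsilon * (sr6c^2 - sr6c)
    e + ifelse(hb, -hb_depth * exp(-(r - hb_r)^2 / (2 * hb_w^2)), 0)
  }
  f <- function(atoms) {
    if (is.null(atoms) || nrow(atoms) == 0) return(0)
    if (length(unique(atoms$molecule)) < 2) return(0)
    P <- as.matrix(atoms[, c("x", "y", "z")])
    d <- proxy_dist(P, P)
    inter <- outer(atoms$molecule, atoms$molecule, "!=")
    is_h <- atoms$element == "H"
    heavy <- outer(!is_h, !is_h, "&")
    hb <- outer(is_h, atoms$element %in% c("N", "O"), "&")
    hb <- hb | t(hb)
    up <- upper.tri(d) & inter
    sum(pair_e(d[up], heavy[up], hb[up]))
  }
  attr(f, "pair_energy") <- pair_e
  class(f) <- c("energy_backend", "function")
  f
}

#' File-based energy backend
#'
#' Reads precomputed per-cluster energies (e.g., from an external
#' quantum-chemistry engine) from a CSV with columns
#' `env_id,e_with,e_without,e_central` (kJ/mol).
#'
#' @param path CSV file path.
#' @return a `file_energy_backend` lookup object usable by
#'   [formation_energy()].
#' @export
file_backend <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("env_id", "e_with", "e_without", "e_central")
  if (!all(need %in% names(d))) {
    stop("energy table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$env_id)) stop("duplicate env_id in energy table")
  structure(list(table = d), class = "file_energy_backend")
}

#' Three-energy formation-energy decomposition of a cluster
#'
#' Three backend evaluations: (i) the environment including the central
#' molecule, (ii) the environment without it, (iii) the central molecule
#' alone. `delta = e_with - e_without - e_central` isolates the
#' interaction (plus, for backends with intramolecular terms,
#' conformational) energy of the central molecule in its environment;
#' `delta_env = e_with - e_without` is also reported.
#'
#' @param cluster a [extract_cluster()] result.
#' @param backend an [toy_backend()]-style function or a [file_backend()].
#' @return a `cluster_energies` list: `env_id`, `e_with`, `e_without`,
#'   `e_central`, `delta`, `delta_env` (kJ/mol).
#' @export
formation_energy <- function(cluster, backend) {
  if (inherits(backend, "file_energy_backend")) {
    i <- match(cluster$env_id, backend$table$env_id)
    if (is.na(i)) stop("no stored energies for cluster ", cluster$env_id)
    e_with <- backend$table$e_with[i]
    e_without <- backend$table$e_without[i]
    e_central <- backend$table$e_central[i]
  } else {
    env_atoms <- cluster$atoms[cluster$atoms$molecule != cluster$central, ,
                               drop = FALSE]
    cen_atoms <- cluster$atoms[cluster$atoms$molecule == cluster$central, ,
                               drop = FALSE]
    e_with <- tryCatch(backend(cluster$atoms), error = function(e)
      stop("backend failed on cluster ", cluster$env_id, ": ",
           conditionMessage(e)))
    e_without <- backend(env_atoms)
    e_central <- backend(cen_atoms)
  }
  structure(list(env_id = cluster$env_id, e_with = e_with,
                 e_without = e_without, e_central = e_central,
                 delta = e_with - e_without - e_central,
                 delta_env = e_with - e_without),
            class = "cluster_energies")
}

#' Randomly sample reference environments from the MD runs
#'
#' Uniform sampling without replacement, `per_run` environments from each
#' run, reproducible under `seed`.
#'
#' @param env_table data.frame from [environments()] (columns `env_id`,
#'   `run_id`).
#' @param per_run environments per run (default 1500).
#' @param seed integer RNG seed.
#' @return character vector of sampled `env_id`s.
#' @export
sample_md_environments <- function(env_table, per_run = 1500, seed = 1L) {
  runs <- sort(unique(env_table$run_id))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- lapply(runs, function(r) {
    ids <- env_table$env_id[env_table$run_id == r]
    if (length(ids) < per_run) {
      stop("run ", r, " has only ", length(ids),
           " environments (need ", per_run, ")")
    }
    sample(ids, per_run)
  })
  unlist(out)
}

#' Binned energy profile along a geometric feature
#'
#' Per-bin mean formation energy, referenced so that the minimum occupied
#' bin of the MD reference sample is at 0 kJ/mol; both sets share that
#' zero. The spread is the standard deviation of the per-environment
#' energies within the bin (`spread = "sd"`) or the standard error of the
#' bin mean (`spread = "se"`).
#'
#' @param features named numeric vector (env_id -> feature value).
#' @param energies named numeric vector (env_id -> delta, kJ/mol).
#' @param bin_edges numeric vector of bin edges (ascending).
#' @param md_ids,nmr_ids environment ids of the MD reference sample and
#'   the NMR set (must overlap `features`/`energies` names).
#' @param spread `"sd"` or `"se"`.
#' @return an `energy_profile` data.frame: `set`, `bin_left`, `bin_right`,
#'   `center`, `mean_rel`, `spread`, `count`; attribute `reference`
#'   (the subtracted zero, kJ/mol).
#' @export
binned_energy_profile <- function(features, energies, bin_edges,
                                  md_ids, nmr_ids = character(0),
                                  spread = c("sd", "se")) {
  spread <- match.arg(spread)
  common <- intersect(names(features), names(energies))
  if (!length(intersect(common, c(md_ids, nmr_ids)))) {
    stop("no overlap between features, energies and the requested sets")
  }
  one_set <- function(ids, set_name) {
    ids <- intersect(ids, common)
    x <- features[ids]; e <- energies[ids]
    ok <- is.finite(x) & is.finite(e)
    x <- x[ok]; e <- e[ok]
    idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
    k <- length(bin_edges) - 1L
    inb <- idx >= 1 & idx <= k
    idx <- idx[inb]; e <- e[inb]
    f <- factor(idx, levels = seq_len(k))
    cnt <- as.integer(table(f))
    mn <- as.numeric(tapply(e, f, mean))
    sdv <- as.numeric(tapply(e, f, stats::sd))
    if (spread == "se") sdv <- sdv / sqrt(pmax(cnt, 1))
    data.frame(set = set_name, bin_left = bin_edges[-length(bin_edges)],
               bin_right = bin_edges[-1],
               center = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
               mean = mn, spread = sdv, count = cnt,
               stringsAsFactors = FALSE)
  }
  md <- one_set(md_ids, "md")
  ref <- min(md$mean[md$count > 0], na.rm = TRUE)
  md$mean_rel <- md$mean - ref
  out <- md
  if (length(nmr_ids)) {
    nmr <- one_set(nmr_ids, "nmr")
    nmr$mean_rel <- nmr$mean - ref
    out <- rbind(md, nmr)
  }
  out$mean <- NULL
  out <- out[, c("set", "bin_left", "bin_right", "center", "mean_rel",
                 "spread", "count")]
  class(out) <- c("energy_profile", "data.frame")
  attr(out, "reference") <- ref
  out
}

#' Export a cluster as an XYZ file
#'
#' Plain XYZ with the central molecule's atoms first; the comment line
#' records the environment id and member molecules.
#'
#' @param cluster a [extract_cluster()] result.
#' @param path output path (conventionally `run_frame_molecule.xyz`).
#' @export
write_cluster_xyz <- function(cluster, path) {
  A <- cluster$atoms
  lines <- c(nrow(A),
             paste0("cluster ", cluster$env_id, " central=",
                    cluster$central, " members=",
                    paste(cluster$members, collapse = ",")),
             sprintf("%-2s %14.8f %14.8f %14.8f", A$element, A$x, A$y, A$z))
  writeLines(lines, path)
  invisible(path)
}
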