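# Internal-coordinate atom placement (NeRF construction): places the next
# atom at the given bond length, bond angle (to c-b) and torsion
# (a-b-c-new, IUPAC sign).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  c + (-bond * cos(ang)) * bc + (bond * sin(ang) * cos(tor)) * m +
    (-bond * sin(ang) * sin(tor)) * n
}

#' The toy molecule template
#'
#' A 12-atom flexible model molecule mirroring a donor / rigid-ring /
#' flexible-linker / acceptor architecture: a hydroxyl-like donor (O1-H1),
#' a backbone of four rotatable torsions tau1..tau4 (about the C2-C3,
#' C3-C4, C4-C5 and C5-C6 bonds), an acceptor nitrogen N7 at the far end,
#' and a rigid four-carbon ring fragment (C8-C11) attached at C2. In the
#' "closed" torsion basin the donor H1 sits ~1.9 Angstrom from N7 with a
#' near-linear O1-H1...N7 arrangement (an intramolecular hydrogen bond);
#' in the "open" basin H1...N7 exceeds 4 Angstrom.
#'
#' @return list with `atom_label`, `element`, donor/acceptor labels,
#'   torsion atom quadruples and the frozen basin centres/widths.
#' @export
toy_molecule <- function() {
  list(atom_label = c("O1", "C2", "C3", "C4", "C5", "C6", "N7", "H1",
                      "C8", "C9", "C10", "C11"),
       element = c("O", "C", "C", "C", "C", "C", "N", "H",
                   "C", "C", "C", "C"),
       donor_h = "H1", donor_heavy = "O1", acceptor = "N7",
       ring = c("C8", "C9", "C10", "C11"),
       torsions = list(tau1 = c("O1", "C2", "C3", "C4"),
                       tau2 = c("C2", "C3", "C4", "C5"),
                       tau3 = c("C3", "C4", "C5", "C6"),
                       tau4 = c("C4", "C5", "C6", "N7")),
       closed_centers = c(-60, 4, 105, -28), closed_width = 3,
       open_centers = c(180, 180, 180, 180), open_width = 15)
}

#' Build the toy molecule's Cartesian geometry from its torsions
#'
#' Deterministic internal-coordinate construction: bond lengths 1.43 (O-C),
#' 1.53 (C-C), 1.47 (C-N), 0.97 (O-H) Angstrom; backbone angles 112
#' degrees; the donor H and the ring fragment are held at fixed internal
#' coordinates, so the geometry is a function of (tau1..tau4) alone.
#'
#' @param tau numeric length-4 torsion vector, degrees.
#' @return 12 x 3 coordinate matrix (rows in [toy_molecule()] atom order).
#' @export
build_toy_geometry <- function(tau) {
  stopifnot(length(tau) == 4)
  X <- matrix(NA_real_, 12, 3)
  X[1, ] <- c(0, 0, 0)
  X[2, ] <- c(1.43, 0, 0)
  th <- 112 * pi / 180
  X[3, ] <- X[2, ] + 1.53 * c(-cos(th), sin(th), 0)
  X[4, ] <- place_atom(X[1, ], X[2, ], X[3, ], 1.53, 112, tau[1])
  X[5, ] <- place_atom(X[2, ], X[3, ], X[4, ], 1.53, 112, tau[2])
  X[6, ] <- place_atom(X[3, ], X[4, ], X[5, ], 1.53, 112, tau[3])
  X[7, ] <- place_atom(X[4, ], X[5, ], X[6, ], 1.47, 112, tau[4])
  X[8, ] <- place_atom(X[3, ], X[2, ], X[1, ], 0.97, 108, 27)
  X[9, ] <- place_atom(X[8, ], X[1, ], X[2, ], 1.50, 109.5, 60)
  X[10, ] <- place_atom(X[1, ], X[2, ], X[9, ], 1.50, 127, 90)
  X[11, ] <- place_atom(X[2, ], X[9, ], X[10, ], 1.50, 90, 0)
  X[12, ] <- place_atom(X[9, ], X[10, ], X[11, ], 1.50, 90, 0)
  X
}

#' Configuration of the synthetic-ensemble generator
#'
#' Defaults define the benchmark study conditions: 4 runs x 50 frames x 25
#' molecules = 5,000 environments in a 30 Angstrom periodic cubic box, a
#' closed-basin (intramolecular H-bond) fraction of 0.40, and an NMR-set
#' size of 500 (10 percent, mirroring a top-5,000-of-many selection at
#' desk scale).
#'
#' @param n_runs,n_frames,molecules_per_frame ensemble dimensions.
#' @param box_edge cubic box edge, Angstrom.
#' @param bias_fraction fraction of molecules in the closed basin.
#' @param min_center_distance minimum molecular centre separation at
#'   placement, Angstrom.
#' @param trunc_sigma torsion jitter truncation, in units of basin width.
#' @param delta0 named baseline shifts, ppm, per shift-bearing site.
#' @param a_hb,a_hb_n H-bond shift amplitudes for H1 and N7, ppm.
#' @param r0 H-bond shift decay length, Angstrom.
#' @param b_tau ring-carbon torsion coupling amplitude, ppm.
#' @param noise_sigma Gaussian prediction noise, ppm.
#' @param sigma_floor lower floor on planted distribution widths, ppm.
#' @param nmr_set_size top-N selection size.
#' @param scored_sites atom labels scored against the distributions.
#' @param seed integer RNG seed for the whole generation.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_runs = 4, n_frames = 50,
                             molecules_per_frame = 25, box_edge = 30,
                             bias_fraction = 0.4,
                             min_center_distance = 8, trunc_sigma = 3,
                             delta0 = c(H1 = 4, N7 = 115, C8 = 126,
                                        C9 = 128, C10 = 130, C11 = 132,
                                        C2 = 62, C3 = 34, C4 = 30,
                                        C5 = 31, C6 = 44),
                             a_hb = 8, a_hb_n = 20, r0 = 1.0, b_tau = 4,
                             noise_sigma = 0.1, sigma_floor = 0.01,
                             nmr_set_size = 500,
                             scored_sites = c("H1", "N7", "C8", "C9",
                                              "C10", "C11"),
                             seed = 42L) {
  stopifnot(bias_fraction >= 0, bias_fraction <= 1, box_edge > 0,
            min_center_distance < box_edge / 2)
  structure(as.list(environment()), class = "synthetic_config")
}

# truncated-normal torsion draw (rejection; truncation keeps basins
# separated so the degenerate bias_fraction guarantees hold)
rtnorm4 <- function(center, width, trunc) {
  repeat {
    z <- stats::rnorm(4)
    if (all(abs(z) <= trunc)) return(center + width * z)
  }
}

# uniform random rotation matrix from a random quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a toy amorphous ensemble with planted ground truth
#'
#' Each molecule's four backbone torsions are drawn from a two-basin
#' mixture: with probability `bias_fraction` the closed basin (planted
#' intramolecular H-bond, H1...N7 < 2.5 Angstrom), otherwise the open
#' basin (H1...N7 > 4 Angstrom). Draws whose geometry violates the basin
#' guarantee are redrawn, so the classification is exact by construction
#' and recomputable from the emitted geometry alone. Molecules are placed
#' at non-overlapping random positions and orientations in a periodic
#' cubic box. Fully reproducible under `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `frames` (list of [new_frame()]) and `ground_truth`
#'   (data.frame: `env_id`, `run_id`, `frame`, `molecule`, `basin`,
#'   `tau1`..`tau4`, `r_ha`).
#' @export
generate_toy_ensemble <- function(config) {
  tm <- toy_molecule()
  set.seed(config$seed)
  cell <- diag(rep(config$box_edge, 3))
  frames <- list()
  gt <- list()
  for (r in seq_len(config$n_runs)) {
    run_id <- paste0("run", r)
    for (fi in seq_len(config$n_frames) - 1L) {
      centers <- matrix(NA_real_, config$molecules_per_frame, 3)
      atoms <- vector("list", config$molecules_per_frame)
      for (m in seq_len(config$molecules_per_frame)) {
        closed <- stats::runif(1) < config$bias_fraction
        X <- NULL
        for (try in 1:100) {
          tau <- if (closed) {
            rtnorm4(tm$closed_centers, tm$closed_width, config$trunc_sigma)
          } else {
            rtnorm4(tm$open_centers, tm$open_width, config$trunc_sigma)
          }
          Xc <- build_toy_geometry(tau)
          r_ha <- sqrt(sum((Xc[8, ] - Xc[7, ])^2))
          if ((closed && r_ha < 2.5) || (!closed && r_ha > 4)) {
            X <- Xc
            break
          }
        }
        if (is.null(X)) stop("basin guarantee unreachable; check template")
        X <- sweep(X, 2, colMeans(X)) %*% t(random_rotation())
        placed <- FALSE
        for (try in 1:500) {
          pos <- stats::runif(3) * config$box_edge
          if (m == 1) { placed <- TRUE; break }
          d <- min_image_disp(sweep(centers[seq_len(m - 1), , drop = FALSE],
                                    2, pos), cell)
          if (min(sqrt(rowSums(d^2))) >= config$min_center_distance) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place molecule ", m, " without overlap; ",
               "increase box_edge or reduce molecules_per_frame")
        }
        centers[m, ] <- pos
        X <- sweep(X, 2, pos, "+")
        atoms[[m]] <- data.frame(molecule = m, atom_label = tm$atom_label,
                                 element = tm$element,
                                 x = X[, 1], y = X[, 2], z = X[, 3],
                                 stringsAsFactors = FALSE)
        tw <- ((tau + 180) %% 360) - 180  # wrap to (-180, 180]
        tw[tw == -180] <- 180
        gt[[length(gt) + 1]] <- data.frame(
          env_id = paste(run_id, fi, m, sep = "_"),
          run_id = run_id, frame = fi, molecule = m,
          basin = if (closed) "closed" else "open",
          tau1 = tw[1], tau2 = tw[2], tau3 = tw[3], tau4 = tw[4],
          r_ha = r_ha, stringsAsFactors = FALSE)
      }
      frames[[length(frames) + 1]] <-
        new_frame(do.call(rbind, atoms), cell, run_id, fi)
    }
  }
  list(frames = frames, ground_truth = do.call(rbind, gt))
}

#' Recompute the planted ground truth from geometry alone
#'
#' Re-derives the basin classification (closed iff H1...N7 < 2.5
#' Angstrom), the backbone torsions and the H...A distance from the
#' emitted coordinates, guaranteeing the generator carries no hidden
#' state.
#'
#' @param frames list of [new_frame()] objects built from the toy
#'   molecule.
#' @return data.frame like the `ground_truth` of
#'   [generate_toy_ensemble()].
#' @export
recompute_ground_truth <- function(frames) {
  tm <- toy_molecule()
  envs <- environments(frames)
  r_ha <- feature_values(frames, feature_spec("distance",
                                              c(tm$donor_h, tm$acceptor)))
  taus <- lapply(tm$torsions, function(q)
    feature_values(frames, feature_spec("dihedral", q)))
  data.frame(env_id = envs$env_id, run_id = envs$run_id,
             frame = envs$frame, molecule = envs$molecule,
             basin = ifelse(r_ha[envs$env_id] < 2.5, "closed", "open"),
             tau1 = as.numeric(taus[[1]][envs$env_id]),
             tau2 = as.numeric(taus[[2]][envs$env_id]),
             tau3 = as.numeric(taus[[3]][envs$env_id]),
             tau4 = as.numeric(taus[[4]][envs$env_id]),
             r_ha = as.numeric(r_ha[envs$env_id]),
             stringsAsFactors = FALSE)
}

#' Closed-form surrogate chemical shifts for one environment
#'
#' Documented geometry-to-shift model standing in for a machine-learned
#' shift predictor:
#' \deqn{\delta(H1) = \delta_0 + A_{hb} e^{-r_{HA}/r_0} + \epsilon}
#' \deqn{\delta(N7) = \delta_0 + A_{hb,N} e^{-r_{HA}/r_0} + \epsilon}
#' \deqn{\delta(C_{ring}) = \delta_0 + B \cos\tau_1 + \epsilon}
#' and baseline + noise for the remaining carbons;
#' `epsilon ~ N(0, noise_sigma^2)` from the current RNG stream (or
#' deterministically seeded via `seed`).
#'
#' @param frame an [new_frame()] object.
#' @param molecule molecule index within the frame.
#' @param config a [synthetic_config()].
#' @param noise add the Gaussian noise term (FALSE gives the noiseless
#'   closed form).
#' @param seed optional integer; when given, seeds the noise stream for
#'   this call alone.
#' @return named numeric vector of predicted shifts, ppm.
#' @export
surrogate_shifts <- function(frame, molecule, config, noise = TRUE,
                             seed = NULL) {
  tm <- toy_molecule()
  A <- frame$atoms[frame$atoms$molecule == molecule, , drop = FALSE]
  if (!setequal(A$atom_label, tm$atom_label)) {
    stop("molecule ", molecule, " does not match the toy template")
  }
  P <- as.matrix(A[match(tm$atom_label, A$atom_label),
                   c("x", "y", "z")])
  r_ha <- sqrt(sum((P[8, ] - P[7, ])^2))
  tau1 <- as.numeric(dihedral(P[1, ], P[2, ], P[3, ], P[4, ]))
  if (!is.null(seed)) set.seed(seed)
  sites <- names(config$delta0)
  delta <- config$delta0
  delta["H1"] <- delta["H1"] + config$a_hb * exp(-r_ha / config$r0)
  delta["N7"] <- delta["N7"] + config$a_hb_n * exp(-r_ha / config$r0)
  ring <- intersect(tm$ring, sites)
  delta[ring] <- delta[ring] + config$b_tau * cos(tau1 * pi / 180)
  if (noise) {
    delta <- delta + stats::rnorm(length(delta), 0, config$noise_sigma)
  }
  delta[sites]
}

#' Predict surrogate shifts for every environment of an ensemble
#'
#' Deterministic given `config$seed` (the noise stream is seeded at
#' `seed + 1`, independent of the geometry stream).
#'
#' @param frames list of [new_frame()] objects.
#' @param config a [synthetic_config()].
#' @return long prediction data.frame (`env_id`, `run_id`, `frame`,
#'   `molecule`, `atom_label`, `shift`) as consumed by [score_dataset()].
#' @export
predict_ensemble <- function(frames, config) {
  set.seed(config$seed + 1L)
  out <- lapply(frames, function(fr) {
    mols <- sort(unique(fr$atoms$molecule))
    do.call(rbind, lapply(mols, function(m) {
      s <- surrogate_shifts(fr, m, config)
      data.frame(env_id = paste(fr$run_id, fr$frame_index, m, sep = "_"),
                 run_id = fr$run_id, frame = fr$frame_index, molecule = m,
                 atom_label = names(s), shift = unname(s),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Derive "experimental" shift distributions from a planted subensemble
#'
#' For each scored site, mu and sigma are the sample mean and standard
#' deviation of the surrogate shifts over the designated subensemble
#' (default: the closed-basin population, emulating an experimentally
#' biased solid). Widths are floored at `config$sigma_floor`.
#'
#' @param predictions long prediction table from [predict_ensemble()].
#' @param ground_truth ground-truth table from [generate_toy_ensemble()].
#' @param config a [synthetic_config()].
#' @param subensemble `"closed"`, `"open"` or `"all"`.
#' @return a [shift_distribution()] table over `config$scored_sites`.
#' @export
plant_experimental_distributions <- function(predictions, ground_truth,
                                             config,
                                             subensemble = c("closed",
                                                             "all",
                                                             "open")) {
  subensemble <- match.arg(subensemble)
  ids <- if (subensemble == "all") {
    ground_truth$env_id
  } else {
    ground_truth$env_id[ground_truth$basin == subensemble]
  }
  if (!length(ids)) stop("empty subensemble '", subensemble, "'")
  sub <- predictions[predictions$env_id %in% ids &
                       predictions$atom_label %in% config$scored_sites, ]
  mu <- tapply(sub$shift, sub$atom_label, mean)
  sg <- tapply(sub$shift, sub$atom_label, stats::sd)
  sg[is.na(sg)] <- 0
  sg <- pmax(sg, config$sigma_floor)
  lab <- config$scored_sites
  shift_distribution(lab, as.numeric(mu[lab]), as.numeric(sg[lab]),
                     source = paste0("synthetic:", subensemble))
}

#' Build a complete benchmark fixture
#'
#' Self-contained end-to-end cases with known ground truth:
#' * `"planted_hbond"` - closed-basin fraction 0.40 in the ensemble,
#'   distributions planted from the closed basin; selection should
#'   strongly enrich the closed basin.
#' * `"planted_torsion"` - same bias but the H-bond shift amplitudes are
#'   zeroed, so the signal is carried solely by the ring-carbon torsion
#'   coupling; the closed tau1 basin should be promoted.
#' * `"null"` - symmetric mixture (bias 0.5) with all geometry-to-shift
#'   couplings zeroed and distributions fitted to the whole ensemble:
#'   predicted shifts carry no conformational information, so selection
#'   is pure noise and every enrichment ratio should be ~ 1. (Merely
#'   fitting distributions to the whole ensemble while keeping the
#'   couplings is *not* a null: selection then favours whichever basin
#'   has the larger within-basin shift variance.)
#'
#' @param preset `"null"`, `"planted_hbond"` or `"planted_torsion"`.
#' @param seed optional integer overriding the config seed.
#' @param out_dir optional directory; when given, the fixture is written
#'   out (extended-XYZ trajectory, predictions and distributions CSV,
#'   `ground_truth.json`, `config.yaml`).
#' @param ... further overrides passed to [synthetic_config()].
#' @return list with `preset`, `config`, `frames`, `ground_truth`,
#'   `predictions`, `distributions`, `expected` (planted quantities the
#'   acceptance checks assert).
#' @export
make_benchmark_case <- function(preset = c("planted_hbond",
                                           "planted_torsion", "null"),
                                seed = NULL, out_dir = NULL, ...) {
  preset <- match.arg(preset)
  over <- list(...)
  args <- switch(preset,
                 planted_hbond = list(bias_fraction = 0.4),
                 planted_torsion = list(bias_fraction = 0.4, a_hb = 0,
                                        a_hb_n = 0),
                 null = list(bias_fraction = 0.5, a_hb = 0, a_hb_n = 0,
                             b_tau = 0))
  args[names(over)] <- over
  if (!is.null(seed)) args$seed <- as.integer(seed)
  config <- do.call(synthetic_config, args)
  ens <- generate_toy_ensemble(config)
  predictions <- predict_ensemble(ens$frames, config)
  distributions <- plant_experimental_distributions(
    predictions, ens$ground_truth, config,
    subensemble = if (preset == "null") "all" else "closed")
  expected <- list(bias_fraction = config$bias_fraction,
                   nmr_set_size = config$nmr_set_size,
                   scored_sites = config$scored_sites,
                   closed_tau1_center = toy_molecule()$closed_centers[1],
                   md_closed_fraction =
                     mean(ens$ground_truth$basin == "closed"))
  case <- list(preset = preset, config = config, frames = ens$frames,
               ground_truth = ens$ground_truth,
               predictions = predictions, distributions = distributions,
               expected = expected)
  if (!is.null(out_dir)) write_benchmark_case(case, out_dir)
  case
}

#' Synthetic solution/solid assignment fixture
#'
#' Emulates the nearest-peak refinement scenario: a set of solid-state
#' peak positions per nucleus, and solution-state shifts that are the
#' solid peaks plus known planted perturbations. The largest planted 13C
#' perturbation is exactly `max_c13` ppm (site `C14`) and the largest 1H
#' perturbation `max_h1` ppm (site `H3`); all perturbations are well
#' below half the peak spacing, so each solution shift's nearest solid
#' peak is its own.
#'
#' @param seed integer seed for the perturbation draw.
#' @param max_c13,max_h1 planted maximum deviations, ppm.
#' @return list with `solution` (data.frame `atom_label`, `shift`),
#'   `solid_peaks` (named list per nucleus) and `planted` (named vector
#'   of true perturbations).
#' @export
make_assignment_fixture <- function(seed = 1L, max_c13 = 3.0,
                                    max_h1 = 0.3) {
  set.seed(seed)
  c_peaks <- seq(12, 172, by = 8)
  h_peaks <- seq(0.8, 11.3, by = 1.5)
  c_pert <- stats::runif(length(c_peaks), -2.5, 2.5)
  c_pert[3] <- max_c13
  h_pert <- stats::runif(length(h_peaks), -0.25, 0.25)
  h_pert[2] <- max_h1
  labels_c <- paste0("C", 11 + seq_along(c_peaks))
  labels_c[3] <- "C14"
  labels_h <- paste0("H", 1 + seq_along(h_peaks))
  labels_h[2] <- "H3"
  solution <- data.frame(
    atom_label = c(labels_c, labels_h),
    shift = c(c_peaks + c_pert, h_peaks + h_pert),
    stringsAsFactors = FALSE)
  list(solution = solution,
       solid_peaks = list("13C" = c_peaks, "1H" = h_peaks),
       planted = stats::setNames(abs(c(c_pert, h_pert)),
                                 c(labels_c, labels_h)))
}

write_benchmark_case <- function(case, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_extxyz(case$frames, file.path(out_dir, "ensemble.extxyz"))
  p <- case$predictions
  utils::write.csv(data.frame(run_id = p$run_id, frame = p$frame,
                              molecule = p$molecule,
                              atom_label = p$atom_label,
                              shift_ppm = p$shift),
                   file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  write_shift_distributions(case$distributions,
                            file.path(out_dir, "distributions.csv"))
  jsonlite::write_json(list(preset = case$preset,
                            expected = case$expected,
                            ground_truth = case$ground_truth),
                       file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  cfg <- case$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
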