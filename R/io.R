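#' Write frames as an extended-XYZ trajectory
#'
#' One block per frame: atom count, a comment line carrying
#' `Lattice="..."` (row-major lattice vectors), a `Properties` descriptor
#' (`species:S:1:pos:R:3:molecule:I:1:label:S:1`) plus `run_id` and
#' `frame_index`, then one line per atom.
#'
#' @param frames list of [new_frame()] objects.
#' @param path output file path.
#' @export
write_extxyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    A <- fr$atoms
    hdr <- paste0(
      if (!is.null(fr$cell)) {
        paste0("Lattice=\"", paste(sprintf("%.10g", t(fr$cell)),
                                   collapse = " "), "\" ")
      } else "",
      "Properties=species:S:1:pos:R:3:molecule:I:1:label:S:1 ",
      "run_id=", fr$run_id, " frame_index=", fr$frame_index)
    writeLines(as.character(nrow(A)), con)
    writeLines(hdr, con)
    writeLines(sprintf("%-2s %.10f %.10f %.10f %d %s", A$element,
                       A$x, A$y, A$z, A$molecule, A$atom_label), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Requires a `molecule` integer column in the `Properties` descriptor
#' (environments are addressed per molecule). Atom labels come from a
#' `label` column, or from a label map CSV (`atom_index,atom_label`,
#' 1-based within each molecule) when the file does not carry them.
#'
#' @param path extended-XYZ file.
#' @param label_map optional path to a label-map CSV, or a data.frame.
#' @return list of [new_frame()] objects.
#' @export
read_extxyz <- function(path, label_map = NULL) {
  lines <- readLines(path)
  if (!is.null(label_map) && !is.data.frame(label_map)) {
    label_map <- utils::read.csv(label_map, comment.char = "#",
                                 stringsAsFactors = FALSE)
  }
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed extxyz: expected atom count at line ", i)
    hdr <- lines[i + 1L]
    cell <- NULL
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    if (length(lat)) {
      v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                               "\\s+")[[1]])
      cell <- matrix(v, 3, 3, byrow = TRUE)
    }
    props <- regmatches(hdr, regexpr("Properties=\\S+", hdr))
    if (!length(props)) stop("malformed extxyz: missing Properties")
    spec <- strsplit(sub("Properties=", "", props), ":")[[1]]
    fields <- spec[seq(1, length(spec), by = 3)]
    widths <- as.integer(spec[seq(3, length(spec), by = 3)])
    col_of <- function(name) {
      k <- match(name, fields)
      if (is.na(k)) return(NA_integer_)
      sum(widths[seq_len(k - 1)]) + 1L
    }
    if (is.na(col_of("molecule"))) {
      stop("extended-XYZ file lacks a molecule column; ",
           "environments cannot be addressed")
    }
    run_id <- sub('.*run_id=([^ "]+).*', "\\1", hdr)
    if (identical(run_id, hdr)) run_id <- "run"
    fidx <- sub(".*frame_index=([0-9]+).*", "\\1", hdr)
    fidx <- if (identical(fidx, hdr)) length(frames) else as.integer(fidx)
    body <- lines[i + 1L + seq_len(n)]
    tok <- strsplit(trimws(body), "\\s+")
    tok <- do.call(rbind, tok)
    atoms <- data.frame(
      molecule = as.integer(tok[, col_of("molecule")]),
      element = tok[, col_of("species")],
      x = as.numeric(tok[, col_of("pos")]),
      y = as.numeric(tok[, col_of("pos") + 1L]),
      z = as.numeric(tok[, col_of("pos") + 2L]),
      stringsAsFactors = FALSE)
    if (!is.na(col_of("label"))) {
      atoms$atom_label <- tok[, col_of("label")]
    } else if (!is.null(label_map)) {
      idx <- stats::ave(seq_len(n), atoms$molecule, FUN = seq_along)
      j <- match(idx, label_map$atom_index)
      if (anyNA(j)) {
        stop("label map mismatch at atom index ",
             paste(utils::head(idx[is.na(j)], 3), collapse = ", "))
      }
      atoms$atom_label <- label_map$atom_label[j]
    } else {
      stop("no atom labels: file has no label column and no label_map ",
           "was given")
    }
    frames[[length(frames) + 1L]] <-
      new_frame(atoms[, c("molecule", "atom_label", "element",
                          "x", "y", "z")], cell, run_id, fidx)
    i <- i + 2L + n
  }
  frames
}

#' Read a PDB file as one frame
#'
#' Chains (or residues, when the file has a single chain) become
#' molecules; atom names become labels. Requires the bio3d package.
#'
#' @param path PDB file path.
#' @param run_id,frame_index provenance for the resulting frame.
#' @return a [new_frame()] object (non-periodic).
#' @export
read_pdb_frames <- function(path, run_id = "pdb", frame_index = 0L) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  chains <- a$chain
  if (length(unique(chains)) <= 1) {
    mol <- as.integer(factor(a$resno))
  } else {
    mol <- as.integer(factor(chains))
  }
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || !any(nzchar(el))) {
    el <- toupper(substr(trimws(a$elety), 1, 1))
  }
  atoms <- data.frame(molecule = mol, atom_label = trimws(a$elety),
                      element = trimws(el), x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  new_frame(atoms, cell = NULL, run_id = run_id, frame_index = frame_index)
}

# provenance header written into every CSV output and the manifest
provenance_header <- function(seed, config_hash, inputs = NULL) {
  c(paste0("shiftsel ", as.character(utils::packageVersion("shiftsel")),
           " seed=", seed, " config=", config_hash),
    if (!is.null(inputs)) paste0("input ", names(inputs), " md5=", inputs))
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Chains the stages score -> select -> structural analysis -> (optional)
#' energetics over one configuration, writing every stage output plus a
#' run manifest. Deterministic and idempotent for fixed inputs and seed.
#'
#' @param frames list of [new_frame()] objects (or a path to an
#'   extended-XYZ trajectory).
#' @param predictions long prediction table (or a CSV path for
#'   [read_predictions()]).
#' @param distributions a [shift_distribution()] table (or a CSV path).
#' @param n NMR-set size.
#' @param features list of [feature_spec()]s to histogram; each may carry
#'   attributes `bin_width` (default 10 degrees / 0.5 Angstrom) via the
#'   `bins` argument.
#' @param bins optional named list feature-name -> list(bin_width,
#'   periodic, range).
#' @param donors data.frame of H-bond donors (`donor_h`, `donor_heavy`),
#'   or NULL to skip the census.
#' @param criterion an [hbond_criterion()].
#' @param class_map optional intermolecular acceptor class map.
#' @param energy NULL to skip energetics, or a list with elements
#'   `backend` (an energy backend or `"toy"`), `per_run` (MD reference
#'   sample size per run), `feature` (index into `features` whose values
#'   the profile is binned along) and `bin_edges`.
#' @param atom_subset scored atom labels (default: all sites with
#'   distributions).
#' @param seed integer seed (used by the energetics reference sampling).
#' @param out_dir output directory (created if needed).
#' @param min_count minimum MD-bin occupancy for promotion classification
#'   in the report's promoted-feature flags.
#' @return a `pipeline_report` list: `selection`, `histograms` (named list
#'   of [promotion_map()]s), `census`, `energy_profile`, `promoted_features`,
#'   `manifest`.
#' @export
run_pipeline <- function(frames, predictions, distributions, n = 500,
                         features = list(), bins = list(), donors = NULL,
                         criterion = hbond_criterion(), class_map = NULL,
                         energy = NULL, atom_subset = NULL, seed = 1L,
                         out_dir = tempfile("shiftsel_run"),
                         min_count = 25) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- c()
  if (is.character(frames)) {
    inputs["trajectory"] <- unname(tools::md5sum(frames))
    frames <- stage("read", read_extxyz(frames))
  }
  if (is.character(predictions)) {
    inputs["predictions"] <- unname(tools::md5sum(predictions))
    predictions <- stage("read", read_predictions(predictions))
  }
  if (is.character(distributions)) {
    inputs["distributions"] <- unname(tools::md5sum(distributions))
    distributions <- stage("read", read_shift_distributions(distributions))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- hash_object(list(n = n, seed = seed,
                               atom_subset = atom_subset,
                               features = lapply(features, unclass),
                               bins = bins, energy = !is.null(energy)))
  hdr <- provenance_header(seed, cfg_hash, inputs)

  selection <- stage("score",
                     score_dataset(predictions, distributions,
                                   atom_subset = atom_subset, n = n))
  write_scores(selection, file.path(out_dir, "scores.csv"), hdr)

  envs <- environments(frames)
  md_ids <- envs$env_id
  nmr_ids <- selection$nmr_set

  histograms <- list()
  feat_values <- list()
  for (sp in features) {
    b <- bins[[sp$name]] %||%
      list(bin_width = if (sp$kind == "dihedral") 10 else 0.5,
           periodic = sp$kind == "dihedral", range = NULL)
    v <- stage(paste0("feature:", sp$name),
               feature_values(frames, sp, criterion, class_map))
    feat_values[[sp$name]] <- v
    if (sp$kind == "hbond") next
    rng <- b$range %||%
      (if (b$periodic) NULL else range(v[md_ids], finite = TRUE))
    hmd <- histogram1d(as.numeric(v[md_ids]), b$bin_width, b$periodic, rng)
    hnm <- histogram1d(as.numeric(v[nmr_ids]), b$bin_width, b$periodic, rng)
    pm <- promotion_map(hmd, hnm)
    pm$count_md <- hmd$count
    histograms[[sp$name]] <- pm
    write_histogram(pm, file.path(out_dir, paste0(
      "hist_", gsub("[^A-Za-z0-9_-]", "_", sp$name), ".csv")), hdr)
  }

  census <- NULL
  if (!is.null(donors)) {
    census <- stage("census",
                    hbond_census(frames, md_ids, nmr_ids, donors,
                                 criterion, class_map))
    con <- file(file.path(out_dir, "hbond_census.csv"), "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.csv(as.data.frame(census), con, row.names = FALSE,
                     quote = FALSE)
    close(con)
  }

  profile <- NULL
  if (!is.null(energy)) {
    backend <- energy$backend %||% "toy"
    if (identical(backend, "toy")) backend <- toy_backend()
    per_run <- energy$per_run %||% 1500
    sample_ids <- stage("energy",
                        sample_md_environments(envs, per_run, seed))
    need_ids <- union(sample_ids, nmr_ids)
    frame_of <- stats::setNames(rep(seq_along(frames),
                                    vapply(frames, function(f)
                                      length(unique(f$atoms$molecule)), 0L)),
                                envs$env_id)
    energies <- stage("energy", vapply(need_ids, function(id) {
      fr <- frames[[frame_of[[id]]]]
      mol <- envs$molecule[envs$env_id == id]
      formation_energy(extract_cluster(fr, mol, energy$cutoff %||% 7),
                       backend)$delta
    }, 0))
    fv <- feat_values[[features[[energy$feature %||% 1L]]$name]]
    profile <- stage("energy",
                     binned_energy_profile(fv[need_ids], energies,
                                           energy$bin_edges,
                                           sample_ids, nmr_ids))
    con <- file(file.path(out_dir, "energy_profile.csv"), "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.csv(as.data.frame(profile), con, row.names = FALSE,
                     quote = FALSE)
    close(con)
  }

  promoted <- lapply(histograms, function(pm) {
    pm$center[pm$class == "promoted" & pm$count_md >= min_count]
  })
  manifest <- list(package = "shiftsel",
                   version = as.character(utils::packageVersion("shiftsel")),
                   r_version = as.character(getRversion()),
                   seed = seed, config_hash = cfg_hash,
                   inputs = as.list(inputs),
                   n_environments = length(md_ids),
                   n_selected = selection$n_selected,
                   min_selected_pvalue = selection$min_selected_pvalue,
                   promoted_features = promoted,
                   any_promoted = any(lengths(promoted) > 0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(selection = selection, histograms = histograms,
                 census = census, energy_profile = profile,
                 feature_values = feat_values,
                 promoted_features = promoted,
                 any_promoted = any(lengths(promoted) > 0),
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("shiftsel pipeline report\n")
  cat("  environments:", length(x$selection$md_set),
      " selected:", x$selection$n_selected, "\n")
  cat("  min selected p-value:",
      format(x$selection$min_selected_pvalue), "\n")
  if (length(x$promoted_features)) {
    for (nm in names(x$promoted_features)) {
      ctr <- x$promoted_features[[nm]]
      cat("  ", nm, ": ",
          if (length(ctr)) paste0("promoted bins at ",
                                  paste(ctr, collapse = ", "))
          else "no promoted bins", "\n", sep = "")
    }
  }
  invisible(x)
}
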