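#' Probability of a predicted shift under an experimental distribution
#'
#' Two-sided Gaussian tail probability: the probability that a draw from
#' N(mu, sigma^2) lies farther from mu than the predicted shift,
#' `p = erfc(|predicted - mu| / (sigma * sqrt(2)))`. Equals 1 at zero
#' deviation and is symmetric in the sign of the deviation.
#'
#' @param predicted numeric vector of predicted shifts, ppm.
#' @param dist one row of a [shift_distribution()] table, or any list with
#'   elements `mu` and `sigma`.
#' @return probabilities in (0, 1].
#' @export
#' @examples
#' d <- shift_distribution("H1", mu = 4, sigma = 0.5)
#' shift_probability(4.0, d)  # 1
#' shift_probability(4.5, d)  # ~0.317 (one-sigma deviation)
shift_probability <- function(predicted, dist) {
  mu <- dist$mu[1]; sigma <- dist$sigma[1]
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
    stop("distribution must have finite mu and sigma > 0")
  }
  if (any(!is.finite(predicted))) stop("non-finite predicted shift")
  # erfc(z/sqrt(2)) = 2 * pnorm(-z)
  2 * stats::pnorm(-abs(predicted - mu) / sigma)
}

# Resolve which distribution row serves each atom label: direct match
# first, then membership of a lumped peak. Returns row indices.
resolve_distributions <- function(labels, dists) {
  idx <- match(labels, dists$atom_label)
  if (anyNA(idx)) {
    members <- lapply(strsplit(dists$lumped_with, ";"), function(x)
      x[nzchar(x)])
    for (i in which(is.na(idx))) {
      hit <- which(vapply(members, function(m) labels[i] %in% m, TRUE))
      if (length(hit)) idx[i] <- hit[1]
    }
  }
  if (anyNA(idx)) {
    stop("no experimental distribution for label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Score one molecular environment against the experimental distributions
#'
#' The environment's p-value is the geometric mean of the per-site
#' probabilities ([shift_probability()]) over the scored atom subset,
#' computed in log space with a probability floor of `p_floor` to keep the
#' log-sum finite. Optionally, predicted shifts of chemically equivalent
#' protons (e.g., the two/three hydrogens of a CH2/CH3 group, averaged by
#' fast rotation or exchange) are arithmetically averaged before scoring.
#'
#' @param shifts named numeric vector: predicted shift (ppm) per atom label.
#' @param dists a [shift_distribution()] table.
#' @param atom_subset labels to score; defaults to every label that has a
#'   distribution (directly or via `lumped_with`) and a prediction.
#' @param equivalent_groups optional named list; each element is a character
#'   vector of labels whose predictions are averaged and scored once under
#'   the first label of the group.
#' @param p_floor lower floor applied to per-site probabilities.
#' @return list with `per_atom_p` (named numeric) and `pvalue`.
#' @export
score_environment <- function(shifts, dists, atom_subset = NULL,
                              equivalent_groups = NULL, p_floor = 1e-300) {
  if (!is.null(equivalent_groups)) {
    for (g in equivalent_groups) {
      present <- g[g %in% names(shifts)]
      if (length(present) > 1) {
        shifts[present[1]] <- mean(shifts[present])
        shifts <- shifts[!names(shifts) %in% present[-1]]
      }
    }
  }
  if (is.null(atom_subset)) {
    dist_members <- unique(c(dists$atom_label,
                             unlist(strsplit(dists$lumped_with, ";"))))
    atom_subset <- intersect(names(shifts), dist_members)
    if (!length(atom_subset)) stop("no scorable atoms")
  }
  miss <- setdiff(atom_subset, names(shifts))
  if (length(miss)) {
    stop("no prediction for label(s): ", paste(miss, collapse = ", "))
  }
  idx <- resolve_distributions(atom_subset, dists)
  p <- 2 * stats::pnorm(-abs(shifts[atom_subset] - dists$mu[idx]) /
                          dists$sigma[idx])
  if (any(!is.finite(p))) stop("non-finite predicted shift in environment")
  names(p) <- atom_subset
  pv <- exp(mean(log(pmax(p, p_floor))))
  list(per_atom_p = p, pvalue = pv)
}

#' Rank environments and select the NMR set
#'
#' Stable descending sort by p-value, ties broken by `env_id`
#' lexicographic order; the NMR set is the top `n` environments and the MD
#' set is all of them.
#'
#' @param scores data.frame with columns `env_id`, `pvalue`.
#' @param n number of environments to select.
#' @return an `ensemble_selection` list with `ranked` (sorted score table),
#'   `nmr_set`, `md_set` (character id vectors), `n_selected` and
#'   `min_selected_pvalue`.
#' @export
rank_and_select <- function(scores, n) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1, n >= 1)
  if (anyDuplicated(scores$env_id)) {
    stop("duplicate env_id in score table")
  }
  o <- order(-scores$pvalue, scores$env_id, method = "radix")
  ranked <- scores[o, , drop = FALSE]
  rownames(ranked) <- NULL
  k <- min(n, nrow(ranked))
  sel <- list(ranked = ranked,
              nmr_set = ranked$env_id[seq_len(k)],
              md_set = ranked$env_id,
              n_selected = k,
              min_selected_pvalue = ranked$pvalue[k])
  class(sel) <- "ensemble_selection"
  sel
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat("ensemble selection:", length(x$md_set), "environments,",
      x$n_selected, "selected\n")
  cat("  min selected p-value:", format(x$min_selected_pvalue), "\n")
  invisible(x)
}

#' Score a whole prediction table and select the NMR set
#'
#' Single pass over the environments of a long-format prediction table.
#' Per-site probabilities are computed vectorized; only one p-value per
#' environment is retained (plus min/median summaries), then
#' [rank_and_select()] picks the top `n`.
#'
#' @param predictions long data.frame with columns `env_id`, `atom_label`,
#'   `shift` (see [read_predictions()]), or a `shift_predictions` object.
#' @param dists a [shift_distribution()] table.
#' @param atom_subset labels to score in every environment; defaults to all
#'   labels with a distribution that appear in the first environment.
#' @param n NMR-set size.
#' @inheritParams score_environment
#' @return an `ensemble_selection` (see [rank_and_select()]) whose `ranked`
#'   element is the full score table; attribute `summary` holds the min and
#'   median p-value over all environments.
#' @export
score_dataset <- function(predictions, dists, atom_subset = NULL, n,
                          equivalent_groups = NULL, p_floor = 1e-300) {
  stopifnot(is.data.frame(predictions), nrow(predictions) > 0,
            all(c("env_id", "atom_label", "shift") %in% names(predictions)))
  ids <- predictions$env_id
  blocks <- rle(ids)
  if (anyDuplicated(blocks$values)) {
    stop("duplicate env_id in prediction stream: ",
         paste(unique(blocks$values[duplicated(blocks$values)]),
               collapse = ", "))
  }
  if (!is.null(equivalent_groups)) {
    # fall back to the per-environment path, which handles averaging
    pv <- vapply(split(predictions, factor(ids, levels = blocks$values)),
                 function(d) {
                   s <- stats::setNames(d$shift, d$atom_label)
                   score_environment(s, dists, atom_subset,
                                     equivalent_groups, p_floor)$pvalue
                 }, 0)
    scores <- data.frame(env_id = blocks$values, pvalue = unname(pv))
  } else {
    if (is.null(atom_subset)) {
      first <- predictions$atom_label[ids == blocks$values[1]]
      dist_members <- unique(c(dists$atom_label,
                               unlist(strsplit(dists$lumped_with, ";"))))
      atom_subset <- intersect(first, dist_members)
      if (!length(atom_subset)) stop("no scorable atoms")
    }
    sub <- predictions[predictions$atom_label %in% atom_subset, ,
                       drop = FALSE]
    cnt <- table(sub$env_id)
    if (any(cnt != length(atom_subset)) ||
        length(cnt) != length(blocks$values)) {
      bad <- union(names(cnt)[cnt != length(atom_subset)],
                   setdiff(blocks$values, names(cnt)))
      stop("environment(s) missing scored-site predictions: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    idx <- resolve_distributions(sub$atom_label, dists)
    if (any(!is.finite(sub$shift))) stop("non-finite predicted shift")
    p <- 2 * stats::pnorm(-abs(sub$shift - dists$mu[idx]) / dists$sigma[idx])
    lp <- log(pmax(p, p_floor))
    f <- factor(sub$env_id, levels = blocks$values)
    pv <- exp(tapply(lp, f, mean))
    scores <- data.frame(env_id = blocks$values, pvalue = as.numeric(pv))
  }
  sel <- rank_and_select(scores, n)
  attr(sel, "summary") <- c(min_pvalue = min(scores$pvalue),
                            median_pvalue = stats::median(scores$pvalue))
  attr(sel, "atom_subset") <- atom_subset
  sel
}

#' Read a predicted-shift table
#'
#' CSV with header `run_id,frame,molecule,atom_label,shift_ppm` (predicted
#' shifts) or `...,shielding_ppm` (computed shieldings, converted through
#' [shielding_to_shift()] with the supplied referencing). Environments are
#' addressed as `run_frame_molecule`.
#'
#' @param path CSV file path.
#' @param ref optional [shift_referencing()]; required when the table holds
#'   shieldings.
#' @return long data.frame with columns `env_id`, `run_id`, `frame`,
#'   `molecule`, `atom_label`, `shift`.
#' @export
read_predictions <- function(path, ref = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("run_id", "frame", "molecule", "atom_label")
  if (!all(need %in% names(d))) {
    stop("prediction table must have columns ", paste(need, collapse = ", "))
  }
  if ("shift_ppm" %in% names(d)) {
    shift <- d$shift_ppm
  } else if ("shielding_ppm" %in% names(d)) {
    if (is.null(ref)) ref <- shift_referencing()
    shift <- shielding_to_shift(d$shielding_ppm,
                                infer_nucleus(d$atom_label), ref)
  } else {
    stop("prediction table needs a shift_ppm or shielding_ppm column")
  }
  data.frame(env_id = paste(d$run_id, d$frame, d$molecule, sep = "_"),
             run_id = d$run_id, frame = d$frame, molecule = d$molecule,
             atom_label = d$atom_label, shift = shift,
             stringsAsFactors = FALSE)
}

#' Write a score table
#'
#' @param selection an `ensemble_selection` from [score_dataset()].
#' @param path output CSV (`env_id,pvalue,selected`).
#' @param header optional provenance comment lines.
#' @export
write_scores <- function(selection, path, header = NULL) {
  out <- selection$ranked
  out$selected <- out$env_id %in% selection$nmr_set
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
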