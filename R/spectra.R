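#' Supported nuclei
#'
#' The three nuclei handled by the shift-referencing and scoring machinery.
#' @keywords internal
NUCLEI <- c("1H", "13C", "15N")

#' Infer the nucleus from an atom label
#'
#' Atom labels follow the element-prefix convention used throughout the
#' package (`H1`, `C14`, `N53`, ...). Hydrogens map to 1H, carbons to 13C
#' and nitrogens to 15N.
#'
#' @param atom_label character vector of site labels.
#' @return character vector of nuclei (`"1H"`, `"13C"`, `"15N"`).
#' @export
#' @examples
#' infer_nucleus(c("H1", "C14", "N53"))
infer_nucleus <- function(atom_label) {
  el <- toupper(substr(atom_label, 1L, 1L))
  out <- c(H = "1H", C = "13C", N = "15N")[el]
  if (anyNA(out)) {
    stop("cannot infer nucleus for label(s): ",
         paste(atom_label[is.na(out)], collapse = ", "))
  }
  unname(out)
}

#' Shielding-to-shift referencing convention
#'
#' Computed isotropic shieldings are converted to the experimental shift
#' scale by the affine map `shift = slope * shielding + offset`, with one
#' (slope, offset) pair per nucleus. The defaults are slope -1 for all
#' three nuclei and offsets 30.78, 170.04 and 227.9 ppm for 1H, 13C and
#' 15N respectively.
#'
#' @param slope named numeric, slope per nucleus (default -1 for all).
#' @param offset named numeric, offset in ppm per nucleus.
#' @return a `shift_referencing` object (data.frame with columns
#'   `nucleus`, `slope`, `offset`).
#' @export
#' @examples
#' shift_referencing()
shift_referencing <- function(slope = c("1H" = -1, "13C" = -1, "15N" = -1),
                              offset = c("1H" = 30.78, "13C" = 170.04,
                                         "15N" = 227.9)) {
  nuc <- union(names(slope), names(offset))
  if (!all(nuc %in% NUCLEI)) {
    stop("unknown nucleus in referencing: ",
         paste(setdiff(nuc, NUCLEI), collapse = ", "))
  }
  ref <- data.frame(nucleus = nuc,
                    slope = unname(slope[nuc]),
                    offset = unname(offset[nuc]),
                    stringsAsFactors = FALSE)
  class(ref) <- c("shift_referencing", "data.frame")
  ref
}

#' Convert computed shieldings to chemical shifts
#'
#' @param value numeric vector of isotropic shieldings, ppm.
#' @param nucleus one of `"1H"`, `"13C"`, `"15N"` (recycled over `value`).
#' @param ref a [shift_referencing()] object.
#' @return numeric vector of chemical shifts, ppm.
#' @export
#' @examples
#' shielding_to_shift(27.78, "1H")   # 3.00 ppm
shielding_to_shift <- function(value, nucleus, ref = shift_referencing()) {
  if (any(!nucleus %in% ref$nucleus)) {
    stop("unknown nucleus: ", paste(setdiff(nucleus, ref$nucleus),
                                    collapse = ", "))
  }
  i <- match(nucleus, ref$nucleus)
  ref$slope[i] * value + ref$offset[i]
}

#' Construct a table of experimental shift distributions
#'
#' One row per assigned site: the experimental chemical-shift distribution
#' of that site is modelled as a Gaussian with mean `mu` and width `sigma`
#' (both ppm). Overlapping sites fitted together to a single peak are
#' represented once, with the co-fitted labels listed in `lumped_with`;
#' every member is scored against the shared (mu, sigma).
#'
#' @param atom_label character, site labels (e.g., `"H1"`, `"C14"`).
#' @param mu numeric, mean shifts (ppm).
#' @param sigma numeric, Gaussian widths (ppm), all > 0.
#' @param nucleus character, inferred from `atom_label` when omitted.
#' @param source free-text spectrum identifier.
#' @param lumped_with list of character vectors (or semicolon-separated
#'   strings) naming additional sites sharing each distribution.
#' @return a `shift_distribution` data.frame.
#' @export
shift_distribution <- function(atom_label, mu, sigma,
                               nucleus = infer_nucleus(atom_label),
                               source = "", lumped_with = "") {
  stopifnot(length(atom_label) == length(mu),
            length(mu) == length(sigma))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("sigma must be finite and > 0")
  }
  if (!all(nucleus %in% NUCLEI)) {
    stop("unknown nucleus: ", paste(setdiff(nucleus, NUCLEI), collapse = ", "))
  }
  if (is.list(lumped_with)) {
    lumped_with <- vapply(lumped_with, paste, "", collapse = ";")
  }
  d <- data.frame(atom_label = atom_label, nucleus = nucleus,
                  mu = mu, sigma = sigma,
                  source = source, lumped_with = lumped_with,
                  stringsAsFactors = FALSE)
  all_members <- unlist(lapply(seq_len(nrow(d)), function(i) {
    c(d$atom_label[i], strsplit(d$lumped_with[i], ";")[[1]])
  }))
  all_members <- all_members[nzchar(all_members)]
  if (anyDuplicated(all_members)) {
    stop("atom label(s) appear in more than one distribution: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  class(d) <- c("shift_distribution", "data.frame")
  d
}

#' Read / write a shift-distribution table
#'
#' CSV dialect: header `atom_label,nucleus,mu_ppm,sigma_ppm,source,lumped_with`
#' with `lumped_with` semicolon-separated. Lines starting with `#` are
#' provenance comments and are skipped on read.
#'
#' @param path file path.
#' @return [read_shift_distributions()] returns a `shift_distribution`
#'   data.frame; the writer returns `path` invisibly.
#' @export
read_shift_distributions <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("atom_label", "nucleus", "mu_ppm", "sigma_ppm")
  if (!all(need %in% names(d))) {
    stop("distribution table must have columns ",
         paste(need, collapse = ", "))
  }
  if (!"source" %in% names(d)) d$source <- ""
  if (!"lumped_with" %in% names(d)) d$lumped_with <- ""
  d$lumped_with[is.na(d$lumped_with)] <- ""
  shift_distribution(d$atom_label, as.numeric(d$mu_ppm),
                     as.numeric(d$sigma_ppm), d$nucleus,
                     d$source, d$lumped_with)
}

#' @rdname read_shift_distributions
#' @param dists a `shift_distribution` data.frame.
#' @param header optional character vector of provenance comment lines
#'   (written verbatim, prefixed with `#`).
#' @export
write_shift_distributions <- function(dists, path, header = NULL) {
  out <- data.frame(atom_label = dists$atom_label, nucleus = dists$nucleus,
                    mu_ppm = dists$mu, sigma_ppm = dists$sigma,
                    source = dists$source, lumped_with = dists$lumped_with)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-dimensional spectrum slice
#'
#' Carrier for a 1D spectrum (or a row/column extracted from a 2D
#' spectrum): a strictly monotone ppm axis with non-negative intensities.
#'
#' @param ppm numeric, strictly monotone axis (ascending or descending).
#' @param intensity numeric, same length, non-negative.
#' @return a `spectrum_slice` data.frame with ascending ppm.
#' @export
spectrum_slice <- function(ppm, intensity) {
  stopifnot(length(ppm) == length(intensity))
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  if (d[1] < 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  s <- data.frame(ppm = ppm, intensity = intensity)
  class(s) <- c("spectrum_slice", "data.frame")
  s
}

#' @rdname spectrum_slice
#' @param path two-column CSV (`ppm,intensity`), either axis direction.
#' @export
read_spectrum_slice <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  spectrum_slice(d[[1]], d[[2]])
}

# Sum-of-Gaussians model used by the peak fitter.
gaussian_sum <- function(x, amp, mu, sigma) {
  y <- numeric(length(x))
  for (k in seq_along(amp)) {
    y <- y + amp[k] * exp(-(x - mu[k])^2 / (2 * sigma[k]^2))
  }
  y
}

#' Fit Gaussian peaks to a spectrum slice
#'
#' Least-squares fit of a sum of `n_components` Gaussians to the intensity
#' inside a ppm window. Means are initialized at successive residual
#' argmaxima, widths at one quarter of the window width, amplitudes at the
#' local maximum intensity; the bounded Levenberg-Marquardt fit is retried
#' with deterministically jittered starting means (up to `max_restarts`
#' times) if it fails to converge.
#'
#' @param slice a [spectrum_slice()].
#' @param window numeric length-2 ppm interval.
#' @param n_components number of Gaussians (>= 1).
#' @param source spectrum identifier stored in the result.
#' @param max_restarts maximum jittered restarts after a failed fit.
#' @return a [shift_distribution()] table, one row per component ordered by
#'   `mu`, with attributes `amplitude` (numeric vector) and `residual`
#'   (residual sum of squares).
#' @export
fit_gaussian_peak <- function(slice, window, n_components = 1L,
                              source = "", max_restarts = 5L) {
  stopifnot(inherits(slice, "spectrum_slice"), length(window) == 2,
            n_components >= 1)
  window <- sort(window)
  sel <- slice$ppm >= window[1] & slice$ppm <= window[2]
  if (!any(sel)) stop("empty window: no axis points inside [",
                      window[1], ", ", window[2], "]")
  x <- slice$ppm[sel]; y <- slice$intensity[sel]
  if (!any(y > 0)) stop("empty window: no positive signal inside the window")
  width <- diff(range(x))
  if (width <= 0) stop("empty window: window narrower than the grid")
  grid_step <- min(diff(x))

  # peel-off initialization: argmax of the running residual
  mu0 <- numeric(n_components); amp0 <- numeric(n_components)
  sigma0 <- rep(width / 4, n_components)
  resid <- y
  for (k in seq_len(n_components)) {
    i <- which.max(resid)
    mu0[k] <- x[i]; amp0[k] <- max(resid[i], max(y) * 1e-3)
    resid <- resid - amp0[k] * exp(-(x - mu0[k])^2 / (2 * sigma0[k]^2))
  }

  # scalar parameters per component (bounded nlsLM needs scalar pars)
  k <- n_components
  pnames <- c(paste0("a", 1:k), paste0("m", 1:k), paste0("s", 1:k))
  terms <- paste0("a", 1:k, " * exp(-(x - m", 1:k, ")^2 / (2 * s", 1:k,
                  "^2))", collapse = " + ")
  form <- stats::as.formula(paste("y ~", terms))
  lower <- stats::setNames(c(rep(0, k), rep(window[1], k),
                             rep(grid_step / 2, k)), pnames)
  upper <- stats::setNames(c(rep(max(y) * 10, k), rep(window[2], k),
                             rep(width, k)), pnames)
  jitter_frac <- c(0, 0.05, -0.05, 0.1, -0.1, 0.2)

  fit <- NULL
  dat <- data.frame(x = x, y = y)
  for (r in seq_len(min(max_restarts, length(jitter_frac) - 1L) + 1L)) {
    mu_r <- pmin(pmax(mu0 + jitter_frac[r] * width, window[1]), window[2])
    start <- stats::setNames(as.list(c(amp0, mu_r, sigma0)), pnames)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("fit failed: no convergence after ", max_restarts,
         " restarts in window [", window[1], ", ", window[2], "]")
  }
  cf <- stats::coef(fit)
  amp <- cf[paste0("a", 1:k)]
  mu <- cf[paste0("m", 1:k)]
  sigma <- abs(cf[paste0("s", 1:k)])
  o <- order(mu)
  out <- shift_distribution(paste0("peak", seq_len(n_components)),
                            mu[o], sigma[o],
                            nucleus = rep("1H", n_components),
                            source = source)
  attr(out, "amplitude") <- unname(amp[o])
  attr(out, "residual") <- sum(stats::resid(fit)^2)
  out
}

#' Refine solution-state assignments to solid-state peaks
#'
#' Each solution-state shift is matched to the nearest solid-state peak of
#' the same nucleus (per-site independent matching, so two solution shifts
#' may map onto the same solid peak). Sites whose deviation exceeds
#' `max_deviation` for their nucleus are flagged `unassigned`.
#'
#' @param solution data.frame with columns `atom_label`, `shift` (ppm) and
#'   optionally `nucleus` (inferred from the label when absent).
#' @param solid_peaks named list, one numeric vector of solid-state peak
#'   positions (ppm) per nucleus.
#' @param max_deviation named numeric, ppm threshold per nucleus. Defaults
#'   to 1.0 for 1H and 5.0 for 13C and 15N.
#' @return an `assignment_table` data.frame with columns `atom_label`,
#'   `nucleus`, `solution_shift`, `solid_shift`, `deviation`, `status`,
#'   and attribute `summary` (assigned/unassigned counts per nucleus).
#' @export
refine_assignment <- function(solution, solid_peaks,
                              max_deviation = c("1H" = 1, "13C" = 5,
                                                "15N" = 5)) {
  stopifnot(is.data.frame(solution),
            all(c("atom_label", "shift") %in% names(solution)))
  if (!"nucleus" %in% names(solution)) {
    solution$nucleus <- infer_nucleus(solution$atom_label)
  }
  for (nuc in unique(solution$nucleus)) {
    pk <- solid_peaks[[nuc]]
    if (is.null(pk) || length(pk) == 0) {
      stop("no solid-state peaks supplied for nucleus ", nuc)
    }
  }
  n <- nrow(solution)
  solid <- dev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pk <- solid_peaks[[solution$nucleus[i]]]
    j <- which.min(abs(pk - solution$shift[i]))
    solid[i] <- pk[j]
    dev[i] <- abs(solution$shift[i] - pk[j])
  }
  maxdev <- max_deviation[solution$nucleus]
  maxdev[is.na(maxdev)] <- Inf
  status <- ifelse(dev <= maxdev, "assigned", "unassigned")
  solid[status == "unassigned"] <- NA_real_
  dev[status == "unassigned"] <- NA_real_
  out <- data.frame(atom_label = solution$atom_label,
                    nucleus = solution$nucleus,
                    solution_shift = solution$shift,
                    solid_shift = solid, deviation = dev,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("assignment_table", "data.frame")
  attr(out, "summary") <- as.data.frame(table(nucleus = out$nucleus,
                                              status = out$status))
  out
}
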