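# Bin index for histogram1d / correlation2d. Periodic binning places bin
# centres at multiples of bin_width on (-180, 180], so one wrap-around bin
# straddles +-180. Returns the index vector plus the edge/centre layout.
bin_layout <- function(values, bin_width, periodic, range = NULL) {
  if (periodic) {
    k <- 360 / bin_width
    if (abs(k - round(k)) > 1e-9) {
      stop("periodic bin_width must divide 360 degrees")
    }
    k <- as.integer(round(k))
    idx <- (floor((values + 180 + bin_width / 2) / bin_width)) %% k + 1L
    centers <- -180 + (seq_len(k) - 1L) * bin_width
    list(idx = idx, k = k, centers = centers,
         left = centers - bin_width / 2, right = centers + bin_width / 2)
  } else {
    if (is.null(range)) range <- range(values)
    lo <- floor(range[1] / bin_width) * bin_width
    hi <- ceiling(range[2] / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    edges <- seq(lo, hi, by = bin_width)
    k <- length(edges) - 1L
    idx <- findInterval(values, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    list(idx = idx, k = k, centers = centers,
         left = edges[-length(edges)], right = edges[-1])
  }
}

#' Histogram of one feature as a probability density
#'
#' Normalized so that `sum(density * bin_width) == 1`. Periodic histograms
#' (dihedrals) use bins centred at multiples of `bin_width` about 0 on
#' (-180, 180], with a single wrap-around bin straddling +-180 (reported
#' at centre -180).
#'
#' @param values numeric, non-empty.
#' @param bin_width bin width (degrees or Angstrom).
#' @param periodic treat values as angles on (-180, 180].
#' @param range optional numeric length-2 range for non-periodic data
#'   (rounded outward to bin multiples); defaults to the data range.
#' @return a `feature_histogram` data.frame with columns `bin_left`,
#'   `bin_right`, `center`, `count`, `density`; attributes `bin_width`,
#'   `periodic`, `n`.
#' @export
histogram1d <- function(values, bin_width, periodic = FALSE, range = NULL) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty values")
  L <- bin_layout(values, bin_width, periodic, range)
  counts <- tabulate(L$idx, nbins = L$k)
  h <- data.frame(bin_left = L$left, bin_right = L$right,
                  center = L$centers, count = counts,
                  density = counts / (length(values) * bin_width))
  class(h) <- c("feature_histogram", "data.frame")
  attr(h, "bin_width") <- bin_width
  attr(h, "periodic") <- periodic
  attr(h, "n") <- length(values)
  h
}

#' Promotion/demotion map between the MD and NMR sets
#'
#' Per-bin ratio of the NMR-set density to the MD-set density, classified
#' as promoted (ratio > `thresholds[1]`), demoted (ratio <
#' `thresholds[2]`) or unchanged. Bins with zero MD density are flagged
#' `"undefined"` (ratio NA) when the NMR set populates them, `"empty"`
#' when neither set does.
#'
#' @param md_hist,nmr_hist [histogram1d()] results on identical binning.
#' @param thresholds numeric length-2: promotion and demotion ratio cuts.
#' @return a `promotion_map` data.frame: `bin_left`, `bin_right`, `center`,
#'   `density_md`, `density_nmr`, `promotion`, `class`.
#' @export
promotion_map <- function(md_hist, nmr_hist, thresholds = c(1.25, 0.8)) {
  if (nrow(md_hist) != nrow(nmr_hist) ||
      any(abs(md_hist$bin_left - nmr_hist$bin_left) > 1e-9) ||
      !identical(attr(md_hist, "periodic"), attr(nmr_hist, "periodic"))) {
    stop("binning mismatch between MD and NMR histograms")
  }
  ratio <- ifelse(md_hist$density > 0,
                  nmr_hist$density / md_hist$density, NA_real_)
  cls <- rep("unchanged", nrow(md_hist))
  cls[!is.na(ratio) & ratio > thresholds[1]] <- "promoted"
  cls[!is.na(ratio) & ratio < thresholds[2]] <- "demoted"
  cls[is.na(ratio) & nmr_hist$density > 0] <- "undefined"
  cls[is.na(ratio) & nmr_hist$density == 0] <- "empty"
  out <- data.frame(bin_left = md_hist$bin_left,
                    bin_right = md_hist$bin_right,
                    center = md_hist$center,
                    density_md = md_hist$density,
                    density_nmr = nmr_hist$density,
                    promotion = ratio, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("promotion_map", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

#' Joint 2D density of two features
#'
#' Environments are paired positionally. The joint density is normalized
#' to unit integral over the grid, so marginalizing over either axis
#' (summing times the other bin width) reproduces the corresponding
#' [histogram1d()] exactly.
#'
#' @param values_a,values_b numeric vectors of equal length.
#' @param bin_width_a,bin_width_b bin widths.
#' @param periodic_a,periodic_b periodic flags per axis.
#' @param range_a,range_b optional ranges (non-periodic axes).
#' @return list with `centers_a`, `centers_b`, `edges_a`, `edges_b`,
#'   `density` (matrix, a x b), `counts`, and `n`.
#' @export
correlation2d <- function(values_a, values_b, bin_width_a, bin_width_b,
                          periodic_a = FALSE, periodic_b = FALSE,
                          range_a = NULL, range_b = NULL) {
  if (length(values_a) != length(values_b)) {
    stop("length mismatch between the two feature vectors")
  }
  ok <- is.finite(values_a) & is.finite(values_b)
  values_a <- values_a[ok]; values_b <- values_b[ok]
  if (!length(values_a)) stop("empty values")
  La <- bin_layout(values_a, bin_width_a, periodic_a, range_a)
  Lb <- bin_layout(values_b, bin_width_b, periodic_b, range_b)
  counts <- matrix(0L, La$k, Lb$k)
  tab <- table(factor(La$idx, levels = seq_len(La$k)),
               factor(Lb$idx, levels = seq_len(Lb$k)))
  counts[] <- as.integer(tab)
  list(centers_a = La$centers, centers_b = Lb$centers,
       edges_a = cbind(La$left, La$right),
       edges_b = cbind(Lb$left, Lb$right),
       counts = counts,
       density = counts / (length(values_a) * bin_width_a * bin_width_b),
       n = length(values_a))
}

#' Hydrogen-bond acceptor census over the MD and NMR sets
#'
#' For each donor and each set, the fraction of environments whose
#' detected acceptor class ([detect_hbond()]) equals each class, including
#' `"none"`. Fractions sum to 1 per donor per set.
#'
#' @param frames list of [new_frame()] objects.
#' @param md_ids,nmr_ids environment id vectors defining the two sets.
#' @param donors data.frame with columns `donor_h`, `donor_heavy` (one row
#'   per donor), or a character vector of length 2 for a single donor.
#' @param criterion an [hbond_criterion()].
#' @param class_map optional intermolecular label -> class map.
#' @return an `hbond_census` data.frame: `donor_h`, `acceptor_class`,
#'   `fraction_md`, `fraction_nmr`.
#' @export
hbond_census <- function(frames, md_ids, nmr_ids, donors,
                         criterion = hbond_criterion(), class_map = NULL) {
  if (is.character(donors)) {
    donors <- data.frame(donor_h = donors[1], donor_heavy = donors[2])
  }
  out <- list()
  for (i in seq_len(nrow(donors))) {
    spec <- feature_spec("hbond",
                         c(donors$donor_h[i], donors$donor_heavy[i]))
    cls <- feature_values(frames, spec, criterion, class_map)
    classes <- sort(unique(cls))
    if (!"none" %in% classes) classes <- c(classes, "none")
    fr_md <- table(factor(cls[md_ids], levels = classes)) / length(md_ids)
    fr_nmr <- table(factor(cls[nmr_ids], levels = classes)) / length(nmr_ids)
    out[[i]] <- data.frame(donor_h = donors$donor_h[i],
                           acceptor_class = classes,
                           fraction_md = as.numeric(fr_md),
                           fraction_nmr = as.numeric(fr_nmr),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("hbond_census", "data.frame")
  res
}

#' Write a paired histogram with promotion ratios
#'
#' @param pm a [promotion_map()].
#' @param path output CSV
#'   (`bin_left,bin_right,center,density_md,density_nmr,promotion,class`).
#' @param header optional provenance comment lines.
#' @export
write_histogram <- function(pm, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(as.data.frame(pm), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
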