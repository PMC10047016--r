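#' Intensity-weighted center of mass
#'
#' Computes the intensity-weighted mean pixel coordinate of an image over a
#' mask (typically the rasterized hand-drawn contour of the finding on the
#' density image). Coordinates are continuous, 0-based `(row, col)` with
#' pixel centers at integers.
#'
#' @param image non-negative intensity matrix
#' @param mask logical matrix of the same shape, or NULL for the whole image
#' @return named numeric `c(row, col)`
#' @export
center_of_mass <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(image), dim(mask)))
  w <- image * mask
  total <- sum(w)
  if (total <= 0)
    stop("degenerate input: masked intensity sums to zero", call. = FALSE)
  rows <- (seq_len(nrow(image)) - 1)
  cols <- (seq_len(ncol(image)) - 1)
  c(row = sum(rowSums(w) * rows) / total,
    col = sum(colSums(w) * cols) / total)
}

#' Radial distribution histogram of image intensity
#'
#' The core imaging feature: concentric equal-width bands are laid around a
#' center point and the intensity in each band is summed, divided by the
#' band's empirical pixel area (which handles clipping at the image border),
#' and finally rescaled to unit sum, yielding the normalized per-area mass of
#' intensity as a function of distance from the center.
#'
#' By default the outermost band edge is the distance from the center to the
#' farthest image corner, so every image yields the same number of bands
#' regardless of where the center falls (relative-radius bands). Fixed-width
#' bands in pixel units are available via `band_width`; pixels beyond the
#' last fixed edge fall in the last band.
#'
#' @param image non-negative intensity matrix
#' @param center `c(row, col)`, 0-based, inside the image
#' @param n_bands number of concentric bands (>= 2)
#' @param band_width optional fixed band width in pixels; NULL (default) uses
#'   relative-radius bands spanning to the farthest corner
#' @param normalize `"area_unit"` (area-normalize then rescale to unit sum,
#'   the default) or `"area"` (area-normalize only)
#' @param mask optional logical matrix restricting the support to the
#'   contoured region; default uses the full rectangular ROI
#' @param channel tag stored on the result (`"density"`/`"contrast"`/other)
#' @return object of class `radial_histogram`: `values` (length `n_bands`),
#'   `band_edges` (length `n_bands + 1`), `band_mass` (raw per-band summed
#'   intensity), `band_area` (pixel counts), `center`, `channel`,
#'   `total_mass` (raw summed intensity before any normalization)
#' @export
radial_histogram <- function(image, center, n_bands = 32, band_width = NULL,
                             normalize = c("area_unit", "area"),
                             mask = NULL, channel = "density") {
  normalize <- match.arg(normalize)
  nr <- nrow(image); nc <- ncol(image)
  if (n_bands < 2) stop("n_bands must be >= 2", call. = FALSE)
  if (center[1] < 0 || center[1] > nr - 1 ||
      center[2] < 0 || center[2] > nc - 1)
    stop("center lies outside the image", call. = FALSE)

  dr <- (seq_len(nr) - 1) - center[1]
  dc <- (seq_len(nc) - 1) - center[2]
  r <- sqrt(outer(dr^2, dc^2, `+`))

  if (is.null(band_width)) {
    r_max <- sqrt(max(dr^2) + max(dc^2))
    if (n_bands > r_max)
      stop("n_bands exceeds the radial extent in pixels; bands would be ",
           "narrower than one pixel", call. = FALSE)
    edges <- seq(0, r_max, length.out = n_bands + 1)
  } else {
    stopifnot(band_width > 0)
    edges <- (0:n_bands) * band_width
  }

  keep <- if (is.null(mask)) rep(TRUE, length(r)) else {
    stopifnot(identical(dim(mask), dim(image)))
    as.vector(mask)
  }
  # half-open bands [e_b, e_{b+1}); last band closed; distances past the last
  # edge (fixed-width mode only) clamp into the last band
  bin <- findInterval(as.vector(r)[keep], edges, all.inside = TRUE)
  int <- as.vector(image)[keep]

  band_area <- tabulate(bin, nbins = n_bands)
  band_mass <- numeric(n_bands)
  bm <- rowsum(int, bin)
  band_mass[as.integer(rownames(bm))] <- bm[, 1]
  total_mass <- sum(int)

  values <- numeric(n_bands)
  nz <- band_area > 0
  if (!all(nz))
    warning(sum(!nz), " empty band(s) set to 0", call. = FALSE)
  values[nz] <- band_mass[nz] / band_area[nz]
  if (normalize == "area_unit") {
    vs <- sum(values)
    if (vs <= 0)
      stop("degenerate input: image has no intensity in any band",
           call. = FALSE)
    values <- values / vs
  }
  structure(list(values = values, band_edges = edges,
                 band_mass = band_mass, band_area = band_area,
                 center = center, channel = channel,
                 total_mass = total_mass),
            class = "radial_histogram")
}

#' @export
print.radial_histogram <- function(x, ...) {
  cat(sprintf("Radial histogram (%s): %d bands to r = %.1f px, total mass %.4g\n",
              x$channel, length(x$values), max(x$band_edges), x$total_mass))
  invisible(x)
}

#' Concatenate density and contrast radial histograms
#'
#' Joins the two channel histograms of one finding into a single feature
#' vector, density block first, without renormalizing across blocks (each
#' block keeps unit sum).
#'
#' @param h_density,h_contrast `radial_histogram` objects with equal band
#'   counts
#' @return numeric vector of length `2 * n_bands`
#' @export
concatenate_histograms <- function(h_density, h_contrast) {
  stopifnot(inherits(h_density, "radial_histogram"),
            inherits(h_contrast, "radial_histogram"))
  b <- length(h_density$values)
  if (b != length(h_contrast$values))
    stop("band counts differ: ", b, " vs ", length(h_contrast$values),
         call. = FALSE)
  stats::setNames(c(h_density$values, h_contrast$values),
                  c(paste0("d", seq_len(b)), paste0("c", seq_len(b))))
}

#' Per-class mean radial profiles
#'
#' Unweighted per-band mean of the normalized radial histograms within each
#' class, e.g. the mean benign and mean malignant profiles used to compare
#' central concentration between groups.
#'
#' @param histograms list of `radial_histogram` objects (or a numeric matrix
#'   with one histogram per row)
#' @param labels binary vector (0/1, logical, or 2-level factor) per histogram
#' @return matrix with two rows (named by label level) and one column per band
#' @export
class_average_profile <- function(histograms, labels) {
  mat <- if (is.matrix(histograms)) histograms else
    do.call(rbind, lapply(histograms, `[[`, "values"))
  f <- as.factor(labels)
  if (nlevels(f) != 2L || any(table(f) < 1L))
    stop("need at least one histogram in each of exactly two classes",
         call. = FALSE)
  out <- rbind(colMeans(mat[f == levels(f)[1], , drop = FALSE]),
               colMeans(mat[f == levels(f)[2], , drop = FALSE]))
  rownames(out) <- levels(f)
  out
}

#' Radial feature matrices for a set of cases
#'
#' Runs the full feature chain for each case: rasterize the contour, compute
#' the center of mass on the contour-masked density image, and build the
#' density and contrast radial histograms around that shared center (the
#' density-derived center is reused for the contrast channel, as the two CEM
#' channels are co-registered). Returns per-channel matrices and their
#' column-wise concatenation.
#'
#' @param cases list of cases (`cem_case` or `synthetic_cohort$cases` entries)
#' @param n_bands bands per channel
#' @param normalize,band_width,support passed through to [radial_histogram()];
#'   `support` is `"full"` (whole rectangular ROI, default) or `"contour"`
#'   (restrict the histogram to the contour mask)
#' @return list with `density`, `contrast` (n x B matrices), `concatenated`
#'   (n x 2B), `centers` (n x 2), and `histograms` (per-case list)
#' @export
cohort_features <- function(cases, n_bands = 32,
                            normalize = "area_unit", band_width = NULL,
                            support = c("full", "contour")) {
  support <- match.arg(support)
  n <- length(cases)
  stopifnot(n >= 1L)
  hists <- vector("list", n)
  centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n)) {
    cs <- cases[[i]]
    msk <- rasterize_contour(cs$contour, dim(cs$density_image))
    ctr <- center_of_mass(cs$density_image, msk)
    hmask <- if (support == "contour") msk else NULL
    hd <- radial_histogram(cs$density_image, ctr, n_bands,
                           band_width = band_width, normalize = normalize,
                           mask = hmask, channel = "density")
    hc <- radial_histogram(cs$contrast_image, ctr, n_bands,
                           band_width = band_width, normalize = normalize,
                           mask = hmask, channel = "contrast")
    hists[[i]] <- list(density = hd, contrast = hc)
    centers[i, ] <- ctr
  }
  density <- do.call(rbind, lapply(hists, function(h) h$density$values))
  contrast <- do.call(rbind, lapply(hists, function(h) h$contrast$values))
  colnames(density) <- paste0("d", seq_len(n_bands))
  colnames(contrast) <- paste0("c", seq_len(n_bands))
  list(density = density, contrast = contrast,
       concatenated = cbind(density, contrast),
       centers = centers, histograms = hists)
}
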