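#' Radial distance from the pore centre
#'
#' `r = sqrt((x - x_c)^2 + (y - y_c)^2)`. No periodic wrapping is applied:
#' distances are measured in the unwrapped analysis frame (the pore is
#' centred and the displayed range stays inside the box).
#'
#' @param com numeric vector `c(x, y)` or an n x 2 matrix of positions
#'   (nm).
#' @param center pore centre `c(x_c, y_c)` (nm).
#' @return numeric vector of radial distances (nm).
#' @examples
#' radial_distance(c(19, 24), c(16, 20))  # 3-4-5 triangle -> 5
#' @export
radial_distance <- function(com, center) {
  if (is.null(dim(com))) com <- matrix(com, ncol = 2)
  if (any(!is.finite(com)) || any(!is.finite(center)))
    stopf("radial_distance requires finite inputs")
  sqrt((com[, 1] - center[1])^2 + (com[, 2] - center[2])^2)
}

#' Pool radial distances from traces or frames
#'
#' `trace_radii()` pools the per-frame radial distances of protein
#' centre-of-mass traces; `frame_radii()` pools the radial distances of
#' a bead species (optionally restricted by leaflet) over frames. Both
#' feed [radial_histogram()].
#'
#' @param traces a `protein_trace` or list of them.
#' @param frames a [bead_frame()] or list of them.
#' @param center pore centre (x_c, y_c) nm.
#' @param discard_frames drop trace frames with `time` below this value
#'   (equilibration window).
#' @param species bead species to pool.
#' @param leaflet optional leaflet filter.
#' @return numeric vector of radial distances (nm).
#' @export
trace_radii <- function(traces, center, discard_frames = 0) {
  if (inherits(traces, "protein_trace")) traces <- list(traces)
  unlist(lapply(traces, function(tr) {
    if (discard_frames > 0) tr <- tr[tr$time >= discard_frames, ]
    radial_distance(cbind(tr$x, tr$y), center)
  }))
}

#' @rdname trace_radii
#' @export
frame_radii <- function(frames, center, species, leaflet = NULL) {
  if (inherits(frames, "bead_frame")) frames <- list(frames)
  unlist(lapply(frames, function(f) {
    i <- f$species %in% species
    if (!is.null(leaflet)) i <- i & f$leaflet %in% leaflet
    radial_distance(cbind(f$x[i], f$y[i]), center)
  }))
}

#' Radial probability histogram
#'
#' Histogram of radial distances over `n_bins` equally spaced bins
#' (default 100 bins between 0 and 25 nm). Densities are frequencies and
#' sum to exactly 1 over all bins; out-of-range points are counted and
#' reported via the `n_outside` attribute, never silently dropped.
#'
#' @param radii numeric vector of radial distances (nm), e.g. from
#'   protein traces or lipid headgroups.
#' @param n_bins number of bins.
#' @param r_range bin range (nm).
#' @param species label stored on the result.
#' @return a `radial_distribution` data frame with columns `bin_lo`,
#'   `bin_hi`, `r` (bin centre), `count`, `density`; attributes
#'   `normalization = "probability"`, `n_total`, `n_outside`.
#' @export
radial_histogram <- function(radii, n_bins = 100, r_range = c(0, 25),
                             species = "protein") {
  radii <- as.numeric(radii)
  if (length(radii) == 0) stopf("empty input: no radii to histogram")
  edges <- seq(r_range[1], r_range[2], length.out = n_bins + 1)
  inside <- radii >= r_range[1] & radii <= r_range[2]
  if (!any(inside))
    stopf("all %d points fall outside [%g, %g] nm", length(radii),
          r_range[1], r_range[2])
  cnt <- tabulate(findInterval(radii[inside], edges,
                               rightmost.closed = TRUE), nbins = n_bins)
  structure(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       r = (edges[-length(edges)] + edges[-1]) / 2,
                       count = cnt, density = cnt / sum(cnt)),
            normalization = "probability", species = species,
            n_total = sum(cnt), n_outside = sum(!inside),
            r_range = r_range,
            class = c("radial_distribution", "data.frame"))
}

# Area of {(x,y): x^2+y^2 <= r^2, 0 <= x <= w, 0 <= y <= h} for w,h >= 0.
quadrant_area <- function(r, w, h) {
  if (r <= 0 || w <= 0 || h <= 0) return(0)
  w <- min(w, r); h <- min(h, r)
  if (w^2 + h^2 <= r^2) return(w * h)   # rectangle corner inside circle
  x1 <- sqrt(r^2 - h^2)                 # arc crosses y = h at x1 <= w
  Fint <- function(x) (x * sqrt(r^2 - x^2) + r^2 * asin(x / r)) / 2
  x1 * h + (Fint(w) - Fint(x1))
}

#' Exact circle / box intersection areas
#'
#' `circle_rect_area()` is the area of a disc of radius `r` centred at
#' `center` intersected with the box `[0, Lx] x [0, Ly]`;
#' `annulus_clipped_area()` the corresponding annulus area. Both are
#' analytic (sums of clipped quadrant areas), not sampled; they are what
#' makes the RDF "uniform occupancy = 1" convention exact out to radii
#' where annuli extend beyond the box.
#'
#' @param r,r_lo,r_hi radii (nm).
#' @param center circle centre (nm).
#' @param box box vectors (only x and y are used) (nm).
#' @return area in nm^2.
#' @export
circle_rect_area <- function(r, center, box) {
  quadrant_area(r, box[1] - center[1], box[2] - center[2]) +
    quadrant_area(r, box[1] - center[1], center[2]) +
    quadrant_area(r, center[1], box[2] - center[2]) +
    quadrant_area(r, center[1], center[2])
}

#' @rdname circle_rect_area
#' @export
annulus_clipped_area <- function(r_lo, r_hi, center, box) {
  circle_rect_area(r_hi, center, box) - circle_rect_area(r_lo, center, box)
}

#' Normalize a radial histogram to a radial distribution function
#'
#' Converts per-bin counts to an RDF: each bin's count is divided by its
#' annular area (clipped analytically to the box where the annulus
#' extends beyond the edges) and by the species' global area density
#' (`total_count / reference_area`). A uniformly distributed species then
#' reads RDF = 1 in every bin — the "bulk" convention; enrichment reads
#' above 1 and depletion below. Bins beyond half the shortest box vector
#' in xy are still computed but flagged `displayed = FALSE`.
#'
#' @param hist a probability-mode [radial_histogram()].
#' @param center pore centre (nm).
#' @param box box vectors (nm).
#' @param total_count total number of observations of the species over
#'   the whole box (defaults to in-range + out-of-range counts of
#'   `hist`).
#' @param reference_area reference membrane area (nm^2); defaults to the
#'   full box xy area.
#' @return a `radial_distribution` with `normalization = "rdf"`, an added
#'   `displayed` column and attribute `r_max_display`.
#' @export
rdf_normalize <- function(hist, center, box, total_count = NULL,
                          reference_area = NULL) {
  stopifnot(inherits(hist, "radial_distribution"))
  if (!identical(attr(hist, "normalization"), "probability"))
    stopf("rdf_normalize expects a probability-mode histogram")
  total_count <- total_count %||%
    (attr(hist, "n_total") + attr(hist, "n_outside"))
  reference_area <- reference_area %||% (box[1] * box[2])
  if (total_count <= 0 || reference_area <= 0)
    stopf("total_count and reference_area must be positive")
  area <- mapply(annulus_clipped_area, hist$bin_lo, hist$bin_hi,
                 MoreArgs = list(center = center, box = box))
  dens0 <- total_count / reference_area
  out <- hist
  out$area <- area
  out$density <- ifelse(area > 0, out$count / area / dens0, NA_real_)
  r_disp <- min(box[1], box[2]) / 2
  out$displayed <- out$bin_hi <= r_disp + 1e-9
  attr(out, "normalization") <- "rdf"
  attr(out, "r_max_display") <- r_disp
  attr(out, "dens0") <- dens0
  out
}

#' Protein centre-of-mass heatmap
#'
#' Bins `|x - x_c|` and `|y - y_c|` on a 50 x 50 grid over `[0, 16]` x
#' `[0, 20]` nm (absolute distances from the pore centre). Frequencies
#' sum to 1; out-of-range points are counted and reported.
#'
#' @param traces a `protein_trace`, a list of them, or an n x 2 xy
#'   matrix.
#' @param center pore centre (nm).
#' @param n_grid grid size per axis.
#' @param x_limits,y_limits absolute-distance limits (nm).
#' @return a `heatmap2d` object: `n_grid x n_grid` matrix of frequencies
#'   with attributes `x_limits`, `y_limits`, `n_outside`.
#' @export
com_heatmap <- function(traces, center, n_grid = 50,
                        x_limits = c(0, 16), y_limits = c(0, 20)) {
  xy <- if (is.matrix(traces)) traces else {
    if (inherits(traces, "protein_trace")) traces <- list(traces)
    do.call(rbind, lapply(traces, function(tr) cbind(tr$x, tr$y)))
  }
  if (is.null(xy) || nrow(xy) == 0) stopf("empty input: no frames")
  ax <- abs(xy[, 1] - center[1]); ay <- abs(xy[, 2] - center[2])
  inside <- ax >= x_limits[1] & ax <= x_limits[2] &
    ay >= y_limits[1] & ay <= y_limits[2]
  if (!any(inside)) stopf("all points fall outside the heatmap limits")
  xe <- seq(x_limits[1], x_limits[2], length.out = n_grid + 1)
  ye <- seq(y_limits[1], y_limits[2], length.out = n_grid + 1)
  ix <- findInterval(ax[inside], xe, rightmost.closed = TRUE)
  iy <- findInterval(ay[inside], ye, rightmost.closed = TRUE)
  m <- matrix(tabulate(ix + (iy - 1L) * n_grid, nbins = n_grid^2),
              nrow = n_grid)
  structure(m / sum(m), x_limits = x_limits, y_limits = y_limits,
            n_outside = sum(!inside), class = "heatmap2d")
}

#' Gaussian kernel density estimate of radial data
#'
#' KDE of the raw radial sample with Scott's-rule bandwidth
#' `sd(x) * n^(-1/5)` (overridable), evaluated on a grid wide enough
#' that the curve integrates to 1 within 1e-3.
#'
#' @param radii numeric sample of radial distances (nm).
#' @param bw bandwidth (nm); default Scott's rule.
#' @param n evaluation grid size.
#' @return data frame `r`, `density` with attribute `bw`.
#' @export
radial_kde <- function(radii, bw = NULL, n = 2048) {
  radii <- as.numeric(radii)
  if (length(unique(radii)) < 2)
    stopf(paste("degenerate sample (fewer than 2 distinct values):",
                "no data-driven bandwidth exists; supply `bw` explicitly",
                "or provide a spread-out sample"))
  bw <- bw %||% (sd(radii) * length(radii)^(-1 / 5))
  d <- density(radii, bw = bw, n = n,
               from = min(radii) - 5 * bw, to = max(radii) + 5 * bw)
  structure(data.frame(r = d$x, density = d$y), bw = bw)
}

#' Locate the peak of a radial distribution
#'
#' Argmax bin centre of the density, with the curvature-region label at
#' that radius. Ties are broken toward smaller r and reported; a flat
#' distribution (max = min), or one whose maximum does not exceed
#' `min_excess` above the bulk level, raises the `no_peak` flag.
#'
#' @param rdf a `radial_distribution` (probability or rdf mode).
#' @param regions a curvature profile from [curvature_and_roc()] (or any
#'   data frame with `r` and `region`), used to label the peak radius.
#' @param min_excess require `max(density) > 1 + min_excess` (rdf mode
#'   only) before calling a peak; default 0 reproduces the bare argmax.
#' @param displayed_only restrict the search to displayed bins (rdf
#'   mode).
#' @param smooth_bins pool counts and annulus areas over a centred
#'   window of this many bins before taking the argmax (rdf mode only;
#'   default 1 = no pooling). Pooling suppresses shot noise from
#'   tiny-area annuli near the pore centre without biasing a uniform
#'   distribution, because counts and areas are pooled together.
#' @return list with `peak_r`, `region`, `tie`, `no_peak`.
#' @export
peak_location <- function(rdf, regions = NULL, min_excess = 0,
                          displayed_only = TRUE, smooth_bins = 1) {
  stopifnot(inherits(rdf, "radial_distribution"))
  d <- rdf
  if (displayed_only && !is.null(d$displayed)) d <- d[d$displayed, ]
  dens <- d$density
  if (smooth_bins > 1 && !is.null(d$area)) {
    k <- rep(1, smooth_bins)
    cs <- as.numeric(stats::filter(d$count, k, sides = 2))
    as <- as.numeric(stats::filter(d$area, k, sides = 2))
    pooled <- cs / as / attr(rdf, "dens0")
    dens <- ifelse(is.na(pooled), dens, pooled)
  }
  flat <- diff(range(dens, na.rm = TRUE)) < 1e-12
  low <- identical(attr(rdf, "normalization"), "rdf") &&
    max(dens, na.rm = TRUE) <= 1 + min_excess
  if (flat || low)
    return(list(peak_r = NA_real_, region = NA_character_,
                tie = FALSE, no_peak = TRUE))
  hit <- which(dens == max(dens, na.rm = TRUE))
  peak_r <- d$r[hit[1]]
  region <- NA_character_
  if (!is.null(regions)) {
    j <- which.min(abs(regions$r - peak_r))
    region <- as.character(regions$region[j])
  }
  list(peak_r = peak_r, region = region, tie = length(hit) > 1,
       no_peak = FALSE)
}
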