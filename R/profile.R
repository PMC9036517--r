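#' Radially averaged membrane height profile
#'
#' Per-annulus mean z of top-leaflet PC headgroup beads versus annulus
#' mid-radius, pooled over frames. Empty annuli are flagged (`n = 0`,
#' `height = NA`), never interpolated.
#'
#' @param frames a [bead_frame()] or list of them.
#' @param center pore centre (x_c, y_c) nm.
#' @param bin_width annulus width (nm).
#' @param r_max outermost radius (nm).
#' @param species headgroup species averaged (default PC only, as in the
#'   standard readout).
#' @return data frame `r` (bin centres), `height` (nm), `n` (bead count),
#'   `empty`.
#' @export
radial_height_profile <- function(frames, center, bin_width = 0.5,
                                  r_max = 25, species = "PC_head") {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  if (inherits(frames, "bead_frame")) frames <- list(frames)
  pool <- do.call(rbind, lapply(frames, function(f) {
    i <- f$species %in% species & f$leaflet == "top"
    data.frame(r = radial_distance(cbind(f$x[i], f$y[i]), center),
               z = f$z[i])
  }))
  if (is.null(pool) || nrow(pool) == 0)
    stopf("empty selection: no top-leaflet %s beads in the input",
          paste(species, collapse = "/"))
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  bin <- findInterval(pool$r, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin < length(edges)
  n <- tabulate(bin[keep], nbins = length(edges) - 1)
  zsum <- vapply(seq_len(length(edges) - 1), function(b)
    sum(pool$z[keep][bin[keep] == b]), 0)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
             height = ifelse(n > 0, zsum / pmax(n, 1), NA_real_),
             n = n, empty = n == 0)
}

# deterministic initial guess: plateaus -> a, d; steepest point -> x0;
# max slope of a logistic is b*d/4 -> b; asymmetry exponent starts at 1
sigmoid_start <- function(r, h) {
  n <- length(r)
  k <- max(2, floor(n / 5))
  a0 <- mean(head(h, k)); hi0 <- mean(tail(h, k))
  d0 <- hi0 - a0
  g <- diff(h) / diff(r)
  j <- which.max(abs(g))
  x00 <- (r[j] + r[j + 1]) / 2
  b0 <- if (abs(d0) > 1e-12) 4 * max(abs(g)) / abs(d0) * sign(d0) *
    sign(g[j]) else 1
  list(a = a0, b = abs(b0), c = 1,
       d = if (sign(g[j]) >= 0) abs(d0) else -abs(d0), x0 = x00)
}

#' Fit the sigmoid membrane model to a height profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) estimate of the
#' parameters (a, b, c, d, x0) of [surface_height()]. The initial guess
#' is deterministic: plateau means give `a` and `d`, the steepest-descent
#' radius gives `x0`, the plateau gap and transition width give `b`, and
#' `c` starts at 1. A constant profile short-circuits to the exact flat
#' limit (`d = 0`). Because the parametrization is not always unique, the
#' contract is on function values: the returned fit's residual sum of
#' squares never exceeds that of the initial guess.
#'
#' @param profile data frame from [radial_height_profile()] (columns `r`,
#'   `height`; empty bins are dropped).
#' @param initial_guess optional named list/vector (a, b, c, d, x0).
#' @return an object of class `sigmoid_fit`: list with `params`,
#'   `covariance` (5 x 5 or NA for the flat shortcut), `rss`, `n_points`,
#'   `converged`, `flat`, `message`.
#' @export
fit_sigmoid <- function(profile, initial_guess = NULL) {
  ok <- is.finite(profile$height)
  r <- profile$r[ok]; h <- profile$height[ok]
  if (length(r) < 5)
    stopf("need >= 5 non-empty profile points for identifiability, got %d",
          length(r))
  if (diff(range(h)) < 1e-8) {
    p <- c(a = mean(h), b = 1, c = 1, d = 0, x0 = mean(r))
    return(new_sigmoid_fit(p, matrix(NA_real_, 5, 5),
                           sum((h - mean(h))^2), length(r),
                           converged = TRUE, flat = TRUE,
                           message = "flat profile shortcut"))
  }
  start <- as.list(initial_guess %||% sigmoid_start(r, h))[c("a", "b", "c",
                                                             "d", "x0")]
  rss_of <- function(p) sum((h - surface_height(r, p))^2)
  starts <- list(start,
                 utils::modifyList(start, list(x0 = unname(quantile(r, .25)))),
                 utils::modifyList(start, list(x0 = unname(quantile(r, .75)))),
                 utils::modifyList(start, list(b = start$b / 4)))
  best <- NULL; msgs <- character()
  for (s in starts) {
    fit <- try(suppressWarnings(
      nlsLM(h ~ a + d * (1 + exp(-b * (r - x0)))^(-c),
            start = s, control = nls.lm.control(maxiter = 500))),
      silent = TRUE)
    if (inherits(fit, "try-error")) {
      msgs <- c(msgs, attr(fit, "condition")$message)
      next
    }
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
    if (rss <= rss_of(start) + 1e-12) break
  }
  if (is.null(best))
    stopf("sigmoid fit failed to converge from %d starts: %s",
          length(starts), paste(unique(msgs), collapse = "; "))
  p <- coef(best$fit)[c("a", "b", "c", "d", "x0")]
  covm <- try(vcov(best$fit), silent = TRUE)
  if (inherits(covm, "try-error")) covm <- matrix(NA_real_, 5, 5)
  if (best$rss > rss_of(start)) {
    # never return worse than the deterministic start
    p <- unlist(start); best$rss <- rss_of(start)
    covm <- matrix(NA_real_, 5, 5)
  }
  new_sigmoid_fit(p, covm, best$rss, length(r), converged = TRUE,
                  flat = FALSE, message = "converged")
}

new_sigmoid_fit <- function(params, covariance, rss, n_points, converged,
                            flat, message) {
  stopifnot(all(is.finite(params)))
  structure(list(params = setNames(as.numeric(params),
                                   c("a", "b", "c", "d", "x0")),
                 covariance = covariance, rss = rss,
                 n_points = as.integer(n_points), converged = converged,
                 flat = flat, message = message),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("sigmoid_fit:", x$message, "\n")
  print(round(x$params, 5))
  cat(sprintf("  rss = %.4g nm^2 over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, r, ...) {
  surface_height(r, object$params)
}

#' Curvature and radius of curvature along the membrane
#'
#' Evaluates the analytic first and second derivatives of the fitted
#' sigmoid (generated symbolically, never finite-differenced) and forms
#' the plane-curve curvature
#' \deqn{K = f'' / (1 + f'^2)^{3/2}, \qquad RoC = 1 / |K|}
#' with flat points mapped to `RoC = Inf`. Sign convention, fixed
#' package-wide: K > 0 where the membrane curves toward the
#' solvent-exposed side (the concave bowl as seen by the protein); K < 0
#' on the convex shoulder.
#'
#' @param fit a [fit_sigmoid()] result (or a named parameter vector).
#' @param r_grid radii at which to evaluate (nm).
#' @param flat_threshold |K| below which a point is labelled `flat`
#'   (nm^-1); the default 0.01 counts RoC > 100 nm as flat.
#' @return a `curvature_profile` data frame: `r`, `height`, `f_prime`,
#'   `f_double_prime`, `K` (nm^-1), `RoC` (nm, unsigned), `region` in
#'   concave/convex/flat.
#' @export
curvature_and_roc <- function(fit, r_grid, flat_threshold = 0.01) {
  p <- if (inherits(fit, "sigmoid_fit")) fit$params else fit
  f1 <- surface_deriv1(r_grid, p)
  f2 <- surface_deriv2(r_grid, p)
  K <- f2 / (1 + f1^2)^1.5
  out <- data.frame(r = r_grid, height = surface_height(r_grid, p),
                    f_prime = f1, f_double_prime = f2, K = K,
                    RoC = ifelse(K == 0, Inf, 1 / abs(K)),
                    region = ifelse(abs(K) < flat_threshold, "flat",
                                    ifelse(K > 0, "concave", "convex")))
  attr(out, "flat_threshold") <- flat_threshold
  attr(out, "params") <- p
  class(out) <- c("curvature_profile", "data.frame")
  out
}

#' Contiguous curvature bands and summary radii
#'
#' Splits a [curvature_and_roc()] profile into contiguous
#' concave/convex/flat bands and reports the most-concave and
#' most-convex radii.
#'
#' @param profile a `curvature_profile`.
#' @return list with `bands` (data frame `region`, `r_start`, `r_end`),
#'   `most_concave_r` (argmax K; NA if never concave), `most_convex_r`
#'   (argmin K; NA if never convex).
#' @export
classify_regions <- function(profile) {
  stopifnot(inherits(profile, "curvature_profile"))
  reg <- as.character(profile$region)
  runs <- rle(reg)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  bands <- data.frame(region = runs$values,
                      r_start = profile$r[starts],
                      r_end = profile$r[ends])
  list(bands = bands,
       most_concave_r = if (any(reg == "concave"))
         profile$r[which.max(profile$K)] else NA_real_,
       most_convex_r = if (any(reg == "convex"))
         profile$r[which.min(profile$K)] else NA_real_)
}

#' Export a curvature profile as a delimited table
#'
#' @param profile a `curvature_profile`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_curvature_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
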