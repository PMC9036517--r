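test_that("radial distance matches the closed form and a scalar loop", {
  expect_equal(radial_distance(c(16, 20), c(16, 20)), 0)
  expect_equal(radial_distance(c(19, 24), c(16, 20)), 5)
  xy <- with_test_seed(7, matrix(runif(400, -10, 40), ncol = 2))
  loop <- vapply(seq_len(nrow(xy)), function(i)
    sqrt((xy[i, 1] - 16)^2 + (xy[i, 2] - 20)^2), 0)
  expect_lt(max(abs(radial_distance(xy, c(16, 20)) - loop)), 1e-12)
  expect_error(radial_distance(c(NA, 1), c(0, 0)), "finite")
})

test_that("radial histograms are exact probability distributions", {
  h <- radial_histogram(with_test_seed(1, runif(5000, 0, 28)))
  expect_lt(abs(sum(h$density) - 1), 1e-12)
  expect_equal(attr(h, "n_outside"),
               sum(with_test_seed(1, runif(5000, 0, 28)) > 25))
  one <- radial_histogram(rep(12.1, 40))
  expect_equal(sum(one$density > 0), 1)
  expect_equal(one$r[one$density > 0], 12.125)
  two <- radial_histogram(c(3, 23))
  expect_equal(sort(two$density[two$density > 0]), c(0.5, 0.5))
  expect_error(radial_histogram(numeric(0)), "empty")
  expect_error(radial_histogram(c(30, 40)), "outside")
})

test_that("heatmaps are normalized, folded and bounds-checked", {
  m <- com_heatmap(matrix(c(18, 21), ncol = 2), c(16, 20))
  expect_equal(sum(m), 1)
  expect_equal(sum(m == 1), 1)
  # symmetric cloud about the centre: folding makes reflections identical
  xy <- with_test_seed(3, matrix(runif(4000, 0, 10), ncol = 2))
  cloud <- rbind(sweep(xy, 2, c(16, 20), "+"),
                 sweep(-xy, 2, c(16, 20), "+"))
  expect_identical(com_heatmap(cloud, c(16, 20)),
                   com_heatmap(sweep(xy, 2, c(16, 20), "+"), c(16, 20)))
  # uniform points: per-cell frequency within 5 SD of 1/2500
  u <- with_test_seed(4, cbind(runif(1e5, 0, 32), runif(1e5, 0, 40)))
  mu <- com_heatmap(u, c(16, 20))
  sd_cell <- sqrt(1e5 * (1 / 2500) * (1 - 1 / 2500)) / 1e5
  expect_lt(max(abs(mu - 1 / 2500)), 5 * sd_cell)
  expect_error(com_heatmap(matrix(c(100, 100), ncol = 2), c(16, 20)),
               "outside")
})

test_that("clipped circle-rectangle areas match a Monte-Carlo oracle", {
  box <- c(32, 40, 33); center <- c(16, 20)
  n_mc <- 1e6
  pts <- with_test_seed(5, cbind(runif(n_mc, 0, 32), runif(n_mc, 0, 40)))
  r <- radial_distance(pts, center)
  for (rad in c(3, 15.9, 18, 22, 25.5)) {
    p_hat <- mean(r <= rad)
    sd_mc <- sqrt(p_hat * (1 - p_hat) / n_mc) * box[1] * box[2]
    expect_lt(abs(circle_rect_area(rad, center, box) -
                    p_hat * box[1] * box[2]), 4 * sd_mc)
  }
  # unclipped annuli are exact circles
  expect_equal(annulus_clipped_area(2, 3, center, box), pi * (9 - 4),
               tolerance = 1e-12)
  # whole box recovered at large radius
  expect_equal(circle_rect_area(100, center, box), 32 * 40,
               tolerance = 1e-9)
})

test_that("the RDF normalization is exactly 1 for expected-count input", {
  # feed each bin its exact expected count under uniform density: the
  # annular-area + global-density normalization must return exactly 1
  h <- radial_histogram(with_test_seed(6, runif(1000, 0, 25)))
  area <- mapply(annulus_clipped_area, h$bin_lo, h$bin_hi,
                 MoreArgs = list(center = c(16, 20), box = c(32, 40, 33)))
  h$count <- area * 7.5   # uniform density 7.5 per nm^2
  rdf <- rdf_normalize(h, c(16, 20), c(32, 40, 33),
                       total_count = 7.5 * 32 * 40)
  expect_lt(max(abs(rdf$density - 1)), 1e-9)
})

test_that("sampled uniform points give bulk RDF = 1 within shot noise", {
  xy <- with_test_seed(8, cbind(runif(1e5, 0, 32), runif(1e5, 0, 40)))
  r <- radial_distance(xy, c(16, 20))
  rdf <- rdf_normalize(radial_histogram(r), c(16, 20), c(32, 40, 33))
  n_exp <- 1e5 * rdf$area / (32 * 40)
  ok <- rdf$displayed & n_exp >= 1000  # bins where Poisson SD <= 3.2%
  expect_gt(sum(ok), 25)
  expect_lt(max(abs(rdf$density[ok] - 1)), 0.12)
  # duplicating the sample leaves the RDF unchanged (density cancels n)
  rdf2 <- rdf_normalize(radial_histogram(c(r, r)), c(16, 20),
                        c(32, 40, 33))
  expect_equal(rdf2$density, rdf$density, tolerance = 1e-12)
})

test_that("all mass in one annulus gives RDF = total area / annulus area", {
  r <- with_test_seed(9, runif(2000, 10, 10.25))
  rdf <- rdf_normalize(radial_histogram(r), c(16, 20), c(32, 40, 33))
  a <- annulus_clipped_area(10, 10.25, c(16, 20), c(32, 40, 33))
  i <- which(rdf$count > 0)
  expect_length(i, 1)
  expect_equal(rdf$density[i], 32 * 40 / a, tolerance = 1e-12)
  expect_error(rdf_normalize(radial_histogram(r), c(16, 20),
                             c(32, 40, 33), total_count = 0),
               "positive")
})

test_that("replica pooling equals the frame-weighted replica average", {
  r1 <- with_test_seed(10, runif(3000, 0, 25))
  r2 <- with_test_seed(11, runif(1000, 0, 25))
  pooled <- radial_histogram(c(r1, r2))
  h1 <- radial_histogram(r1); h2 <- radial_histogram(r2)
  w <- c(3000, 1000) / 4000
  expect_equal(pooled$density, w[1] * h1$density + w[2] * h2$density,
               tolerance = 1e-12)
})

test_that("the KDE integrates to 1 and finds a Gaussian mode", {
  x <- with_test_seed(12, rnorm(1e5, mean = 11, sd = 1.5))
  k <- radial_kde(x)
  expect_lt(abs(trapz_h(k$r, k$density) - 1), 1e-3)
  # Scott's rule bandwidth
  expect_equal(attr(k, "bw"), sd(x) * 1e5^(-1 / 5), tolerance = 1e-12)
  # mode recovery, checked at a bandwidth where the mode's sampling SD
  # (~ sqrt(f / (n bw^3 f''^2))) is well below the 0.5 bw tolerance
  k4 <- radial_kde(x, bw = 0.4)
  expect_lt(abs(k4$r[which.max(k4$density)] - 11), 0.5 * 0.4)
  # bandwidth -> 0 resolves three separated points into three peaks
  # (count maxima above floating-point noise in the zero-density gaps)
  k3 <- radial_kde(c(2, 10, 20), bw = 0.05)
  dens <- k3$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  expect_equal(sum(dens[peaks] > 0.01 * max(dens)), 3)
  expect_error(radial_kde(rep(5, 10)), "degenerate")
})


test_that("peak location honours ties, regions and the no-peak flag", {
  curv <- curvature_and_roc(default_params, seq(0, 25, by = 0.1))
  h <- radial_histogram(rep(11.2, 100))  # single spike at bin centre 11.125
  pk <- peak_location(h, curv)
  expect_equal(pk$peak_r, 11.125)
  expect_equal(pk$region, "convex")
  expect_false(pk$no_peak)
  # tie broken toward smaller r and reported
  h2 <- radial_histogram(c(rep(3.1, 5), rep(19.1, 5)))
  pk2 <- peak_location(h2, curv)
  expect_true(pk2$tie)
  expect_lt(pk2$peak_r, 4)
  # flat distribution flags no peak
  h3 <- radial_histogram(seq(0.125, 24.875, by = 0.25))
  expect_true(peak_location(h3)$no_peak)
})

trapz_t <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
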