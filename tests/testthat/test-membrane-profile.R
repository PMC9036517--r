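make_surface_frame <- function(params, n = 6000, box = c(32, 40, 33),
                               center = c(16, 20), seed = 4, sigma = 0) {
  with_test_seed(seed, {
    x <- runif(n, 0, box[1]); y <- runif(n, 0, box[2])
    r <- radial_distance(cbind(x, y), center)
    z <- surface_height(r, params) + rnorm(n, 0, sigma)
    bead_frame(x, y, z, rep("PC_head", n), rep("top", n), box = box)
  })
}

test_that("constant headgroup height gives a constant profile", {
  f <- with_test_seed(2, bead_frame(runif(500, 0, 32), runif(500, 0, 40),
                                    rep(15, 500), rep("PC_head", 500),
                                    rep("top", 500), box = c(32, 40, 33)))
  prof <- radial_height_profile(f, c(16, 20))
  expect_true(all(prof$height[!prof$empty] == 15))
  expect_error(radial_height_profile(
    bead_frame(1, 1, 1, "tail", "top", box = c(32, 40, 33)), c(16, 20)),
    "empty selection")
})

test_that("noiseless beads reproduce the analytic surface within
           discretization error", {
  f <- make_surface_frame(default_params)
  prof <- radial_height_profile(f, c(16, 20), bin_width = 0.5)
  ok <- !prof$empty
  max_slope <- max(abs(surface_deriv1(seq(0, 25, 0.1), default_params)))
  expect_lt(max(abs(prof$height[ok] -
                      surface_height(prof$r[ok], default_params))),
            0.5 * max_slope)
})

test_that("multi-frame averaging equals one brute-force pooled pass", {
  f1 <- make_surface_frame(default_params, n = 800, seed = 5, sigma = 0.2)
  f2 <- make_surface_frame(default_params, n = 1200, seed = 6, sigma = 0.2)
  prof <- radial_height_profile(list(f1, f2), c(16, 20))
  pool <- rbind(as.data.frame(f1), as.data.frame(f2))
  r <- radial_distance(cbind(pool$x, pool$y), c(16, 20))
  bin <- findInterval(r, seq(0, 25, by = 0.5), rightmost.closed = TRUE)
  for (b in unique(bin[bin >= 1 & bin <= 50])) {
    expect_equal(prof$height[b], mean(pool$z[bin == b]), tolerance = 1e-12)
  }
})

test_that("a noiseless sigmoid profile is recovered to 1e-6 in values", {
  prof <- synthetic_profile()
  fit <- fit_sigmoid(prof)
  expect_true(fit$converged)
  expect_lt(max(abs(predict(fit, prof$r) -
                      surface_height(prof$r, default_params))), 1e-6)
  expect_lte(fit$rss, 1e-10)
})

test_that("noisy fits stay within the Monte-Carlo calibration band", {
  r <- seq(0.25, 24.75, length.out = 50)
  truth <- surface_height(r, default_params)
  ok <- vapply(1:100, function(s) {
    prof <- synthetic_profile(r = r, sigma = 0.1, seed = 1000 + s)
    fit <- fit_sigmoid(prof)
    all(abs(predict(fit, r) - truth) < 3 * 0.1)
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("a constant profile collapses to the flat limit", {
  prof <- data.frame(r = seq(0.5, 10, by = 0.5), height = 13.7)
  fit <- fit_sigmoid(prof)
  expect_true(fit$flat)
  expect_equal(fit$params[["d"]], 0)
  expect_lt(max(abs(predict(fit, seq(0, 25, 0.1)) - 13.7)), 1e-6)
})

test_that("refitting the fitted curve reproduces it (idempotence)", {
  fit <- fit_sigmoid(synthetic_profile(sigma = 0.05, seed = 3))
  r <- seq(0.25, 24.75, by = 0.5)
  refit <- fit_sigmoid(data.frame(r = r, height = predict(fit, r)))
  expect_lt(max(abs(predict(refit, r) - predict(fit, r))), 1e-9)
})

test_that("too-short profiles and hopeless fits raise errors", {
  expect_error(fit_sigmoid(data.frame(r = 1:4, height = c(1, 2, 3, 4))),
               ">= 5")
})

test_that("a circular arc yields its radius of curvature within 5%", {
  r <- seq(6.5, 8.5, length.out = 50)      # flank of the arc, apex excluded
  prof <- data.frame(r = r, height = sqrt(25 - (r - 10)^2))
  fit <- fit_sigmoid(prof)
  mid <- mean(range(r))
  curv <- curvature_and_roc(fit, mid)
  expect_lt(abs(curv$RoC - 5) / 5, 0.05)
  expect_equal(curv$region, "convex")      # arc bulges toward the protein side
})

test_that("K and RoC are reciprocal and flat fits are labelled flat", {
  curv <- curvature_and_roc(default_params, seq(0, 25, by = 0.1))
  nz <- curv$K != 0
  expect_equal(curv$RoC[nz] * abs(curv$K[nz]), rep(1, sum(nz)))
  flat <- curvature_and_roc(c(a = 15, b = 1, c = 1, d = 0, x0 = 8),
                            seq(0, 25, by = 0.5))
  expect_true(all(flat$K == 0))
  expect_true(all(flat$region == "flat"))
  expect_true(all(is.infinite(flat$RoC)))
})

test_that("default geometry gives one concave band below one convex band", {
  curv <- curvature_and_roc(default_params, seq(0, 25, by = 0.1))
  bands <- classify_regions(curv)
  nb <- bands$bands[bands$bands$region != "flat", ]
  expect_identical(nb$region, c("concave", "convex"))
  expect_lt(bands$most_concave_r, bands$most_convex_r)
  expect_equal(bands$most_concave_r, 6, tolerance = 0.15)
  expect_equal(bands$most_convex_r, 11, tolerance = 0.15)
})

test_that("flipping the membrane swaps concave and convex labels exactly", {
  p_flip <- default_params
  p_flip["d"] <- -p_flip["d"]
  r <- seq(0, 25, by = 0.1)
  up <- curvature_and_roc(default_params, r)
  dn <- curvature_and_roc(p_flip, r)
  expect_equal(dn$K, -up$K, tolerance = 1e-12)
  swap <- c(concave = "convex", convex = "concave", flat = "flat")
  expect_identical(unname(swap[up$region]), dn$region)
})
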