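simple_frame <- function(prot, targets, box = c(20, 20, 20),
                         target_species = "tail") {
  n_p <- nrow(prot); n_t <- nrow(targets)
  bead_frame(c(prot[, 1], targets[, 1]), c(prot[, 2], targets[, 2]),
             c(prot[, 3], targets[, 3]),
             species = c(rep("protein", n_p), rep(target_species, n_t)),
             leaflet = c(rep("none", n_p),
                         rep(if (target_species == "PIP2_head") "top"
                             else "none", n_t)),
             residue = c(seq_len(n_p), rep(NA, n_t)), box = box)
}

test_that("contact counting honours the cutoff exactly", {
  prot <- matrix(c(10, 10, 10), ncol = 3)
  # nearest target just beyond the cutoff
  f <- simple_frame(prot, matrix(c(10, 10, 10.61), ncol = 3))
  expect_equal(unname(count_contacts(f, "tail", cutoff = 0.6)), 0L)
  # three targets inside
  t3 <- matrix(c(10.3, 10, 10, 10, 10.4, 10, 10, 10, 9.5), ncol = 3,
               byrow = TRUE)
  f3 <- simple_frame(prot, t3)
  expect_equal(unname(count_contacts(f3, "tail", cutoff = 0.6)), 3L)
  expect_error(count_contacts(f3, "PIP2_head"), "empty selection")
})

test_that("counts match the O(n^2) double-loop oracle on random frames", {
  for (seed in c(1, 2)) {
    f <- with_test_seed(seed, {
      n <- 200
      bead_frame(runif(n, 0, 8), runif(n, 0, 8), runif(n, 0, 8),
                 species = rep(c("protein", "tail"), each = n / 2),
                 residue = c(rep(1:20, each = 5), rep(NA, n / 2)),
                 box = c(8, 8, 8))
    })
    for (cutoff in c(0.5, 1.0, 2.5)) {
      expect_identical(unname(count_contacts(f, "tail", cutoff)),
                       contact_oracle(f, "tail", cutoff))
    }
  }
})

test_that("counts are invariant under rigid translation and image shifts", {
  f <- with_test_seed(3, bead_frame(
    runif(60, 0, 8), runif(60, 0, 8), runif(60, 0, 8),
    species = rep(c("protein", "tail"), each = 30),
    residue = c(rep(1:10, each = 3), rep(NA, 30)), box = c(8, 8, 8)))
  base <- count_contacts(f, "tail", 0.8)
  shift <- function(fr, dx) {
    d <- as.data.frame(fr)
    d$x <- (d$x + dx[1]) %% 8; d$y <- (d$y + dx[2]) %% 8
    d$z <- (d$z + dx[3]) %% 8
    bead_frame(d$x, d$y, d$z, d$species, d$leaflet, d$residue,
               box = c(8, 8, 8))
  }
  expect_identical(count_contacts(shift(f, c(3.1, -2.2, 5.5)), "tail", 0.8),
                   base)
  # shifting only the target selection by a full box image
  d <- as.data.frame(f)
  d$x[d$species == "tail"] <- (d$x[d$species == "tail"] + 8) %% 8
  expect_identical(count_contacts(
    bead_frame(d$x, d$y, d$z, d$species, d$leaflet, d$residue,
               box = c(8, 8, 8)), "tail", 0.8), base)
})

test_that("increasing the cutoff never decreases any count", {
  f <- with_test_seed(4, bead_frame(
    runif(120, 0, 8), runif(120, 0, 8), runif(120, 0, 8),
    species = rep(c("protein", "tail"), each = 60),
    residue = c(rep(1:12, each = 5), rep(NA, 60)), box = c(8, 8, 8)))
  sweep <- lapply(seq(0.3, 2.1, by = 0.3), function(ct)
    count_contacts(f, "tail", ct))
  for (i in seq_len(length(sweep) - 1))
    expect_true(all(sweep[[i + 1]] >= sweep[[i]]))
})

test_that("averaging over frames and replicas pools correctly", {
  cfg <- generator_config(seed = 11)  # full lipid density: planted
  frames <- lapply(0:3, function(t)   # anchors reliably touch tails
    add_protein_beads(generate_membrane_frame(cfg, time = t), cfg,
                      c(20, 22), embedded_residues = c(6L, 10L)))
  f <- frames[[1]]
  prof1 <- average_contact_profile(frames, "tail",
                                   codes = cfg$protein$sequence)
  prof3 <- average_contact_profile(list(f), "tail",
                                   codes = cfg$protein$sequence)
  expect_equal(prof3$mean_contacts,
               as.numeric(count_contacts(f, "tail")))
  # embedded residues strictly dominate every other residue
  emb <- prof1$mean_contacts[c(6, 10)]
  expect_true(all(emb > max(prof1$mean_contacts[-c(6, 10)])))
  # pooled mean equals the frame-weighted average of per-replica means
  f2 <- add_protein_beads(generate_membrane_frame(cfg, time = 9), cfg,
                          c(10, 12), embedded_residues = c(6L, 10L))
  pooled <- average_contact_profile(list(f, f2, f2), "tail",
                                    replica_ids = c(1, 2, 2),
                                    codes = cfg$protein$sequence)
  pr <- attr(pooled, "per_replica")
  expect_equal(pooled$mean_contacts,
               unname((1 * pr[1, ] + 2 * pr[2, ]) / 3), tolerance = 1e-12)
})

test_that("top residues are ranked with deterministic tie handling", {
  prof <- structure(data.frame(residue_index = 1:55,
                               residue_code = default_sequence(),
                               class = residue_classes(default_sequence()),
                               mean_contacts = 0),
                    class = c("contact_profile", "data.frame"))
  prof$mean_contacts[c(6, 10, 17)] <- c(5, 4, 3)
  expect_equal(top_contact_residues(prof, 3)$residue_index, c(6, 10, 17))
  prof$mean_contacts[c(44, 52)] <- 3  # tie with residue 17 at rank 3
  top <- top_contact_residues(prof, 3)
  expect_equal(top$residue_index, c(6, 10, 17))
  expect_true(attr(top, "ties"))
  zero <- prof; zero$mean_contacts <- 0
  expect_true(attr(top_contact_residues(zero, 3), "no_peak"))
  expect_warning(top_contact_residues(prof, 99), "truncated")
})

test_that("tilt angle matches rod geometry and known rotations", {
  rod_z <- bead_frame(rep(5, 5), rep(5, 5), seq(2, 6, by = 1),
                      species = rep("protein", 5), residue = 1:5,
                      box = c(10, 10, 10))
  expect_equal(tilt_angle(rod_z), 0, tolerance = 1e-8)
  rod_x <- bead_frame(seq(2, 6, by = 1), rep(5, 5), rep(5, 5),
                      species = rep("protein", 5), residue = 1:5,
                      box = c(10, 10, 10))
  expect_equal(tilt_angle(rod_x), 90, tolerance = 1e-8)
  # rotating the rod about y by a known angle changes the tilt to match
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  pos <- cbind(rep(0, 5), rep(0, 5), seq(-2, 2, by = 1)) %*% t(R)
  rot <- bead_frame(pos[, 1] + 5, pos[, 2] + 5, pos[, 3] + 5,
                    species = rep("protein", 5), residue = 1:5,
                    box = c(10, 10, 10))
  expect_equal(tilt_angle(rot), 35, tolerance = 1e-6)
  # coincident beads are degenerate
  expect_error(tilt_angle(bead_frame(rep(5, 3), rep(5, 3), rep(5, 3),
                                     species = rep("protein", 3),
                                     residue = 1:3, box = c(10, 10, 10))),
               "degenerate")
})
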