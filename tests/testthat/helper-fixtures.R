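# shared fixtures: small, fast configurations built in code

default_params <- c(a = 12, b = 0.527, c = 1, d = 3, x0 = 8.5)

small_config <- function(...) {
  generator_config(n_pc = 1000, n_frames = 2, n_replicas = 2,
                   trace = list(n_steps = 2000L), seed = 11, ...)
}

# noiseless profile sampled from a known sigmoid surface
synthetic_profile <- function(params = default_params,
                              r = seq(0.25, 24.75, by = 0.5),
                              sigma = 0, seed = 1) {
  h <- surface_height(r, params)
  if (sigma > 0) h <- h + with_test_seed(seed, rnorm(length(r), 0, sigma))
  data.frame(r = r, height = h, n = 1L, empty = FALSE)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# brute-force O(n^2) per-residue contact oracle with minimum-image PBC
contact_oracle <- function(frame, target_species, cutoff) {
  box <- attr(frame, "box")
  pr <- which(frame$species == "protein" & !is.na(frame$residue))
  tg <- which(frame$species %in% target_species)
  cnt <- integer(max(frame$residue[pr]))
  for (i in pr) {
    for (j in tg) {
      dx <- min_image_t(frame$x[i] - frame$x[j], box[1])
      dy <- min_image_t(frame$y[i] - frame$y[j], box[2])
      dz <- min_image_t(frame$z[i] - frame$z[j], box[3])
      if (dx^2 + dy^2 + dz^2 <= cutoff^2)
        cnt[frame$residue[i]] <- cnt[frame$residue[i]] + 1L
    }
  }
  cnt
}

min_image_t <- function(dx, L) dx - L * round(dx / L)

# empirical radial occupancy of traces on the standard 100-bin grid,
# with an overflow bin, matching boltzmann_occupancy()
empirical_occupancy <- function(traces, center,
                                edges = seq(0, 25, length.out = 101)) {
  if (inherits(traces, "protein_trace")) traces <- list(traces)
  r <- unlist(lapply(traces, function(tr)
    radial_distance(cbind(tr$x, tr$y), center)))
  b <- findInterval(r, edges, rightmost.closed = TRUE)
  b[b == 0 | b >= length(edges)] <- length(edges)
  m <- tabulate(b, nbins = length(edges))
  m / sum(m)
}

tv_distance <- function(p, q) sum(abs(p - q)) / 2

trapz_h <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
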