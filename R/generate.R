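#' Generate one curved-membrane bead frame
#'
#' Lipid sites are placed uniformly over the box area and split evenly
#' between leaflets. Headgroup beads sit on the sigmoid surface
#' `surface_height(r)` (top leaflet) or 4 nm below it (bottom leaflet),
#' plus isotropic Gaussian roughness `noise_sigma`; glycerol and two tail
#' beads are offset toward the bilayer midplane. PIP2 replaces PC at
#' top-leaflet sites with probability proportional to
#' `exp(pip2_curvature_weight * K(r))`, so a positive weight enriches PIP2
#' in the concave band (K > 0) and depletes it on the convex shoulder
#' (K < 0), while the expected PIP2 count stays `pip2_fraction * n_pc`.
#'
#' @param config a [generator_config()].
#' @param time frame index; the per-frame RNG stream is derived from the
#'   master seed and this index.
#' @param seed optional override of the master seed.
#' @return a [bead_frame()].
#' @export
generate_membrane_frame <- function(config, time = 0L, seed = config$seed) {
  cfg <- validate_generator_config(config)
  n <- cfg$n_pc
  if (cfg$pip2_fraction > 0 && n == 0)
    stopf("pip2_fraction > 0 requires a non-zero lipid count")
  with_seed(derive_seed(seed, "frame", time + 1L), {
    n_top <- ceiling(n / 2); n_bot <- n - n_top
    xy <- cbind(runif(n, 0, cfg$box[1]), runif(n, 0, cfg$box[2]))
    leaf <- rep(c("top", "bottom"), c(n_top, n_bot))
    r <- sqrt((xy[, 1] - cfg$pore_center[1])^2 +
              (xy[, 2] - cfg$pore_center[2])^2)
    h_top <- surface_height(r, cfg$profile_params) +
      rnorm(n, 0, cfg$noise_sigma)
    head_z <- ifelse(leaf == "top", h_top, h_top - 4)
    # PIP2 assignment on top-leaflet sites, Boltzmann-weighted by curvature
    is_pip2 <- rep(FALSE, n)
    if (cfg$pip2_fraction > 0) {
      K <- surface_curvature(r[leaf == "top"], cfg$profile_params)
      w <- exp(cfg$pip2_curvature_weight * K)
      p <- cfg$pip2_fraction * n / n_top * w / mean(w)
      if (any(p > 1)) {
        warning("PIP2 placement probabilities clipped at 1; ",
                "sorting weight too strong for this fraction")
        p <- pmin(p, 1)
      }
      is_pip2[leaf == "top"] <- runif(n_top) < p
    }
    # per-lipid beads: head, glycerol, two tails, offset toward midplane
    sgn <- ifelse(leaf == "top", -1, 1)
    off <- c(head = 0, glycerol = 0.7, tail1 = 1.4, tail2 = 2.0)
    zb <- cbind(head_z, head_z + sgn * off["glycerol"],
                head_z + sgn * off["tail1"], head_z + sgn * off["tail2"])
    head_sp <- ifelse(is_pip2, "PIP2_head", "PC_head")
    ord <- rep(seq_len(n), each = 4L)
    species <- as.vector(rbind(head_sp, "glycerol", "tail", "tail"))
    bead_frame(x = wrap_pbc(xy[ord, 1], cfg$box[1]),
               y = wrap_pbc(xy[ord, 2], cfg$box[2]),
               z = pmin(pmax(as.vector(t(zb)), 0), cfg$box[3]),
               species = species,
               leaflet = leaf[ord],
               box = cfg$box, time = time)
  })
}

#' Add protein beads to a bead frame
#'
#' Places one backbone bead per residue along a line through the given
#' centre of mass (periodic in x), riding on the membrane surface.
#' Residues listed in `embedded_residues` are lowered into the
#' hydrophobic tail region (surface - 1.5 nm), basic residues (K, H, R)
#' sit headgroup-proximal (surface + 0.3 nm) and all others ride above
#' the headgroups (surface + 0.8 nm). This planted geometry gives
#' embedded residues high tail contacts and basic residues the highest
#' PIP2-headgroup contacts, emulating an inserted amphipathic anchor.
#'
#' @param frame a [bead_frame()] to extend.
#' @param config the [generator_config()] the frame came from.
#' @param com_xy protein centre-of-mass (x, y) in nm.
#' @param embedded_residues residue indices inserted among the tails;
#'   defaults to `config$protein$embedded_residues`.
#' @return the frame with protein beads appended.
#' @export
add_protein_beads <- function(frame, config, com_xy,
                              embedded_residues =
                                config$protein$embedded_residues) {
  cfg <- config
  nres <- cfg$protein$n_residues
  seqc <- cfg$protein$sequence
  spacing <- 0.35
  xs <- wrap_pbc(com_xy[1] + (seq_len(nres) - (nres + 1) / 2) * spacing,
                 cfg$box[1])
  ys <- rep(wrap_pbc(com_xy[2], cfg$box[2]), nres)
  r <- sqrt((xs - cfg$pore_center[1])^2 + (ys - cfg$pore_center[2])^2)
  h <- surface_height(r, cfg$profile_params)
  dz <- rep(0.8, nres)
  dz[seqc %in% c("K", "H", "R")] <- 0.3
  dz[embedded_residues] <- -1.5
  prot <- bead_frame(xs, ys, pmin(pmax(h + dz, 0), cfg$box[3]),
                     species = rep("protein", nres),
                     leaflet = rep("none", nres),
                     residue = seq_len(nres),
                     box = attr(frame, "box"), time = attr(frame, "time"))
  out <- rbind(as.data.frame(frame), as.data.frame(prot))
  bead_frame(out$x, out$y, out$z, out$species, out$leaflet, out$residue,
             box = attr(frame, "box"), time = attr(frame, "time"))
}

#' Radial PIP2 area density from membrane frames
#'
#' Pools PIP2 headgroup radii over frames, bins them into 0.5 nm annuli
#' (areas clipped analytically to the box) and forms a kernel-smoothed
#' area density: at each radius the Gaussian-weighted sum of bin counts
#' is divided by the equally weighted sum of bin areas. This local
#' Poisson-rate estimate pools information across neighbouring annuli,
#' which keeps the tiny innermost annuli from dominating through shot
#' noise. The result is normalized to a maximum of 1 (the relative local
#' PIP2 area density used in the protein energy model).
#'
#' @param frames list of [bead_frame()]s.
#' @param center pore centre (x_c, y_c) nm.
#' @param box box vectors nm.
#' @param r_max maximum radius of the density grid (nm).
#' @param bw Gaussian smoothing bandwidth (nm).
#' @return data frame with columns `r` (bin centres) and `rho` in `[0, 1]`
#'   (all zero when no PIP2 is present).
#' @export
pip2_radial_density <- function(frames, center, box, r_max = 25, bw = 1) {
  if (inherits(frames, "bead_frame")) frames <- list(frames)
  radii <- unlist(lapply(frames, function(f) {
    i <- f$species == "PIP2_head"
    sqrt((f$x[i] - center[1])^2 + (f$y[i] - center[2])^2)
  }))
  edges <- seq(0, r_max, by = 0.5)
  mids <- edges[-1] - 0.25
  if (length(radii) == 0)
    return(data.frame(r = mids, rho = 0))
  cnt <- tabulate(findInterval(radii, edges, rightmost.closed = TRUE),
                  nbins = length(mids))
  area <- vapply(seq_along(mids), function(i)
    annulus_clipped_area(edges[i], edges[i + 1], center, box), 0)
  w <- exp(-outer(mids, mids, "-")^2 / (2 * bw^2))
  dens <- as.numeric(w %*% cnt) / as.numeric(w %*% area)
  if (max(dens) > 0) dens <- dens / max(dens)
  data.frame(r = mids, rho = dens)
}

#' Radial protein energy model
#'
#' The two-term surface energy governing the synthetic protein:
#' \deqn{U(r) = -w_{hydro} A_{convex}(r) - w_{pip2} \rho_{PIP2}(r)}
#' in units of kT, where `A_convex(r) = max(0, -K(r)) / max(-K)` is the
#' normalized convexity score of the membrane profile (1 at the most
#' convex radius, 0 where the membrane is flat or concave) and
#' `rho_PIP2(r)` the relative local PIP2 area density from
#' [pip2_radial_density()]. Hydrophobic attraction therefore pulls the
#' protein to the convex shoulder while PIP2 attraction pulls it to the
#' concave, PIP2-enriched band.
#'
#' @param config a [generator_config()].
#' @param frames membrane frames used for the PIP2 density lookup; if
#'   omitted, `config$n_frames` frames are generated.
#' @param dr grid spacing (nm) of the returned energy table.
#' @param r_max grid extent (nm).
#' @return list with `r` (grid), `U` (kT), `A_convex`, `rho_pip2`.
#' @export
radial_energy <- function(config, frames = NULL, dr = 0.05, r_max = 30) {
  cfg <- validate_generator_config(config)
  if (is.null(frames) && cfg$pip2_fraction > 0)
    frames <- lapply(seq_len(cfg$n_frames) - 1L, function(t)
      generate_membrane_frame(cfg, time = t))
  r <- seq(0, r_max, by = dr)
  K <- surface_curvature(r, cfg$profile_params)
  conv <- pmax(0, -K)
  A <- if (max(conv) > 0) conv / max(conv) else conv
  rho <- rep(0, length(r))
  if (cfg$pip2_fraction > 0) {
    tab <- pip2_radial_density(frames, cfg$pore_center, cfg$box)
    rho <- approx(tab$r, tab$rho, xout = r, rule = 2)$y
  }
  U <- -cfg$protein$w_hydro * A - cfg$protein$w_pip2 * rho
  list(r = r, U = U, A_convex = A, rho_pip2 = rho, dr = dr)
}

#' Generate a protein centre-of-mass trace
#'
#' Metropolis Monte Carlo walk of the protein centre of mass over the
#' periodic box, sampling the Boltzmann distribution of the radial energy
#' [radial_energy()]. The proposal is a mixture of an isotropic Gaussian
#' step (`step_sigma`) and, with probability `jump_prob`, a uniform
#' independence jump over the whole box; both components are symmetric, so
#' the standard Metropolis acceptance `min(1, exp(-dU))` leaves the target
#' invariant, and the jumps keep deep multi-well energies mixing. With
#' both weights zero every proposal is accepted and the walk is free
#' diffusion, uniform over the box.
#'
#' @param config a [generator_config()].
#' @param energy precomputed energy table from [radial_energy()]; required
#'   (generate it once and share across replicas).
#' @param replica_id replica index (seeds the derived RNG stream).
#' @param n_steps number of Metropolis steps; default
#'   `config$trace$n_steps`.
#' @param seed optional master-seed override.
#' @return an object of class `protein_trace`: data frame with columns
#'   `time`, `x`, `y`, `z` (nm) and attribute `replica_id`.
#' @export
generate_protein_trace <- function(config, energy, replica_id = 1L,
                                   n_steps = config$trace$n_steps,
                                   seed = config$seed) {
  cfg <- validate_generator_config(config)
  if (missing(energy) || is.null(energy))
    stopf("supply an energy table from radial_energy()")
  Lx <- cfg$box[1]; Ly <- cfg$box[2]
  xc <- cfg$pore_center[1]; yc <- cfg$pore_center[2]
  U <- energy$U; dr <- energy$dr; nU <- length(U)
  step <- cfg$trace$step_sigma; pjump <- cfg$trace$jump_prob
  n_steps <- as.integer(n_steps)
  u_at <- function(x, y) {
    i <- floor(sqrt((x - xc)^2 + (y - yc)^2) / dr) + 1
    U[min(i, nU)]
  }
  with_seed(derive_seed(seed, "replica", replica_id), {
    xs <- numeric(n_steps); ys <- numeric(n_steps)
    # pre-drawn randomness keeps the loop tight
    jump <- runif(n_steps) < pjump
    gx <- rnorm(n_steps, 0, step); gy <- rnorm(n_steps, 0, step)
    ux <- runif(n_steps, 0, Lx); uy <- runif(n_steps, 0, Ly)
    acc <- runif(n_steps)
    x <- runif(1, 0, Lx); y <- runif(1, 0, Ly)
    u0 <- u_at(x, y)
    for (s in seq_len(n_steps)) {
      if (jump[s]) {
        xp <- ux[s]; yp <- uy[s]
      } else {
        xp <- x + gx[s]; yp <- y + gy[s]
        if (xp < 0 || xp >= Lx) xp <- xp - Lx * floor(xp / Lx)
        if (yp < 0 || yp >= Ly) yp <- yp - Ly * floor(yp / Ly)
      }
      i <- floor(sqrt((xp - xc)^2 + (yp - yc)^2) / dr) + 1
      u1 <- U[if (i > nU) nU else i]
      if (u1 <= u0 || acc[s] < exp(u0 - u1)) {
        x <- xp; y <- yp; u0 <- u1
      }
      xs[s] <- x; ys[s] <- y
    }
    r <- sqrt((xs - xc)^2 + (ys - yc)^2)
    z <- surface_height(r, cfg$profile_params) + 1
    structure(data.frame(time = seq_len(n_steps) - 1L, x = xs, y = ys, z = z),
              replica_id = as.integer(replica_id),
              class = c("protein_trace", "data.frame"))
  })
}

#' Direct Boltzmann occupancy on the radial grid
#'
#' Reference stationary distribution of [generate_protein_trace()]:
#' direct summation of `exp(-U)` over a fine xy grid of the box, binned
#' by radial distance. Used to check Metropolis convergence.
#'
#' @param energy energy table from [radial_energy()].
#' @param center pore centre (nm).
#' @param box box vectors (nm).
#' @param edges radial bin edges (nm); mass beyond the last edge is
#'   returned in an overflow bin.
#' @param dx xy grid spacing (nm).
#' @return numeric vector of bin masses summing to 1 (last element =
#'   overflow).
#' @export
boltzmann_occupancy <- function(energy, center, box,
                                edges = seq(0, 25, length.out = 101),
                                dx = 0.1) {
  gx <- seq(dx / 2, box[1] - dx / 2, by = dx)
  gy <- seq(dx / 2, box[2] - dx / 2, by = dx)
  r <- sqrt(outer((gx - center[1])^2, (gy - center[2])^2, "+"))
  i <- pmin(floor(r / energy$dr) + 1, length(energy$U))
  w <- exp(-energy$U[i])
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  bin[bin == 0 | bin >= length(edges)] <- length(edges)  # overflow
  m <- vapply(seq_len(length(edges)), function(b) sum(w[bin == b]), 0)
  m <- m[c(seq_len(length(edges) - 1), length(edges))]
  m / sum(m)
}
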