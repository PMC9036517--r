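#' Synthetic generator configuration
#'
#' Builds and validates the configuration of the synthetic curved-membrane
#' generator. Defaults emulate the study system: a 32 x 40 x 33 nm box, a
#' radially symmetric membrane curved over a central pore at
#' (x_c, y_c) = (16, 20) nm with a tapered transition band, lipid
#' composition 100% PC or 97.5% PC + 2.5% PIP2 with PIP2 confined to the
#' top (solvent-exposed) leaflet, PIP2 enrichment at concave and depletion
#' at convex curvature, and 8 replica protein traces per condition.
#'
#' The default height profile places the concave band near r = 6 nm and
#' the convex band near r = 11 nm: `x0` is the midpoint of the taper
#' radii, `d` the pore depth, and `b` is set so the curvature extrema of
#' the logistic fall at the taper radii.
#'
#' @param box numeric length-3, box vectors (Lx, Ly, Lz) in nm.
#' @param pore_center numeric length-2, pore centre (x_c, y_c) in nm.
#' @param pore_depth nm the membrane sinks into the pore.
#' @param taper_inner_radius,taper_outer_radius nm, the tapered transition
#'   band of the underlying wafer (inner < outer).
#' @param profile_params named (a, b, c, d, x0) sigmoid parameters; by
#'   default derived from the geometry above.
#' @param n_pc total number of lipid sites (both leaflets; PIP2 replaces PC
#'   at top-leaflet sites).
#' @param pip2_fraction fraction of all lipid sites that are PIP2, in
#'   `[0, 1]`.
#' @param pip2_curvature_weight dimensionless Boltzmann weight coupling
#'   PIP2 placement to local curvature: placement probability is
#'   proportional to `exp(weight * K(r))`, so a positive weight enriches
#'   PIP2 where K > 0 (concave) and depletes it where K < 0 (convex).
#' @param protein list with `n_residues`, `sequence` (one-letter string),
#'   `w_hydro`, `w_pip2` (dimensionless energy weights, units of kT) and
#'   `embedded_residues` (indices whose beads insert among the lipid
#'   tails).
#' @param n_frames membrane frames per condition.
#' @param n_replicas protein trace replicas.
#' @param noise_sigma isotropic Gaussian roughness of headgroup heights
#'   (nm).
#' @param trace list with Metropolis sampler settings: `n_steps`,
#'   `step_sigma` (nm), `jump_prob` (probability of a uniform
#'   independence proposal, which keeps multi-well energies mixing).
#' @param seed master integer seed; frame and replica streams are derived
#'   from it by fixed offsets.
#' @return an object of class `generator_config`.
#' @examples
#' cfg <- generator_config(pip2_fraction = 0)
#' cfg$profile_params
#' @export
generator_config <- function(box = c(32, 40, 33),
                             pore_center = c(16, 20),
                             pore_depth = 3,
                             taper_inner_radius = 6,
                             taper_outer_radius = 11,
                             profile_params = NULL,
                             n_pc = 4000,
                             pip2_fraction = 0.025,
                             pip2_curvature_weight = 6,
                             protein = NULL,
                             n_frames = 20,
                             n_replicas = 8,
                             noise_sigma = 0.3,
                             trace = NULL,
                             seed = 42) {
  if (is.null(profile_params)) {
    half_width <- (taper_outer_radius - taper_inner_radius) / 2
    profile_params <- c(
      a = 15 - pore_depth,
      # logistic (c = 1) curvature extrema sit at x0 +/- log(2 + sqrt(3))/b
      # ~= x0 +/- 1.317/b; pin them to the taper radii
      b = 1.317 / half_width,
      c = 1,
      d = pore_depth,
      x0 = (taper_inner_radius + taper_outer_radius) / 2
    )
  }
  protein <- utils::modifyList(default_protein(), as.list(protein %||% list()))
  trace <- utils::modifyList(
    list(n_steps = 10000L, step_sigma = 1.5, jump_prob = 0.05),
    as.list(trace %||% list()))
  cfg <- structure(list(
    box = as.numeric(box), pore_center = as.numeric(pore_center),
    pore_depth = pore_depth,
    taper_inner_radius = taper_inner_radius,
    taper_outer_radius = taper_outer_radius,
    profile_params = profile_params,
    n_pc = as.integer(n_pc), pip2_fraction = pip2_fraction,
    pip2_curvature_weight = pip2_curvature_weight,
    protein = protein, n_frames = as.integer(n_frames),
    n_replicas = as.integer(n_replicas), noise_sigma = noise_sigma,
    trace = trace, seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

default_protein <- function() {
  list(
    n_residues = 55L,
    sequence = default_sequence(),
    w_hydro = 5,
    w_pip2 = 6,
    embedded_residues = c(6L, 10L, 17L, 44L, 52L)
  )
}

#' Default synthetic protein sequence
#'
#' A synthetic 55-residue sequence standing in for the N-terminal region
#' of an ANTH-domain construct (no deposited sequence is bundled). It
#' places the key hydrophobic anchors L6, I10, V17, Y44 and M52 and the
#' PIP2-binding lysines K24, K28, K38, K39 and K40 at their canonical
#' indices; remaining positions are polar/charged filler.
#'
#' @return a length-55 character vector of one-letter residue codes.
#' @export
default_sequence <- function() {
  s <- rep("S", 55)
  s[seq(2, 55, by = 5)] <- "T"
  s[seq(3, 55, by = 7)] <- "E"
  s[seq(4, 55, by = 11)] <- "N"
  s[c(6, 10, 17, 44, 52)] <- c("L", "I", "V", "Y", "M")
  s[c(24, 28, 38, 39, 40)] <- "K"
  s
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stopf("box must be three positive lengths (nm)")
    if (pip2_fraction < 0 || pip2_fraction > 1)
      stopf("pip2_fraction must lie in [0, 1]")
    if (!(taper_inner_radius < taper_outer_radius))
      stopf("taper_inner_radius must be < taper_outer_radius")
    if (taper_outer_radius >= min(box[1], box[2]) / 2)
      stopf("taper_outer_radius must be < min(Lx, Ly)/2")
    if (n_frames < 1) stopf("n_frames must be >= 1")
    if (pore_depth <= 0 || noise_sigma < 0)
      stopf("length scales must be positive")
    if (pip2_fraction > 0 && n_pc == 0)
      stopf("pip2_fraction > 0 requires a non-zero lipid count")
    if (protein$w_hydro < 0 || protein$w_pip2 < 0)
      stopf("energy weights must be >= 0 (attractive contributions)")
    if (trace$jump_prob < 0 || trace$jump_prob > 1)
      stopf("trace$jump_prob must lie in [0, 1]")
  })
  check_profile_params(cfg$profile_params)
  if (length(cfg$protein$sequence) == 1)
    cfg$protein$sequence <- strsplit(cfg$protein$sequence, "")[[1]]
  if (length(cfg$protein$sequence) != cfg$protein$n_residues)
    stopf("protein sequence length (%d) != n_residues (%d)",
          length(cfg$protein$sequence), cfg$protein$n_residues)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:\n")
  cat(sprintf("  box %.0f x %.0f x %.0f nm, pore centre (%.0f, %.0f) nm\n",
              x$box[1], x$box[2], x$box[3],
              x$pore_center[1], x$pore_center[2]))
  cat(sprintf("  %d lipid sites, PIP2 fraction %.3f (curvature weight %.1f)\n",
              x$n_pc, x$pip2_fraction, x$pip2_curvature_weight))
  cat(sprintf("  protein: %d residues, w_hydro %.1f kT, w_pip2 %.1f kT\n",
              x$protein$n_residues, x$protein$w_hydro, x$protein$w_pip2))
  cat(sprintf("  %d frames, %d replicas, seed %d\n",
              x$n_frames, x$n_replicas, x$seed))
  invisible(x)
}

#' Read a generator/run configuration from YAML
#'
#' The YAML file mirrors the field names of [generator_config()] (for the
#' `generator:` block) and of [run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  gen <- do.call(generator_config, as.list(y$generator %||% list()))
  do.call(run_config, c(list(generator = gen),
                        as.list(y$analysis %||% list()),
                        as.list(y$io %||% list()),
                        if (!is.null(y$seed)) list(seed = y$seed)))
}
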