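#' Residue classification
#'
#' Field-standard classes used to highlight contact profiles:
#' hydrophobic = L, I, A, V, M, Y; basic (positively charged) = K, H, R;
#' everything else = other.
#'
#' @param codes character vector of one-letter residue codes.
#' @return character vector in `{hydrophobic, basic, other}`.
#' @export
residue_classes <- function(codes) {
  ifelse(codes %in% c("L", "I", "A", "V", "M", "Y"), "hydrophobic",
         ifelse(codes %in% c("K", "H", "R"), "basic", "other"))
}

#' Per-residue contact counts in one frame
#'
#' For each protein residue, the number of (residue bead, target bead)
#' pairs within `cutoff` under minimum-image periodic distance in all
#' three dimensions (a reimplementation of the usual minimum-distance
#' contact count).
#'
#' @param frame a [bead_frame()] containing protein beads.
#' @param target_species species counted as targets, e.g. `"tail"`
#'   (hydrophobic lipid tails) or `"PIP2_head"`; glycerol belongs to
#'   neither standard group.
#' @param cutoff contact distance (nm).
#' @param residue_beads optional data frame (`bead`, `residue`) mapping
#'   frame row indices to residues; defaults to the frame's own
#'   protein-bead annotation.
#' @return named integer vector of contact counts, one entry per residue
#'   index over the contiguous residue range.
#' @export
count_contacts <- function(frame, target_species, cutoff = 0.6,
                           residue_beads = NULL) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  box <- attr(frame, "box")
  if (is.null(residue_beads)) {
    pr <- which(frame$species == "protein" & !is.na(frame$residue))
    residue_beads <- data.frame(bead = pr, residue = frame$residue[pr])
  }
  if (nrow(residue_beads) == 0)
    stopf("empty selection: no protein residue beads")
  tg <- which(frame$species %in% target_species)
  if (length(tg) == 0)
    stopf("empty selection: no beads of species %s",
          paste(target_species, collapse = "/"))
  res_range <- seq_len(max(residue_beads$residue))
  cnt <- integer(length(res_range))
  a <- as.matrix(frame[residue_beads$bead, c("x", "y", "z")])
  b <- as.matrix(frame[tg, c("x", "y", "z")])
  within <- matrix(TRUE, nrow(a), nrow(b))
  for (k in 1:3) {
    dxk <- min_image(outer(a[, k], b[, k], "-"), box[k])
    within <- within & abs(dxk) <= cutoff  # cheap prefilter per axis
    if (k == 1) d2 <- dxk^2 else d2 <- d2 + dxk^2
  }
  hits <- d2 <= cutoff^2 & within
  per_bead <- rowSums(hits)
  for (i in seq_len(nrow(residue_beads)))
    cnt[residue_beads$residue[i]] <- cnt[residue_beads$residue[i]] +
      per_bead[i]
  setNames(as.integer(cnt), res_range)
}

#' Average contact profile over frames and replicas
#'
#' Per-residue mean contacts per frame over all frames of all replicas;
#' per-replica means are retained for dispersion. The pooled mean equals
#' the frame-weighted average of per-replica means.
#'
#' @param frames list of [bead_frame()]s with protein beads.
#' @param target_species species counted as targets (see
#'   [count_contacts()]).
#' @param cutoff contact distance (nm).
#' @param codes one-letter residue codes (length = residue count).
#' @param replica_ids optional integer vector, one per frame.
#' @param group label stored on the profile (`hydrophobic_tails`,
#'   `pip2_heads`, ...).
#' @return a `contact_profile` data frame: `residue_index`,
#'   `residue_code`, `class`, `mean_contacts`; attributes `per_replica`
#'   (replica x residue matrix of means), `n_frames`, `n_replicas`,
#'   `group`.
#' @export
average_contact_profile <- function(frames, target_species, cutoff = 0.6,
                                    codes = NULL, replica_ids = NULL,
                                    group = paste(target_species,
                                                  collapse = "+")) {
  if (inherits(frames, "bead_frame")) frames <- list(frames)
  if (length(frames) == 0) stopf("need >= 1 frame")
  counts <- t(vapply(frames, count_contacts,
                     FUN.VALUE = numeric(max(frames[[1]]$residue,
                                             na.rm = TRUE)),
                     target_species = target_species, cutoff = cutoff))
  replica_ids <- replica_ids %||% rep(1L, length(frames))
  per_rep <- do.call(rbind, lapply(split(seq_along(frames), replica_ids),
                                   function(i) colMeans(counts[i, ,
                                                               drop = FALSE])))
  nres <- ncol(counts)
  codes <- codes %||% rep("X", nres)
  out <- data.frame(residue_index = seq_len(nres),
                    residue_code = codes[seq_len(nres)],
                    class = residue_classes(codes[seq_len(nres)]),
                    mean_contacts = colMeans(counts))
  structure(out, per_replica = per_rep, n_frames = length(frames),
            n_replicas = length(unique(replica_ids)), group = group,
            class = c("contact_profile", "data.frame"))
}

#' Top contact residues
#'
#' The `k` residues of highest mean contacts, ties broken toward the
#' lower index (and reported via the `ties` attribute). An all-zero
#' profile returns zero rows with the `no_peak` attribute set.
#'
#' @param profile a `contact_profile`.
#' @param k number of residues to return.
#' @return data frame `residue_index`, `residue_code`, `mean_contacts`
#'   (attributes `ties`, `no_peak`), truncated with a warning when
#'   `k` exceeds the residue count.
#' @export
top_contact_residues <- function(profile, k) {
  stopifnot(inherits(profile, "contact_profile"))
  n <- nrow(profile)
  if (k > n) {
    warning(sprintf("k = %d exceeds residue count %d; truncated", k, n))
    k <- n
  }
  if (all(profile$mean_contacts == 0)) {
    out <- profile[0, c("residue_index", "residue_code", "mean_contacts")]
    attr(out, "no_peak") <- TRUE
    return(out)
  }
  ord <- order(-profile$mean_contacts, profile$residue_index)
  top <- profile[ord[seq_len(k)],
                 c("residue_index", "residue_code", "mean_contacts")]
  rownames(top) <- NULL
  tied <- k < n &&
    profile$mean_contacts[ord[k]] == profile$mean_contacts[ord[k + 1]]
  attr(top, "ties") <- tied
  attr(top, "no_peak") <- FALSE
  top
}

#' Protein tilt angle
#'
#' Angle between the protein's principal axis (largest-variance axis of
#' its bead positions, orientation disambiguated so it points from the
#' first to the second reference residue) and the membrane normal (z),
#' in degrees in `[0, 180]`. This principal-axis measure is the
#' package's declared stand-in for a full rotation-matrix orientation
#' analysis and is labelled as such in outputs.
#'
#' @param frame a [bead_frame()] with protein beads.
#' @param reference_axis_residues length-2 residue indices fixing the
#'   axis orientation (default: first and last residue present).
#' @return tilt angle in degrees.
#' @export
tilt_angle <- function(frame, reference_axis_residues = NULL) {
  pr <- frame$species == "protein"
  pos <- as.matrix(frame[pr, c("x", "y", "z")])
  if (nrow(pos) < 2) stopf("need >= 2 protein beads")
  cen <- sweep(pos, 2, colMeans(pos))
  if (sum(cen^2) < 1e-12)
    stopf("degenerate geometry: protein beads are coincident")
  ax <- svd(cen, nu = 0, nv = 1)$v[, 1]
  res <- frame$residue[pr]
  ref <- reference_axis_residues %||% range(res, na.rm = TRUE)
  i1 <- which(res == ref[1])[1]; i2 <- which(res == ref[2])[1]
  if (!is.na(i1) && !is.na(i2) && i1 != i2) {
    dirv <- pos[i2, ] - pos[i1, ]
    if (sum(ax * dirv) < 0) ax <- -ax
  }
  acos(max(-1, min(1, ax[3] / sqrt(sum(ax^2))))) * 180 / pi
}

#' Export a contact profile as a delimited table
#'
#' @param profile a `contact_profile`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  pr <- attr(profile, "per_replica")
  if (!is.null(pr) && nrow(pr) > 1) {
    reps <- as.data.frame(t(pr))
    names(reps) <- paste0("replica_", seq_len(ncol(reps)))
    df <- cbind(df, reps)
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
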