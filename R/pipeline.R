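#' Protein weight presets
#'
#' Three protein analogues differing only in their hydrophobic anchor
#' set, calibrated so the hydrophobic energy weight scales with the
#' number of anchoring residues (1 kT per anchor: full 5, split 2,
#' short 2 -- the 5:2:2 ratio) while the PIP2 weight, reflecting an
#' identical PIP2-binding site of four engaged lysines at 1.5 kT each,
#' is the same for all three.
#'
#' @return named list of presets (`full`, `split`, `short`), each with
#'   `w_hydro`, `w_pip2` and `embedded_residues`.
#' @export
protein_presets <- function() {
  list(
    full = list(w_hydro = 5, w_pip2 = 6,
                embedded_residues = c(6L, 10L, 17L, 44L, 52L)),
    split = list(w_hydro = 2, w_pip2 = 6,
                 embedded_residues = c(6L, 10L)),
    short = list(w_hydro = 2, w_pip2 = 6,
                 embedded_residues = c(44L, 52L))
  )
}

#' Run configuration
#'
#' Bundles the generator configuration with the analysis settings and
#' output location of one pipeline run.
#'
#' @param generator a [generator_config()].
#' @param center analysis pore centre; defaults to the generator's.
#' @param bins radial histogram bin count.
#' @param r_range radial histogram range (nm).
#' @param cutoff contact cutoff (nm).
#' @param flat_threshold |K| below which curvature counts as flat
#'   (nm^-1).
#' @param discard_frames initial trace frames discarded as equilibration
#'   (default 0: all frames enter the statistics).
#' @param peak_min_excess minimum RDF excess above bulk (1) required to
#'   call a localization peak; below it the verdict is indeterminate.
#' @param input paths list (or `"synthetic"`, the default, to generate
#'   inputs).
#' @param out_dir output directory (`NULL` for no file output).
#' @param seed run seed; overrides the generator seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       center = NULL, bins = 100, r_range = c(0, 25),
                       cutoff = 0.6, flat_threshold = 0.01,
                       discard_frames = 0, peak_min_excess = 0.25,
                       input = "synthetic", out_dir = NULL,
                       seed = generator$seed) {
  generator$seed <- as.integer(seed)
  structure(list(generator = generator,
                 analysis = list(center = center %||% generator$pore_center,
                                 bins = bins, r_range = r_range,
                                 cutoff = cutoff,
                                 flat_threshold = flat_threshold,
                                 discard_frames = discard_frames,
                                 peak_min_excess = peak_min_excess),
                 io = list(input = input, out_dir = out_dir),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full curvature-sensing pipeline for one condition
#'
#' Orchestrates generate -> membrane profile -> localization -> contacts
#' and returns a sensing report. In synthetic mode the stages are:
#' generate membrane frames; extract and fit the radial height profile
#' and compute curvature regions; build the radial energy model and
#' sample protein traces for each replica; compute probability
#' histograms, RDFs (protein, PC, PIP2), the CoM heatmap and the KDE;
#' profile per-residue contacts with protein placements drawn from the
#' traces; and assign the verdict from the RDF peak region. All stage
#' outputs are written to `out_dir` (when set) together with a manifest
#' carrying the config hash and seed; rerunning the same config
#' reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @param n_contact_frames protein placements used for contact
#'   profiling.
#' @param verbose print per-stage progress.
#' @return a `sensing_report` list: `verdict`
#'   (`convex_sensing` / `concave_localized` / `indeterminate`),
#'   `peak_r`, `peak_region`, `pip2_enrichment_region`, `fit`,
#'   `curvature`, `rdf_protein`, `rdf_pc`, `rdf_pip2`, `heatmap`,
#'   `contacts_tails`, `contacts_pip2`, `top_tails`, `top_pip2`,
#'   `traces`, `manifest`.
#' @export
run_pipeline <- function(config, n_contact_frames = 20, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  gen <- validate_generator_config(config$generator)
  an <- config$analysis
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- "generate"
  report <- try({
    frames <- lapply(seq_len(gen$n_frames) - 1L, function(t)
      generate_membrane_frame(gen, time = t))
    say("generate: %d frames x %d beads", length(frames),
        nrow(frames[[1]]))

    stage <- "profile"
    prof <- radial_height_profile(frames, an$center, bin_width = 0.5,
                                  r_max = an$r_range[2])
    fit <- fit_sigmoid(prof)
    curv <- curvature_and_roc(fit, seq(an$r_range[1], an$r_range[2],
                                       by = 0.1),
                              flat_threshold = an$flat_threshold)
    say("profile: rss %.3g nm^2, most convex at %.1f nm", fit$rss,
        classify_regions(curv)$most_convex_r)

    stage <- "localize"
    energy <- radial_energy(gen, frames = frames)
    traces <- lapply(seq_len(gen$n_replicas), function(k)
      generate_protein_trace(gen, energy, replica_id = k))
    radii <- trace_radii(traces, an$center,
                         discard_frames = an$discard_frames)
    hist_p <- radial_histogram(radii, n_bins = an$bins,
                               r_range = an$r_range)
    rdf_p <- rdf_normalize(hist_p, an$center, gen$box)
    rdf_pc <- rdf_normalize(
      radial_histogram(frame_radii(frames, an$center, "PC_head"),
                       n_bins = an$bins, r_range = an$r_range,
                       species = "PC"),
      an$center, gen$box)
    rdf_pip2 <- if (gen$pip2_fraction > 0) rdf_normalize(
      radial_histogram(frame_radii(frames, an$center, "PIP2_head"),
                       n_bins = an$bins, r_range = an$r_range,
                       species = "PIP2"),
      an$center, gen$box) else NULL
    heat <- com_heatmap(traces, an$center)
    pk <- peak_location(rdf_p, curv, min_excess = an$peak_min_excess,
                        smooth_bins = 5)
    say("localize: peak %.2f nm in %s region", pk$peak_r %||% NA,
        pk$region %||% "none")

    stage <- "contacts"
    contact_frames <- contact_placements(gen, frames, traces,
                                         n_contact_frames)
    ct_tail <- average_contact_profile(
      contact_frames$frames, "tail", cutoff = an$cutoff,
      codes = gen$protein$sequence,
      replica_ids = contact_frames$replica_ids,
      group = "hydrophobic_tails")
    ct_pip2 <- if (gen$pip2_fraction > 0) average_contact_profile(
      contact_frames$frames, "PIP2_head", cutoff = an$cutoff,
      codes = gen$protein$sequence,
      replica_ids = contact_frames$replica_ids,
      group = "pip2_heads") else NULL

    stage <- "report"
    pip2_region <- if (!is.null(rdf_pip2))
      peak_location(rdf_pip2, curv, smooth_bins = 5)$region
      else NA_character_
    verdict <- if (pk$no_peak) "indeterminate"
      else if (identical(pk$region, "convex")) "convex_sensing"
      else if (identical(pk$region, "concave")) "concave_localized"
      else "indeterminate"
    list(verdict = verdict, peak_r = pk$peak_r, peak_region = pk$region,
         pip2_enrichment_region = pip2_region,
         fit = fit, curvature = curv, profile = prof, energy = energy,
         rdf_protein = rdf_p, rdf_pc = rdf_pc, rdf_pip2 = rdf_pip2,
         heatmap = heat,
         contacts_tails = ct_tail, contacts_pip2 = ct_pip2,
         top_tails = top_contact_residues(ct_tail,
                                          length(gen$protein$embedded_residues)),
         top_pip2 = if (!is.null(ct_pip2))
           top_contact_residues(ct_pip2, 5) else NULL,
         traces = traces)
  }, silent = TRUE)
  if (inherits(report, "try-error"))
    stopf("pipeline stage '%s' failed: %s", stage,
          attr(report, "condition")$message)
  report$manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("curvsense")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "sensing_report"
  if (!is.null(config$io$out_dir)) write_report(report, config)
  report
}

# protein placements for contact profiling: frames with the protein
# added at positions subsampled from the traces
contact_placements <- function(gen, frames, traces, n_contact_frames) {
  n_rep <- length(traces)
  per_rep <- max(1L, ceiling(n_contact_frames / n_rep))
  out <- list(); reps <- integer()
  fi <- 1L
  for (k in seq_len(n_rep)) {
    tr <- traces[[k]]
    pick <- round(seq(nrow(tr) / 2, nrow(tr), length.out = per_rep))
    for (s in pick) {
      base <- frames[[((fi - 1L) %% length(frames)) + 1L]]
      out[[fi]] <- add_protein_beads(base, gen,
                                     c(tr$x[s], tr$y[s]))
      reps <- c(reps, k)
      fi <- fi + 1L
    }
  }
  list(frames = out, replica_ids = reps)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_recursive(config), digits = NA,
                              auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

write_report <- function(report, config) {
  dir.create(config$io$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$io$out_dir, f)
  wt <- function(df, f) write.table(df, out(f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  wt(report$profile, "height_profile.tsv")
  write_curvature_profile(report$curvature, out("curvature.tsv"))
  wt(as.data.frame(report$rdf_protein), "rdf_protein.tsv")
  wt(as.data.frame(report$rdf_pc), "rdf_pc.tsv")
  if (!is.null(report$rdf_pip2))
    wt(as.data.frame(report$rdf_pip2), "rdf_pip2.tsv")
  wt(as.data.frame(unclass(report$heatmap)), "heatmap.tsv")
  write_contact_profile(report$contacts_tails, out("contacts_tails.tsv"))
  if (!is.null(report$contacts_pip2))
    write_contact_profile(report$contacts_pip2, out("contacts_pip2.tsv"))
  write_traces(report$traces, out("traces.tsv"))
  summ <- list(verdict = report$verdict, peak_r = report$peak_r,
               peak_region = report$peak_region,
               pip2_enrichment_region = report$pip2_enrichment_region,
               manifest = report$manifest)
  writeLines(jsonlite::toJSON(summ, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), out("report.json"))
  invisible(config$io$out_dir)
}

#' @export
print.sensing_report <- function(x, ...) {
  cat("sensing_report:\n")
  cat(sprintf("  verdict: %s (peak %.2f nm, region %s)\n", x$verdict,
              as.numeric(x$peak_r), x$peak_region %||% "none"))
  if (!is.null(x$pip2_enrichment_region) &&
      !is.na(x$pip2_enrichment_region))
    cat(sprintf("  PIP2 enriched in the %s region\n",
                x$pip2_enrichment_region))
  cat(sprintf("  top tail-contact residues: %s\n",
              paste(x$top_tails$residue_index, collapse = ", ")))
  invisible(x)
}

#' Condition matrix: presets x membrane compositions
#'
#' Runs the pipeline for each protein preset (`full`, `split`, `short`)
#' on each membrane composition (PC-only and PC/PIP2) and tabulates the
#' localization verdicts — the synthetic analogue of the study's
#' six-condition design.
#'
#' @param base a [generator_config()] providing geometry and sampling
#'   defaults.
#' @param presets list of presets, see [protein_presets()].
#' @param pip2_fractions named numeric vector of membrane compositions.
#' @param seed master seed.
#' @param ... passed to [run_pipeline()].
#' @return data frame with one row per condition: `protein`, `membrane`,
#'   `peak_r`, `peak_region`, `verdict`.
#' @export
run_condition_matrix <- function(base = generator_config(),
                                 presets = protein_presets(),
                                 pip2_fractions = c(PC = 0,
                                                    `PC/PIP2` = 0.025),
                                 seed = base$seed, ...) {
  rows <- list()
  for (mem in names(pip2_fractions)) {
    for (pn in names(presets)) {
      gen <- base
      gen$pip2_fraction <- unname(pip2_fractions[[mem]])
      gen$protein <- utils::modifyList(gen$protein, presets[[pn]])
      gen$seed <- derive_seed(seed, "misc",
                              match(pn, names(presets)) +
                                10L * match(mem, names(pip2_fractions)))
      rep <- run_pipeline(run_config(generator = gen, seed = gen$seed), ...)
      rows[[paste(pn, mem)]] <- data.frame(
        protein = pn, membrane = mem,
        peak_r = rep$peak_r %||% NA_real_,
        peak_region = rep$peak_region %||% NA_character_,
        verdict = rep$verdict)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
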