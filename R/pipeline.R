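# Config-driven two-system comparison: contact maps and their difference,
# focal-residue reports, named distance distributions with peaks, RMSF for
# both systems, interaction counts, and (optionally) nonbonded energies.

#' Build an analysis configuration
#'
#' @param trajectory_variant,trajectory_reference paths to multi-model PDB
#'   files, or [md_trajectory()] objects.
#' @param params_variant,params_reference optional nonbonded parameter table
#'   paths (or `nonbonded_params` objects); energetics run only when both are
#'   given.
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom (default 4.5).
#' @param population_threshold stable-contact reporting threshold (default 0.5).
#' @param hbond an [hbond_criteria()].
#' @param pipi a [pipi_criteria()].
#' @param bin_width histogram bin width, Angstrom (default 0.1).
#' @param rmsf_selection `"calpha"` or `"heavy"`.
#' @param align_selection alignment selection for [align_trajectory()].
#' @param stride frame stride for all per-frame analyses (default 1).
#' @param focal_residues integer vector of residue serial indices to report
#'   contact partners for.
#' @param distance_pairs list of `list(label, a, b)` selection pairs (see
#'   [select_atom()], [select_ring()]) for distance distributions.
#' @param ring_templates extra aromatic templates for nonstandard residues.
#' @param output_dir directory for TSV outputs and the summary.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(trajectory_variant, trajectory_reference,
                            params_variant = NULL, params_reference = NULL,
                            contact_cutoff = 4.5, population_threshold = 0.5,
                            hbond = hbond_criteria(), pipi = pipi_criteria(),
                            bin_width = 0.1, rmsf_selection = "calpha",
                            align_selection = "calpha", stride = 1L,
                            focal_residues = integer(0),
                            distance_pairs = list(),
                            ring_templates = NULL,
                            output_dir = tempfile("trajcontact_")) {
  stopifnot(contact_cutoff > 0, population_threshold >= 0,
            population_threshold <= 1, bin_width > 0, stride >= 1)
  structure(list(trajectory_variant = trajectory_variant,
                 trajectory_reference = trajectory_reference,
                 params_variant = params_variant,
                 params_reference = params_reference,
                 contact_cutoff = contact_cutoff,
                 population_threshold = population_threshold,
                 hbond = hbond, pipi = pipi, bin_width = bin_width,
                 rmsf_selection = rmsf_selection,
                 align_selection = align_selection,
                 stride = as.integer(stride),
                 focal_residues = as.integer(focal_residues),
                 distance_pairs = distance_pairs,
                 ring_templates = ring_templates,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised keys mirror the [analysis_config()] arguments; selection pairs
#' are given as `distance_pairs: [{label: ..., a: {atom: [chain, resno,
#' name]}, b: {ring: [chain, resno]}}, ...]`.
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  sel <- function(s) {
    if (!is.null(s$atom)) select_atom(s$atom[[1]], as.integer(s$atom[[2]]), s$atom[[3]])
    else if (!is.null(s$ring)) select_ring(s$ring[[1]], as.integer(s$ring[[2]]))
    else stop("selection must have 'atom' or 'ring'")
  }
  pairs <- lapply(y$distance_pairs, function(p)
    list(label = p$label, a = sel(p$a), b = sel(p$b)))
  hb <- do.call(hbond_criteria, as.list(y$hbond %||% list()))
  pp <- do.call(pipi_criteria, as.list(y$pipi %||% list()))
  analysis_config(
    trajectory_variant = y$trajectory_variant,
    trajectory_reference = y$trajectory_reference,
    params_variant = y$params_variant, params_reference = y$params_reference,
    contact_cutoff = y$contact_cutoff %||% 4.5,
    population_threshold = y$population_threshold %||% 0.5,
    hbond = hb, pipi = pp, bin_width = y$bin_width %||% 0.1,
    rmsf_selection = y$rmsf_selection %||% "calpha",
    align_selection = y$align_selection %||% "calpha",
    stride = y$stride %||% 1L,
    focal_residues = unlist(y$focal_residues) %||% integer(0),
    distance_pairs = pairs,
    output_dir = y$output_dir %||% tempfile("trajcontact_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_traj <- function(x) {
  if (inherits(x, "md_trajectory")) x else read_multimodel_pdb(x)
}

#' Run the full two-system comparison
#'
#' Executes, for both systems: contact-population maps (then their
#' difference), focal-residue partner reports, configured distance
#' distributions with peak lists, alignment and per-residue RMSF,
#' interaction counts, and nonbonded energies when parameters are supplied.
#' All results are written as TSVs plus a plain-text summary under
#' `config$output_dir`. The analysis itself is deterministic: rerunning the
#' same config on the same inputs reproduces the outputs byte for byte.
#'
#' @param config an [analysis_config()].
#' @return object of class `"comparison_report"` (named list of all results,
#'   with the config echoed in `$config`).
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  tv <- .load_traj(config$trajectory_variant)
  tr <- .load_traj(config$trajectory_reference)
  if (n_residues(tv) != n_residues(tr))
    stop("systems have different residue counts: ", n_residues(tv), " vs ",
         n_residues(tr))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  if (config$stride > 1L) {
    tv <- subset_frames(tv, seq(1L, n_frames(tv), by = config$stride))
    tr <- subset_frames(tr, seq(1L, n_frames(tr), by = config$stride))
  }

  cmap_v <- contact_population(tv, config$contact_cutoff)
  cmap_r <- contact_population(tr, config$contact_cutoff)
  dmap <- diff_contact_map(cmap_v, cmap_r)
  write_contact_map(cmap_v, out("contact_map_variant.tsv"))
  write_contact_map(cmap_r, out("contact_map_reference.tsv"))
  write_contact_map(dmap, out("contact_map_difference.tsv"))

  focal <- lapply(config$focal_residues, function(si)
    list(serial_index = si,
         variant = contacts_of_residue(cmap_v, si, config$population_threshold),
         reference = contacts_of_residue(cmap_r, si, config$population_threshold)))
  names(focal) <- as.character(config$focal_residues)

  # a configured pair may be resolvable in only one system (e.g. a ring that
  # exists only in the modified residue); the other side is reported as absent
  dists <- lapply(config$distance_pairs, function(p) {
    slug <- gsub("[^A-Za-z0-9]+", "_", p$label)
    one <- function(traj, sys) {
      s <- tryCatch(distance_series(traj, p$a, p$b,
                                    label = paste0(p$label, " (", sys, ")")),
                    error = function(e) NULL)
      if (is.null(s)) return(list(series = NULL, hist = NULL, peaks = NULL))
      h <- distance_histogram(s, config$bin_width)
      write_distribution(h, out(paste0("dist_", slug, "_", sys, ".tsv")))
      list(series = s, hist = h, peaks = find_peaks(h))
    }
    v <- one(tv, "variant"); r <- one(tr, "reference")
    if (is.null(v$series) && is.null(r$series))
      stop("distance pair '", p$label, "' resolves in neither system")
    list(label = p$label, series_variant = v$series, series_reference = r$series,
         hist_variant = v$hist, hist_reference = r$hist,
         peaks_variant = v$peaks, peaks_reference = r$peaks)
  })

  rmsf_v <- rmsf(align_trajectory(tv, config$align_selection), config$rmsf_selection)
  rmsf_r <- rmsf(align_trajectory(tr, config$align_selection), config$rmsf_selection)
  write_rmsf(rmsf_v, out("rmsf_variant.tsv"))
  write_rmsf(rmsf_r, out("rmsf_reference.tsv"))

  counts_v <- count_interactions(tv, config$hbond, config$pipi, config$ring_templates)
  counts_r <- count_interactions(tr, config$hbond, config$pipi, config$ring_templates)
  utils::write.table(counts_v, out("interaction_counts_variant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts_r, out("interaction_counts_reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  energy_v <- energy_r <- NULL
  if (!is.null(config$params_variant) && !is.null(config$params_reference)) {
    pv <- if (inherits(config$params_variant, "nonbonded_params"))
      config$params_variant else read_params_table(config$params_variant, tv$topology)
    pr <- if (inherits(config$params_reference, "nonbonded_params"))
      config$params_reference else read_params_table(config$params_reference, tr$topology)
    energy_v <- energy_report(tv, pv)
    energy_r <- energy_report(tr, pr)
    utils::write.table(energy_v, out("energies_variant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(energy_r, out("energies_reference.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- structure(list(config = config,
                           contact_variant = cmap_v, contact_reference = cmap_r,
                           diff_contact = dmap, focal = focal,
                           distances = dists,
                           rmsf_variant = rmsf_v, rmsf_reference = rmsf_r,
                           counts_variant = counts_v, counts_reference = counts_r,
                           energy_variant = energy_v, energy_reference = energy_r),
                      class = "comparison_report")
  writeLines(.report_summary(report), out("summary.txt"))
  report
}

.report_summary <- function(report) {
  cfg <- report$config
  ln <- c("trajcontact comparison report",
          "=============================",
          "",
          sprintf("contact cutoff: %.2f A; population threshold: %.2f; stride: %d",
                  cfg$contact_cutoff, cfg$population_threshold, cfg$stride),
          sprintf("H-bond criteria: H...A <= %.2f A, angle >= %.0f deg, D...A <= %.2f A",
                  cfg$hbond$max_ha, cfg$hbond$min_angle, cfg$hbond$max_da),
          sprintf("pi-pi criteria: COM <= %.2f A, parallel <= %.0f deg, T-shaped >= %.0f deg",
                  cfg$pipi$max_dist, cfg$pipi$parallel_max, cfg$pipi$tshaped_min),
          sprintf("histogram bin width: %.3f A; RMSF selection: %s; alignment: %s",
                  cfg$bin_width, cfg$rmsf_selection, cfg$align_selection),
          "")
  up <- upper.tri(report$diff_contact)
  ln <- c(ln, sprintf("contact pairs strengthened in variant (dC > 0): %d; weakened: %d",
                      sum(report$diff_contact[up] > 0),
                      sum(report$diff_contact[up] < 0)))
  for (si in names(report$focal))
    ln <- c(ln, "", summarize_focal_residue(report, as.integer(si)))
  for (d in report$distances) {
    pk <- function(p) {
      if (is.null(p)) return("n/a (selection not present)")
      if (nrow(p)) sprintf("%.2f A (p = %.3f)", p$center[1], p$prob[1]) else "none"
    }
    ln <- c(ln, "", sprintf("distance '%s': variant peak %s; reference peak %s",
                            d$label, pk(d$peaks_variant), pk(d$peaks_reference)))
  }
  ln <- c(ln, "",
          sprintf("mean H-bonds per frame: variant %.2f, reference %.2f",
                  attr(report$counts_variant, "mean_hbond"),
                  attr(report$counts_reference, "mean_hbond")),
          sprintf("mean pi-pi per frame: variant %.2f, reference %.2f",
                  attr(report$counts_variant, "mean_pipi"),
                  attr(report$counts_reference, "mean_pipi")))
  if (!is.null(report$energy_variant))
    ln <- c(ln, "",
            sprintf("E_elec mean (kcal/mol): variant %.3f, reference %.3f",
                    attr(report$energy_variant, "mean_elec"),
                    attr(report$energy_reference, "mean_elec")),
            sprintf("E_vdw mean (kcal/mol): variant %.3f, reference %.3f",
                    attr(report$energy_variant, "mean_vdw"),
                    attr(report$energy_reference, "mean_vdw")))
  ln
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(.report_summary(x), sep = "\n")
  invisible(x)
}

#' Text block describing one focal residue's contact partners
#'
#' Lists, for both systems, the partners whose contact population meets the
#' configured threshold, with the population difference.
#'
#' @param report a [run_compare()] result.
#' @param serial_index focal residue serial index.
#' @return character vector of text lines.
#' @export
summarize_focal_residue <- function(report, serial_index) {
  stopifnot(inherits(report, "comparison_report"))
  R <- nrow(report$contact_variant)
  if (serial_index < 1 || serial_index > R)
    stop("serial index out of range: ", serial_index)
  th <- report$config$population_threshold
  cv <- contacts_of_residue(report$contact_variant, serial_index, th)
  cr <- contacts_of_residue(report$contact_reference, serial_index, th)
  lab <- attr(report$contact_variant, "labels")[serial_index]
  ln <- sprintf("focal residue %s (population threshold %.2f):", lab, th)
  fmt <- function(df, sys) {
    if (!nrow(df))
      return(sprintf("  %s: no partners at or above threshold", sys))
    dc <- unclass(report$diff_contact)[serial_index, df$partner]
    c(sprintf("  %s:", sys),
      sprintf("    %-22s population %.3f  dC %+0.3f", df$label, df$population, dc))
  }
  c(ln, fmt(cv, "variant"), fmt(cr, "reference"))
}
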