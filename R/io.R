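#' Particle-table I/O
#'
#' Particle sets are exchanged as TSV, one row per subunit, with
#' mandatory header `particle_id, symmetry_order, hub_x_nm, hub_y_nm,
#' vertex_x_nm, vertex_y_nm, kinase_x_nm, kinase_y_nm, label` and `.`
#' for missing values. Subunit j is anchored at hub vertex ceiling(j/2),
#' so each vertex row is repeated for its two subunits. Coordinates are
#' written at 0.001 nm precision (image frame: x right, y down, angles
#' clockwise-positive). Unknown extra columns are preserved on read in
#' `attr(, "extra_columns")`.
#'
#' @param particle_set a `particle_set` (or list of `holo_particle`).
#' @param path file path.
#' @return `write_particles()` returns `path` invisibly;
#'   `read_particles()` returns a `particle_set` (with `config = NULL`).
#' @export
write_particles <- function(particle_set, path) {
  particles <- if (inherits(particle_set, "particle_set")) {
    particle_set$particles
  } else {
    particle_set
  }
  rows <- lapply(seq_along(particles), function(i) {
    p <- particles[[i]]
    n_sub <- nrow(p$kinase_centers)
    anchor <- rep(seq_len(nrow(p$hub_vertices)), each = 2)[seq_len(n_sub)]
    data.frame(
      particle_id = i,
      symmetry_order = if (isTRUE(p$ambiguous)) "." else p$symmetry_order,
      hub_x_nm = sprintf("%.3f", p$hub_center[1]),
      hub_y_nm = sprintf("%.3f", p$hub_center[2]),
      vertex_x_nm = sprintf("%.3f", p$hub_vertices[anchor, 1]),
      vertex_y_nm = sprintf("%.3f", p$hub_vertices[anchor, 2]),
      kinase_x_nm = sprintf("%.3f", p$kinase_centers[, 1]),
      kinase_y_nm = sprintf("%.3f", p$kinase_centers[, 2]),
      label = p$subunit_labels
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

particle_columns <- c("particle_id", "symmetry_order", "hub_x_nm", "hub_y_nm",
                      "vertex_x_nm", "vertex_y_nm", "kinase_x_nm",
                      "kinase_y_nm", "label")

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(particle_columns, names(tab))
  if (length(missing_cols)) {
    stop("particle table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("particle table has a header but no rows: empty particle set")
    return(structure(list(particles = list(), config = NULL),
                     class = "particle_set"))
  }
  num <- function(col) {
    x <- tab[[col]]
    x[x == "."] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != "NA")
    if (length(bad)) {
      stop(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                   bad[1], col, tab[bad[1], col]))
    }
    v
  }
  cols <- lapply(stats::setNames(nm = c("hub_x_nm", "hub_y_nm", "vertex_x_nm",
                                        "vertex_y_nm", "kinase_x_nm",
                                        "kinase_y_nm")), num)
  ids <- tab$particle_id
  particles <- lapply(split(seq_len(nrow(tab)), factor(ids, unique(ids))),
                      function(idx) {
    n_sub <- length(idx)
    sym <- tab$symmetry_order[idx[1]]
    ambiguous <- sym == "."
    k <- n_sub %/% 2L
    if (!ambiguous) {
      k_stated <- as.integer(sym)
      if (n_sub != 2L * k_stated) {
        stop(sprintf(
          "particle '%s': %d subunit rows inconsistent with symmetry_order %s",
          tab$particle_id[idx[1]], n_sub, sym))
      }
      k <- k_stated
    }
    anchor_first <- idx[seq(1, n_sub, by = 2)]
    structure(list(
      hub_center = c(cols$hub_x_nm[idx[1]], cols$hub_y_nm[idx[1]]),
      symmetry_order = k,
      hub_vertices = cbind(cols$vertex_x_nm[anchor_first],
                           cols$vertex_y_nm[anchor_first]),
      kinase_centers = cbind(cols$kinase_x_nm[idx], cols$kinase_y_nm[idx]),
      subunit_labels = tab$label[idx],
      ambiguous = ambiguous
    ), class = "holo_particle")
  })
  names(particles) <- NULL
  out <- structure(list(particles = particles, config = NULL),
                   class = "particle_set")
  extra <- setdiff(names(tab), particle_columns)
  if (length(extra)) attr(out, "extra_columns") <- tab[, extra, drop = FALSE]
  out
}

#' Field-table I/O
#'
#' Fields of holoenzymes are exchanged as TSV with columns
#' `holoenzyme_id, hub_x_nm, hub_y_nm, clustered_truth`.
#'
#' @param field a `field_set` or a compatible data.frame.
#' @param path file path.
#' @export
write_field <- function(field, path) {
  tab <- if (inherits(field, "field_set")) field$table else field
  out <- tab
  out$hub_x_nm <- sprintf("%.3f", tab$hub_x_nm)
  out$hub_y_nm <- sprintf("%.3f", tab$hub_y_nm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("holoenzyme_id", "hub_x_nm", "hub_y_nm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("field table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab
}

#' Dose-response CSV I/O
#'
#' CSV with columns `cam_molar, replicate, activity` (CaM concentration
#' in mol/L, activity as fraction of Vmax).
#'
#' @param dataset a `dose_response` data.frame.
#' @param path file path.
#' @export
write_dose_response <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, c("cam_molar", "replicate",
                                              "activity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("cam_molar", "replicate", "activity")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("dose-response table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(tab$cam_molar <= 0)) stop("concentrations must be strictly positive")
  class(tab) <- c("dose_response", "data.frame")
  tab
}

#' Measurement-table TSV output
#'
#' @param mt a `measurement_table` from [measure_particles()].
#' @param path file path.
#' @export
write_measurements <- function(mt, path) {
  utils::write.table(mt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulation-config YAML I/O
#'
#' The YAML mirrors [simulation_config()] field names one-to-one.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$stoichiometry_mix <- as.list(x$stoichiometry_mix)
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  mix <- unlist(x$stoichiometry_mix)
  x$stoichiometry_mix <- mix
  do.call(simulation_config, x)
}

#' Run the full analysis pipeline on a synthetic ensemble
#'
#' Wires the stages end to end: simulate an ensemble (and optionally a
#' clustered field and a dose-response dataset), measure every subunit,
#' summarize the radius and separation distributions, run the state
#' classifiers and stoichiometry census, evaluate the polymer null, and
#' fit the Hill model. Returns (and optionally writes, as YAML) a
#' machine-readable report of every printed-style summary together with
#' the seed and config, so a rerun with the same arguments is
#' reproducible field for field.
#'
#' @param config a [simulation_config()].
#' @param n_particles ensemble size.
#' @param seed integer seed for every stochastic stage.
#' @param field optional list of arguments to [simulate_field()]
#'   (e.g. `list(n_holoenzymes = 300, extent = 2000,
#'   cluster_fraction = 0.58)`); `NULL` skips the clustering stage.
#' @param dose_response optional list with `vmax`, `ec50`, `hill_h` (and
#'   optionally `noise_sd`, `replicates`) for the activation stage;
#'   `NULL` skips it.
#' @param out_dir optional directory; when given, the report is written
#'   to `report.yaml` and the tables to TSV alongside it.
#' @return A `pipeline_report` list.
#' @export
#' @examples
#' rep <- run_pipeline(alpha_config(), n_particles = 100, seed = 1)
#' rep$radius$mean_nm
run_pipeline <- function(config, n_particles = 1000, seed = 1,
                         field = NULL, dose_response = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ens <- simulate_ensemble(config, n_particles, seed = seed)
  mt <- measure_particles(
    ens,
    hub_radius = config$hub_radius, kinase_radius = config$kinase_radius,
    compact_cutoff = config$compact_cutoff)

  rad <- gaussian_summary(mt$kinase_radius_nm)
  sep <- gaussian_summary(mt$neighbor_separation_nm)
  compact <- classify_compact(mt$kinase_radius_nm, config$compact_cutoff)
  dimers <- classify_dimers(mt$neighbor_separation_nm)
  census <- stoichiometry_census(ens)
  mean_ext <- mean(mt$linker_extension_nm)
  b_cal <- calibrate_step(max(mean_ext, 1e-6), config$linker_residues)

  report <- list(
    package_version = as.character(utils::packageVersion("holokin")),
    seed = seed,
    n_particles = n_particles,
    n_subunits = nrow(mt),
    config = {
      x <- unclass(config)
      x$stoichiometry_mix <- as.list(x$stoichiometry_mix)
      x
    },
    radius = list(
      mean_nm = round(rad$mean, 2), sd_nm = round(rad$sd, 2),
      sem_nm = round(rad$sem, 3), envelope95_nm = round(rad$envelope95, 1),
      gaussian_fit_mean_nm = round(rad$fit$mean, 2),
      gaussian_fit_sd_nm = round(rad$fit$sd, 2)
    ),
    linker = list(
      mean_extension_nm = round(mean_ext, 2),
      chain_n_residues = config$linker_residues,
      calibrated_step_b_nm = round(b_cal, 4),
      chain_rms_extension_nm = round(
        expected_end_to_end(config$linker_residues, b_cal), 2)
    ),
    separation = list(
      mean_nm = round(sep$mean, 2), sd_nm = round(sep$sd, 2),
      sem_nm = round(sep$sem, 3)
    ),
    state_fractions = list(
      compact_percent = round(100 * compact$fraction, 1),
      dimer_percent = as.list(stats::setNames(
        round(100 * dimers$fractions, 1),
        paste0("cutoff_", names(dimers$fractions), "_nm")))
    ),
    local_concentration_mM = round(local_concentration(12, rad$mean), 2),
    census = stats::setNames(as.list(round(census$percent, 2)),
                             paste0("called_", census$call))
  )

  if (!is.null(field)) {
    fargs <- utils::modifyList(list(config = config, seed = seed,
                                    particles = FALSE), field)
    fs <- do.call(simulate_field, fargs)
    det <- detect_clusters(fs)
    report$clustering <- list(
      n_holoenzymes = nrow(fs$table),
      truth_percent = round(100 * mean(fs$table$clustered_truth), 1),
      detected_percent = round(100 * det$fraction, 1),
      n_clusters = det$n_components
    )
  }
  if (!is.null(dose_response)) {
    dargs <- utils::modifyList(list(seed = seed), dose_response)
    dr <- do.call(simulate_dose_response, dargs)
    hf <- fit_hill(dr)
    report$hill_fit <- list(
      vmax = round(hf$vmax, 4),
      ec50_nM = round(hf$ec50 * 1e9, 2),
      hill_h = round(hf$hill_h, 3),
      se_ec50_nM = round(hf$se[["ec50"]] * 1e9, 2),
      se_hill_h = round(hf$se[["hill_h"]], 3),
      rss = signif(hf$rss, 4), df = hf$df
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
    write_particles(ens, file.path(out_dir, "particles.tsv"))
    write_measurements(mt, file.path(out_dir, "measurements.tsv"))
  }
  structure(report, class = c("pipeline_report", "list"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d particles (seed %d)\n", x$n_particles, x$seed))
  cat(sprintf("  kinase radius: %.1f +/- %.1f nm (SEM %.2f), 95%% envelope %.0f nm\n",
              x$radius$mean_nm, x$radius$sd_nm, x$radius$sem_nm,
              x$radius$envelope95_nm))
  cat(sprintf("  linker extension: %.1f nm (chain b = %.3f nm over %d residues)\n",
              x$linker$mean_extension_nm, x$linker$calibrated_step_b_nm,
              x$linker$chain_n_residues))
  cat(sprintf("  neighbor separation: %.1f +/- %.1f nm\n",
              x$separation$mean_nm, x$separation$sd_nm))
  cat(sprintf("  compact: %.1f%%; dimers: %s\n",
              x$state_fractions$compact_percent,
              paste(sprintf("%s %.1f%%",
                            names(x$state_fractions$dimer_percent),
                            unlist(x$state_fractions$dimer_percent)),
                    collapse = ", ")))
  cat(sprintf("  local concentration (12-mer): %.2f mM\n",
              x$local_concentration_mM))
  cat("  census:", paste(sprintf("%s %.2f%%", names(x$census),
                                 unlist(x$census)), collapse = ", "), "\n")
  invisible(x)
}
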