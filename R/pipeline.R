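# End-to-end orchestration: the three analysis entry points used by the
# command-line front-end (inst/cli/stretchplate.R). Each takes a config list
# (or YAML path), writes CSV/JSON outputs stamped with the seed and a config
# hash, and returns its results invisibly.

check_config <- function(config, allowed, required = character(0)) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "))
  config
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  z <- utf8ToInt(s)
  sprintf("%08x", sum(z * (seq_along(z) %% 97 + 1)) %% .Machine$integer.max)
}

layout_from_config <- function(config) {
  if (is.null(config$layout)) return(plate_layout())
  do.call(plate_layout, config$layout)
}

stamp <- function(config) {
  list(seed = config$seed %||% NA, config_hash = config_hash(config))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Strain calibration: per-well strain map and distribution summary
#'
#' Reads a fiducial-dot measurement CSV (columns well, replicate, pre_width,
#' pre_height, post_width, post_height, unit), computes the per-well
#' equibiaxial Lagrangian strain map, summarizes the across-well
#' distribution, and optionally fits the displacement-strain line when a
#' displacement CSV (columns displacement, strain) is supplied.
#'
#' @param config list or YAML path. Keys: \code{measurements_csv} (required),
#'   \code{out_dir} (required), \code{layout} (list of plate_layout args),
#'   \code{displacement_csv}, \code{negligible_threshold}, \code{seed}.
#' @return (invisibly) list with \code{strain_map}, \code{summary} and
#'   optionally \code{displacement_curve}.
#' @export
run_strain_calibration <- function(config) {
  config <- check_config(config,
    allowed = c("measurements_csv", "out_dir", "layout", "displacement_csv",
                "negligible_threshold", "seed"),
    required = c("measurements_csv", "out_dir"))
  if (!file.exists(config$measurements_csv))
    stop("measurements CSV not found: ", config$measurements_csv)
  meas <- utils::read.csv(config$measurements_csv, stringsAsFactors = FALSE)
  need <- c("well", "pre_width", "pre_height", "post_width", "post_height")
  if (!all(need %in% names(meas)))
    stop("malformed measurements CSV; need columns: ",
         paste(need, collapse = ", "))
  layout <- layout_from_config(config)
  smap <- plate_strain_map(meas, layout)
  summ <- summarize_strain_distribution(smap)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(smap, file.path(config$out_dir, "well_strain.csv"),
                   row.names = FALSE)
  out <- list(strain_map = smap, summary = summ)
  if (!is.null(config$displacement_csv)) {
    dd <- utils::read.csv(config$displacement_csv, stringsAsFactors = FALSE)
    curve <- displacement_strain_curve(
      dd$displacement, dd$strain,
      negligible_threshold = config$negligible_threshold %||% 0.02)
    out$displacement_curve <- curve
    summ$displacement_slope <- curve$slope
    summ$displacement_intercept <- curve$intercept
    summ$negligible_levels <- sum(curve$negligible)
  }
  write_json_out(c(summ, stamp(config)),
                 file.path(config$out_dir, "strain_summary.json"))
  invisible(out)
}

read_channel <- function(path) {
  img <- EBImage::readImage(path)
  ebi_mat(img)
}

#' Injury morphometry and dose-response fitting
#'
#' Three input modes. \code{well_table_csv}: a ready per-well table with
#' \code{strain} and metric columns is fitted directly. \code{plate_map_csv}:
#' rows (well, channel, path) pointing at nuclear/viability TIFFs per well,
#' joined with \code{strain_csv} (well, E), are segmented and measured, then
#' fitted. \code{synthetic}: a seeded simulated experiment is generated and
#' fitted. Writes the per-well metrics CSV and a fit-report CSV/JSON.
#'
#' @param config list or YAML path. Keys: one of \code{well_table_csv},
#'   \code{plate_map_csv} (+ \code{strain_csv}), or \code{synthetic} (list of
#'   \code{\link{simulate_injury_experiment}} args); plus \code{out_dir}
#'   (required), \code{pixel_size}, \code{reference_count}, \code{seed}.
#' @return (invisibly) list with \code{well_table} and \code{fit_report}.
#' @export
run_injury_analysis <- function(config) {
  config <- check_config(config,
    allowed = c("well_table_csv", "plate_map_csv", "strain_csv", "synthetic",
                "out_dir", "pixel_size", "reference_count", "seed"),
    required = "out_dir")
  if (!is.null(config$well_table_csv)) {
    tab <- utils::read.csv(config$well_table_csv, stringsAsFactors = FALSE)
  } else if (!is.null(config$plate_map_csv)) {
    pm <- utils::read.csv(config$plate_map_csv, stringsAsFactors = FALSE)
    strains <- utils::read.csv(config$strain_csv, stringsAsFactors = FALSE)
    wells <- unique(pm$well)
    rows <- list()
    for (w in wells) {
      sub <- pm[pm$well == w, ]
      nuc_path <- sub$path[sub$channel == "nuclear"]
      via_path <- sub$path[sub$channel == "viability"]
      if (length(nuc_path) != 1 || length(via_path) != 1 ||
          !file.exists(nuc_path) || !file.exists(via_path)) {
        warning("well ", w, " skipped: missing or unreadable channels")
        next
      }
      res <- analyze_live_image(read_channel(nuc_path), read_channel(via_path),
                                pixel_size = config$pixel_size %||% 0.33,
                                reference_count = config$reference_count)
      rows[[w]] <- cbind(data.frame(well = w, stringsAsFactors = FALSE),
                         res$metrics)
      message("well ", w, ": ", res$metrics$viable_cells_per_image,
              " viable cells")
    }
    tab <- do.call(rbind, rows)
    tab <- merge(tab, strains[, c("well", "E")], by = "well")
    names(tab)[names(tab) == "E"] <- "strain"
  } else if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (!is.null(config$seed) && is.null(args$seed)) args$seed <- config$seed
    tab <- do.call(simulate_injury_experiment, args)
  } else stop("supply well_table_csv, plate_map_csv or synthetic")
  fits <- fit_all_metrics(tab)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab, file.path(config$out_dir, "well_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fits$summary, file.path(config$out_dir, "fit_report.csv"),
                   row.names = FALSE)
  write_json_out(c(list(fits = fits$summary,
                        Et_range = fits$Et_range), stamp(config)),
                 file.path(config$out_dir, "fit_report.json"))
  invisible(list(well_table = tab, fit_report = fits))
}

#' Compartmentalized synaptophysin density and group comparison
#'
#' For each well listed in the plate map (channels map2, synaptophysin),
#' builds the cell mask by background thresholding the median-filtered MAP2
#' channel, splits it into soma and neurite compartments, computes the three
#' synaptophysin densities, and compares control vs injured groups per
#' compartment with Welch t-tests at the Bonferroni-corrected 0.05/3 level.
#'
#' @param config list or YAML path. Keys: \code{plate_map_csv} (well,
#'   channel, path), \code{groups_csv} (well, group with values control /
#'   injured), \code{out_dir} (required), \code{erosion_radius},
#'   \code{dilation_px}, \code{seed}; or \code{densities_csv} (precomputed
#'   well, group, ratio_cell, ratio_soma, ratio_neurite).
#' @return (invisibly) list with \code{densities} and \code{comparison}.
#' @export
run_synapse_analysis <- function(config) {
  config <- check_config(config,
    allowed = c("plate_map_csv", "groups_csv", "densities_csv", "out_dir",
                "erosion_radius", "dilation_px", "seed"),
    required = "out_dir")
  if (!is.null(config$densities_csv)) {
    dens <- utils::read.csv(config$densities_csv, stringsAsFactors = FALSE)
  } else {
    pm <- utils::read.csv(config$plate_map_csv, stringsAsFactors = FALSE)
    groups <- utils::read.csv(config$groups_csv, stringsAsFactors = FALSE)
    rows <- list()
    for (w in unique(pm$well)) {
      sub <- pm[pm$well == w, ]
      m_path <- sub$path[sub$channel == "map2"]
      s_path <- sub$path[sub$channel == "synaptophysin"]
      if (length(m_path) != 1 || length(s_path) != 1) {
        warning("well ", w, " skipped: missing channels"); next
      }
      map2 <- ebi_mat(EBImage::medianFilter(
        EBImage::Image(clip01(read_channel(m_path))), size = 1))
      masks <- split_compartments(background_threshold(map2),
                                  erosion_radius = config$erosion_radius %||% 4,
                                  dilation_px = config$dilation_px %||% 3)
      d <- synaptophysin_density(read_channel(s_path), masks)
      rows[[w]] <- cbind(data.frame(well = w, stringsAsFactors = FALSE), d)
    }
    dens <- do.call(rbind, rows)
    dens <- merge(dens, groups, by = "well")
  }
  ctrl <- dens[dens$group == "control", ]
  inj <- dens[dens$group == "injured", ]
  comparison <- NULL
  if (nrow(ctrl) >= 2 && nrow(inj) >= 2) {
    comparison <- compare_groups(ctrl, inj)
  } else warning("a group has fewer than 2 wells; comparison skipped")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dens, file.path(config$out_dir, "densities.csv"),
                   row.names = FALSE)
  if (!is.null(comparison)) {
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    write_json_out(c(list(comparison = comparison,
                          n_control = nrow(ctrl), n_injured = nrow(inj)),
                     stamp(config)),
                   file.path(config$out_dir, "comparison.json"))
  }
  invisible(list(densities = dens, comparison = comparison))
}

#' Write rendered culture-scene channels and ground truth to disk
#'
#' Channels are written as single-plane grayscale TIFFs, the scalar ground
#' truth as CSV, and the scene parameters plus seed as a JSON sidecar.
#'
#' @param rendered result of \code{\link{gen_culture_image}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return (invisibly) the paths written.
#' @export
write_scene <- function(rendered, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(rendered$channels)) {
    p <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    EBImage::writeImage(EBImage::Image(rendered$channels[[ch]]), p, type = "tiff")
    paths <- c(paths, p)
  }
  t <- rendered$truth
  truth_df <- data.frame(
    viable_count = t$viable_count, dead_count = t$dead_count,
    total_neurite_length_um = t$total_neurite_length_um,
    total_processes = t$total_processes, total_branches = t$total_branches,
    n_puncta_soma = t$n_puncta_soma, n_puncta_neurite = t$n_puncta_neurite,
    injury_level = t$injury_level)
  csv <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(truth_df, csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_scene.json"))
  sc <- rendered$scene
  write_json_out(list(width = sc$width, height = sc$height,
                      pixel_size = sc$pixel_size, seed = sc$seed,
                      n_cells = nrow(sc$somata),
                      injury_level = t$injury_level), js)
  invisible(c(paths, csv, js))
}
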