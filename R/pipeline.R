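#' Reference measurement tables for the bark/straw milling study
#'
#' Small tables of measured indicator values for pine bark and wheat straw
#' powders shipped with the package: per-mill rheology indices (Carr index,
#' 15 kPa compressibility, Mohr-Coulomb cohesion) for the six ultrafine
#' powders, and the shape medians and density pair of the two impact-milled
#' feed powders. They serve as ground-truth anchors for the synthetic study
#' and as worked-example inputs.
#'
#' @param which One of `"rheology"`, `"feed_shape"`, `"feed_density"`.
#' @return A `data.frame`.
#' @export
reference_table <- function(which = c("rheology", "feed_shape",
                                      "feed_density")) {
  which <- match.arg(which)
  file <- switch(which,
                 rheology = "rheology_reference.csv",
                 feed_shape = "feed_shape_reference.csv",
                 feed_density = "feed_density_reference.csv")
  utils::read.csv(system.file("extdata", file, package = "powdermetrics",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

# per-powder ground-truth parameters of the synthetic six-powder study.
# PSD mode tweaks give VBM powders more fines (attrition erodes surfaces);
# planted agglomeration follows the observed pattern: bark >= 14 % total with
# hard-dominated VBM (> 20 % total), straw lighter with very little
# agglomeration in the SBM; shape medians: bark ~0.35 at all mills, straw
# small particles rounder than coarse, VBM coarse most elongated.
study_truth <- function() {
  rheo <- reference_table("rheology")
  truth <- data.frame(
    powder = c("RBM_bark", "SBM_bark", "VBM_bark",
               "RBM_straw", "SBM_straw", "VBM_straw"),
    biomass = rep(c("bark", "straw"), each = 3),
    soft = c(0.09, 0.08, 0.10, 0.05, 0.03, 0.09),
    hard = c(0.05, 0.08, 0.12, 0.06, 0.01, 0.03),
    fines_weight = c(0.30, 0.25, 0.42, 0.20, 0.20, 0.35),
    elong_small = c(0.35, 0.35, 0.36, 0.39, 0.39, 0.45),
    elong_large = c(0.33, 0.34, 0.36, 0.50, 0.52, 0.62),
    roughness = c(0.18, 0.18, 0.20, 0.17, 0.17, 0.19),
    rho_a = c(300, 310, 295, 150, 145, 140))
  m <- merge(truth, rheo[, c("powder", "carr_index_pct",
                             "compressibility_pct", "cohesion_kpa")],
             by = "powder")
  m[match(truth$powder, m$powder), ]
}

# dry/wet PSD spec for one synthetic powder
powder_psd_spec <- function(biomass, fines_weight, bin_grid) {
  if (biomass == "bark")
    psd_spec(data.frame(gm = c(7, 32), gsd = c(1.9, 1.9),
                        weight = c(fines_weight, 1 - fines_weight)),
             bin_grid)
  else
    psd_spec(data.frame(gm = c(6, 24), gsd = c(1.8, 2.6),
                        weight = c(fines_weight, 1 - fines_weight)),
             bin_grid)
}

#' Simulate a complete six-powder milling study
#'
#' Writes synthetic instrument exports for the 3 mills x 2 biomasses study
#' into `dir`, in the exact CSV dialects [run_pipeline()] reads:
#' `psd/<powder>_dry.csv` plus the `_ND/_LG/_EP` wet triplet,
#' `shape/<powder>.csv` (fine x20 and coarse x10 magnification records), and
#' `rheology/densities.csv`, `compression.csv`, `shear.csv`. Ground truth
#' (planted soft/hard fractions, true cohesion, shape medians, ...) is
#' returned so closed-loop tests can compare recovered against planted
#' values.
#'
#' @param dir Output directory (created if needed).
#' @param seed Base integer seed; every powder and stage derives its own
#'   sub-seed from it.
#' @param config A [study_config()].
#' @param n_shape_particles Silhouettes per magnification population.
#' @return Invisibly, the ground-truth `data.frame` (one row per powder).
#' @export
simulate_study <- function(dir, seed = 1L, config = study_config(seed = seed),
                           n_shape_particles = 300L) {
  truth <- study_truth()
  for (sub in c("psd", "shape", "rheology"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  dens <- comp <- shear <- list()
  for (i in seq_len(nrow(truth))) {
    tw <- truth[i, ]
    s0 <- as.integer(seed) * 1000L + i * 10L
    spec <- powder_psd_spec(tw$biomass, tw$fines_weight, config$bin_grid)

    dry <- generate_psd(spec, seed = s0 + 1L, label = tw$powder,
                        treatment = "dry")
    write_psd_csv(dry, file.path(dir, "psd", paste0(tw$powder, "_dry.csv")))

    wet <- generate_psd(spec, seed = s0 + 2L, label = tw$powder)
    trip <- plant_agglomeration(
      wet, agglomeration_plan(tw$soft, tw$hard),
      lower_cut_um = config$ssa_lower_cut_um,
      renormalize = config$ssa_renormalize)
    for (tr in c("ND", "LG", "EP"))
      write_psd_csv(trip[[tolower(tr)]],
                    file.path(dir, "psd", paste0(tw$powder, "_", tr, ".csv")))

    shp <- rbind(
      simulate_shape_records(tw$elong_small, tw$roughness, log(8), 0.45,
                             "x20", upper_um = config$merge_boundary_um,
                             n = n_shape_particles, seed = s0 + 3L),
      simulate_shape_records(tw$elong_large, tw$roughness, log(38), 0.40,
                             "x10", lower_um = config$merge_boundary_um,
                             n = n_shape_particles, seed = s0 + 4L))
    shp$particle_id <- seq_len(nrow(shp))
    write_shape_csv(shp, file.path(dir, "shape", paste0(tw$powder, ".csv")))

    dens[[i]] <- cbind(powder = tw$powder,
                       density_pair_for_carr(tw$rho_a, tw$carr_index_pct))
    comp[[i]] <- cbind(powder = tw$powder,
                       generate_compression_test(
                         85, tw$compressibility_pct,
                         config$compression_stresses_kpa))
    shear[[i]] <- cbind(powder = tw$powder,
                        generate_shear_test(
                          tw$cohesion_kpa, friction = 0.6,
                          noise_sd_kpa = 0.01,
                          stresses_kpa = config$shear_stresses_kpa,
                          seed = s0 + 5L))
  }
  utils::write.csv(do.call(rbind, dens),
                   file.path(dir, "rheology", "densities.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, comp),
                   file.path(dir, "rheology", "compression.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, shear),
                   file.path(dir, "rheology", "shear.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(truth)
}

# generate one magnification population and return measured shape records
# restricted to the requested size side (draws falling across the merge
# boundary are discarded, as they would be imaged with the other lens)
simulate_shape_records <- function(median_elongation, roughness,
                                   diameter_meanlog, diameter_sdlog,
                                   magnification, n, seed,
                                   lower_um = NULL, upper_um = NULL) {
  spec <- shape_population_spec(
    n_particles = n,
    diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
    elongation_shape1 = 2,
    elongation_shape2 = elongation_beta_for_median(median_elongation),
    roughness = roughness, n_vertices = 64L)
  recs <- shape_table(generate_shapes(spec, seed), magnification)
  if (!is.null(lower_um)) recs <- recs[recs$esd_um > lower_um, , drop = FALSE]
  if (!is.null(upper_um)) recs <- recs[recs$esd_um < upper_um, , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

# weighted medians of the merged shape records
shape_medians <- function(records) {
  if (is.null(records$weight_pct)) records <- volume_weights(records)
  data.frame(
    median_esd_um = cumulative_distribution(records$esd_um,
                                            records$weight_pct)$median,
    median_elongation = cumulative_distribution(records$elongation,
                                                records$weight_pct)$median,
    median_convexity = cumulative_distribution(records$convexity,
                                               records$weight_pct)$median)
}

write_output_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full powder-characterization pipeline on a study directory
#'
#' Reads every powder found under `input_dir` (layout as written by
#' [simulate_study()]) and computes, per powder: the dry-PSD size summary
#' (d10/d50/d90, span, SSA), soft/hard agglomeration and the size-class
#' shift table from the wet ND/LG/EP triplet, volume-weighted shape medians
#' (after the 50/50 magnification merge, or after the minimum-size filter
#' for single-lens feed records), and the rheology indices (Carr index,
#' compressibility, cohesion). The per-powder indicators are then normalized
#' and ranked by relative radar area.
#'
#' Powders with an incomplete wet triplet keep their other results; the
#' agglomeration stage is skipped for them with a message.
#'
#' @param input_dir Directory with `psd/`, `shape/`, `rheology/` inputs.
#' @param output_dir Optional; when given, tidy CSVs (stamped with the
#'   configuration hash) and a run log are written there.
#' @param config A [study_config()].
#' @return A list with `size_summary`, `agglomeration`, `class_shift`,
#'   `shape_summary`, `rheology`, `profiles`, `ranking` and `config_hash`.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL,
                         config = study_config()) {
  psd_dir <- file.path(input_dir, "psd")
  dry_files <- sort(list.files(psd_dir, pattern = "_dry\\.csv$",
                               full.names = TRUE))
  if (length(dry_files) == 0L)
    stop("no '<powder>_dry.csv' PSD inputs found under ", psd_dir,
         call. = FALSE)
  powders <- sub("_dry\\.csv$", "", basename(dry_files))
  hash <- config_hash(config)
  log_lines <- c(sprintf("powdermetrics run"),
                 sprintf("config_hash: %s", hash),
                 sprintf("seed: %d", config$seed),
                 sprintf("powders: %s", paste(powders, collapse = ", ")))

  size_summary <- list(); agglo <- list(); shifts <- list()
  shape_sum <- list(); rheo <- list()
  read_or_empty <- function(path) {
    if (file.exists(path)) utils::read.csv(path, stringsAsFactors = FALSE)
    else data.frame(powder = character())
  }
  dens <- read_or_empty(file.path(input_dir, "rheology", "densities.csv"))
  comp <- read_or_empty(file.path(input_dir, "rheology", "compression.csv"))
  shear <- read_or_empty(file.path(input_dir, "rheology", "shear.csv"))

  for (pw in powders) {
    dry <- read_psd_csv(file.path(psd_dir, paste0(pw, "_dry.csv")))
    size_summary[[pw]] <- psd_summary(dry, config$ssa_lower_cut_um,
                                      config$ssa_renormalize)

    trip_files <- file.path(psd_dir, paste0(pw, "_", c("ND", "LG", "EP"),
                                            ".csv"))
    if (all(file.exists(trip_files))) {
      trip <- deagglomeration_triplet(
        read_psd_csv(trip_files[1]), read_psd_csv(trip_files[2]),
        read_psd_csv(trip_files[3]),
        lower_cut_um = config$ssa_lower_cut_um,
        renormalize = config$ssa_renormalize)
      sh <- soft_hard(trip)
      agglo[[pw]] <- data.frame(powder = pw, soft = sh$soft, hard = sh$hard,
                                total = sh$total, ssa_nd = sh$ssa,
                                ssa_lg = sh$ssa_lg, ssa_ep = sh$ssa_ep)
      shifts[[pw]] <- cbind(powder = pw,
                            class_shift(trip, config$class_edges))
    } else {
      message("skipping agglomeration for '", pw,
              "': incomplete ND/LG/EP triplet")
      log_lines <- c(log_lines,
                     sprintf("WARNING: %s lacks a full wet triplet", pw))
    }

    shp_file <- file.path(input_dir, "shape", paste0(pw, ".csv"))
    if (file.exists(shp_file)) {
      recs <- read_shape_csv(shp_file)
      if (all(recs$magnification == "x5")) {
        recs <- apply_min_size_filter(recs, config$shape_min_size_um)
        merged <- volume_weights(recs)
      } else {
        merged <- merge_magnifications(
          recs[recs$magnification == "x20", , drop = FALSE],
          recs[recs$magnification == "x10", , drop = FALSE],
          config$merge_boundary_um)
      }
      shape_sum[[pw]] <- cbind(powder = pw, shape_medians(merged),
                               n_particles = nrow(merged))
    }

    d <- dens[dens$powder == pw, ]
    cp_tab <- comp[comp$powder == pw, ]
    sh_tab <- shear[shear$powder == pw, ]
    if (nrow(d) == 1L && nrow(cp_tab) > 1L && nrow(sh_tab) >= 3L) {
      fit <- cohesion_fit(sh_tab$sigma_kpa, sh_tab$tau_kpa)
      ci <- carr_index(d$rho_a, d$rho_p)
      rheo[[pw]] <- data.frame(
        powder = pw, carr_index_pct = ci,
        flowability = flowability_class(ci),
        compressibility_pct = compression_test_cp(cp_tab$stress_kpa,
                                                  cp_tab$volume_ml),
        cohesion_kpa = fit$cohesion_kpa, friction = fit$friction,
        r_squared = fit$r_squared)
    }
  }

  size_summary <- do.call(rbind, size_summary)
  agglo <- if (length(agglo)) do.call(rbind, agglo) else NULL
  shifts <- if (length(shifts)) do.call(rbind, shifts) else NULL
  shape_sum <- if (length(shape_sum)) do.call(rbind, shape_sum) else NULL
  rheo <- if (length(rheo)) do.call(rbind, rheo) else NULL

  profiles <- ranking <- NULL
  if (!is.null(agglo) && !is.null(shape_sum) && !is.null(rheo)) {
    common <- Reduce(intersect, list(size_summary$label, agglo$powder,
                                     shape_sum$powder, rheo$powder))
    if (length(common) >= 2L) {
      raw <- do.call(rbind, lapply(common, function(pw) {
        data.frame(
          powder = pw,
          indicator = c("span", "ssa", "elongation", "agglomeration",
                        "compressibility", "cohesion"),
          value = c(size_summary$span[size_summary$label == pw],
                    size_summary$ssa_um_inv[size_summary$label == pw],
                    shape_sum$median_elongation[shape_sum$powder == pw],
                    agglo$total[agglo$powder == pw],
                    rheo$compressibility_pct[rheo$powder == pw],
                    rheo$cohesion_kpa[rheo$powder == pw]))
      }))
      profiles <- normalize_indicators(raw)
      ranking <- rank_powders(profiles, config$indicator_order)
      log_lines <- c(log_lines,
                     sprintf("best powder: %s (100%%)", ranking$powder[1]))
    }
  }

  res <- list(size_summary = size_summary, agglomeration = agglo,
              class_shift = shifts, shape_summary = shape_sum,
              rheology = rheo, profiles = profiles, ranking = ranking,
              config_hash = hash)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("size_summary", "agglomeration", "class_shift",
                 "shape_summary", "rheology", "profiles")) {
      if (!is.null(res[[nm]]))
        write_output_csv(res[[nm]], file.path(output_dir,
                                              paste0(nm, ".csv")), hash)
    }
    if (!is.null(ranking))
      write_output_csv(as.data.frame(ranking),
                       file.path(output_dir, "ranking.csv"), hash)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  }
  res
}
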