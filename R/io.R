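#' @name io-formats
#' @title CSV dialects
#' @description
#' All files are plain CSV with a mandatory header. Sizes are um, densities
#' kg m-3, stresses kPa, volumes mL; SSA is written in both um^-1 and
#' m2.mm-3.
#'
#' * PSD: `size_um_lo, size_um_hi, volume_pct` (one file per powder and
#'   treatment, named `<powder>_<treatment>.csv`);
#' * shape records: `particle_id, magnification, esd_um, length_um,
#'   width_um, elongation, convexity`;
#' * densities: `powder, rho_a, rho_p`;
#' * compression: `powder, stress_kpa, volume_ml`;
#' * shear: `powder, sigma_kpa, tau_kpa`.
NULL

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

check_numeric_cols <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop(basename(path), ": non-numeric value in column '", cl,
           "' (data row ", if (length(bad)) bad[1] else "?", ")",
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a PSD CSV export
#'
#' @param path CSV file with columns `size_um_lo`, `size_um_hi`,
#'   `volume_pct`; rows must form a contiguous ascending bin grid.
#' @param label,treatment Metadata for the [psd] object; defaults are parsed
#'   from a `<powder>_<treatment>.csv` file name when possible.
#' @return A validated, normalized [psd].
#' @export
read_psd_csv <- function(path, label = NULL, treatment = NULL) {
  df <- read_csv_strict(path, c("size_um_lo", "size_um_hi", "volume_pct"))
  check_numeric_cols(df, c("size_um_lo", "size_um_hi", "volume_pct"), path)
  if (nrow(df) < 1L) stop(basename(path), ": no bins", call. = FALSE)
  neg <- which(df$volume_pct < 0)
  if (length(neg))
    stop(basename(path), ": negative volume in data row ", neg[1],
         call. = FALSE)
  if (any(diff(df$size_um_lo) <= 0))
    stop(basename(path), ": bins are not sorted ascending", call. = FALSE)
  if (any(abs(df$size_um_hi[-nrow(df)] - df$size_um_lo[-1]) >
          1e-9 * df$size_um_hi[-nrow(df)]))
    stop(basename(path), ": bins are not contiguous", call. = FALSE)
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  guess_tr <- parts[length(parts)]
  if (is.null(treatment))
    treatment <- if (guess_tr %in% c("ND", "LG", "EP", "dry")) guess_tr
      else "dry"
  if (is.null(label))
    label <- if (guess_tr %in% c("ND", "LG", "EP", "dry"))
      paste(parts[-length(parts)], collapse = "_") else base
  psd(c(df$size_um_lo, df$size_um_hi[nrow(df)]), df$volume_pct,
      label = label, treatment = treatment, normalize = TRUE)
}

#' Write a PSD to CSV
#'
#' @param x A [psd].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(x, path) {
  stopifnot_psd(x)
  n <- length(x$volume_pct)
  utils::write.csv(
    data.frame(size_um_lo = x$bin_edges[-(n + 1L)],
               size_um_hi = x$bin_edges[-1L],
               volume_pct = x$volume_pct),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write shape-record CSVs
#'
#' @param path CSV with columns `particle_id, magnification, esd_um,
#'   length_um, width_um, elongation, convexity`.
#' @return A `data.frame` of shape records.
#' @export
read_shape_csv <- function(path) {
  cols <- c("particle_id", "magnification", "esd_um", "length_um",
            "width_um", "elongation", "convexity")
  df <- read_csv_strict(path, cols)
  check_numeric_cols(df, setdiff(cols, c("particle_id", "magnification")),
                     path)
  if (any(df$esd_um <= 0) || any(df$width_um > df$length_um + 1e-9))
    stop(basename(path), ": invalid shape record (esd <= 0 or W > L)",
         call. = FALSE)
  df
}

#' @rdname read_shape_csv
#' @param records Shape records (e.g. from [shape_table()]).
#' @export
write_shape_csv <- function(records, path) {
  cols <- c("particle_id", "magnification", "esd_um", "length_um",
            "width_um", "elongation", "convexity")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study configuration
#'
#' Bundles every tunable of the pipeline. All sizes are um, stresses kPa.
#'
#' @param bin_grid PSD bin edges.
#' @param class_edges Grading-class edges for the shift analysis.
#' @param ssa_lower_cut_um Lower size cut for SSA.
#' @param ssa_renormalize Renormalize retained fractions after the cut.
#' @param shape_min_size_um Minimum particle size kept in low-magnification
#'   shape analysis.
#' @param merge_boundary_um Fine/coarse magnification merge boundary.
#' @param shear_stresses_kpa Shear-cell consolidation schedule.
#' @param compression_stresses_kpa Compression schedule.
#' @param indicator_order Radar axis order.
#' @param seed Base seed for synthetic generation.
#' @return A list of class `study_config`.
#' @export
study_config <- function(bin_grid = default_bin_grid(),
                         class_edges = c(2, 5, 20, 80, 200),
                         ssa_lower_cut_um = 2,
                         ssa_renormalize = TRUE,
                         shape_min_size_um = 4.5,
                         merge_boundary_um = 20,
                         shear_stresses_kpa = c(1, 1.3, 1.5, 1.7, 2),
                         compression_stresses_kpa = c(0.5, 1, 2, 4, 6, 8,
                                                      10, 12, 15),
                         indicator_order = default_axis_order(),
                         seed = 1L) {
  stopifnot(ssa_lower_cut_um > 0, shape_min_size_um > 0,
            merge_boundary_um > 0, !is.unsorted(class_edges, strictly = TRUE))
  structure(list(bin_grid = bin_grid, class_edges = class_edges,
                 ssa_lower_cut_um = ssa_lower_cut_um,
                 ssa_renormalize = ssa_renormalize,
                 shape_min_size_um = shape_min_size_um,
                 merge_boundary_um = merge_boundary_um,
                 shear_stresses_kpa = shear_stresses_kpa,
                 compression_stresses_kpa = compression_stresses_kpa,
                 indicator_order = indicator_order,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Write / read a study configuration as a flat key-value text file
#'
#' One `key: value(s)` line per field; numbers are written with 17
#' significant digits so the round trip reproduces every double bit-exactly
#' (and therefore leaves [config_hash()] unchanged).
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `read_config()` returns the [study_config()]; `write_config()`
#'   returns `path` invisibly. The round trip is lossless.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "study_config"))
    stop("expected a 'study_config'", call. = FALSE)
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = " ")
    else if (is.logical(v)) paste(tolower(as.character(v)), collapse = " ")
    else paste(v, collapse = " ")
  }
  writeLines(vapply(names(config),
                    function(k) paste0(k, ": ", fmt(config[[k]])),
                    character(1)),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  parse_num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  num_fields <- c("bin_grid", "class_edges", "ssa_lower_cut_um",
                  "shape_min_size_um", "merge_boundary_um",
                  "shear_stresses_kpa", "compression_stresses_kpa", "seed")
  out <- list()
  for (k in names(vals)) {
    out[[k]] <- if (k %in% num_fields) parse_num(vals[[k]])
      else if (k == "ssa_renormalize") trimws(vals[[k]]) == "true"
      else strsplit(trimws(vals[[k]]), "\\s+")[[1]]
  }
  do.call(study_config, out)
}

#' Hash of a study configuration
#'
#' MD5 digest of the canonical YAML serialization; stamped into every output
#' table so results can be traced to the exact configuration.
#'
#' @param config A [study_config()].
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
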