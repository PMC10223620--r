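# End-to-end pipeline: implant extraction -> texture partition -> BI,
# with artifact writing and a validated configuration record.

#' Build and validate a full pipeline configuration
#'
#' Combines [stage1_config()] and [stage2_config()] with I/O settings. Every
#' run records this configuration next to its outputs, which is sufficient to
#' reproduce the run bit-exactly.
#'
#' @param stage1,stage2 Stage parameter lists (see [stage1_config()],
#'   [stage2_config()]).
#' @param seed Seed recorded for any stochastic option (the default pipeline
#'   is fully deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stage1 = stage1_config(),
                            stage2 = stage2_config(), seed = 1L) {
  validate_keys(stage1, names(stage1_config()), "stage1")
  validate_keys(stage2, names(stage2_config()), "stage2")
  check_range <- function(v, nm, lo, hi) {
    if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi)) {
      stop("config key ", nm, " out of range [", lo, ", ", hi, "]")
    }
  }
  check_range(stage1$window, "stage1$window", 2, 4096)
  check_range(stage1$stride, "stage1$stride", 1, 4096)
  check_range(stage1$edge_frac, "stage1$edge_frac", 0, 1)
  check_range(stage1$min_edge_frac, "stage1$min_edge_frac", 0, 1)
  check_range(stage1$close_radius, "stage1$close_radius", 1, 1024)
  check_range(stage2$mu, "stage2$mu", 0, 100)
  check_range(stage2$tol, "stage2$tol", 0, 1)
  check_range(stage2$max_iter, "stage2$max_iter", 1, 1e6)
  check_range(stage2$hole_seed_max, "stage2$hole_seed_max", 0, 1)
  check_range(stage2$hole_mean_max, "stage2$hole_mean_max", 0, 1)
  check_range(stage2$neighborhood, "stage2$neighborhood", 1, 255)
  structure(list(stage1 = stage1, stage2 = stage2, seed = as.integer(seed)),
            class = "pipeline_config")
}

validate_keys <- function(x, allowed, label) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown ", label, " config keys: ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may override any subset of keys under `stage1:`, `stage2:` and
#' `seed:`; unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  raw <- yaml::read_yaml(path)
  validate_keys(raw, c("stage1", "stage2", "seed"), "top-level")
  s1 <- stage1_config(); s2 <- stage2_config()
  s1[names(raw$stage1)] <- raw$stage1
  s2[names(raw$stage2)] <- raw$stage2
  pipeline_config(stage1 = s1, stage2 = s2,
                  seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Run the full bone-ingrowth pipeline on one micrograph
#'
#' Segments the implant, partitions it into metal / bone / holes, and
#' computes the bone-ingrowth ratio. When `out_dir` is given, writes the
#' three masks plus the implant mask as PNG, the full parameter record as
#' JSON, and a one-row CSV report.
#'
#' @param image A micrograph (matrix/array in `[0, 1]`) or a path to a
#'   PNG/TIFF file.
#' @param config A [pipeline_config()].
#' @param image_id,lattice_type,timepoint Provenance labels for the report.
#' @param out_dir Optional output directory for artifacts.
#' @param verbose Log stage timings and mask areas to the console.
#' @return List with `bi` (a `bi_result`), `segmentation`
#'   (`segmentation_result`), `implant` (`implant_region`), and `artifacts`
#'   (paths written, or `NULL`).
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         image_id = NULL, lattice_type = "unknown",
                         timepoint = "n/a", out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) {
    if (is.null(image_id)) {
      image_id <- tools::file_path_sans_ext(basename(image))
    }
    image <- load_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  gray <- to_grayscale(image)

  say <- function(stage, t0, extra = "") {
    if (verbose) {
      message(sprintf("[%s] %s: %.2fs%s", image_id, stage,
                      as.numeric(Sys.time()) - t0, extra))
    }
  }
  t0 <- as.numeric(Sys.time())
  implant <- segment_implant(gray, config$stage1)
  say("segment_implant", t0, sprintf(" (area %d px)", implant$area_px))

  t0 <- as.numeric(Sys.time())
  seg <- segment_textures(gray, implant, config$stage2)
  say("segment_textures", t0,
      sprintf(" (metal %d, bone %d, holes %d px)",
              sum(seg$implant_metal), sum(seg$bone), sum(seg$holes)))

  bi <- compute_bi(seg, image_id = image_id, lattice_type = lattice_type,
                   timepoint = timepoint)

  artifacts <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(out_dir, image_id)
    artifacts <- c(
      implant = save_mask(implant$mask, paste0(pre, "_implant.png")),
      metal = save_mask(seg$implant_metal, paste0(pre, "_metal.png")),
      bone = save_mask(seg$bone, paste0(pre, "_bone.png")),
      holes = save_mask(seg$holes, paste0(pre, "_holes.png")),
      params = write_params_json(config, seg, paste0(pre, "_params.json")),
      report = write_report(list(bi), paste0(pre, "_bi.csv"))
    )
  }
  list(bi = bi, segmentation = seg, implant = implant, artifacts = artifacts)
}

write_params_json <- function(config, seg, path) {
  rec <- list(stage1 = config$stage1,
              stage2 = config$stage2,
              seed = config$seed,
              roughness_threshold_used =
                seg$params$roughness_threshold_used)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Run the pipeline over a directory of images
#'
#' Per-image failures are caught, logged and skipped; the summary names them.
#'
#' @param paths Character vector of image paths (e.g. from `Sys.glob`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @param verbose Log per-image progress.
#' @return List with `results` (successful `bi_result`s) and `failures`
#'   (named character vector of error messages).
#' @export
run_batch <- function(paths, config = pipeline_config(), out_dir = NULL,
                      verbose = FALSE) {
  results <- list()
  failures <- character()
  for (p in paths) {
    id <- tools::file_path_sans_ext(basename(p))
    r <- tryCatch(
      run_pipeline(p, config, image_id = id, out_dir = out_dir,
                   verbose = verbose),
      error = function(e) e
    )
    if (inherits(r, "error")) {
      failures[id] <- conditionMessage(r)
      if (verbose) message(sprintf("[%s] FAILED: %s", id, failures[id]))
    } else {
      results[[id]] <- r$bi
    }
  }
  list(results = results, failures = failures)
}
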