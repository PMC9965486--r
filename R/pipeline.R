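#' Pipeline run configuration
#'
#' Assembles every tunable of a full run — simulation, preprocessing,
#' binarization, tile order, risk cutoffs, statistical switchovers and the
#' seed — into one serializable object.  The config is echoed into every
#' output for provenance and round-trips losslessly through JSON.
#'
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @param images_dir,masks_dir,cohort_csv Input paths for file-based runs
#'   (`simulate = FALSE`).
#' @param simulate Generate a synthetic cohort instead of reading files.
#' @param cohort_params [cohort_gen_params()] for simulation.
#' @param image_params [image_gen_params()] template for simulation.
#' @param correct_magnification Apply axial-length magnification correction
#'   before cropping.
#' @param reference_axial_length Reference axial length (mm).
#' @param target_field_mm Analyzed field (mm).
#' @param phansalkar [phansalkar_params()].
#' @param tile_order Tile-grid order.
#' @param risk_cutoffs Named `c(ccfa = , cv = )`.
#' @param exact_threshold_mw,exact_threshold_wsr Exact-test switchovers.
#' @param seed Integer seed governing all randomness of the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = NULL, images_dir = NULL, masks_dir = NULL,
                       cohort_csv = NULL, simulate = TRUE,
                       cohort_params = cohort_gen_params(),
                       image_params = image_gen_params(),
                       correct_magnification = FALSE,
                       reference_axial_length = 24.46,
                       target_field_mm = 2.7,
                       phansalkar = phansalkar_params(),
                       tile_order = 18L,
                       risk_cutoffs = c(ccfa = 58.5, cv = 0.165),
                       exact_threshold_mw = 20L, exact_threshold_wsr = 15L,
                       seed = 1L) {
  for (p in c(images_dir, masks_dir, cohort_csv))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  structure(list(out_dir = out_dir, images_dir = images_dir,
                 masks_dir = masks_dir, cohort_csv = cohort_csv,
                 simulate = simulate, cohort_params = cohort_params,
                 image_params = image_params,
                 correct_magnification = correct_magnification,
                 reference_axial_length = reference_axial_length,
                 target_field_mm = target_field_mm,
                 phansalkar = phansalkar, tile_order = as.integer(tile_order),
                 risk_cutoffs = risk_cutoffs,
                 exact_threshold_mw = as.integer(exact_threshold_mw),
                 exact_threshold_wsr = as.integer(exact_threshold_wsr),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_to_list <- function(config, drop_paths = FALSE) {
  x <- unclass(config)
  # named vectors must become objects, not bare arrays, to survive JSON
  cp <- unclass(x$cohort_params)
  for (nm in names(cp))
    if (!is.null(names(cp[[nm]]))) cp[[nm]] <- as.list(cp[[nm]])
  x$cohort_params <- cp
  x$image_params <- unclass(x$image_params)
  x$phansalkar <- unclass(x$phansalkar)
  x$risk_cutoffs <- as.list(x$risk_cutoffs)
  if (drop_paths)
    x[c("out_dir", "images_dir", "masks_dir", "cohort_csv")] <- NULL
  x
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpl <- lapply(x$cohort_params, function(v)
    if (is.list(v)) unlist(v) else v)
  cp <- do.call(cohort_gen_params, cpl)
  ip <- do.call(image_gen_params, x$image_params)
  pp <- do.call(phansalkar_params, x$phansalkar)
  run_config(out_dir = x$out_dir, images_dir = x$images_dir,
             masks_dir = x$masks_dir, cohort_csv = x$cohort_csv,
             simulate = x$simulate, cohort_params = cp, image_params = ip,
             correct_magnification = x$correct_magnification,
             reference_axial_length = x$reference_axial_length,
             target_field_mm = x$target_field_mm, phansalkar = pp,
             tile_order = x$tile_order,
             risk_cutoffs = unlist(x$risk_cutoffs),
             exact_threshold_mw = x$exact_threshold_mw,
             exact_threshold_wsr = x$exact_threshold_wsr, seed = x$seed)
}

log_info <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

#' Read and write slab images with JSON sidecar metadata
#'
#' Rasters are 8-bit (or 16-bit) grayscale PNG (TIFF supported when the
#' tiff package is installed); intensities are normalized by the bit-depth
#' maximum on read.  Metadata (`pixel_scale` mm/px, `axial_length` mm,
#' optional mask filenames) travels in a JSON sidecar next to the image
#' (same basename, `.json` extension).
#'
#' @param image A [slab_image()].
#' @param path Image file path (`.png` or `.tif`/`.tiff`).
#' @param meta_path Sidecar path; defaults to the image path with a `.json`
#'   extension.
#' @return `read_slab_image` returns a `slab_image`.
#' @export
write_slab_image <- function(image, path, meta_path = sidecar_path(path)) {
  stopifnot(inherits(image, "slab_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF")
    tiff::writeTIFF(image$pixels, path)
  } else stop("unsupported image format: ", ext)
  meta <- list(pixel_scale = image$pixel_scale,
               axial_length = if (is.na(image$axial_length)) NULL
                              else image$axial_length,
               field_mm = image$field_mm)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_slab_image
#' @param require_axial_length Error when the sidecar lacks `axial_length`
#'   (needed for magnification correction).
#' @export
read_slab_image <- function(path, meta_path = sidecar_path(path),
                            require_axial_length = FALSE) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)  # already divided by the bit-depth maximum
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$pixel_scale))
    stop("metadata missing required key 'pixel_scale'")
  al <- meta$axial_length
  if (is.null(al)) {
    if (require_axial_length)
      stop("metadata missing required key 'axial_length'")
    al <- NA_real_
  }
  slab_image(px, pixel_scale = meta$pixel_scale, axial_length = al)
}

#' Write a binary flow map as a PNG
#'
#' @param flow A `flow_map`.
#' @param path PNG path.
#' @export
write_flow_map <- function(flow, path) {
  png::writePNG(as_flow_pixels(flow) * 1.0, path)
  invisible(path)
}

ccfa_result_to_list <- function(res) {
  list(ccfa_ratio = res$ccfa_ratio, cv = res$cv,
       tile_ratios = res$tile_grid$ratios,
       tile_order = res$tile_grid$order,
       region_ratios = res$region_ratios,
       sides = if (is.null(res$sides)) NULL else
         lapply(res$sides, as.list),
       high_risk = res$high_risk,
       provenance = res$provenance)
}

#' Write / read a per-image quantification result as JSON
#'
#' All floats are serialized at full precision; the parameter provenance
#' (Phansalkar parameters, tile order, cutoffs, geometry) is embedded.
#'
#' @param res A `ccfa_result`.
#' @param path JSON path.
#' @return `read_ccfa_result` returns the result as a list (matrices
#'   restored).
#' @export
write_ccfa_result <- function(res, path) {
  stopifnot(inherits(res, "ccfa_result"))
  jsonlite::write_json(ccfa_result_to_list(res), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ccfa_result
#' @export
read_ccfa_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tile_ratios <- matrix(x$tile_ratios, x$tile_order, x$tile_order)
  x
}

#' Read a cohort table from CSV
#'
#' Requires columns `id`, `group`, `age`, `sex`; unknown extra columns are
#' accepted and preserved.
#'
#' @param path CSV path.
#' @return Data.frame of subject records.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("id", "group", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort CSV missing required columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), c("amd_fellow", "control"))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  for (cl in c("faf_abnormal", "asymmetric_vasculature"))
    if (cl %in% names(df)) df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Write a cohort table to CSV
#'
#' @param records Data.frame of subject records.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

test_to_list <- function(t) {
  if (is.null(t)) return(NULL)
  list(statistic = t$statistic, p_value = t$p_value,
       n = unname(t$n_per_group), method = t$method, test = t$test)
}

fit_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  list(odds_ratio = f$odds_ratio, ci95 = f$ci95, p_value = f$p_value,
       exposure = f$exposure, n = f$n,
       coefficients = as.data.frame(f$coefficients))
}

cohort_result_to_list <- function(res) {
  list(n_per_group = as.list(res$n_per_group),
       cutoffs = as.list(res$cutoffs),
       tests = lapply(res$tests, test_to_list),
       paired = lapply(res$paired, test_to_list),
       roc = lapply(res$roc, function(r) if (is.null(r)) NULL else
         r[c("auc", "cutoff", "direction", "youden",
             "sensitivity", "specificity")]),
       logistic = lapply(res$logistic, fit_to_list),
       faf_table = as.data.frame(res$faf_table),
       risk_counts = as.data.frame.matrix(res$risk_counts),
       skipped = res$skipped)
}

#' Write the cohort analysis report as JSON
#'
#' The report embeds the exact configuration that produced it (and the
#' package version), so a report is reproducible from its own provenance
#' block.  Machine-specific paths and wall-clock timestamps are excluded:
#' reports from identical configs and seeds are byte-identical.
#'
#' @param result A `cohort_result`.
#' @param path JSON path.
#' @param config Optional [run_config()] echoed into the provenance block.
#' @export
write_report <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "cohort_result"))
  out <- cohort_result_to_list(result)
  out$provenance <- list(
    package = "choriomap",
    version = as.character(utils::packageVersion("choriomap")),
    config = if (is.null(config)) NULL else
      config_to_list(config, drop_paths = TRUE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and quantify one subject's image
#'
#' Realizes the synthetic slab for one subject of a generated cohort and
#' runs the quantification stack on it (optional magnification correction,
#' crop, Phansalkar binarization, CCFA/CV, regions, sides).
#'
#' @param cohort A [generate_cohort()] result.
#' @param i Subject index.
#' @param config A [run_config()].
#' @return A list: `slab`, `truth` (ground-truth flow map), `result`
#'   (`ccfa_result`).
#' @export
quantify_subject <- function(cohort, i, config = run_config()) {
  ip <- cohort$image_params[[i]]
  subj <- cohort$subjects[i, ]
  truth <- generate_flow_map(ip$params, base_fraction = ip$base_fraction)
  slab <- render_grayscale(truth, ip$params, axial_length = subj$axial_length)
  if (config$correct_magnification) {
    slab <- correct_magnification(slab, config$reference_axial_length)
    slab <- crop_to_field(slab, config$target_field_mm, config$tile_order)
  }
  masks <- list()
  if (!is.null(ip$faf_mask)) masks$faf_abnormal <- ip$faf_mask
  res <- quantify_slab(slab, phansalkar = config$phansalkar,
                       tile_order = config$tile_order, masks = masks,
                       thicker_side = if (subj$thicker_side %in%
                                          c("upper", "lower"))
                         subj$thicker_side else NULL,
                       cutoffs = config$risk_cutoffs)
  list(slab = slab, truth = truth, result = res)
}

#' Run the full pipeline
#'
#' Composes all stages into one reproducible run: simulate (or load) a
#' cohort, quantify every eye (preprocess, binarize, CCFA/CV, regions),
#' assemble the subject records with measured metrics, and run the
#' cohort-level inference.  Per-image failures are logged and skipped; the
#' run continues and errors only if no image processes successfully.
#' Deterministic under a fixed config seed (reports hash-equal across
#' runs).
#'
#' @param config A [run_config()].
#' @return An object of class `choriomap_run`: `records` (subject table
#'   with measured metrics), `per_image` (list of `ccfa_result`),
#'   `cohort_result`, `image_skips`, `config`.
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (isTRUE(config$simulate)) {
    cp <- config$cohort_params
    cp$seed <- config$seed
    cohort <- generate_cohort(cp, config$image_params)
    records <- cohort$subjects
    n <- nrow(records)
    log_info("simulated cohort of %d eyes", n)
    per_image <- vector("list", n)
    names(per_image) <- records$id
    skips <- list()
    for (i in seq_len(n)) {
      q <- tryCatch(quantify_subject(cohort, i, config),
                    error = function(e) e)
      if (inherits(q, "error")) {
        skips[[records$id[i]]] <- conditionMessage(q)
        log_info("skipping %s: %s", records$id[i], conditionMessage(q))
        next
      }
      per_image[[i]] <- q$result
    }
  } else {
    if (is.null(config$images_dir) || is.null(config$cohort_csv))
      stop("file-based runs need images_dir and cohort_csv")
    records <- read_cohort_csv(config$cohort_csv)
    n <- nrow(records)
    per_image <- vector("list", n)
    names(per_image) <- records$id
    skips <- list()
    for (i in seq_len(n)) {
      img_path <- file.path(config$images_dir, paste0(records$id[i], ".png"))
      q <- tryCatch({
        slab <- read_slab_image(img_path,
                                require_axial_length = config$correct_magnification)
        if (config$correct_magnification) {
          slab <- correct_magnification(slab, config$reference_axial_length)
          slab <- crop_to_field(slab, config$target_field_mm, config$tile_order)
        }
        masks <- list()
        if (!is.null(config$masks_dir)) {
          mp <- file.path(config$masks_dir, paste0(records$id[i], "_faf.png"))
          if (file.exists(mp))
            masks$faf_abnormal <- png::readPNG(mp) > 0.5
        }
        ts <- if ("thicker_side" %in% names(records) &&
                  records$thicker_side[i] %in% c("upper", "lower"))
          records$thicker_side[i] else NULL
        quantify_slab(slab, phansalkar = config$phansalkar,
                      tile_order = config$tile_order, masks = masks,
                      thicker_side = ts, cutoffs = config$risk_cutoffs)
      }, error = function(e) e)
      if (inherits(q, "error")) {
        skips[[records$id[i]]] <- conditionMessage(q)
        log_info("skipping %s: %s", records$id[i], conditionMessage(q))
        next
      }
      per_image[[i]] <- q
    }
  }

  ok <- !vapply(per_image, is.null, TRUE)
  if (!any(ok)) stop("no image processed successfully")
  records <- records[ok, , drop = FALSE]
  per_image <- per_image[ok]
  log_info("quantified %d of %d eyes", sum(ok), n)

  records$ccfa_ratio <- vapply(per_image, function(r) r$ccfa_ratio, 1)
  records$cv <- vapply(per_image, function(r) r$cv, 1)
  getr <- function(r, nm) r$region_ratios[[nm]] %||% NA_real_
  records$ccfa_faf_abnormal <- vapply(per_image, getr, 1, nm = "faf_abnormal")
  records$ccfa_faf_normal <- vapply(per_image, getr, 1, nm = "faf_normal")
  gets <- function(r, side, what)
    if (is.null(r$sides)) NA_real_ else r$sides[[side]][[what]]
  records$ccfa_thinner <- vapply(per_image, gets, 1, side = "thinner", what = "ccfa")
  records$ccfa_thicker <- vapply(per_image, gets, 1, side = "thicker", what = "ccfa")
  records$cv_thinner <- vapply(per_image, gets, 1, side = "thinner", what = "cv")
  records$cv_thicker <- vapply(per_image, gets, 1, side = "thicker", what = "cv")
  records$high_risk <- vapply(per_image, function(r) r$high_risk, TRUE)

  cohort_result <- run_cohort_analysis(
    records, cutoffs = config$risk_cutoffs,
    exact_threshold_mw = config$exact_threshold_mw,
    exact_threshold_wsr = config$exact_threshold_wsr)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(cohort_result, file.path(config$out_dir, "report.json"),
                 config)
    write_cohort_csv(records, file.path(config$out_dir, "records.csv"))
    for (i in seq_along(per_image))
      write_ccfa_result(per_image[[i]],
                        file.path(config$out_dir,
                                  paste0(records$id[i], "_result.json")))
  }
  log_info("pipeline finished in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(records = records, per_image = per_image,
                 cohort_result = cohort_result, image_skips = skips,
                 config = config),
            class = "choriomap_run")
}

#' @export
print.choriomap_run <- function(x, ...) {
  cat(sprintf("choriomap_run: %d eyes quantified (%d skipped)\n",
              nrow(x$records), length(x$image_skips)))
  print(x$cohort_result)
  invisible(x)
}

#' Simulate a cohort to disk
#'
#' Writes each subject's slab PNG + JSON sidecar, FAF mask PNGs where
#' present, and the cohort CSV, in the layout [run_full_pipeline()] reads
#' back for file-based runs.
#'
#' @param config A [run_config()] with `simulate = TRUE`.
#' @param dir Output directory.
#' @return Invisibly, the cohort table.
#' @export
simulate_to_dir <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  cp <- config$cohort_params
  cp$seed <- config$seed
  cohort <- generate_cohort(cp, config$image_params)
  for (i in seq_len(nrow(cohort$subjects))) {
    ip <- cohort$image_params[[i]]
    truth <- generate_flow_map(ip$params, base_fraction = ip$base_fraction)
    slab <- render_grayscale(truth, ip$params,
                             axial_length = cohort$subjects$axial_length[i])
    id <- cohort$subjects$id[i]
    write_slab_image(slab, file.path(dir, "images", paste0(id, ".png")))
    if (!is.null(ip$faf_mask))
      png::writePNG(ip$faf_mask * 1.0,
                    file.path(dir, "masks", paste0(id, "_faf.png")))
  }
  write_cohort_csv(cohort$subjects, file.path(dir, "cohort.csv"))
  invisible(cohort$subjects)
}
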