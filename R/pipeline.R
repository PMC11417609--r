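#' Read and write outcome tables
#'
#' Outcome tables are CSV files with the fixed header
#' `subject_id,parameter,scanner,method,value,units`. Unknown parameter
#' names are rejected (the allowed set is printed), malformed numeric values
#' are reported with their line number, and literal `NA` values are parsed
#' as missing.
#'
#' @param path CSV path.
#' @return `read_outcome_table` returns the validated data frame with an
#'   attribute `n_missing`; `write_outcome_table` returns `path` invisibly.
#' @export
read_outcome_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "parameter", "scanner", "method", "value", "units")
  if (!identical(names(tab), need))
    stop("outcome table must have header: ", paste(need, collapse = ","))
  bad <- setdiff(unique(tab$parameter), .param_levels)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.param_levels, collapse = ", "))
  raw <- tab$value
  val <- suppressWarnings(as.numeric(raw))
  malformed <- which(is.na(val) & !(raw %in% c("NA", "", NA)))
  if (length(malformed))
    stop("malformed value(s) at line(s): ",
         paste(malformed + 1L, collapse = ", "))
  tab$value <- val
  attr(tab, "n_missing") <- sum(is.na(val))
  tab
}

#' @param table Outcome table data frame.
#' @rdname read_outcome_table
#' @export
write_outcome_table <- function(table, path) {
  need <- c("subject_id", "parameter", "scanner", "method", "value", "units")
  if (!all(need %in% names(table)))
    stop("outcome table must have columns: ", paste(need, collapse = ","))
  bad <- setdiff(unique(table$parameter), .param_levels)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Run configurations are YAML files driving [run_pipeline()]; they
#' round-trip losslessly through serialization.
#'
#' @param path YAML path.
#' @return `read_run_config` returns the configuration list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @param config Configuration list.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Path to the shipped demonstration configuration
#' @return File path inside the installed package.
#' @export
demo_config_path <- function()
  system.file("extdata", "demo_config.yaml", package = "bonexcal",
              mustWork = TRUE)

phantom_from_config <- function(pc) {
  args <- pc[setdiff(names(pc), c("name", "raster_voxel_um"))]
  do.call(phantom_spec, args)
}

profile_from_config <- function(pc) do.call(scanner_profile, pc)

# Morphometry of one segmented arm; failures become warnings collected by the
# caller (not every metric exists for every phantom family).
phantom_outcome_rows <- function(subject, scanner, method, vol, bone_trab,
                                 bone_cort, masks, matrix_density,
                                 indirect = FALSE) {
  rows <- list(); warn <- character()
  add <- function(parameter, f) {
    v <- tryCatch(f(), error = function(e) {
      warn[[length(warn) + 1L]] <<- sprintf("%s %s/%s: %s", subject, scanner,
                                            parameter, conditionMessage(e))
      NA_real_
    })
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject, parameter = parameter, scanner = scanner,
      method = method, value = v, units = unname(.param_units[parameter]),
      stringsAsFactors = FALSE)
  }
  dg <- density_geometry(vol, masks)
  add("Tt.BMD", function() dg$tt_bmd)
  if (!is.null(masks$trabecular)) {
    tm <- masks$trabecular
    add("Tb.BMD", function() dg$tb_bmd)
    add("Tb.Ar", function() dg$tb_ar_mm2)
    add("Tb.N", function() direct_tb_n(bone_trab, tm))
    if (indirect) {
      # first-generation style: Tb.N measured directly, the rest derived
      # from density under the plate model
      tbn <- tryCatch(direct_tb_n(bone_trab, tm), error = function(e) NA_real_)
      ind <- if (is.na(tbn) || is.na(dg$tb_bmd)) NULL
             else indirect_morphometry(dg$tb_bmd, tbn, matrix_density)
      add("BV/TV", function() if (is.null(ind)) NA_real_ else ind$bvtv)
      add("Tb.Th", function() if (is.null(ind)) NA_real_ else ind$tb_th_mm)
      add("Tb.Sp", function() if (is.null(ind)) NA_real_ else ind$tb_sp_mm)
    } else {
      add("BV/TV", function() bvtv(bone_trab, tm))
      add("Tb.Th", function() direct_tb_th(bone_trab, tm))
      add("Tb.Sp", function() direct_tb_sp(bone_trab, tm))
    }
    add("Tb.1/N.SD", function() tb_1_n_sd(bone_trab, tm))
  }
  if (!is.null(masks$cortical)) {
    cm <- masks$cortical
    add("Ct.BMD", function() dg$ct_bmd)
    add("Ct.Ar", function() dg$ct_ar_mm2)
    add("Ct.Pm", function() dg$ct_pm_mm)
    cmx <- tryCatch(cortical_metrics(bone_cort, cm), error = function(e) {
      warn[[length(warn) + 1L]] <<- sprintf("%s %s cortical: %s", subject,
                                            scanner, conditionMessage(e))
      list(ct_th_mm = NA_real_, ct_po = NA_real_, ct_po_dm_mm = NA_real_)
    })
    add("Ct.Po", function() cmx$ct_po)
    add("Ct.Th", function() cmx$ct_th_mm)
    add("Ct.Po.Dm", function() cmx$ct_po_dm_mm)
  }
  list(rows = do.call(rbind, rows), warnings = warn)
}

#' Run the full cross-calibration pipeline
#'
#' Drives every stage from one configuration: phantom generation, paired
#' scan simulation at both scanner profiles, segmentation (Laplace-Hamming on
#' the XCTI-like arm; both Gaussian and Laplace-Hamming on the XCTII-like
#' arm), direct morphometry, measurement-level cohort simulation, cohort
#' split, bootstrap calibration, and validation (percent error, Bland-Altman,
#' correlation classification). All artifacts are CSV/JSON in `out_dir`; the
#' returned manifest lists every file with its checksum, per-stage timings
#' and all collected warnings. Identical configurations produce byte-identical
#' CSV and report outputs.
#'
#' @param config Configuration list (see the shipped demo config,
#'   [demo_config_path()]).
#' @param out_dir Output directory (created if missing).
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list(); warnings <- character(); files <- character()
  seed <- as.integer(config$seed %||% 1L)

  # fail fast on an invalid calibration layout, before any compute
  n_sub <- config$cohort$n_subjects
  n_test <- config$calibration$n_test %||% 12
  if (n_test >= n_sub)
    stop("invalid config [calibration]: n_test (", n_test,
         ") must be smaller than n_subjects (", n_sub, ")")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, f) {
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(f(), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - ts, 3)
    out
  }

  gp <- do.call(gaussian_seg_params, config$segmentation$gaussian %||% list())
  lp <- do.call(lh_seg_params, config$segmentation$lh %||% list())
  matrix_density <- config$morphometry$matrix_density_mgHA %||% 1200
  prof_x1 <- profile_from_config(config$profiles$xcti %||% list(name = "XCTI_like"))
  prof_x2 <- profile_from_config(config$profiles$xctii %||% list(name = "XCTII_like"))

  phantom_tab <- stage("imaging", function() {
    all_rows <- list()
    for (i in seq_along(config$phantoms)) {
      pc <- config$phantoms[[i]]
      nm <- pc$name %||% sprintf("phantom%02d", i)
      ph <- generate_phantom(phantom_from_config(pc),
                             voxel_um = pc$raster_voxel_um %||% 20)
      for (arm in list(list(prof = prof_x1, scanner = "XCTI", methods = "LH"),
                       list(prof = prof_x2, scanner = "XCTII",
                            methods = c("standard", "LH")))) {
        scan <- simulate_scan(ph$truth, ph$spec$tissue_density_mgHA, arm$prof,
                              seed = seed + 11L * i + (arm$prof$voxel_um == 61))
        masks <- lapply(ph$masks, function(m)
          binary_volume(resample_mask(m$voxels, m$voxel_um, arm$prof$voxel_um),
                        arm$prof$voxel_um))
        for (method in arm$methods) {
          seg <- function(mask, compartment) {
            if (method == "standard")
              gaussian_binarize(scan, mask, gp, compartment)
            else laplace_hamming_binarize(scan, mask, lp)
          }
          bt <- if (!is.null(masks$trabecular))
            seg(masks$trabecular, "trabecular") else NULL
          bc <- if (!is.null(masks$cortical))
            seg(masks$cortical, "cortical") else NULL
          res <- phantom_outcome_rows(nm, arm$scanner, method, scan, bt, bc,
                                      masks, matrix_density,
                                      indirect = arm$scanner == "XCTI" &&
                                        isTRUE(config$morphometry$xcti_indirect %||% TRUE))
          warnings <<- c(warnings, res$warnings)
          all_rows[[length(all_rows) + 1L]] <- res$rows
        }
      }
    }
    if (length(all_rows)) do.call(rbind, all_rows) else NULL
  })
  if (!is.null(phantom_tab)) {
    f <- file.path(out_dir, "phantom_outcomes.csv")
    write_outcome_table(phantom_tab, f); files <- c(files, f)
  }

  pair <- stage("cohort", function() {
    cp <- config$cohort
    spec <- cohort_sim_spec(cp$n_subjects,
                            do.call(rbind, lapply(cp$parameters, as.data.frame)),
                            seed = seed + 1000L)
    generate_paired_cohort(spec)
  })
  f1 <- file.path(out_dir, "cohort_xcti.csv")
  f2 <- file.path(out_dir, "cohort_xctii.csv")
  write_outcome_table(pair$xcti, f1); write_outcome_table(pair$xctii, f2)
  files <- c(files, f1, f2)

  cal <- stage("calibration", function() {
    plan <- split_cohort(pair$xcti, n_test = n_test, seed = seed + 2000L)
    eqs <- calibrate_all(pair,
                         n_boot = config$calibration$n_boot %||% 1000,
                         draw_size = config$calibration$draw_size %||% 12,
                         seed = seed + 3000L, training_ids = plan$training_ids)
    list(plan = plan, eqs = eqs)
  })
  f <- file.path(out_dir, "equations.csv")
  write.csv(equations_table(cal$eqs), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  warnings <- c(warnings, unlist(lapply(cal$eqs, function(e)
    if (e$n_redrawn > 0)
      sprintf("%s: %d degenerate bootstrap draw(s) redrawn", e$parameter,
              e$n_redrawn))))

  validation <- stage("validation", function() {
    rows <- lapply(names(cal$eqs), function(p) {
      pv <- paired_values(pair, p, cal$plan$test_ids)
      est <- apply_calibration(cal$eqs[[p]], pv$x)
      pe <- percent_error(est, pv$y)
      ba <- bland_altman(est$estimates, pv$y)
      data.frame(parameter = p, n_test = pe$n,
                 mean_pct_error = pe$mean, ci_low = pe$ci_low,
                 ci_high = pe$ci_high,
                 ba_mean_diff = ba$mean_difference, loa_low = ba$loa_low,
                 loa_high = ba$loa_high,
                 prop_bias_slope = ba$prop_bias_slope,
                 prop_bias_p = ba$prop_bias_p,
                 r_squared = cal$eqs[[p]]$r_squared,
                 correlation = classify_correlation(
                   min(1, max(0, cal$eqs[[p]]$r_squared))),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  f <- file.path(out_dir, "validation.csv")
  write.csv(validation, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  report <- list(split = list(training_ids = cal$plan$training_ids,
                              test_ids = cal$plan$test_ids),
                 equations = equations_table(cal$eqs),
                 validation = validation,
                 note = paste("percent-error intervals are t-based 95% CIs;",
                              "method comparisons use a paired two-sided t-test"))
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, f, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)

  manifest <- list(
    package_version = as.character(utils::packageVersion("bonexcal")),
    config_hash = config_hash(config),
    seed = seed,
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3),
    warnings = if (length(warnings)) warnings else character(0),
    files = lapply(stats::setNames(files, basename(files)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
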