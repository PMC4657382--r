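#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full simulate ->
#' standardize -> measure -> clearance -> summarize run. A seed is
#' mandatory whenever simulation is enabled so that every run is exactly
#' reproducible.
#'
#' @param n_femurs number of femurs to simulate (two per subject).
#' @param seed integer seed (required for simulation).
#' @param n_slices,trim_fraction centerline extraction controls.
#' @param clearance_samples torus-surface samples for the clearance check
#'   (0 disables the clearance stage).
#' @param measurement_noise standard deviations passed to
#'   [make_cohort_table()] (`noise_sd`); zero gives cohorts that follow the
#'   generating models exactly.
#' @param arc_span,apex_offset,mesh_resolution generator settings shared by
#'   all simulated femurs.
#' @param out_dir optional output directory: writes `cohort.csv`,
#'   `records.json` and per-femur STL meshes.
#' @return A validated `fem_run_config` list with a stable `hash`.
#' @export
run_config <- function(n_femurs = 6L, seed = NULL,
                       n_slices = 96L, trim_fraction = 0.10,
                       clearance_samples = 4000L,
                       measurement_noise = cohort_default_noise(),
                       arc_span = 16, apex_offset = 0,
                       mesh_resolution = c(circumferential = 37, axial = 110),
                       out_dir = NULL) {
  if (is.null(seed)) {
    fc_abort("a seed is required when simulation is enabled",
             "femcurve_config_error")
  }
  cfg <- list(n_femurs = as.integer(n_femurs), seed = as.integer(seed),
              n_slices = as.integer(n_slices), trim_fraction = trim_fraction,
              clearance_samples = as.integer(clearance_samples),
              measurement_noise = measurement_noise,
              arc_span = arc_span, apex_offset = apex_offset,
              mesh_resolution = mesh_resolution, out_dir = out_dir)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "fem_run_config")
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  cfg$hash <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full measurement pipeline on a simulated cohort
#'
#' Simulates a cohort table, builds a synthetic femur for each row (RFC,
#' banking angle, isthmus diameter and femoral length taken from the
#' table), measures every femur end to end ([measure_femur()]), optionally
#' checks nail-surrogate clearance, and summarizes the measured cohort the
#' way a morphometric study reports it: means and SDs by gender with
#' group tests, paired left/right differences, and the Pearson correlation
#' matrix. Per-femur failures are caught and reported without aborting the
#' cohort.
#'
#' @param config a [run_config()] object.
#' @param cohort optional pre-built cohort tibble (as from
#'   [make_cohort_table()]) to measure instead of simulating one; rows
#'   beyond `n_femurs` are ignored.
#' @return A `fem_pipeline` list: `cohort` (measured tibble), `records`,
#'   `clearances`, `failures`, `summary` (list of tibbles /
#'   `pearson_matrix`), `config`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "fem_run_config"))
  n <- config$n_femurs
  tab <- if (is.null(cohort)) {
    make_cohort_table(max(10L, ceiling(n / 2)),
                      noise_sd = config$measurement_noise,
                      seed = config$seed)
  } else cohort
  n <- min(n, nrow(tab))
  tab <- tab[seq_len(n), , drop = FALSE]

  records <- vector("list", n)
  clearances <- vector("list", n)
  failures <- list()
  measured <- vector("list", n)
  for (i in seq_len(n)) {
    row <- tab[i, ]
    res <- tryCatch({
      R <- max(300, row$rfc_mm)
      span <- config$arc_span
      chord <- 2 * R * sin(deg2rad(span) / 2)
      params <- femur_params(
        R_curvature = R,
        banking = min(175, max(5, row$banking_deg)),
        arc_span = span, apex_offset = config$apex_offset,
        canal_radius_min = row$isthmus_mm / 2,
        canal_radius_max = row$isthmus_mm / 2 * 1.4,
        length_total = max(row$length_mm, chord + 70),
        side = row$side, mesh_resolution = config$mesh_resolution,
        seed = config$seed + i
      )
      fem <- make_femur_meshes(params)
      rec <- measure_femur(fem$cortex, fem$canal, side = row$side,
                           subject_id = as.character(row$subject_id),
                           n_slices = config$n_slices,
                           trim_fraction = config$trim_fraction)
      cl_rep <- NULL
      if (config$clearance_samples > 0) {
        rng <- canal_arc_range(rec$circle, rec$canal_std)
        torus <- build_torus(rec$circle, rec$isthmus_diameter, rng)
        cl_rep <- check_clearance(torus, rec$canal_std,
                                  n_samples = config$clearance_samples)
      }
      list(rec = rec, clearance = cl_rep, fem = fem, params = params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(femur = i, message = conditionMessage(res))
      next
    }
    records[[i]] <- res$rec
    clearances[[i]] <- res$clearance
    m <- tidy(res$rec)
    m$subject_id <- row$subject_id
    m$age_y <- row$age_y; m$height_m <- row$height_m
    m$weight_kg <- row$weight_kg; m$gender <- row$gender
    m$laterality <- row$laterality
    m$min_clearance_mm <- if (is.null(res$clearance)) NA_real_ else
      res$clearance$min_clearance
    measured[[i]] <- m
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_stl(res$fem$cortex,
                file.path(config$out_dir, sprintf("femur_%03d_cortex.stl", i)))
      write_stl(res$fem$canal,
                file.path(config$out_dir, sprintf("femur_%03d_canal.stl", i)))
    }
  }
  if (length(failures) == n) {
    fc_abort("all femurs failed to process", "femcurve_pipeline_error")
  }
  cohort <- dplyr::bind_rows(measured)
  cohort$config_hash <- config$hash
  cohort$seed <- config$seed

  out <- structure(list(
    cohort = cohort,
    records = records,
    clearances = clearances,
    failures = if (length(failures)) dplyr::bind_rows(failures) else
      tibble::tibble(femur = integer(), message = character()),
    summary = summarize_cohort(cohort),
    config = config
  ), class = "fem_pipeline")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    rec_json <- lapply(records[!vapply(records, is.null, logical(1))],
                       record_as_list)
    writeLines(jsonlite::toJSON(list(config_hash = config$hash,
                                     seed = config$seed,
                                     records = rec_json),
                                auto_unbox = TRUE, digits = NA, pretty = TRUE),
               file.path(config$out_dir, "records.json"))
  }
  out
}

record_as_list <- function(rec) {
  list(subject_id = rec$subject_id, side = rec$side,
       femoral_length_mm = rec$femoral_length, rfc_mm = rec$rfc,
       banking_deg = rec$banking, isthmus_mm = rec$isthmus_diameter,
       fit_rmse_mm = rec$fit_rmse,
       circle = list(center = rec$circle$center, radius = rec$circle$radius,
                     normal = rec$circle$normal),
       transform = list(rotation = as.numeric(t(rec$transform$rotation)),
                        translation = rec$transform$translation))
}

#' Cohort summary tables
#'
#' Means and SDs of the measured morphometrics by gender with independent
#' t-tests, paired left/right differences, and the Pearson correlation
#' matrix. Tables are computed from whatever cohort is passed in; groups
#' too small for a test are reported without one.
#'
#' @param cohort measured cohort tibble (from [run_pipeline()] or
#'   [make_cohort_table()] with measurement columns).
#' @return List with `by_gender`, `laterality` and `correlations`.
#' @export
summarize_cohort <- function(cohort) {
  vars <- intersect(c("length_mm", "rfc_mm", "banking_deg", "isthmus_mm"),
                    names(cohort))
  by_gender <- NULL
  if ("gender" %in% names(cohort) && length(unique(cohort$gender)) == 2L) {
    by_gender <- dplyr::bind_rows(lapply(vars, function(v) {
      m <- cohort[[v]][cohort$gender == 0]
      f <- cohort[[v]][cohort$gender == 1]
      tst <- if (length(m) >= 2 && length(f) >= 2) {
        compare_groups(m, f, "independent_t")
      } else tibble::tibble(statistic = NA_real_, p_value = NA_real_)
      tibble::tibble(variable = v,
                     male_mean = mean(m), male_sd = sd(m),
                     female_mean = mean(f), female_sd = sd(f),
                     t = tst$statistic, p_value = tst$p_value)
    }))
  }
  laterality <- NULL
  if (all(c("subject_id", "laterality") %in% names(cohort))) {
    wide_ok <- names(which(table(cohort$subject_id) == 2L))
    sub <- cohort[cohort$subject_id %in% wide_ok, ]
    if (length(wide_ok) >= 2) {
      sub <- sub[order(sub$subject_id, -sub$laterality), ]
      left <- sub[sub$laterality == 1, ]
      right <- sub[sub$laterality == 0, ]
      laterality <- dplyr::bind_rows(lapply(vars, function(v) {
        tst <- compare_groups(left[[v]], right[[v]], "paired_t")
        tibble::tibble(variable = v,
                       left_mean = mean(left[[v]]), left_sd = sd(left[[v]]),
                       right_mean = mean(right[[v]]), right_sd = sd(right[[v]]),
                       difference = mean(left[[v]] - right[[v]]),
                       t = tst$statistic, p_value = tst$p_value)
      }))
    }
  }
  correlations <- tryCatch(
    pearson_matrix(cohort, intersect(
      c("age_y", "height_m", "weight_kg", "isthmus_mm", "rfc_mm",
        "banking_deg", "length_mm"), names(cohort))),
    error = function(e) NULL)
  list(by_gender = by_gender, laterality = laterality,
       correlations = correlations)
}

#' @export
print.fem_pipeline <- function(x, ...) {
  cat(sprintf("<fem_pipeline> %d femurs measured, %d failed (config %s)\n",
              nrow(x$cohort), nrow(x$failures), substr(x$config$hash, 1, 8)))
  if (!is.null(x$summary$by_gender)) print(x$summary$by_gender)
  invisible(x)
}
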