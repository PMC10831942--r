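#' Write an analysis table to delimited text
#'
#' Comma-separated with a header row; numeric columns round-trip at full
#' double precision (15 significant digits).
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read an analysis table, checking its schema
#'
#' @param path CSV path with header row.
#' @param required Character vector of required column names.
#' @return data.frame.
#' @export
read_table <- function(path, required = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(x))
    if (length(miss))
      stop("schema mismatch in ", basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read/write a 16-bit multi-page TIFF frame stack
#'
#' @param stack Integer array `[ny, nx, n_frames]` of counts (0..65535).
#' @param path TIFF path.
#' @return `path` invisibly (write) or the integer array (read).
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) stack[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  stack <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    stack[, , f] <- as.integer(round(pages[[f]] * 65535))
  stack
}

#' Pipeline configuration with the analysis defaults
#'
#' Stage parameters default to the settings the analysis is built around:
#' 30 ms dwell time, 500 nm linking radius, minimum trajectory length 5,
#' MSD eligibility at 9 frames, 0.2-decade histogram bins, and 2 um annuli
#' out to 10 um.
#'
#' @param sim A [sim_config()] for the simulate stage, or `NULL` to start
#'   from an existing localization table.
#' @param locs Localization data.frame (when `sim` is `NULL`).
#' @param dt Frame interval, s.
#' @param search_radius_nm Linking radius, nm.
#' @param min_len Minimum trajectory length, frames.
#' @param min_traj_len MSD-eligibility length, frames.
#' @param bin_width Histogram bin width, decades.
#' @param J Mixture components to fit (`NULL` skips the mixture stage).
#' @param lesion_center Optional lesion `c(x, y)`, um (enables the spatial
#'   stage).
#' @param outer_radii Annulus outer radii, um.
#' @param seed Master seed; per-stage streams are derived deterministically
#'   from it so toggling one stage does not perturb another.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, locs = NULL, dt = 0.03,
                            search_radius_nm = 500, min_len = 5,
                            min_traj_len = 9, bin_width = 0.2, J = NULL,
                            lesion_center = NULL,
                            outer_radii = c(2, 4, 6, 8, 10), seed = 1) {
  if (is.null(sim) && is.null(locs))
    stop("provide either a sim config or a localization table", call. = FALSE)
  structure(list(sim = sim, locs = locs, dt = dt,
                 search_radius_nm = search_radius_nm, min_len = min_len,
                 min_traj_len = min_traj_len, bin_width = bin_width, J = J,
                 lesion_center = lesion_center, outer_radii = outer_radii,
                 seed = seed),
            class = "pipeline_config")
}

.stage_seed <- function(master, k) (master * 7919L + k * 104729L) %% 2147483647L

#' Run the tracking-to-diffusivity pipeline
#'
#' Executes simulate (optional) -> filter -> link -> MSD/D estimation ->
#' mixture fit (optional) -> annulus profile (optional), writing every
#' intermediate table plus a key-value summary and a log of parameters and
#' rejection counts into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return List with elements locs, filtered, trajs, estimates, pdf, and
#'   (when configured) model, profile, exp_fit, plus `summary` (named list)
#'   and `log` (character).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- .stage_seed(config$seed, 1L)
    simr <- simulate_trajectories(sim)
    locs <- simr$localizations
    note("simulate: %d localizations from %d molecules", nrow(locs),
         sim$n_molecules)
  } else {
    locs <- config$locs
    note("input: %d localizations", nrow(locs))
  }

  filtered <- filter_localizations(locs)
  rej <- attr(filtered, "rejections")
  note("filter: kept %d, rejected %d (spot_sd) + %d (precision)",
       nrow(filtered), rej[["spot_sd"]], rej[["precision"]])

  trajs <- link_trajectories(filtered,
                             search_radius_nm = config$search_radius_nm,
                             min_len = config$min_len)
  note("link: %d trajectories (radius %g nm, min length %d)",
       length(unique(trajs$traj_id)), config$search_radius_nm,
       config$min_len)

  estimates <- estimate_diffusion(trajs, dt = config$dt,
                                  lesion_center = config$lesion_center,
                                  min_traj_len = config$min_traj_len)
  note("diffusion: %d eligible trajectories (>= %d frames)",
       nrow(estimates), config$min_traj_len)

  out <- list(locs = locs, filtered = filtered, trajs = trajs,
              estimates = estimates)
  summary <- list(n_localizations = nrow(locs), n_filtered = nrow(filtered),
                  n_trajectories = length(unique(trajs$traj_id)),
                  n_estimates = nrow(estimates))

  if (nrow(estimates) > 0) {
    out$pdf <- build_pdf(estimates$D_log, bin_width = config$bin_width)
    if (!is.null(config$J)) {
      out$model <- fit_mixture_global(out$pdf, J = config$J,
                                      seed = .stage_seed(config$seed, 2L))
      summary$centers <- out$model$centers
      summary$sigma <- out$model$sigmas[1]
      summary$fractions <- out$model$fractions[1, ]
      note("mixture: J = %d, centers %s", config$J,
           paste(signif(out$model$centers, 3), collapse = ", "))
      pk <- tryCatch(find_peak_D(out$pdf), error = function(e) NULL)
      if (!is.null(pk)) { out$peak <- pk; summary$D_pk <- pk$D_pk }
    }
    if (!is.null(config$lesion_center)) {
      assigned <- assign_annuli(estimates, config$lesion_center,
                                outer_radii = config$outer_radii)
      out$profile <- annulus_profile(assigned)
      if (nrow(out$profile) >= 3) {
        out$exp_fit <- tryCatch(
          fit_distance_profile(out$profile, "exponential"),
          error = function(e) NULL)
        if (!is.null(out$exp_fit)) {
          summary$gradient <- out$exp_fit$parameters
          summary$gradient_R2 <- out$exp_fit$R2
        }
      }
      note("spatial: %d annuli populated", nrow(out$profile))
    }
  }
  out$summary <- summary
  out$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(locs, file.path(out_dir, "localizations.csv"))
    write_table(filtered, file.path(out_dir, "localizations_filtered.csv"))
    write_table(trajs, file.path(out_dir, "trajectories.csv"))
    write_table(estimates, file.path(out_dir, "diffusion_estimates.csv"))
    if (!is.null(out$profile))
      write_table(out$profile, file.path(out_dir, "annulus_profile.csv"))
    if (!is.null(out$model))
      writeLines(.serialize_model(out$model), file.path(out_dir, "model.txt"))
    writeLines(c(sprintf("seed = %d", config$seed), log),
               file.path(out_dir, "run.log"))
    kv <- unlist(summary)
    writeLines(paste(names(kv), kv, sep = " = "),
               file.path(out_dir, "summary.txt"))
  }
  out
}

# flat key-value serialization of a fitted mixture
.serialize_model <- function(model) {
  lines <- c(sprintf("J = %d", length(model$centers)),
             sprintf("centers = %s",
                     paste(format(model$centers, digits = 15), collapse = ",")),
             sprintf("sigmas = %s",
                     paste(format(model$sigmas, digits = 15), collapse = ",")))
  for (d in seq_len(nrow(model$fractions)))
    lines <- c(lines, sprintf("fractions.%s = %s", model$datasets[d],
                              paste(format(model$fractions[d, ], digits = 15),
                                    collapse = ",")))
  if (!is.null(model$gof))
    lines <- c(lines, sprintf("R2 = %s",
                              paste(format(model$gof, digits = 6),
                                    collapse = ",")))
  lines
}
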