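# Experiment orchestration: manifests over (width, amplitude) grids,
# ensemble execution, aggregation into fits and trend tables.

#' Experiment manifest
#'
#' Fully determines an ensemble experiment: sequence, the (width, amplitude)
#' grid, ensemble size, durations, integrator settings and every
#' per-realisation seed (expanded from the master seed by a counter-based
#' scheme and stored, so re-running the manifest reproduces all results).
#'
#' @param sequence `"AT"` or `"GC"`.
#' @param widths bubble widths (bp, odd).
#' @param amplitudes bubble amplitudes (A).
#' @param n_runs realisations per grid cell.
#' @param thermalisation_ns thermalisation length (ns).
#' @param post_ns post-insertion recording length (ns); a scalar, or one
#'   value per grid cell (wider bubbles relax more slowly and need longer
#'   records).
#' @param seed master seed.
#' @param dt_fs integrator timestep (fs).
#' @param n_sites chain length (default 300).
#' @param share_thermalisation if `TRUE`, each seed's thermalised chain is
#'   reused across all grid cells (the bubble stage differs per cell). This
#'   cuts the thermalisation cost by the number of cells while leaving each
#'   cell's ensemble statistically valid; cells are then correlated with one
#'   another, which is immaterial for per-cell fits and trend comparisons.
#' @param n_boot bootstrap resamples per fit.
#' @param grid optionally, an explicit data frame of cells (columns `w`,
#'   `h`), overriding the `widths` x `amplitudes` cross product; lets an
#'   experiment cover a non-rectangular design.
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(sequence = "AT", widths = c(9, 11, 13, 15, 17, 19),
                                amplitudes = seq(2.5, 5.5, by = 0.5),
                                n_runs = 200, thermalisation_ns = 10,
                                post_ns = 20, seed = 1, dt_fs = 10,
                                n_sites = 300, share_thermalisation = FALSE,
                                n_boot = 200, grid = NULL) {
  grid <- if (is.null(grid)) {
    tidyr::expand_grid(w = as.integer(widths), h = amplitudes)
  } else {
    tibble::as_tibble(grid[, c("w", "h")])
  }
  stopifnot(length(post_ns) == 1 || length(post_ns) == nrow(grid))
  post_ns <- rep_len(post_ns, nrow(grid))
  seeds <- if (share_thermalisation) {
    matrix(derive_seeds(seed, n_runs), nrow = 1)
  } else {
    matrix(derive_seeds(seed, n_runs * nrow(grid)), nrow = nrow(grid),
           byrow = TRUE)
  }
  structure(list(sequence = sequence, grid = grid, n_runs = n_runs,
                 thermalisation_ns = thermalisation_ns, post_ns = post_ns,
                 seed = seed, dt_fs = dt_fs, n_sites = n_sites,
                 share_thermalisation = share_thermalisation,
                 n_boot = n_boot, seeds = seeds),
            class = "experiment_manifest")
}

#' Named experiment profiles
#'
#' `"AT_desk"` is the desk-scale default (200 runs, 20 ns post-insertion,
#' shared thermalisation). `"AT_full"` (2000 runs, 100 ns) and `"GC_full"`
#' (1000 runs, 5 microseconds) are the full production profiles; at roughly
#' one core-second per simulated nanosecond they are cluster-scale jobs
#' (GC_full integrates 5 ms of chain time in total), not desk runs.
#'
#' @param name profile name.
#' @param seed master seed.
#' @return An `experiment_manifest`.
#' @export
experiment_profile <- function(name = c("AT_desk", "AT_full", "GC_full"),
                               seed = 1) {
  name <- match.arg(name)
  switch(name,
    AT_desk = experiment_manifest("AT", widths = c(9, 13, 19),
                                  amplitudes = c(2.5, 3.5, 4.5, 5.5),
                                  n_runs = 200, thermalisation_ns = 10,
                                  post_ns = 20, seed = seed,
                                  share_thermalisation = TRUE),
    AT_full = experiment_manifest("AT", n_runs = 2000,
                                  thermalisation_ns = 10, post_ns = 100,
                                  seed = seed),
    GC_full = experiment_manifest("GC", n_runs = 1000,
                                  thermalisation_ns = 10, post_ns = 5000,
                                  seed = seed)
  )
}

#' @export
print.experiment_manifest <- function(x, ...) {
  cat(sprintf(
    "<experiment_manifest> %s, %d cells (w in %s; h in %s), %d runs/cell, %g + %s ns, seed %d%s\n",
    x$sequence, nrow(x$grid),
    paste(unique(x$grid$w), collapse = ","),
    paste(unique(x$grid$h), collapse = ","),
    x$n_runs, x$thermalisation_ns, paste(unique(x$post_ns), collapse = "/"),
    x$seed,
    if (x$share_thermalisation) " (shared thermalisation)" else ""))
  invisible(x)
}

#' Serialise a manifest to JSON
#'
#' @param manifest an [experiment_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  obj <- unclass(manifest)
  obj$grid <- as.data.frame(obj$grid)
  obj$seeds <- as.vector(obj$seeds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a full bubble-relaxation experiment
#'
#' Executes every realisation of the manifest (serially; realisations are
#' embarrassingly parallel and seed-determined, so scheduling cannot affect
#' results), builds the ensemble energy autocorrelation for each (w, h)
#' cell, fits the stretched exponential with bootstrap uncertainties, and
#' fits the per-width amplitude trends plus the width trend when the grid
#' is large enough. Individual realisation failures are recorded by seed;
#' aggregation proceeds if at least 90% of a cell's runs completed.
#'
#' @param manifest an [experiment_manifest()].
#' @param t_start_ns optional fixed fit-window start (ns); by default the
#'   later of [select_fit_start()] and `fit_min_start_ns` per cell.
#' @param fit_min_start_ns floor on the automatic fit-window start (ns).
#'   The first tens of ps of the energy autocorrelation are dominated by
#'   kinetic-energy decorrelation and bubble rearrangement rather than the
#'   rapid decay stage the stretched exponential describes; 0.04 ns sits
#'   just past the oscillatory window of both homopolymers.
#' @param truncate_tail truncate each cell's fit window via
#'   [select_fit_end()] once the mean curve has converged to its limiting
#'   value (default TRUE).
#' @param keep_series keep each cell's `correlation_series` in the result.
#' @param progress print per-cell progress lines.
#' @return An object of class `experiment_result`: `fits` tibble
#'   (w, h, A, tau_ns, beta, tau_av_ns and bootstrap sds), `trends`
#'   (per-width `trend_fit`s), `width_trend`, `series` (optional), `failed`
#'   (seeds), and the manifest.
#' @export
run_experiment <- function(manifest, t_start_ns = NULL,
                           fit_min_start_ns = 0.04, truncate_tail = TRUE,
                           keep_series = TRUE, progress = FALSE) {
  params <- pbd_params(manifest$sequence)
  cfg <- integrator_config(dt_fs = manifest$dt_fs)
  grid <- manifest$grid

  therm_bank <- NULL
  if (manifest$share_thermalisation) {
    therm_bank <- purrr::map(manifest$seeds[1, ], function(s) {
      st <- initial_state(manifest$n_sites, params$energy_per_site, s, params)
      thermalise(st, params, cfg, duration_ns = manifest$thermalisation_ns)
    })
  }

  failed <- integer(0)
  cells <- purrr::map(seq_len(nrow(grid)), function(ci) {
    spec <- bubble_spec(grid$h[ci], grid$w[ci], n_sites = manifest$n_sites)
    post_ci <- manifest$post_ns[ci]
    record_times <- log_time_grid(post_ci * 1e3)
    seeds <- if (manifest$share_thermalisation) {
      manifest$seeds[1, ]
    } else {
      manifest$seeds[ci, ]
    }
    results <- purrr::imap(seeds, function(s, k) {
      tryCatch(
        run_realisation(params, cfg, spec, seed = s,
                        post_ns = post_ci,
                        thermalisation_ns = manifest$thermalisation_ns,
                        record_times_ps = record_times,
                        thermalised_state = if (is.null(therm_bank)) NULL
                                            else therm_bank[[k]]),
        error = function(e) {
          warning(sprintf("realisation seed %d failed: %s", s,
                          conditionMessage(e)))
          NULL
        })
    })
    ok <- !vapply(results, is.null, logical(1))
    failed <<- c(failed, seeds[!ok])
    if (mean(ok) < 0.9) {
      rlang::abort(sprintf("cell (w=%d, h=%g): only %.0f%% of runs completed",
                           spec$w, spec$h, 100 * mean(ok)))
    }
    results <- results[ok]
    ce <- energy_autocorrelation(results)
    ts <- t_start_ns %||% max(select_fit_start(ce), fit_min_start_ns)
    te <- if (truncate_tail) select_fit_end(ce, t_start_ns = ts) else NULL
    fit <- fit_stretched_exponential(ce, t_start_ns = ts, t_end_ns = te)
    fit <- bootstrap_uncertainty(ce, fit, n_boot = manifest$n_boot,
                                 seed = manifest$seed + ci)
    if (progress) {
      message(sprintf("cell w=%d h=%g: tau_av = %s ns", spec$w, spec$h,
                      format_uncertainty(fit$tau_av_ns, fit$se$tau_av_ns)))
    }
    list(w = spec$w, h = spec$h, series = if (keep_series) ce else NULL,
         fit = fit, n_ok = sum(ok))
  })

  fits <- dplyr::bind_rows(purrr::map(cells, function(cc) {
    tibble::tibble(w = cc$w, h = cc$h, A = cc$fit$A, tau_ns = cc$fit$tau_ns,
                   beta = cc$fit$beta, chi = cc$fit$chi,
                   tau_av_ns = cc$fit$tau_av_ns,
                   A_sd = cc$fit$se$A %||% NA_real_,
                   tau_sd = cc$fit$se$tau_ns %||% NA_real_,
                   beta_sd = cc$fit$se$beta %||% NA_real_,
                   tau_av_sd = cc$fit$se$tau_av_ns %||% NA_real_,
                   t_start_ns = cc$fit$t_start_ns, n_runs = cc$n_ok)
  }))

  trends <- NULL
  wtrend <- NULL
  widths_with_enough <- fits |>
    dplyr::count(.data$w) |>
    dplyr::filter(.data$n >= 3) |>
    dplyr::pull(.data$w)
  if (length(widths_with_enough) > 0) {
    trends <- purrr::map(widths_with_enough, function(wv) {
      amplitude_linear_fit(
        dplyr::rename(dplyr::filter(fits, .data$w == wv),
                      tau_av = "tau_av_ns", tau_av_sd = "tau_av_sd"),
        width = wv)
    })
    if (length(trends) >= 3) wtrend <- width_trend_fit(trends)
  }

  structure(list(fits = fits, trends = trends, width_trend = wtrend,
                 series = if (keep_series) purrr::map(cells, "series") else NULL,
                 failed = failed, manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, %d cells, %d failed runs\n",
              x$manifest$sequence, nrow(x$fits), length(x$failed)))
  print(x$fits)
  invisible(x)
}

#' Summary tables of an experiment
#'
#' Produces the per-cell parameter table (with compact parenthesis
#' uncertainties), the per-width amplitude-trend table, and, when available,
#' the composed width-trend relations as human-readable strings.
#'
#' @param x an `experiment_result`.
#' @return A list of tibbles `cells`, `trends`, and `relations` (character).
#' @export
summarise_experiment <- function(x) {
  cells <- x$fits |>
    dplyr::mutate(
      A_fmt = purrr::map2_chr(.data$A, .data$A_sd, format_uncertainty),
      tau_fmt = purrr::map2_chr(.data$tau_ns, .data$tau_sd, format_uncertainty),
      beta_fmt = purrr::map2_chr(.data$beta, .data$beta_sd, format_uncertainty),
      tau_av_fmt = purrr::map2_chr(.data$tau_av_ns, .data$tau_av_sd,
                                   format_uncertainty)
    ) |>
    dplyr::select("w", "h", "A_fmt", "tau_fmt", "beta_fmt", "tau_av_fmt",
                  "n_runs")
  trends <- if (!is.null(x$trends)) {
    dplyr::bind_rows(purrr::map(x$trends, function(t) {
      tibble::tibble(w = t$width,
                     tau0 = format_uncertainty(t$tau0, t$tau0_sd),
                     alpha = format_uncertainty(t$alpha, t$alpha_sd))
    }))
  } else {
    NULL
  }
  relations <- if (!is.null(x$width_trend)) {
    wt <- x$width_trend
    c(tau0 = sprintf("tau0(w) = %s w + %s ns",
                     format_uncertainty(wt$tau0_line$slope,
                                        wt$tau0_line$slope_sd),
                     format_uncertainty(wt$tau0_line$intercept,
                                        wt$tau0_line$intercept_sd)),
      alpha = sprintf("alpha(w) = %s w + %s ns/A",
                      format_uncertainty(wt$alpha_line$slope,
                                         wt$alpha_line$slope_sd),
                      format_uncertainty(wt$alpha_line$intercept,
                                         wt$alpha_line$intercept_sd)))
  } else {
    NULL
  }
  list(cells = cells, trends = trends, relations = relations)
}

#' Write experiment outputs to disk
#'
#' Per-cell correlation series as CSV (`time_ps`, `mean`, `sem`) with a JSON
#' sidecar (kind, chi, n_runs), the fits table as CSV, and the manifest as
#' JSON.
#'
#' @param x an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$fits, file.path(dir, "fits.csv"), row.names = FALSE)
  write_manifest(x$manifest, file.path(dir, "manifest.json"))
  if (!is.null(x$series)) {
    for (i in seq_along(x$series)) {
      s <- x$series[[i]]
      if (is.null(s)) next
      base <- sprintf("cell_w%d_h%g", x$fits$w[i], x$fits$h[i])
      utils::write.csv(as.data.frame(s), file.path(dir, paste0(base, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(kind = attr(s, "kind"), chi = attr(s, "chi"),
             n_runs = attr(s, "n_runs")),
        file.path(dir, paste0(base, ".json")), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}
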