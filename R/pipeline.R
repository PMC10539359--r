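#' Structure-level comparison report
#'
#' Runs the single-structure analyses (elbow angle with dyad diagnostics, gap
#' records, formal charge over a pH grid) for every configured structure and,
#' for every pair, the matched-Calpha RMSD for the all/variable/constant
#' selections. Results are returned as tibbles and optionally written as
#' JSON + TSV under `out_dir`.
#'
#' @param structures Named list of `fab_structure` objects.
#' @param pH_grid Numeric vector of pH values for the charge table.
#' @param out_dir Optional output directory (created if needed).
#' @return A `fab_structure_report`: list with `structures`, `gaps`,
#'   `charge`, `pairwise` tibbles and the resolved `config`.
#' @export
run_structure_report <- function(structures, pH_grid = c(4, 7, 9),
                                 out_dir = NULL) {
  if (length(structures) == 0) abort("configure at least one structure")
  if (is.null(names(structures)) || any(names(structures) == "")) {
    names(structures) <- paste0("structure_", seq_along(structures))
  }
  errors <- character()
  struct_tab <- purrr::map_dfr(names(structures), function(nm) {
    res <- tryCatch(elbow_angle(structures[[nm]]), error = function(e) e)
    if (inherits(res, "error")) {
      errors <<- c(errors, paste0(nm, ": ", conditionMessage(res)))
      return(tibble::tibble(name = nm, elbow_angle = NA_real_))
    }
    dplyr::mutate(glance(res), name = nm, .before = 1)
  })
  gaps <- purrr::map_dfr(names(structures), function(nm) {
    g <- detect_gaps(structures[[nm]])
    if (nrow(g) > 0) dplyr::mutate(g, name = nm, .before = 1) else g
  })
  charge <- purrr::map_dfr(names(structures), function(nm) {
    purrr::map_dfr(pH_grid, function(p) {
      dplyr::mutate(total_formal_charge(structures[[nm]], pH = p)[, c("pH", "charge")],
                    name = nm, .before = 1)
    })
  })
  pairwise <- NULL
  if (length(structures) >= 2) {
    combos <- utils::combn(names(structures), 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(combos, function(pr) {
      purrr::map_dfr(c("all", "variable", "constant"), function(sel) {
        r <- tryCatch(rmsd_matched_ca(structures[[pr[1]]], structures[[pr[2]]], sel),
                      error = function(e) {
                        errors <<- c(errors, paste0(pr[1], " vs ", pr[2], ": ",
                                                    conditionMessage(e)))
                        tibble::tibble(selection = sel, rmsd = NA_real_,
                                       n_matched = NA_integer_)
                      })
        dplyr::mutate(r, a = pr[1], b = pr[2], .before = 1)
      })
    })
  }
  report <- structure(
    list(structures = struct_tab, gaps = gaps, charge = charge,
         pairwise = pairwise, errors = errors,
         config = list(names = names(structures), pH_grid = pH_grid)),
    class = "fab_structure_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir, "structure_report")
  report
}

#' Ensemble (trajectory) report with repeat statistics and SAXS fitting
#'
#' Computes per-repeat time series of radius of gyration, Calpha RMSD to the
#' starting frame, elbow angle and APR SASA; aggregates them to mean +/- SEM
#' over repeats; averages each metric over a final time window; and, when an
#' experimental SAXS curve is supplied, fits every frame by reduced
#' chi-square and extracts the top-N best-fitting frames with their pairwise
#' Calpha RMSD matrix.
#'
#' @param trajectories List of `fab_trajectory` repeats on a common grid.
#' @param fab The annotated topology.
#' @param exp_curve Optional `fab_exp_curve`; when `NULL` the chi-square
#'   sections are omitted.
#' @param windows APR window table (default [default_apr_windows()]); `NULL`
#'   skips SASA.
#' @param final_window `c(start, end)` ns for end-point averages (default:
#'   final 20% of the trajectory).
#' @param discard_ns Initial equilibration time to drop from aggregated
#'   statistics (default 0).
#' @param top_n Number of best-fit frames to extract (default 10).
#' @param radii A [radii_set()] for the SASA stage.
#' @param out_dir Optional output directory.
#' @return A `fab_ensemble_report` list: `series` (per-repeat tibbles),
#'   `stats` (per-metric `fab_timeseries_stat`), `final_averages`, `fits`,
#'   `chi_rg`, `top_frames`, `config`.
#' @export
run_ensemble_report <- function(trajectories, fab, exp_curve = NULL,
                                windows = default_apr_windows(),
                                final_window = NULL, discard_ns = 0,
                                top_n = 10, radii = radii_set(),
                                out_dir = NULL) {
  if (inherits(trajectories, "fab_trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < 2) abort("need >= 2 repeat trajectories")
  times <- frame_times(trajectories[[1]])
  if (is.null(final_window)) {
    final_window <- c(stats::quantile(times, 0.8), max(times))
  }
  keep_t <- function(s) dplyr::filter(s, .data$time_ns >= discard_ns)
  rg_series <- lapply(trajectories, rg_timeseries)
  rmsd_series <- lapply(trajectories, rmsd_to_start)
  elbow_series <- lapply(trajectories, elbow_trajectory, fab = fab)
  series <- list(rg = rg_series, rmsd = rmsd_series, elbow = elbow_series)
  stats_list <- list(
    rg = aggregate_repeats(lapply(rg_series, keep_t), value = "rg"),
    rmsd = aggregate_repeats(lapply(rmsd_series, keep_t), value = "rmsd"),
    elbow = aggregate_repeats(lapply(elbow_series, keep_t), value = "elbow")
  )
  finals <- purrr::map_dfr(names(stats_list), function(metric) {
    dplyr::mutate(window_average(series[[metric]], final_window), metric = metric)
  })
  sasa_series <- NULL
  if (!is.null(windows)) {
    sasa_series <- lapply(trajectories, apr_sasa_timeseries, fab = fab,
                          windows = windows, radii = radii)
    series$apr_sasa <- sasa_series
    for (lab in unique(sasa_series[[1]]$label)) {
      per_rep <- lapply(sasa_series, function(s) dplyr::filter(s, .data$label == lab))
      stats_list[[paste0("sasa:", lab)]] <-
        aggregate_repeats(lapply(per_rep, keep_t), value = "sasa")
      finals <- dplyr::bind_rows(
        finals,
        dplyr::mutate(window_average(per_rep, final_window),
                      metric = paste0("sasa:", lab))
      )
    }
  }
  fits <- chi_rg <- top_frames <- NULL
  if (!is.null(exp_curve)) {
    fits <- fit_trajectory(trajectories, exp_curve)
    chi_rg <- fits[, c("repeat_id", "frame", "time_ns", "rg", "chi_square")]
    top_frames <- top_n_frames(fits, trajectories, n = top_n)
  }
  report <- structure(
    list(series = series, stats = stats_list, final_averages = finals,
         fits = fits, chi_rg = chi_rg, top_frames = top_frames,
         config = list(n_repeats = length(trajectories),
                       dt_ns = trajectories[[1]]$dt_ns,
                       final_window = final_window, discard_ns = discard_ns,
                       top_n = top_n, has_exp_curve = !is.null(exp_curve))),
    class = "fab_ensemble_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir, "ensemble_report")
  report
}

write_report <- function(report, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drop_series <- report[setdiff(names(report), c("series", "top_frames"))]
  jsonlite::write_json(drop_series, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  tabs <- purrr::keep(report, is.data.frame)
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]][, !vapply(tabs[[nm]], is.list, logical(1)), drop = FALSE],
                       file.path(out_dir, paste0(stem, "_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
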