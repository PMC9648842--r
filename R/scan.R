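#' Coexistence summary of one pulsed run
#'
#' Averages the species biomass fractions over the last `window` share of the
#' simulated time and flags each species as persistent when its averaged
#' fraction exceeds `threshold` (and total biomass has not washed out).
#'
#' @param traj A multi-species `reactor_trajectory`.
#' @param threshold Persistence threshold on the averaged fraction.
#' @param window Final share of the run used for averaging (default 0.2).
#' @return A one-row tibble with `frac_*`, `min_frac_*` and `persistent_*`
#'   per species and a `coexistence` flag.
#' @export
coexistence_metrics <- function(traj, threshold = 0.01, window = 0.2) {
  sp <- traj_attr(traj, "species")
  t_end <- max(traj$t)
  fr <- biomass_fractions(traj) |>
    dplyr::filter(.data$t >= (1 - window) * t_end)
  out <- tibble::tibble(.rows = 1)
  persistent <- logical(length(sp))
  for (i in seq_along(sp)) {
    fi <- fr$fraction[fr$species == sp[i]]
    def <- fr$defined[fr$species == sp[i]]
    mean_f <- if (any(def)) mean(fi[def]) else NA_real_
    min_f <- if (any(def)) min(fi[def]) else NA_real_
    washed <- mean(def) < 1 # total biomass vanished somewhere in the window
    persistent[i] <- !washed && isTRUE(mean_f > threshold)
    out[[paste0("frac_", sp[i])]] <- mean_f
    out[[paste0("min_frac_", sp[i])]] <- min_f
    out[[paste0("persistent_", sp[i])]] <- persistent[i]
  }
  out$coexistence <- all(persistent)
  out
}

#' Scan pulsed-feeding space for coexistence
#'
#' Simulates a pulsed continuous co-culture over a grid of dilution rates
#' `D`, pulse frequencies `w` and duty cycles `s`, and summarises each grid
#' point by the averaged final biomass fractions and a persistence flag per
#' species (fraction above `threshold` averaged over the last 20% of the
#' run). The derived summary reports the largest `D` for which at least one
#' `(w, s)` profile keeps every species persistent. Integrator failures are
#' recorded in the `status` column for the affected point rather than
#' aborting the scan. The scan is deterministic.
#'
#' @param species List of [species_model()]s (two or more).
#' @param D_grid,w_grid,s_grid Grid axes: dilution rate (h^-1), pulse
#'   frequency (h^-1), duty-cycle fraction. Defaults: the study range
#'   `D` in 0.025..0.3 with `w`, `s` in 0.1..0.5.
#' @param t_end Simulated time per point, h (default 200, at least 20 pulse
#'   periods for every default grid frequency).
#' @param threshold Persistence threshold (fraction), in (0, 0.5).
#' @param dt Reporting step used for the scan runs, h.
#' @param checkpoint Optional CSV path: completed grid points are appended as
#'   they finish, and on re-run any `(D, w, s)` already present is skipped, so
#'   an interrupted scan resumes where it stopped.
#' @param ... Passed to [run_pulsed()].
#' @return A `coexistence_scan` tibble (one row per grid point with columns
#'   `D, w, s, frac_*, min_frac_*, persistent_*, coexistence, status`);
#'   [glance()] returns the grid dimensions and the largest
#'   coexistence-supporting `D`.
#' @export
coexistence_scan <- function(species,
                             D_grid = c(0.025, 0.05, 0.075, 0.1, 0.15, 0.2, 0.3),
                             w_grid = seq(0.1, 0.5, by = 0.1),
                             s_grid = seq(0.1, 0.5, by = 0.1),
                             t_end = 200, threshold = 0.01, dt = 0.25,
                             checkpoint = NULL, ...) {
  if (!length(D_grid) || !length(w_grid) || !length(s_grid)) {
    abort("Grids must be non-empty.", class = "comonod_config_error")
  }
  if (threshold <= 0 || threshold >= 0.5) {
    abort("`threshold` must lie in (0, 0.5).", class = "comonod_config_error")
  }
  species <- as_species_list(species)
  if (length(species) < 2) {
    abort("The scan needs at least two species.", class = "comonod_config_error")
  }
  grid <- tidyr::expand_grid(D = D_grid, w = w_grid, s = s_grid)

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tibble::as_tibble(utils::read.csv(checkpoint))
  }
  key <- function(d) sprintf("%.10g|%.10g|%.10g", d$D, d$w, d$s)

  rows <- purrr::pmap(grid, function(D, w, s) {
    point <- tibble::tibble(D = D, w = w, s = s)
    if (!is.null(done) && key(point) %in% key(done)) {
      return(done[key(done) == key(point), , drop = FALSE][1, ])
    }
    res <- tryCatch({
      fp <- feed_program("pulsed", D = D, w = w, s = s)
      traj <- run_pulsed(species, fp, t_end = t_end, dt = dt, ...)
      dplyr::bind_cols(point,
                       coexistence_metrics(traj, threshold = threshold),
                       tibble::tibble(status = "ok"))
    }, error = function(e) {
      empty <- point
      for (spn in names(species)) {
        empty[[paste0("frac_", spn)]] <- NA_real_
        empty[[paste0("min_frac_", spn)]] <- NA_real_
        empty[[paste0("persistent_", spn)]] <- FALSE
      }
      empty$coexistence <- FALSE
      empty$status <- paste0("error: ", conditionMessage(e))
      empty
    })
    if (!is.null(checkpoint)) {
      if (file.exists(checkpoint)) {
        utils::write.table(res, checkpoint, sep = ",", row.names = FALSE,
                           col.names = FALSE, append = TRUE)
      } else {
        utils::write.table(res, checkpoint, sep = ",", row.names = FALSE)
      }
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("coexistence_scan", class(tibble::tibble())),
            comonod_species = names(species), comonod_threshold = threshold)
}

#' Largest dilution rate supporting coexistence
#'
#' @param x A `coexistence_scan`.
#' @return The largest `D` in the scanned grid with at least one `(w, s)`
#'   profile where all species persist, or `NA` if none.
#' @export
max_coexistence_D <- function(x) {
  stopifnot(inherits(x, "coexistence_scan"))
  ok <- x$D[x$coexistence %in% TRUE]
  if (length(ok)) max(ok) else NA_real_
}

#' @export
glance.coexistence_scan <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    n_D = dplyr::n_distinct(x$D),
    n_w = dplyr::n_distinct(x$w),
    n_s = dplyr::n_distinct(x$s),
    n_coexistence = sum(x$coexistence %in% TRUE),
    n_failed = sum(x$status != "ok"),
    max_coexistence_D = max_coexistence_D(x)
  )
}

#' @export
print.coexistence_scan <- function(x, ...) {
  cat(sprintf(
    "<coexistence_scan> %d grid points; coexistence at %d; largest D = %s 1/h\n",
    nrow(x), sum(x$coexistence %in% TRUE), format(max_coexistence_D(x))))
  NextMethod()
}
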