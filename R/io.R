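#' Write and read reactor trajectories
#'
#' Trajectories are exchanged as plain CSV (comma separator, `.` decimal,
#' UTF-8, mandatory header) with one row per reporting time and the column
#' layout `t, D, X_<species>..., GLU, ACE, ETH, psi_rel_*, u_*, v_*, mu_*`.
#' Units and run metadata live in a YAML sidecar (`<path>.meta.yml`), never
#' in the header. Numbers are written with 17 significant digits, so a
#' write/read round trip reproduces the in-memory object exactly.
#'
#' @param traj A `reactor_trajectory`.
#' @param path Output CSV path.
#' @return `path` (write) or the reconstructed `reactor_trajectory` (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "reactor_trajectory"))
  write_numeric_csv(as.data.frame(traj), path)
  fp <- traj_attr(traj, "fp")
  meta <- list(
    units = list(t = "h", D = "1/h", X = "g/L", metabolites = "g/L",
                 psi_rel = "dimensionless", u = "dimensionless",
                 v = "dimensionless", mu = "1/h"),
    species = as.list(traj_attr(traj, "species")),
    pathways = purrr::map(traj_attr(traj, "pathways"), as.list),
    metabolites = as.list(traj_attr(traj, "metabolites")),
    dt = traj_attr(traj, "dt"),
    dynamic_enzymes = traj_attr(traj, "dynamic_enzymes"),
    feed_program = list(mode = fp$mode, D_on = fp$D_on, w = fp$w, s = fp$s,
                        feed = as.list(fp$feed), t_start = fp$t_start)
  )
  yaml::write_yaml(meta, sidecar(path), precision = 15)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
  meta <- yaml::read_yaml(sidecar(path))
  fpm <- meta$feed_program
  fp <- feed_program(fpm$mode, D = fpm$D_on, w = fpm$w, s = fpm$s,
                     feed = unlist(fpm$feed), t_start = fpm$t_start)
  structure(df, class = c("reactor_trajectory", class(tibble::tibble()))) |>
    set_traj_attrs(species = unlist(meta$species),
                   pathways = purrr::map(meta$pathways, unlist),
                   metabolites = unlist(meta$metabolites),
                   fp = fp, dt = meta$dt,
                   dynamic_enzymes = meta$dynamic_enzymes)
}

sidecar <- function(path) paste0(path, ".meta.yml")

# Deterministic full-precision CSV writer (all columns numeric or logical).
write_numeric_csv <- function(df, path) {
  cols <- purrr::map(df, function(col) {
    if (is.logical(col)) ifelse(col, "TRUE", "FALSE")
    else if (is.numeric(col)) sprintf("%.17g", col)
    else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read synthetic batch datasets
#'
#' Tidy CSV exchange format with columns
#' `condition, replicate, t, channel, value` plus a YAML sidecar holding the
#' generating design, seed and noise descriptors, so the read object is
#' attribute-identical to the generated one.
#'
#' @param data A `batch_dataset`.
#' @param path Output CSV path.
#' @return `path` (write) or the reconstructed `batch_dataset` (read).
#' @export
write_batch_dataset <- function(data, path) {
  stopifnot(inherits(data, "batch_dataset"))
  write_numeric_csv(as.data.frame(data), path)
  meta <- list(design = as.list(attr(data, "comonod_design")),
               cv = attr(data, "comonod_cv"),
               seed = attr(data, "comonod_seed"),
               times = as.list(attr(data, "comonod_times")),
               species = attr(data, "comonod_species"),
               X0 = attr(data, "comonod_X0"),
               additive_sd = attr(data, "comonod_additive_sd"))
  yaml::write_yaml(meta, sidecar(path), precision = 15)
  invisible(path)
}

#' @rdname write_batch_dataset
#' @export
read_batch_dataset <- function(path) {
  df <- utils::read.csv(path, colClasses = c(channel = "character"))
  df <- tibble::as_tibble(df)
  meta <- yaml::read_yaml(sidecar(path))
  structure(df, class = c("batch_dataset", class(tibble::tibble())),
            comonod_design = unlist(meta$design), comonod_cv = meta$cv,
            comonod_seed = meta$seed, comonod_times = unlist(meta$times),
            comonod_species = meta$species, comonod_X0 = meta$X0,
            comonod_additive_sd = meta$additive_sd)
}

#' Serialise a kinetics fit
#'
#' Writes estimates, fit diagnostics and full provenance (generating seed,
#' noise level, design, free parameters) to structured text; `read_fit_result`
#' returns them as a list of tibbles/values.
#'
#' @param fit A `kinetics_fit`.
#' @param path Output YAML path.
#' @return `path` (write) or a list with `estimate`, `diagnostics` and
#'   `provenance` (read).
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "kinetics_fit"))
  out <- list(
    estimate = purrr::transpose(as.list(tidy(fit))),
    diagnostics = list(residual_norm = fit$residual_norm,
                       converged = fit$converged,
                       iterations = as.integer(fit$iterations),
                       message = fit$message),
    provenance = list(pathway = fit$pathway, free = as.list(fit$free),
                      seed = fit$seed, cv = fit$cv,
                      design = as.list(fit$design))
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    estimate = dplyr::bind_rows(purrr::map(raw$estimate, tibble::as_tibble)),
    diagnostics = raw$diagnostics,
    provenance = raw$provenance
  )
}

#' Write a coexistence scan
#'
#' CSV with one grid point per row (`D, w, s, frac_*, min_frac_*,
#' persistent_*, coexistence, status`).
#'
#' @param scan A `coexistence_scan`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "coexistence_scan"))
  write_numeric_csv(as.data.frame(scan), path)
  invisible(path)
}
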