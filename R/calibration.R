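#' Generate a synthetic mini-bioreactor batch dataset
#'
#' Emulates the parallel micro-bioreactor design used to calibrate the
#' packaged organisms: a series of batch mono-cultures at different initial
#' glucose concentrations, sampled every 3 h, with biomass, glucose, acetate
#' and ethanol measured on each sample. Observations are the simulated true
#' trajectories with multiplicative Gaussian noise,
#' `obs = true * (1 + cv * z)` (plus an optional additive detection-limit
#' floor), clamped at zero. Replicate wells share the true trajectory and
#' differ only by noise draws. The dataset regenerates bit-identically from
#' the same design and seed; the caller's RNG state is left untouched.
#'
#' @param species A single [species_model()] (the generating truth).
#' @param design Initial glucose concentrations, g/L.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Integer seed for the noise draws.
#' @param times Sampling times, h. Default: every 3 h to 30 h, extended to
#'   36 h for the yeast (its batches run longer).
#' @param replicates Number of replicate wells per condition.
#' @param X0 Inoculum, g/L.
#' @param additive_sd Additive Gaussian noise floor, g/L (default 0; 0.01 is
#'   a realistic HPLC detection-limit scale).
#' @param ... Passed to [run_batch()].
#'
#' @return A `batch_dataset`: a tidy tibble with columns
#'   `condition` (initial GLU, g/L), `replicate`, `t`, `channel`
#'   (`X`, `GLU`, `ACE`, `ETH`) and `value`, carrying the design, seed and
#'   noise descriptors as attributes.
#' @export
generate_batch_dataset <- function(species, design = c(20, 10, 5, 2.5, 1.25),
                                   cv = 0.05, seed = 1L, times = NULL,
                                   replicates = 1, X0 = 0.05,
                                   additive_sd = 0, ...) {
  if (cv < 0) abort("`cv` must be non-negative.", class = "comonod_config_error")
  if (!length(design)) abort("`design` must be non-empty.",
                             class = "comonod_config_error")
  species <- as_species_list(species)
  if (length(species) != 1) {
    abort("The generator emulates mono-culture batches: one species.",
          class = "comonod_config_error")
  }
  sp <- species[[1]]
  if (is.null(times)) {
    t_max <- if (grepl("cerevisiae|scer|yeast", sp$name)) 36 else 30
    times <- seq(0, t_max, by = 3)
  }
  truth <- purrr::map(design, function(S0) {
    traj <- run_batch(sp, S0 = S0, X0 = X0, t_end = max(times), ...)
    idx <- vapply(times, function(tt) which.min(abs(traj$t - tt)), integer(1))
    tibble::tibble(
      t = times,
      X = traj[[paste0("X_", sp$name)]][idx],
      GLU = traj$GLU[idx], ACE = traj$ACE[idx], ETH = traj$ETH[idx]
    )
  })

  obs <- with_local_seed(seed, {
    purrr::map2_dfr(design, truth, function(S0, tr) {
      purrr::map_dfr(seq_len(replicates), function(r) {
        long <- tidyr::pivot_longer(tr, cols = c("X", "GLU", "ACE", "ETH"),
                                    names_to = "channel", values_to = "true")
        z <- rnorm(nrow(long))
        z2 <- if (additive_sd > 0) rnorm(nrow(long)) else 0
        tibble::tibble(
          condition = S0, replicate = r, t = long$t, channel = long$channel,
          value = pmax(long$true * (1 + cv * z) + additive_sd * z2, 0)
        )
      })
    })
  })
  structure(obs, class = c("batch_dataset", class(tibble::tibble())),
            comonod_design = design, comonod_cv = cv, comonod_seed = seed,
            comonod_times = times, comonod_species = sp$name,
            comonod_X0 = X0, comonod_additive_sd = additive_sd)
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fit Monod/yield parameters to batch trajectories
#'
#' Bounded weighted least squares (Levenberg-Marquardt) over all observed
#' channels jointly. Free parameters (a subset of `mu_max`, `Ks`, `q_max`,
#' `Yx` of one pathway of the template species) are adjusted so the simulated
#' batch trajectories match the observations at the sampling times; each
#' channel is weighted by the reciprocal root-mean-square of its observations
#' so g/L-scale glucose and sub-g/L byproducts count comparably. The
#' parameter family is kept internally consistent: when `q_max` is not free
#' it is tied to `mu_max / Yx`, and when it is free a penalty residual holds
#' `|mu_max - Yx * q_max| / mu_max` within 2%. Enzyme-dynamics constants are
#' never fitted (they are literature-derived, not identifiable from these
#' data).
#'
#' @param data A `batch_dataset` (missing values allowed and skipped).
#' @param template A [species_model()] providing structure and starting
#'   values.
#' @param free Character vector of free parameter names among
#'   `c("mu_max", "Ks", "q_max", "Yx")`. May be empty: the template is then
#'   only evaluated (residuals computed, nothing moved).
#' @param pathway Pathway id to fit; default the first pathway of the
#'   template.
#' @param bounds Optional list with `lower`/`upper` named numeric vectors
#'   over the free parameters. Defaults: a factor of 20 around the template
#'   values.
#' @param conf_level Confidence level of the reported intervals (from the
#'   local quadratic approximation at the optimum).
#' @param n_starts Number of deterministic starting points (the template
#'   values scaled by 1, 2, 1/2, 4, 1/4, clipped to the bounds); the
#'   lowest-residual solution wins. The default 3 guards against the local
#'   minima that bounded Monod fits are prone to when the starting guess is
#'   far off; set to 1 for speed when the start is known to be close.
#' @param ... Passed to [run_batch()] for the model evaluations.
#'
#' @return A `kinetics_fit` object; see [tidy()] and [glance()] methods for
#'   tabular access, and [recovery_report()] to compare against a known
#'   truth.
#' @export
fit_kinetics <- function(data, template, free = c("mu_max", "Ks", "Yx"),
                         pathway = NULL, bounds = NULL, conf_level = 0.95,
                         n_starts = 3, ...) {
  stopifnot(inherits(data, "batch_dataset"))
  template <- as_species_list(template)[[1]]
  pw <- template$pathways
  pathway <- pathway %||% pw$id[1]
  if (!pathway %in% pw$id) {
    abort(sprintf("Unknown pathway '%s' in template.", pathway),
          class = "comonod_config_error")
  }
  allowed <- c("mu_max", "Ks", "q_max", "Yx")
  if (!all(free %in% allowed)) {
    abort(sprintf("Free parameters must be among %s.",
                  paste(allowed, collapse = ", ")),
          class = "comonod_config_error")
  }
  conditions <- sort(unique(data$condition))
  if (length(conditions) < 2) {
    abort("Need at least two batch conditions to fit.",
          class = "comonod_config_error")
  }
  check_identifiable(data, template, pathway)

  obs <- dplyr::filter(data, !is.na(.data$value)) |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(weight = 1 / max(sqrt(mean(.data$value^2)), 1e-6)) |>
    dplyr::ungroup()
  times <- attr(data, "comonod_times")
  X0 <- attr(data, "comonod_X0") %||% 0.05

  j <- match(pathway, pw$id)
  start <- unlist(pw[j, free, drop = FALSE])
  if (length(free) && any(start <= 0)) {
    abort("Template starting values for free parameters must be positive.",
          class = "comonod_config_error")
  }
  if (is.null(bounds)) {
    bounds <- list(lower = start / 20, upper = start * 20)
  }
  tie_q <- !("q_max" %in% free)
  # if the template uses the default induction-constant coupling
  # (K_ind = Ks), keep it coupled while Ks moves; an explicitly different
  # K_ind is an enzyme constant and stays fixed
  couple_K_ind <- isTRUE(all.equal(pw$K_ind[j], pw$Ks[j]))

  patched <- function(theta) {
    pw2 <- pw
    for (nm in free) pw2[[nm]][j] <- theta[[nm]]
    if (tie_q && any(c("mu_max", "Yx") %in% free)) {
      pw2$q_max[j] <- pw2$mu_max[j] / pw2$Yx[j]
    }
    if (couple_K_ind && "Ks" %in% free) pw2$K_ind[j] <- pw2$Ks[j]
    sp <- structure(list(name = template$name,
                         metabolites = template$metabolites,
                         pathways = pw2, psi = NULL),
                    class = "species_model")
    sp$psi <- build_psi(sp)
    sp
  }

  predict_obs <- function(sp) {
    pred <- purrr::map(conditions, function(S0) {
      traj <- run_batch(sp, S0 = S0, X0 = X0, t_end = max(times), ...)
      idx <- vapply(times, function(tt) which.min(abs(traj$t - tt)), integer(1))
      tibble::tibble(condition = S0, t = times,
                     X = traj[[paste0("X_", sp$name)]][idx],
                     GLU = traj$GLU[idx], ACE = traj$ACE[idx],
                     ETH = traj$ETH[idx]) |>
        tidyr::pivot_longer(cols = c("X", "GLU", "ACE", "ETH"),
                            names_to = "channel", values_to = "pred")
    }) |> dplyr::bind_rows()
    dplyr::left_join(obs, pred, by = c("condition", "t", "channel"))
  }

  # the optimiser works on log parameters: kinetic constants are positive
  # and span decades, and the log scale conditions the mu_max/Ks ridge
  residual_fn <- function(lpar) {
    theta <- setNames(as.list(exp(lpar)), free)
    sp <- patched(theta)
    tab <- predict_obs(sp)
    res <- (tab$value - tab$pred) * tab$weight
    if (!tie_q) {
      # soft constraint: a 2% relative inconsistency costs as much as ten
      # weighted data residuals of size one
      pwj <- sp$pathways[j, ]
      res <- c(res, (pwj$mu_max - pwj$Yx * pwj$q_max) / (0.002 * pwj$mu_max))
    }
    res
  }

  if (length(free) == 0) {
    sp <- patched(list())
    tab <- predict_obs(sp)
    res <- (tab$value - tab$pred) * tab$weight
    return(new_kinetics_fit(
      estimate = tibble::tibble(pathway = character(0), term = character(0),
                                estimate = numeric(0), std_error = numeric(0),
                                conf_low = numeric(0), conf_high = numeric(0)),
      residual_norm = sqrt(sum(res^2)), converged = TRUE, iterations = 0L,
      message = "no free parameters", species = sp, pathway = pathway,
      data = data, free = free))
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                     ptol = 1e-12)
  lo <- log(pmax(unname(bounds$lower[free]), 1e-12))
  hi <- log(unname(bounds$upper[free]))
  factors <- c(1, 2, 0.5, 4, 0.25)[seq_len(max(1, min(n_starts, 5)))]
  runs <- lapply(factors, function(f) {
    par0 <- pmin(pmax(log(start * f), lo + 1e-6), hi - 1e-6)
    minpack.lm::nls.lm(par = par0, lower = lo, upper = hi,
                       fn = residual_fn, control = ctrl)
  })
  opt <- runs[[which.min(vapply(runs, function(r) r$deviance, numeric(1)))]]
  lest <- setNames(as.numeric(opt$par), free)
  est <- exp(lest)
  nres <- length(opt$fvec)
  dof <- max(nres - length(free), 1)
  # local quadratic approximation on the log scale with a
  # heteroscedasticity-robust (HC3 sandwich) middle term: multiplicative
  # measurement noise makes residual variance grow with the signal, which a
  # plain (J'J)^-1 badly understates, and residuals at influential points
  # are shrunk by the fit itself, hence the (1 - h_ii) rescaling
  vcov_log <- tryCatch({
    J <- num_jacobian(residual_fn, opt$par)
    bread <- solve(crossprod(J))
    h <- pmin(rowSums((J %*% bread) * J), 0.99)
    meat <- crossprod(J * (opt$fvec / (1 - h)))
    v <- bread %*% meat %*% bread
    dimnames(v) <- list(free, free)
    v
  }, error = function(e) {
    matrix(NA_real_, length(free), length(free),
           dimnames = list(free, free))
  })
  se_log <- sqrt(pmax(diag(vcov_log), 0))
  tq <- qt(1 - (1 - conf_level) / 2, df = dof)
  # natural-scale covariance by the delta method; intervals exp-transformed
  # (positive and asymmetric, as befits scale parameters)
  vcov <- diag(est, length(est)) %*% vcov_log %*% diag(est, length(est))
  dimnames(vcov) <- list(free, free)

  new_kinetics_fit(
    estimate = tibble::tibble(
      pathway = pathway, term = free, estimate = unname(est),
      std_error = unname(est * se_log),
      conf_low = unname(exp(lest - tq * se_log)),
      conf_high = unname(exp(lest + tq * se_log))),
    residual_norm = sqrt(sum(opt$fvec^2)),
    converged = opt$info %in% 1:4, iterations = opt$niter,
    message = opt$message, species = patched(as.list(est)),
    pathway = pathway, data = data, free = free, vcov = vcov)
}

# Central-difference jacobian of a vector-valued function.
num_jacobian <- function(fn, par) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- max(1e-6 * abs(par[i]), 1e-8)
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    J[, i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# A pathway is only identifiable if its substrate signal (or a byproduct it
# feeds) actually varies in the observations.
check_identifiable <- function(data, template, pathway) {
  j <- match(pathway, template$pathways$id)
  sub <- template$pathways$substrate[j]
  vals <- data$value[data$channel == sub & !is.na(data$value)]
  if (length(vals) == 0 || diff(range(vals)) <= 0) {
    abort(sprintf(paste0(
      "Pathway '%s' is not identifiable: its substrate channel '%s' ",
      "carries no varying observations."), pathway, sub),
      class = "comonod_identifiability_error")
  }
  invisible(TRUE)
}

new_kinetics_fit <- function(estimate, residual_norm, converged, iterations,
                             message, species, pathway, data, free,
                             vcov = NULL) {
  structure(
    list(estimate = estimate, residual_norm = residual_norm,
         converged = converged, iterations = iterations, message = message,
         species = species, pathway = pathway, free = free, vcov = vcov,
         seed = attr(data, "comonod_seed"), cv = attr(data, "comonod_cv"),
         design = attr(data, "comonod_design")),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> pathway '%s' (%s), %s after %d iterations\n",
              x$pathway, paste(x$free, collapse = ", "),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  residual norm %.5g\n", x$residual_norm))
  print(x$estimate)
  invisible(x)
}

#' @describeIn fit_kinetics Parameter estimates with standard errors and
#'   confidence intervals, one row per free parameter.
#' @param x A `kinetics_fit`.
#' @export
tidy.kinetics_fit <- function(x, ...) x$estimate

#' @describeIn fit_kinetics One-row fit summary (residual norm, convergence,
#'   iterations, data descriptors).
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, converged = x$converged,
                 iterations = x$iterations, n_free = length(x$free),
                 n_conditions = length(x$design), cv = x$cv, seed = x$seed)
}

#' Compare fitted parameters against a known truth
#'
#' Per-parameter relative errors `|estimate - true| / true` of a
#' [fit_kinetics()] result against the generating species model, with a flag
#' for parameters outside their declared tolerance. The default tolerances
#' reflect identifiability from batch data: growth rate and yield are well
#' constrained, while `Ks` is weakly identified when most observations sit
#' far above saturation.
#'
#' @param truth The generating [species_model()].
#' @param fit A `kinetics_fit`.
#' @param tol Named relative-error tolerances per parameter.
#' @return A tibble with columns `pathway`, `term`, `true`, `estimate`,
#'   `rel_error`, `tolerance`, `within`.
#' @export
recovery_report <- function(truth, fit,
                            tol = c(mu_max = 0.1, Ks = 0.5, q_max = 0.1,
                                    Yx = 0.1)) {
  stopifnot(inherits(fit, "kinetics_fit"))
  truth <- as_species_list(truth)[[1]]
  j <- match(fit$pathway, truth$pathways$id)
  if (is.na(j)) {
    abort("Fit pathway not present in the truth model.",
          class = "comonod_config_error")
  }
  est <- fit$estimate
  true_vals <- vapply(est$term, function(nm) truth$pathways[[nm]][j],
                      numeric(1))
  rel <- abs(est$estimate - true_vals) / abs(true_vals)
  tibble::tibble(
    pathway = fit$pathway, term = est$term, true = unname(true_vals),
    estimate = est$estimate, rel_error = unname(rel),
    tolerance = unname(tol[est$term]),
    within = unname(rel <= tol[est$term]))
}
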