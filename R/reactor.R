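#' Feed program for a bioreactor run
#'
#' Describes how fresh medium is supplied: `batch` (no flow), `chemostat`
#' (constant dilution rate) or `pulsed` (square-wave dilution with frequency
#' `w` and duty cycle `s`: within each period `1/w` the feed is on for the
#' first fraction `s` at rate `D` and off for the remainder). Working volume
#' is constant, so outflow always equals inflow and the off-phase has neither.
#'
#' @param mode One of `"batch"`, `"chemostat"`, `"pulsed"`.
#' @param D Dilution rate during the feed-on phase, h^-1. With
#'   `D_is_average = TRUE` the value is interpreted as the time-averaged
#'   dilution rate instead and the on-phase rate becomes `D / s`.
#' @param w Pulse frequency, h^-1 (period `1/w`); required in pulsed mode.
#' @param s Feed-on fraction of the period, in `(0, 1]`. `s = 1` degenerates
#'   to a chemostat.
#' @param feed Named metabolite composition of the inflow, g/L.
#' @param t_start Time at which feeding begins, h; before it the reactor runs
#'   as a batch (the usual start-up phase of a continuous culture).
#' @param D_is_average Interpret `D` as the period-averaged dilution rate.
#'
#' @return An object of class `feed_program`.
#' @examples
#' feed_program("pulsed", D = 0.1, w = 0.14, s = 0.28) # 2 h on : 5.1 h off
#' @export
feed_program <- function(mode = c("batch", "chemostat", "pulsed"),
                         D = 0, w = NULL, s = 1,
                         feed = c(GLU = 30, ACE = 0, ETH = 0),
                         t_start = 0, D_is_average = FALSE) {
  mode <- match.arg(mode)
  if (D < 0) abort("`D` must be non-negative.", class = "comonod_config_error")
  if (mode == "pulsed") {
    if (is.null(w) || w <= 0) {
      abort("Pulsed mode requires a positive pulse frequency `w`.",
            class = "comonod_config_error")
    }
    if (s <= 0 || s > 1) {
      abort("`s` must lie in (0, 1].", class = "comonod_config_error")
    }
  }
  if (mode == "batch") D <- 0
  D_on <- if (D_is_average && mode == "pulsed") D / s else D
  structure(
    list(mode = mode, D_on = D_on, w = w, s = s,
         feed = feed, t_start = t_start),
    class = "feed_program"
  )
}

#' @export
print.feed_program <- function(x, ...) {
  cat("<feed_program> mode =", x$mode)
  if (x$mode != "batch") {
    cat(sprintf(", D_on = %g 1/h", x$D_on))
    if (x$mode == "pulsed") {
      cat(sprintf(", w = %g 1/h, s = %g (on %.2f h : off %.2f h)",
                  x$w, x$s, x$s / x$w, (1 - x$s) / x$w))
    }
    if (x$t_start > 0) cat(sprintf(", feed from t = %g h", x$t_start))
  }
  cat("\n  feed:", paste(names(x$feed), x$feed, sep = "=", collapse = ", "),
      "g/L\n")
  invisible(x)
}

#' Realised dilution rate of a feed program
#'
#' Square-wave evaluation: in pulsed mode `D(t) = D_on` while
#' `((t - t_start) mod 1/w) < s/w` and zero otherwise; constant `D_on` for a
#' chemostat; identically zero for a batch. The time average over one full
#' period is `s * D_on`.
#'
#' @param t Time(s), h; vectorised.
#' @param fp A [feed_program()].
#' @return Numeric vector of dilution rates, h^-1.
#' @examples
#' fp <- feed_program("pulsed", D = 0.1, w = 0.14, s = 0.28)
#' dilution_profile(c(0, 1.9, 2.1, 7.2), fp)
#' @export
dilution_profile <- function(t, fp) {
  stopifnot(inherits(fp, "feed_program"), all(t >= 0))
  if (fp$mode == "batch") return(rep(0, length(t)))
  active <- t >= fp$t_start
  if (fp$mode == "chemostat" || isTRUE(fp$s == 1)) {
    return(ifelse(active, fp$D_on, 0))
  }
  period <- 1 / fp$w
  phase <- (t - fp$t_start) %% period
  ifelse(active & phase < fp$s * period, fp$D_on, 0)
}

# Pulse edge times (feeding switch points) in (t0, t_end): used to restart
# the integrator so that discontinuities in D(t) are never stepped over.
pulse_edges <- function(fp, t0, t_end) {
  edges <- numeric(0)
  if (fp$t_start > t0 && fp$t_start < t_end && fp$mode != "batch") {
    edges <- fp$t_start
  }
  if (fp$mode == "pulsed" && fp$s < 1) {
    period <- 1 / fp$w
    k_max <- ceiling((t_end - fp$t_start) / period) + 1
    k <- 0:k_max
    cand <- fp$t_start + c(k * period, (k + fp$s) * period)
    edges <- c(edges, cand[cand > t0 & cand < t_end])
  }
  sort(unique(edges))
}

#' Initial reactor state
#'
#' @param species A [species_model()] or list of them.
#' @param X0 Initial biomass per species, g/L; recycled across species. The
#'   default 0.05 g/L corresponds to an inoculum of roughly 0.1 OD at an
#'   assumed 0.5 g dry weight per litre per OD unit.
#' @param M0 Named initial metabolite pool, g/L.
#' @param psi0 Optional list (per species) of initial relative enzyme levels;
#'   defaults to the resting-cell constitutive steady state
#'   `(eps_c / delta) / Psi_max` of each pathway.
#' @return A list with components `X`, `M`, `psi` used by
#'   [simulate_reactor()].
#' @export
reactor_init <- function(species, X0 = 0.05,
                         M0 = c(GLU = 20, ACE = 0, ETH = 0), psi0 = NULL) {
  species <- as_species_list(species)
  X <- setNames(rep_len(X0, length(species)), names(species))
  if (!is.null(psi0) && is.null(names(psi0))) names(psi0) <- names(species)
  list(X = X, M = M0, psi = psi0)
}

as_species_list <- function(species) {
  if (is_species_model(species)) species <- list(species)
  stopifnot(all(purrr::map_lgl(species, is_species_model)))
  nm <- purrr::map_chr(species, "name")
  if (anyDuplicated(nm)) {
    abort("Species names must be unique within a reactor.",
          class = "comonod_config_error")
  }
  setNames(species, nm)
}

# Flatten per-species parameter tables once, for a fast ODE right-hand side.
compile_system <- function(species, metabolites) {
  purrr::map(species, function(sp) {
    if (!identical(sp$metabolites, metabolites)) {
      abort(sprintf(
        "Species '%s' metabolite list differs from the reactor pool.", sp$name),
        class = "comonod_config_error")
    }
    pw <- sp$pathways
    list(
      n = nrow(pw),
      sub = match(pw$substrate, metabolites),
      Ks = pw$Ks, q_max = pw$q_max, Yx = pw$Yx,
      YxQ = pw$Yx * pw$q_max, K_ind = pw$K_ind,
      eps_c = pw$eps_c, eps_i = pw$eps_i, delta = pw$delta,
      gain = (pw$delta + pw$mu_max) / (pw$eps_c + pw$eps_i),
      psi_met = sp$psi[-1, , drop = FALSE]
    )
  })
}

#' Joint right-hand side of the co-culture reactor
#'
#' Derivatives of biomasses, metabolite pool and relative enzyme levels at a
#' given instant: per-species cybernetic fluxes summed simultaneously into
#' the shared pool plus the standard constant-volume CSTR dilution terms
#' `dX/dt -= D X`, `dM/dt += D (feed - M)`. Exposed mainly for inspection and
#' testing; [simulate_reactor()] uses the same computation internally.
#'
#' @param t Time, h.
#' @param state A list with `X` (named biomass vector), `M` (named metabolite
#'   vector) and `psi` (list of relative enzyme vectors per species).
#' @param species A [species_model()] or list of them.
#' @param fp A [feed_program()].
#' @return A list with `dX`, `dM`, `dpsi` (same shapes as the state).
#' @export
coculture_rhs <- function(t, state, species, fp) {
  species <- as_species_list(species)
  met <- species[[1]]$metabolites
  sys <- compile_system(species, met)
  y <- c(unlist(state$X), unname(state$M[met]),
         unlist(state$psi[names(species)]))
  if (any(!is.finite(y))) {
    abort("Non-finite reactor state.", class = "comonod_numeric_error")
  }
  d <- rhs_core(y, length(species), length(met), sys,
                D = dilution_profile(t, fp), feed = feed_vector(fp, met),
                dynamic_enzymes = TRUE, scaled_by_biomass = FALSE)
  K <- length(species); nm <- length(met)
  off <- K + nm
  dpsi <- purrr::map(seq_along(sys), function(k) {
    n <- sys[[k]]$n
    out <- d[off + seq_len(n)]
    off <<- off + n
    setNames(out, species[[k]]$pathways$id)
  })
  list(dX = setNames(d[seq_len(K)], names(species)),
       dM = setNames(d[K + seq_len(nm)], met),
       dpsi = setNames(dpsi, names(species)))
}

feed_vector <- function(fp, metabolites) {
  f <- setNames(rep(0, length(metabolites)), metabolites)
  known <- intersect(names(fp$feed), metabolites)
  if (length(known) < length(fp$feed)) {
    abort("Feed composition names must be reactor metabolites.",
          class = "comonod_config_error")
  }
  f[known] <- fp$feed[known]
  unname(f)
}

# Core derivative computation on the flat state vector
# y = (X_1..X_K, M_1..M_m, psi_sp1..., psi_spK...). `D` is constant within an
# integration segment. Negative excursions (integrator undershoot) are
# clamped to zero for rate evaluation only.
rhs_core <- function(y, K, nm, sys, D, feed, dynamic_enzymes,
                     scaled_by_biomass, psi_fixed = NULL) {
  X <- pmax(y[seq_len(K)], 0)
  M <- pmax(y[K + seq_len(nm)], 0)
  dy <- numeric(length(y))
  dM <- D * (feed - y[K + seq_len(nm)])
  off <- K + nm
  for (k in seq_len(K)) {
    p <- sys[[k]]
    psi <- if (dynamic_enzymes) pmax(y[off + seq_len(p$n)], 0)
           else psi_fixed[[k]]
    S <- M[p$sub]
    H <- S / (p$Ks + S)
    mu <- p$YxQ * psi * H
    smu <- sum(mu)
    if (smu > 1e-12) {
      u <- mu / smu
      v <- mu / max(mu)
    } else {
      u <- rep(1 / p$n, p$n)
      v <- rep(1, p$n)
    }
    rate <- v * p$q_max * psi * H * X[k]
    dy[k] <- sum(p$Yx * rate) - D * y[k]
    dM <- dM + drop(p$psi_met %*% rate)
    if (dynamic_enzymes) {
      mu_tot <- sum(v * mu)
      H_ind <- S / (p$K_ind + S)
      inducible <- u * p$eps_i * H_ind
      if (scaled_by_biomass) inducible <- inducible * X[k]
      dy[off + seq_len(p$n)] <-
        (p$eps_c + inducible) * p$gain - (p$delta + mu_tot) * psi
      off <- off + p$n
    }
  }
  dy[K + seq_len(nm)] <- dM
  dy
}

#' Integrate a co-culture bioreactor
#'
#' Adaptive stiff-capable integration (lsoda) of the joint species/pool
#' system. The integration is restarted at every pulse edge of the feed
#' program, so square-wave discontinuities in the dilution rate are honoured
#' exactly rather than stepped over; within each segment the dilution rate is
#' constant. Output is sampled on a uniform reporting grid and concentrations
#' below `1e-12` g/L are clamped to zero. The result is fully deterministic
#' given its inputs.
#'
#' @param species A [species_model()] or list of them.
#' @param fp A [feed_program()].
#' @param init Initial state from [reactor_init()].
#' @param t_end Final time, h.
#' @param dt Reporting grid step, h (default 0.05).
#' @param rtol,atol Integrator tolerances.
#' @param dynamic_enzymes If `FALSE`, relative enzyme levels are pinned at 1
#'   (fully expressed machinery); with a single pathway this reduces the
#'   model exactly to classical Monod kinetics.
#' @param enzyme_synthesis_scaled_by_biomass Use the extensive form of the
#'   inducible enzyme synthesis term (see [enzyme_odes()]).
#' @param engine `"compiled"` evaluates the right-hand side in C (the
#'   default; much faster for long pulsed runs and scans), `"R"` uses the
#'   pure-R implementation. Both compute identical derivatives and are
#'   cross-checked in the test suite.
#'
#' @return A `reactor_trajectory`: a tibble with one row per reporting time
#'   and columns `t`, `D`, `X_<species>`, the metabolites, and per-species
#'   diagnostic series `psi_rel_*`, `u_*`, `v_*` (per pathway) and `mu_*`
#'   (realised total specific growth rate).
#' @seealso [run_batch()], [run_chemostat()], [run_pulsed()]
#' @export
simulate_reactor <- function(species, fp, init, t_end,
                             dt = 0.05, rtol = 1e-8, atol = 1e-10,
                             dynamic_enzymes = TRUE,
                             enzyme_synthesis_scaled_by_biomass = FALSE,
                             engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(fp, "feed_program"), t_end > 0)
  species <- as_species_list(species)
  met <- species[[1]]$metabolites
  sys <- compile_system(species, met)
  K <- length(species)
  nm <- length(met)
  feed <- feed_vector(fp, met)

  psi0 <- purrr::map(names(species), function(nmsp) {
    given <- init$psi[[nmsp]]
    if (!is.null(given)) return(unname(given))
    # default: resting constitutive level for dynamic enzymes, fully
    # expressed machinery when the enzyme layer is pinned
    if (dynamic_enzymes) unname(resting_psi_rel(species[[nmsp]]))
    else rep(1, nrow(species[[nmsp]]$pathways))
  })
  y0 <- c(unname(init$X[names(species)]), unname(init$M[met]),
          if (dynamic_enzymes) unlist(psi0))
  if (any(is.na(y0))) {
    abort("Initial state incomplete: check species/metabolite names.",
          class = "comonod_config_error")
  }

  grid <- seq(0, t_end, by = dt)
  if (tail(grid, 1) < t_end) grid <- c(grid, t_end)
  breaks <- c(0, pulse_edges(fp, 0, t_end), t_end)
  # merge segment boundaries closer than 1 ns of an hour (floating-point
  # coincidences between pulse edges and the reporting grid)
  breaks <- breaks[c(TRUE, diff(breaks) > 1e-9)]

  deriv <- function(t, y, parms) {
    list(rhs_core(y, K, nm, sys, D = parms[3], feed = feed,
                  dynamic_enzymes = dynamic_enzymes,
                  scaled_by_biomass = enzyme_synthesis_scaled_by_biomass,
                  psi_fixed = psi0))
  }
  base_parms <- pack_parms(sys, K, nm, feed,
                           dynamic = dynamic_enzymes,
                           scaled = enzyme_synthesis_scaled_by_biomass,
                           psi_fixed = psi0)

  rows <- vector("list", length(breaks) - 1)
  y <- y0
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    Dseg <- dilution_profile((t0 + t1) / 2, fp)
    inner <- grid[grid > t0 + 1e-9 & grid < t1 - 1e-9]
    times <- unique(c(t0, inner, t1))
    parms <- base_parms
    parms[3] <- Dseg
    sol <- if (engine == "compiled") {
      deSolve::ode(y = y, times = times, func = "comonod_derivs",
                   parms = parms, dllname = "comonod",
                   initfunc = "comonod_initmod", method = "lsoda",
                   rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      deSolve::ode(y = y, times = times, func = deriv,
                   parms = parms, method = "lsoda",
                   rtol = rtol, atol = atol, maxsteps = 50000)
    }
    if (attr(sol, "istate")[1] < 0) {
      abort(sprintf(
        "Integrator failed in segment [%.4f, %.4f] h (istate %d).",
        t0, t1, attr(sol, "istate")[1]), class = "comonod_numeric_error")
    }
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% grid & (sol[, 1] < t1 | i == length(breaks) - 1)
    rows[[i]] <- sol[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  state <- pmax(out[, -1, drop = FALSE], 0)
  state[state < 1e-12] <- 0

  build_trajectory(time = out[, 1], state = state, species = species,
                   met = met, sys = sys, fp = fp,
                   dynamic_enzymes = dynamic_enzymes, psi_fixed = psi0,
                   dt = dt)
}

# Flatten the system description into the flat double vector consumed by the
# compiled right-hand side (padded to the fixed length the C side expects).
pack_parms <- function(sys, K, nm, feed, dynamic, scaled, psi_fixed) {
  per <- purrr::map(seq_along(sys), function(k) {
    p <- sys[[k]]
    c(p$n, p$sub, p$Ks, p$q_max, p$Yx, p$YxQ, p$K_ind, p$eps_c, p$eps_i,
      p$delta, p$gain, as.vector(p$psi_met), psi_fixed[[k]])
  })
  v <- c(K, nm, 0, as.numeric(dynamic), as.numeric(scaled), 0,
         feed, unlist(per))
  if (length(v) > 4096) {
    abort("System too large for the compiled solver; use engine = \"R\".",
          class = "comonod_config_error")
  }
  c(v, numeric(4096 - length(v)))
}

# Assemble the wide diagnostics tibble from the integrated state matrix.
build_trajectory <- function(time, state, species, met, sys, fp,
                             dynamic_enzymes, psi_fixed, dt) {
  K <- length(species)
  nm <- length(met)
  Xmat <- state[, seq_len(K), drop = FALSE]
  Mmat <- state[, K + seq_len(nm), drop = FALSE]
  df <- tibble::tibble(t = time, D = dilution_profile(time, fp))
  for (k in seq_len(K)) df[[paste0("X_", names(species)[k])]] <- Xmat[, k]
  for (m in seq_len(nm)) df[[met[m]]] <- Mmat[, m]

  off <- K + nm
  for (k in seq_len(K)) {
    p <- sys[[k]]
    spn <- names(species)[k]
    ids <- species[[k]]$pathways$id
    psi <- if (dynamic_enzymes) {
      state[, off + seq_len(p$n), drop = FALSE]
    } else {
      matrix(psi_fixed[[k]], nrow = length(time), ncol = p$n, byrow = TRUE)
    }
    off <- off + if (dynamic_enzymes) p$n else 0
    S <- Mmat[, p$sub, drop = FALSE]
    H <- sweep(S, 2, p$Ks, function(s, ks) s / (ks + s))
    mu <- sweep(psi * H, 2, p$YxQ, `*`)
    smu <- rowSums(mu)
    mx <- do.call(pmax, c(as.data.frame(mu), list(0)))
    degen <- smu <= 1e-12
    u <- mu / ifelse(degen, 1, smu)
    u[degen, ] <- 1 / p$n
    v <- mu / ifelse(degen | mx == 0, 1, mx)
    v[degen, ] <- 1
    for (j in seq_len(p$n)) {
      df[[paste0("psi_rel_", spn, "_", ids[j])]] <- psi[, j]
      df[[paste0("u_", spn, "_", ids[j])]] <- u[, j]
      df[[paste0("v_", spn, "_", ids[j])]] <- v[, j]
    }
    df[[paste0("mu_", spn)]] <- rowSums(v * mu)
  }
  structure(df,
            class = c("reactor_trajectory", class(tibble::tibble()))) |>
    set_traj_attrs(species = names(species),
                   pathways = purrr::map(species, ~ .x$pathways$id),
                   metabolites = met, fp = fp, dt = dt,
                   dynamic_enzymes = dynamic_enzymes)
}

set_traj_attrs <- function(df, ...) {
  dots <- list(...)
  for (nm in names(dots)) attr(df, paste0("comonod_", nm)) <- dots[[nm]]
  df
}

traj_attr <- function(traj, what) attr(traj, paste0("comonod_", what))

#' @export
print.reactor_trajectory <- function(x, ...) {
  sp <- traj_attr(x, "species")
  fp <- traj_attr(x, "fp")
  cat(sprintf("<reactor_trajectory> %d time points over %.4g h, mode %s\n",
              nrow(x), max(x$t), fp$mode))
  cat("  species:", paste(sp, collapse = ", "), "\n")
  NextMethod()
}
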