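#' Batch mono- or co-culture simulation
#'
#' Closed-vessel growth on an initial glucose charge. With the packaged
#' organisms at high initial glucose this reproduces the diauxic pattern:
#' overflow byproducts (acetate for *E. coli*; ethanol and acetate for the
#' yeast) accumulate during glucose consumption and are re-assimilated after
#' its exhaustion, with the corresponding key enzymes induced only once
#' glucose runs low.
#'
#' @param species A [species_model()] or list of them.
#' @param S0 Initial glucose concentration, g/L (> 0).
#' @param X0 Initial biomass per species, g/L (default 0.05, i.e. ~0.1 OD at
#'   0.5 gDW/L per OD unit).
#' @param t_end Duration, h.
#' @param ... Passed to [simulate_reactor()] (`dt`, tolerances,
#'   `dynamic_enzymes`, ...).
#' @return A `reactor_trajectory`.
#' @export
run_batch <- function(species, S0, X0 = 0.05, t_end = 30, ...) {
  if (S0 <= 0) abort("`S0` must be positive.", class = "comonod_config_error")
  fp <- feed_program("batch")
  init <- reactor_init(species, X0 = X0, M0 = c(GLU = S0, ACE = 0, ETH = 0))
  simulate_reactor(species, fp, init, t_end = t_end, ...)
}

#' Continuous (chemostat) co-culture simulation
#'
#' Constant-dilution continuous culture, preceded by a batch start-up phase
#' (default 10 h) before the feed pump starts — the standard protocol for
#' continuous co-cultivations. With the packaged pair at `D = 0.1` h^-1 the
#' yeast fraction rises transiently while the overflow metabolites built up
#' during the batch phase are re-assimilated, then declines towards
#' competitive exclusion once they are exhausted.
#'
#' @param species A [species_model()] or list of them.
#' @param D Dilution rate, h^-1 (> 0).
#' @param t_end Duration, h.
#' @param inoculum_ratio Named biomass ratio across species (default equal,
#'   the 1:1 g/L inoculum); scaled so the total inoculum is `X_total`.
#' @param X_total Total inoculum biomass, g/L.
#' @param S0 Initial glucose in the vessel, g/L.
#' @param feed Feed composition, g/L (default 30 g/L glucose).
#' @param batch_phase Batch start-up duration before feeding, h.
#' @param ... Passed to [simulate_reactor()].
#' @return A `reactor_trajectory`.
#' @export
run_chemostat <- function(species, D, t_end = 80, inoculum_ratio = NULL,
                          X_total = 0.1, S0 = 20,
                          feed = c(GLU = 30, ACE = 0, ETH = 0),
                          batch_phase = 10, ...) {
  if (D <= 0) abort("`D` must be positive.", class = "comonod_config_error")
  species <- as_species_list(species)
  X0 <- inoculum_vector(species, inoculum_ratio, X_total)
  fp <- feed_program("chemostat", D = D, feed = feed, t_start = batch_phase)
  init <- reactor_init(species, X0 = X0, M0 = c(GLU = S0, ACE = 0, ETH = 0))
  simulate_reactor(species, fp, init, t_end = t_end, ...)
}

#' Pulsed-feed continuous co-culture simulation
#'
#' Continuous culture under square-wave dilution pulsing. Each feed-off phase
#' lets glucose run out and triggers a diauxic shift: the yeast re-induces
#' its ethanol-assimilation enzyme and gains a periodic fitness advantage
#' that can sustain non-decaying oscillations of the species fractions,
#' where a constant-dilution culture at the same rate excludes it.
#'
#' @param species A [species_model()] or list of them.
#' @param fp A [feed_program()] with `mode = "pulsed"` (its `t_start` is the
#'   batch start-up duration).
#' @param t_end Duration, h.
#' @param inoculum_ratio,X_total,S0 As in [run_chemostat()].
#' @param ... Passed to [simulate_reactor()].
#' @return A `reactor_trajectory`.
#' @export
run_pulsed <- function(species, fp, t_end = 80, inoculum_ratio = NULL,
                       X_total = 0.1, S0 = 20, ...) {
  if (!inherits(fp, "feed_program") || fp$mode != "pulsed") {
    abort("`fp` must be a pulsed feed program.", class = "comonod_config_error")
  }
  species <- as_species_list(species)
  X0 <- inoculum_vector(species, inoculum_ratio, X_total)
  init <- reactor_init(species, X0 = X0, M0 = c(GLU = S0, ACE = 0, ETH = 0))
  simulate_reactor(species, fp, init, t_end = t_end, ...)
}

inoculum_vector <- function(species, ratio, X_total) {
  K <- length(species)
  if (is.null(ratio)) ratio <- setNames(rep(1, K), names(species))
  if (is.null(names(ratio))) names(ratio) <- names(species)
  if (!setequal(names(ratio), names(species))) {
    abort("`inoculum_ratio` names must match the species.",
          class = "comonod_config_error")
  }
  ratio <- ratio[names(species)]
  X_total * ratio / sum(ratio)
}

#' Biomass fraction time series
#'
#' Per-species biomass-concentration fractions along a multi-species
#' trajectory. Fractions are computed on g/L biomass — the model's state —
#' not on cell counts, so comparisons with flow-cytometry event fractions
#' are qualitative (cell mass differs ~50x between yeast and bacteria).
#' Where total biomass is at or below `1e-9` g/L the fraction is undefined
#' and flagged.
#'
#' @param traj A `reactor_trajectory` with at least two species.
#' @return A tibble with columns `t`, `species`, `fraction`, `defined`.
#' @export
biomass_fractions <- function(traj) {
  sp <- traj_attr(traj, "species")
  if (length(sp) < 2) {
    abort("Fractions need a trajectory with at least two species.",
          class = "comonod_config_error")
  }
  X <- as.matrix(traj[paste0("X_", sp)])
  total <- rowSums(X)
  defined <- total > 1e-9
  frac <- X / ifelse(defined, total, NA_real_)
  tibble::tibble(
    t = rep(traj$t, times = length(sp)),
    species = rep(sp, each = nrow(traj)),
    fraction = as.vector(frac),
    defined = rep(defined, times = length(sp))
  )
}

#' Reduction of the maximal batch growth rate between glucose charges
#'
#' Runs two batch simulations at a high and a low initial glucose
#' concentration and reports `100 * (1 - max mu_lo / max mu_hi)`, the
#' percentage by which the maximum instantaneous specific growth rate drops
#' at the lower charge. The maximum is taken over the reporting grid after a
#' burn-in (default 0.5 h) that skips the enzyme-initialisation transient.
#'
#' @param species A single [species_model()].
#' @param S0_hi,S0_lo High and low initial glucose, g/L (`S0_hi > S0_lo > 0`).
#' @param X0 Inoculum, g/L.
#' @param t_end Batch duration, h.
#' @param burn_in Burn-in excluded from the maximum, h.
#' @param ... Passed to [run_batch()].
#' @return Percentage reduction (a single number).
#' @export
growth_rate_reduction <- function(species, S0_hi = 20, S0_lo = 1.25,
                                  X0 = 0.05, t_end = 30, burn_in = 0.5, ...) {
  if (!(S0_hi > S0_lo && S0_lo > 0)) {
    abort("Need S0_hi > S0_lo > 0.", class = "comonod_config_error")
  }
  species <- as_species_list(species)
  if (length(species) != 1) {
    abort("`growth_rate_reduction` is a mono-culture diagnostic.",
          class = "comonod_config_error")
  }
  peak <- function(S0) {
    traj <- run_batch(species, S0 = S0, X0 = X0, t_end = t_end, ...)
    mu <- traj[[paste0("mu_", names(species))]][traj$t >= burn_in]
    max(mu)
  }
  hi <- peak(S0_hi)
  lo <- peak(S0_lo)
  if (hi <= 0) {
    abort("No growth in the high-substrate run.", class = "comonod_numeric_error")
  }
  100 * (1 - lo / hi)
}
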