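#' Monod saturation fraction
#'
#' The dimensionless Monod (hyperbolic) factor `S / (K + S)` that scales a
#' pathway's uptake rate down at low substrate concentration. At `S = K` the
#' fraction is exactly 0.5, which is why `K` is called the half-saturation
#' constant.
#'
#' @param S Substrate concentration, g/L. Vectorised; must be non-negative.
#' @param K Half-saturation constant, g/L. Must be strictly positive.
#'
#' @return Numeric vector in `[0, 1)`, strictly increasing in `S`.
#' @examples
#' monod_fraction(0.112, 0.112) # 0.5 at the half-saturation point
#' monod_fraction(c(0, 1, 1e6), 1)
#' @export
monod_fraction <- function(S, K) {
  if (any(!is.finite(S)) || any(S < 0)) {
    abort("`S` must be finite and non-negative.", class = "comonod_domain_error")
  }
  if (any(!is.finite(K)) || any(K <= 0)) {
    abort("`K` must be finite and strictly positive.", class = "comonod_domain_error")
  }
  S / (K + S)
}

#' Potential growth returns of each pathway
#'
#' The specific growth rate each pathway would deliver at the current
#' substrate pool and enzyme state, `mu_i = Yx_i * q_max_i * psi_rel_i * H_i`,
#' with `H_i` the Monod fraction of the pathway's own substrate. These are the
#' *un-gated* returns fed to the matching law: the activity weight `v` is not
#' applied here, so the allocation compares what each pathway could yield.
#'
#' @param M Named numeric vector of metabolite concentrations, g/L; names must
#'   cover the species' metabolite list.
#' @param psi_rel Numeric vector of relative key-enzyme levels, one per
#'   pathway, in `[0, 1]`.
#' @param species A [species_model()].
#'
#' @return Named numeric vector of growth returns, h^-1, one per pathway.
#' @examples
#' sp <- ecoli_k12()
#' pathway_growth_returns(c(GLU = 20, ACE = 0, ETH = 0),
#'                        rep(1, nrow(sp$pathways)), sp)
#' @export
pathway_growth_returns <- function(M, psi_rel, species) {
  stopifnot(is_species_model(species))
  pw <- species$pathways
  if (!all(species$metabolites %in% names(M))) {
    abort("`M` must be named and cover all species metabolites.",
          class = "comonod_config_error")
  }
  if (length(psi_rel) != nrow(pw)) {
    abort("`psi_rel` must have one entry per pathway.", class = "comonod_config_error")
  }
  if (any(M[species$metabolites] < 0)) {
    abort("Metabolite concentrations must be non-negative.", class = "comonod_domain_error")
  }
  S <- unname(M[pw$substrate])
  mu <- pw$Yx * pw$q_max * psi_rel * monod_fraction(S, pw$Ks)
  setNames(mu, pw$id)
}

#' Cybernetic matching-law weights
#'
#' Allocation weights `u_i = mu_i / sum(mu)` (how synthesis capacity for key
#' enzymes is divided among pathways) and activity weights
#' `v_i = mu_i / max(mu)` (how strongly each pathway's uptake machinery is
#' engaged), computed against the growth-rate objective. When every return is
#' zero (below `1e-12` total) the allocation is declared degenerate: `u` is
#' uniform and `v` is all ones. This convention is harmless because the Monod
#' factors already null all fluxes there, and it keeps constitutive enzyme
#' synthesis spread across pathways so that re-induction remains possible.
#'
#' @param mu Numeric vector of non-negative growth returns, h^-1.
#'
#' @return A list with components `u` and `v` (numeric vectors, same names as
#'   `mu`); `sum(u) == 1` and `max(v) == 1` always.
#' @examples
#' cybernetic_weights(c(0.3, 0.1))
#' cybernetic_weights(c(0, 0, 0)) # degenerate convention
#' @export
cybernetic_weights <- function(mu) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    abort("`mu` must be finite and non-negative.", class = "comonod_domain_error")
  }
  total <- sum(mu)
  if (total <= 1e-12) {
    n <- length(mu)
    return(list(u = setNames(rep(1 / n, n), names(mu)),
                v = setNames(rep(1, n), names(mu))))
  }
  list(u = mu / total, v = mu / max(mu))
}

# Maximum attainable key-enzyme level: synthesis at full allocation balanced
# against degradation plus dilution at the pathway's own maximal growth rate.
psi_max <- function(pw) (pw$eps_c + pw$eps_i) / (pw$delta + pw$mu_max)

#' Key-enzyme dynamics in relative form
#'
#' Time derivative of the relative key-enzyme level of each pathway,
#' `d psi_i/dt = (eps_c_i + u_i * eps_i_i * H_ind_i) / Psi_max_i
#'               - (delta_i + mu_total) * psi_i`,
#' where `H_ind_i` is the Monod induction factor of the pathway's substrate
#' (constant `K_ind`), `u_i` the matching-law allocation weight, and
#' `Psi_max_i = (eps_c_i + eps_i_i) / (delta_i + mu_max_i)` the maximal
#' enzyme level attainable at full allocation. The enzyme is treated as an
#' intensive (per-biomass) quantity; set `scaled_by_biomass = TRUE` to make
#' the inducible synthesis term proportional to the biomass concentration
#' instead (the literal extensive reading of the synthesis rate).
#'
#' By construction the derivative vanishes at `psi = 1` under full allocation,
#' saturating substrate and `mu_total = mu_max`, which keeps `psi_rel` inside
#' `[0, 1]` along trajectories whenever `eps_c * mu_max <= eps_i * delta`
#' (amply satisfied by the packaged defaults).
#'
#' @param psi_rel Relative enzyme levels, one per pathway.
#' @param M Named metabolite vector, g/L.
#' @param mu_total Realised total specific growth rate of the species, h^-1
#'   (dilutes the enzyme pool as the cell grows).
#' @param u Allocation weights from [cybernetic_weights()].
#' @param species A [species_model()].
#' @param scaled_by_biomass Logical; use the extensive synthesis form.
#' @param X Biomass concentration, g/L; only used when
#'   `scaled_by_biomass = TRUE`.
#'
#' @return Named numeric vector `d psi_rel / dt`, h^-1.
#' @export
enzyme_odes <- function(psi_rel, M, mu_total, u, species,
                        scaled_by_biomass = FALSE, X = 1) {
  stopifnot(is_species_model(species), mu_total >= 0)
  pw <- species$pathways
  S <- pmax(unname(M[pw$substrate]), 0)
  H_ind <- S / (pw$K_ind + S)
  inducible <- u * pw$eps_i * H_ind
  if (scaled_by_biomass) inducible <- inducible * X
  synth <- (pw$eps_c + inducible) / (pw$eps_c + pw$eps_i) * (pw$delta + pw$mu_max)
  setNames(synth - (pw$delta + mu_total) * psi_rel, pw$id)
}

#' Stoichiometric flux assembly
#'
#' Rates of change of biomass and metabolite pool contributed by one species:
#' the stoichiometric matrix applied to the per-pathway uptake rates
#' `rate_i = v_i * q_max_i * psi_rel_i * H_i * X` (g substrate/L/h). The own
#' substrate row carries -1 per column, so substrate contributions are
#' non-positive; biomass and byproduct rows carry the yields.
#'
#' @param M Named metabolite vector, g/L.
#' @param psi_rel Relative enzyme levels per pathway.
#' @param v Activity weights per pathway.
#' @param X Biomass concentration of the species, g/L.
#' @param species A [species_model()].
#'
#' @return Named numeric vector of rates, g/L/h, over `c("X", metabolites)`.
#' @examples
#' sp <- ecoli_k12()
#' species_flux(c(GLU = 20, ACE = 0, ETH = 0),
#'              rep(1, nrow(sp$pathways)), rep(1, nrow(sp$pathways)),
#'              X = 0.5, sp)
#' @export
species_flux <- function(M, psi_rel, v, X, species) {
  stopifnot(is_species_model(species), X >= 0)
  pw <- species$pathways
  if (!all(species$metabolites %in% names(M))) {
    abort("`M` must cover all species metabolites.", class = "comonod_config_error")
  }
  S <- pmax(unname(M[pw$substrate]), 0)
  rate <- v * pw$q_max * psi_rel * monod_fraction(pmax(S, 0), pw$Ks) * X
  drop(species$psi %*% rate)
}
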