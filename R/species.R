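#' Define one substrate-assimilation pathway
#'
#' A pathway bundles the Monod kinetics, yields and key-enzyme dynamics
#' constants for the assimilation of a single substrate by one species.
#' Consumption magnitudes are stored positive: if `q_max` is supplied negative
#' (the usual sign convention in parameter tables, where consumption rates
#' print as negative) its absolute value is taken and the sign is carried by
#' the stoichiometric matrix instead.
#'
#' @param id Short pathway label, e.g. `"GLU_ferm"`.
#' @param substrate Metabolite consumed, one of the species' metabolite list.
#' @param mu_max Maximal specific growth rate through this pathway, h^-1.
#' @param Ks Monod half-saturation constant, g/L (> 0).
#' @param q_max Maximal specific substrate consumption rate magnitude,
#'   g substrate / g biomass / h. Negative input is interpreted as a printed
#'   consumption rate and converted to its magnitude.
#' @param Yx Biomass yield, g biomass / g substrate.
#' @param Yp Named numeric vector of byproduct yields, g product / g
#'   substrate (e.g. `c(ACE = 0.835)`); may be empty.
#' @param eps_c,eps_i Constitutive and inducible key-enzyme synthesis rates,
#'   enzyme units / h. Only their ratio matters for the relative enzyme
#'   dynamics; defaults 0.01 and 1.
#' @param K_ind Induction half-saturation constant, g/L; defaults to `Ks`.
#' @param delta Key-enzyme degradation rate, h^-1; default 0.05.
#'
#' @return A one-row tibble describing the pathway.
#' @seealso [species_model()]
#' @export
pathway <- function(id, substrate, mu_max, Ks, q_max, Yx, Yp = NULL,
                    eps_c = 0.01, eps_i = 1, K_ind = Ks, delta = 0.05) {
  if (q_max < 0) q_max <- abs(q_max)
  Yp <- if (is.null(Yp) || length(Yp) == 0) {
    setNames(numeric(0), character(0))
  } else {
    if (is.null(names(Yp)) || any(!nzchar(names(Yp)))) {
      abort("`Yp` must be a named numeric vector of byproduct yields.",
            class = "comonod_config_error")
    }
    unlist(Yp)
  }
  tibble::tibble(
    id = as.character(id), substrate = as.character(substrate),
    mu_max = as.numeric(mu_max), Ks = as.numeric(Ks),
    q_max = as.numeric(q_max), Yx = as.numeric(Yx),
    Yp = list(Yp),
    eps_c = as.numeric(eps_c), eps_i = as.numeric(eps_i),
    K_ind = as.numeric(K_ind), delta = as.numeric(delta)
  )
}

#' Assemble a species model
#'
#' A named organism defined by its metabolite list and its set of
#' substrate-assimilation pathways. The stoichiometric matrix `psi` is derived
#' on construction: one column per pathway with `+Yx` on the biomass row, `-1`
#' on the pathway's own substrate row and `+Yp` on byproduct rows, all in
#' g per g substrate consumed, so metabolite dynamics are a clean matrix
#' product of `psi` with the per-pathway uptake rates.
#'
#' @param name Species name (used to label trajectory columns).
#' @param pathways A list of [pathway()] rows (or a tibble binding them).
#' @param metabolites Ordered character vector of pool names shared with the
#'   reactor; default `c("GLU", "ACE", "ETH")`.
#'
#' @return An object of class `species_model`: a list with `name`,
#'   `metabolites`, `pathways` (tibble) and `psi` (stoichiometric matrix with
#'   rows `c("X", metabolites)`).
#' @examples
#' mono <- species_model("mono", list(
#'   pathway("GLU", "GLU", mu_max = 0.4, Ks = 0.1, q_max = 2.0, Yx = 0.2)
#' ))
#' mono$psi
#' @export
species_model <- function(name, pathways, metabolites = c("GLU", "ACE", "ETH")) {
  pw <- if (inherits(pathways, "data.frame")) tibble::as_tibble(pathways)
        else dplyr::bind_rows(pathways)
  sp <- structure(
    list(name = as.character(name), metabolites = as.character(metabolites),
         pathways = pw, psi = NULL),
    class = "species_model"
  )
  sp$psi <- build_psi(sp)
  validate_species(sp)
  sp
}

#' @export
is_species_model <- function(x) inherits(x, "species_model")

build_psi <- function(sp) {
  pw <- sp$pathways
  met <- sp$metabolites
  psi <- matrix(0, nrow = 1 + length(met), ncol = nrow(pw),
                dimnames = list(c("X", met), pw$id))
  for (j in seq_len(nrow(pw))) {
    if (!pw$substrate[j] %in% met) {
      abort(sprintf("Pathway '%s': substrate '%s' is not in the metabolite list.",
                    pw$id[j], pw$substrate[j]), class = "comonod_config_error")
    }
    psi["X", j] <- pw$Yx[j]
    psi[pw$substrate[j], j] <- -1
    yp <- pw$Yp[[j]]
    for (m in names(yp)) {
      if (!m %in% met) {
        abort(sprintf("Pathway '%s': byproduct '%s' is not in the metabolite list.",
                      pw$id[j], m), class = "comonod_config_error")
      }
      if (m == pw$substrate[j]) {
        abort(sprintf("Pathway '%s': byproduct cannot be the consumed substrate.",
                      pw$id[j]), class = "comonod_config_error")
      }
      psi[m, j] <- yp[[m]]
    }
  }
  psi
}

# Row-level invariant checks. `consistency_tol` allows for the printed
# precision of parameter tables: growth rates reported with two significant
# digits can disagree with Yx * q_max by up to ~3% from rounding alone.
validate_species <- function(sp, consistency_tol = 0.03) {
  pw <- sp$pathways
  if (nrow(pw) == 0) abort("A species needs at least one pathway.",
                           class = "comonod_config_error")
  if (anyDuplicated(pw$id)) abort("Pathway ids must be unique.",
                                  class = "comonod_config_error")
  problems <- character(0)
  for (j in seq_len(nrow(pw))) {
    row <- pw[j, ]
    chk <- function(ok, msg) {
      if (!ok) problems <<- c(problems, sprintf("pathway '%s': %s", row$id, msg))
    }
    chk(all(c(row$mu_max, row$q_max, row$Yx, row$eps_c, row$eps_i,
              row$K_ind) >= 0), "kinetic constants must be non-negative")
    chk(row$Ks > 0, "Ks must be > 0")
    chk(row$delta > 0, "delta must be > 0")
    if (row$mu_max > 0) {
      rel <- abs(row$mu_max - row$Yx * row$q_max) / row$mu_max
      chk(rel <= consistency_tol,
          sprintf("mu_max inconsistent with Yx*q_max (rel. dev. %.3f)", rel))
    }
    mass <- row$Yx + sum(row$Yp[[1]])
    chk(mass <= 1 + 1e-9,
        sprintf("Yx + sum(Yp) = %.3f exceeds 1 (mass bound)", mass))
  }
  # column structure of psi
  for (j in seq_len(ncol(sp$psi))) {
    col <- sp$psi[-1, j]
    if (sum(col == -1) != 1) {
      problems <- c(problems, sprintf(
        "pathway '%s': psi column must carry exactly one -1 substrate entry",
        colnames(sp$psi)[j]))
    }
  }
  if (length(problems)) {
    abort(paste0("Invalid species model '", sp$name, "':\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "comonod_config_error")
  }
  invisible(sp)
}

#' @export
print.species_model <- function(x, ...) {
  cat("<species_model> ", x$name, "\n", sep = "")
  cat("  metabolites: ", paste(x$metabolites, collapse = ", "), "\n", sep = "")
  pw <- x$pathways
  for (j in seq_len(nrow(pw))) {
    yp <- pw$Yp[[j]]
    cat(sprintf("  %-10s %s  mu_max=%.3f Ks=%.3f q_max=%.3f Yx=%.3f%s\n",
                pw$id[j], pw$substrate[j], pw$mu_max[j], pw$Ks[j],
                pw$q_max[j], pw$Yx[j],
                if (length(yp)) paste0(" Yp[", paste(names(yp), round(yp, 3),
                                                    sep = "=", collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

# Resting-cell constitutive steady state of the relative enzyme level:
# synthesis eps_c only, no growth dilution.
resting_psi_rel <- function(sp) {
  pw <- sp$pathways
  setNames((pw$eps_c / pw$delta) / psi_max(pw), pw$id)
}
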