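#' Read a species parameter file
#'
#' Loads a species definition from a structured text (YAML) file with nested
#' pathway blocks and validates every model invariant, reporting violations
#' with the offending pathway and field. Negative `q_max` entries (the printed
#' sign convention for consumption rates) are converted to magnitudes with a
#' note. Unknown keys are errors, not warnings, because pathway and metabolite
#' names key the stoichiometry.
#'
#' @param path Path to the species file.
#' @param quiet Suppress the sign-conversion note.
#'
#' @return A validated [species_model()].
#' @seealso [ecoli_k12()], [scerevisiae_cenpk()], [write_species()]
#' @export
load_species <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Species file not found: '%s'", path), class = "comonod_io_error")
  }
  raw <- yaml::read_yaml(path)
  allowed <- c("name", "metabolites", "enzyme_defaults", "pathways")
  check_keys(raw, allowed, sprintf("species file '%s'", basename(path)))
  for (k in c("name", "pathways")) {
    if (is.null(raw[[k]])) {
      abort(sprintf("Species file '%s' is missing the '%s' block.",
                    basename(path), k), class = "comonod_io_error")
    }
  }
  metabolites <- raw$metabolites %||% c("GLU", "ACE", "ETH")
  defaults <- raw$enzyme_defaults %||% list()
  check_keys(defaults, c("eps_c", "eps_i", "delta", "K_ind"),
             "enzyme_defaults block")
  converted <- character(0)
  rows <- purrr::imap(raw$pathways, function(block, id) {
    check_keys(block, c("substrate", "mu_max", "Ks", "q_max", "Yx", "Yp",
                        "eps_c", "eps_i", "K_ind", "delta"),
               sprintf("pathway '%s'", id))
    for (k in c("substrate", "mu_max", "Ks", "q_max", "Yx")) {
      if (is.null(block[[k]])) {
        abort(sprintf("Pathway '%s' is missing required field '%s'.", id, k),
              class = "comonod_io_error")
      }
    }
    if (block$q_max < 0) converted <<- c(converted, id)
    pathway(
      id = id, substrate = block$substrate,
      mu_max = block$mu_max, Ks = block$Ks, q_max = block$q_max,
      Yx = block$Yx, Yp = if (!is.null(block$Yp)) unlist(block$Yp),
      eps_c = block$eps_c %||% defaults$eps_c %||% 0.01,
      eps_i = block$eps_i %||% defaults$eps_i %||% 1,
      K_ind = block$K_ind %||% defaults$K_ind %||% block$Ks,
      delta = block$delta %||% defaults$delta %||% 0.05
    )
  })
  if (length(converted) && !quiet) {
    rlang::inform(sprintf(
      "%s: negative q_max converted to consumption magnitude for pathway(s) %s.",
      basename(path), paste(converted, collapse = ", ")))
  }
  species_model(raw$name, rows, metabolites = metabolites)
}

#' Write a species parameter file
#'
#' Serialises a [species_model()] back to the structured text format read by
#' [load_species()]. `q_max` is written positive (magnitude convention).
#'
#' @param species A [species_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species <- function(species, path) {
  stopifnot(is_species_model(species))
  pw <- species$pathways
  blocks <- setNames(purrr::map(seq_len(nrow(pw)), function(j) {
    b <- list(substrate = pw$substrate[j], mu_max = pw$mu_max[j],
              Ks = pw$Ks[j], q_max = pw$q_max[j], Yx = pw$Yx[j])
    yp <- pw$Yp[[j]]
    if (length(yp)) b$Yp <- as.list(yp)
    c(b, list(eps_c = pw$eps_c[j], eps_i = pw$eps_i[j],
              K_ind = pw$K_ind[j], delta = pw$delta[j]))
  }), pw$id)
  yaml::write_yaml(
    list(name = species$name, metabolites = species$metabolites,
         pathways = blocks),
    path, precision = 15)
  invisible(path)
}

species_file <- function(which) {
  system.file("extdata", "species", which, package = "comonod", mustWork = TRUE)
}

#' Packaged organisms
#'
#' The two organisms shipped with the package, parameterised from
#' mono-culture batch fermentations: *Escherichia coli* K-12 W3110 with three
#' pathways (fermentative and oxidative glucose assimilation, acetate
#' re-assimilation) and *Saccharomyces cerevisiae* CEN.PK 117D with four
#' (additionally ethanol re-assimilation). Fermentative pathways excrete
#' overflow byproducts (acetate for the bacterium; ethanol and acetate for
#' the yeast), which is what makes diauxic cross-feeding possible.
#'
#' @return A validated [species_model()].
#' @examples
#' ecoli_k12()
#' @export
ecoli_k12 <- function() load_species(species_file("ecoli_k12_table1.yml"), quiet = TRUE)

#' @rdname ecoli_k12
#' @export
scerevisiae_cenpk <- function() {
  load_species(species_file("scerevisiae_cenpk_table1.yml"), quiet = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, what) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("Unknown key(s) in %s: %s", what,
                  paste(extra, collapse = ", ")),
          class = "comonod_config_error")
  }
  invisible(x)
}
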