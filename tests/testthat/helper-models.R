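# Small fixture organisms and shared expensive computations.

# Single-pathway Monod organism: the minimal cybernetic system, cheap to
# integrate and analytically tractable (classical Monod when enzymes are
# pinned at 1).
mono_species <- function(name = "mono", mu_max = 0.4, Ks = 0.1, Yx = 0.2,
                         Yp = NULL, ...) {
  species_model(name, list(
    pathway("GLU", "GLU", mu_max = mu_max, Ks = Ks, q_max = mu_max / Yx,
            Yx = Yx, Yp = Yp, ...)
  ))
}

# Two-pathway organism with a byproduct loop (glucose -> acetate -> growth),
# used for diauxie-flavoured unit tests without the full Table-derived pair.
diauxic_species <- function(name = "diaux") {
  species_model(name, list(
    pathway("GLU", "GLU", mu_max = 0.4, Ks = 0.1, q_max = 2.0, Yx = 0.2,
            Yp = c(ACE = 0.8)),
    pathway("ACE", "ACE", mu_max = 0.1, Ks = 0.05, q_max = 0.5, Yx = 0.2)
  ))
}

default_pair <- function() list(ecoli_k12(), scerevisiae_cenpk())

# The default coexistence scan is used by several tests; run it once per
# test session.
.scan_cache <- new.env(parent = emptyenv())
cached_default_scan <- function() {
  if (is.null(.scan_cache$scan)) {
    .scan_cache$scan <- coexistence_scan(default_pair())
  }
  .scan_cache$scan
}

expect_rel_equal <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)),
                      tol)
}
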