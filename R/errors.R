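# Classed error conditions so callers (and the energy minimiser) can react to
# specific failure modes rather than matching on message text.

aggdiff_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "aggdiffenv_error", "error"),
                      call = call))
}

abort_domain     <- function(msg) aggdiff_error(msg, "aggdiffenv_domain_error")
abort_regime     <- function(msg) aggdiff_error(msg, "aggdiffenv_regime_error")
abort_resonance  <- function(msg) aggdiff_error(msg, "aggdiffenv_resonance_error")
abort_candidate  <- function(msg) aggdiff_error(msg, "aggdiffenv_no_candidate_error")
abort_minimiser  <- function(msg) aggdiff_error(msg, "aggdiffenv_no_minimiser_error")
abort_boundary   <- function(msg) aggdiff_error(msg, "aggdiffenv_boundary_leak_error")
abort_instability<- function(msg) aggdiff_error(msg, "aggdiffenv_instability_error")
abort_config     <- function(msg) aggdiff_error(msg, "aggdiffenv_config_error")

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort_config(sprintf("'%s' must be positive", name))
  invisible(x)
}
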