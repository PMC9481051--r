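# Classed conditions shared by all modules. Every user-facing error carries a
# specific class under "phytodisc_error" so callers (and the CLI) can branch.

pd_stop <- function(message, class) {
  stop(structure(
    class = c(class, "phytodisc_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

pd_check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pd_stop(sprintf("`%s` must be a finite numeric scalar", name), "domain_error")
  }
  if (positive && x <= 0) {
    pd_stop(sprintf("`%s` must be > 0 (got %g)", name, x), "domain_error")
  }
  if (nonneg && x < 0) {
    pd_stop(sprintf("`%s` must be >= 0 (got %g)", name, x), "domain_error")
  }
  invisible(x)
}

pd_match_group <- function(group) {
  match.arg(group, c("non_diatom", "diatom"))
}
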