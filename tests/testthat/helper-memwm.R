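# Shared fixtures: all built in code at test time.

table_params <- function(...) memristor_params(...)

# Small network config used by most network-level tests; the package
# defaults are exercised by the behaviour tests.
quick_config <- function(seed = 1, ...) network_config(seed = seed, ...)

# Independent reference for the I-V law, written from the piecewise
# definition rather than via memristor_current().
ref_current <- function(V, x, p) {
  a <- if (V >= 0) p$a1 else p$a2
  a * (1 / p$r + (p$r - 1) * x / p$r) * sinh(p$b * V)
}
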