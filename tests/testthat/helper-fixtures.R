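# Shared fixtures for the test suite.

ref_human <- function() human_parameters()
ref_mouse <- function(arm = "miRNA") mouse_parameters(arm = arm)

# Packed parameter vector with selected entries patched (used to switch
# individual processes off at the right-hand-side level, e.g. for mass
# bookkeeping checks: index 13 = NP clearance, 14 = NP permeability).
patched_parms <- function(ps, regimen, patch = list()) {
  p <- mir22sim:::pack_parms(ps, regimen)
  for (i in names(patch)) p[as.integer(i)] <- patch[[i]]
  p
}

quick_tgi <- function(ps, regimen, ...) simulate_tgi(ps, regimen, ...)$tgi
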