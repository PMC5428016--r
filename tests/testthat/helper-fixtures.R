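# Shared fixtures. The replenishment sweep is the one expensive computation
# (a dozen PDE solves); memoize it so every test file can use the same
# fitted law without re-running the sweep.

.fixture_env <- new.env(parent = emptyenv())

default_replenishment_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- sweep_and_fit_replenishment()
  .fixture_env$fit
}

# reference tissue/trap used throughout: 250 um tissue, 500 um cubic trap
ref_tissue <- function(rho_T = 1010) tissue_sample(250e-6, rho_T = rho_T)
ref_trap <- function() trap_geometry(500e-6, 500e-6)

# brute-force grid-scan oracle for the settling optimum (independent of the
# optimizer path in optimal_trap_ratio)
grid_scan_optimum <- function(step = 1e-4) {
  lam <- seq(0.05, 0.9 - 1e-9, by = step)
  K <- (1 - 0.76 * lam^5) /
    (1 - 2.1 * lam + 2.1 * lam^3 - 1.7 * lam^5 + 0.73 * lam^6)
  lam[which.min(K / lam^2)]
}
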