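# Small fixtures shared across test files. Everything is generated in
# code at coarse resolution so the suite stays fast.

coarse_refs <- function(n = 2L, n_ax = 21L, n_circ = 8L, n_rad = 2L) {
  reference_vessels(n, n_ax = n_ax, n_circ = n_circ, n_rad = n_rad)
}

# a constant-radius reference tube (analytic test cases)
const_ref <- function(r0 = 1.5, n_ax = 21L, length_mm = 30,
                      n_circ = 8L, n_rad = 2L) {
  reference_vessel("C", seq(0, length_mm, length.out = n_ax),
                   rep(r0, n_ax), n_circ = n_circ, n_rad = n_rad)
}

# a small solved ensemble for POD tests
coarse_solutions <- function(n_refs = 2L, n_perturb = 5L, seed = 42L) {
  ds <- generate_dataset(coarse_refs(n_refs), n_perturb, seed = seed)
  list(dataset = ds, solutions = lapply(ds, solve_flow))
}

# fast pipeline configuration for smoke/end-to-end tests
smoke_config <- function(seed = 7L, outdir = NULL) {
  run_config(n_refs = 2L, n_perturb = 10L, n_ax = 21L, n_circ = 8L,
             n_rad = 2L, n_modes = 5L, perplexity = 5, tsne_iter = 250L,
             chain = chain_config(trees = 30L, depth = 10L),
             seed = seed, outdir = outdir)
}
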