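# Independent oracles used across the suite.

# Brute-force count of dimer species between one molecule of form a and one
# of form b: unphosphorylated sites on one member that the other member (a
# distinct molecule) can occupy.
oracle_pair_dimers <- function(a, b) {
  n_sites <- function(f) sum(strsplit(f, "")[[1]] == "U")
  if (a == b) n_sites(a) else n_sites(a) + n_sites(b)
}

# Hand-coded enzyme/substrate/complex/product ODE system for a single
# Michaelis-Menten pair (association kon, dissociation koff, catalysis kcat).
oracle_mm_traj <- function(E0, S0, kon, koff, kcat, times) {
  rhs <- function(t, y, p) {
    b <- kon * y["E"] * y["S"]
    u <- koff * y["C"]
    cat_ <- kcat * y["C"]
    list(c(E = -b + u + cat_, S = -b + u, C = b - u - cat_, P = cat_))
  }
  deSolve::lsoda(c(E = E0, S = S0, C = 0, P = 0), times, rhs, NULL,
                 rtol = 1e-10, atol = 1e-14)
}

# Toy observable/data pair with known hand-computed WSSR values.
toy_sim <- function() data.frame(time_min = c(1, 2), y394 = c(0.4, 0.9),
                                 y505 = c(0.30, 0.45))
toy_data <- function() {
  structure(data.frame(time_min = c(1, 2), y394 = c(0.5, 1.0),
                       y505 = c(0.25, 0.5)),
            class = c("lck_dataset", "data.frame"))
}

# Cheap synthetic campaign pieces reused by selection tests: an ensemble of
# copies of a base parameter set with one row perturbed.
synthetic_ensemble <- function(par_rows, wssr_quant, wssr_hybr = wssr_quant) {
  structure(list(params = par_rows, wssr_quant = wssr_quant,
                 wssr_hybr = wssr_hybr,
                 provenance = data.frame(
                   global_run = seq_len(nrow(par_rows)),
                   refinement = 1, seed = seq_len(nrow(par_rows))),
                 free = param_names(), config = NULL),
            class = "lck_ensemble")
}
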