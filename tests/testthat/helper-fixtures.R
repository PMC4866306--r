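# Shared fixtures, built in code and cached for the session.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# small full diallel with the default correlated 9-trait architecture scaled
# down: 10x10 parents, 4 chromosomes
small_diallel <- function() {
  cached("small_diallel", simulate_diallel(
    n_a = 10, n_alpha = 10, n_chrom = 4, sites_per_chrom = 20,
    n_traits = 3, n_qtl = 8, pool_size = 16, seed = 101))
}

# a manual single-trait architecture: one causal site, explicit noise
monogenic_arch <- function(site, beta = 1, resid_sd = 0, rep_sd = 0) {
  trait_architecture(list(list(
    trait = "mono",
    additive = tibble::tibble(site_id = site, beta = beta),
    resid_sd = resid_sd, rep_sd = rep_sd)))
}

# dense MVN conditioning oracle: returns conditional mean and marginal
# conditional SDs of the unknown entries given the observed ones
mvn_condition_oracle <- function(mu, V, obs_idx, unk_idx, y_obs) {
  Voo <- V[obs_idx, obs_idx, drop = FALSE]
  Vuo <- V[unk_idx, obs_idx, drop = FALSE]
  cm <- mu[unk_idx] + as.vector(Vuo %*% solve(Voo, y_obs - mu[obs_idx]))
  cv <- V[unk_idx, unk_idx, drop = FALSE] - Vuo %*% solve(Voo, t(Vuo))
  list(mean = unname(cm), sd = unname(sqrt(pmax(diag(cv), 0))))
}
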