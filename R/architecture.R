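# Trait architectures: the generative ground truth used by the simulator and
# by parameter-recovery tests.

#' Construct a trait architecture
#'
#' A trait architecture holds, for each simulated trait, the generative
#' effects: sparse additive effects per site, dominance effects applied to the
#' heterozygote indicator `1{dosage == 1}`, epistatic coefficients for site
#' pairs, a loading on a latent per-individual factor shared across traits
#' (inducing cross-trait covariance that is stable over replicates but not
#' additively heritable), a stable per-individual residual standard deviation
#' and a per-replicate measurement noise standard deviation.
#'
#' Dominance acts on the heterozygote indicator, deliberately different from
#' the squared-dosage encoding the prediction models use for self-interaction
#' terms, so that recovery tests are not circular.
#'
#' @param traits A list, one element per trait, each a list with components
#'   `trait` (name), `additive` (tibble with `site_id`, `beta`), `dominance`
#'   (tibble with `site_id`, `delta`), `epistasis` (tibble with `site_a`,
#'   `site_b`, `gamma`), `shared_loading`, `resid_sd`, `rep_sd`.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(traits) {
  if (!is.list(traits) || length(traits) < 1L) {
    abort_arg("`traits` must be a non-empty list of trait definitions")
  }
  traits <- lapply(seq_along(traits), function(i) {
    tr <- traits[[i]]
    tr$trait <- tr$trait %||% paste0("trait", i)
    tr$additive <- as_tibble(tr$additive %||%
      tibble(site_id = character(), beta = numeric()))
    tr$dominance <- as_tibble(tr$dominance %||%
      tibble(site_id = character(), delta = numeric()))
    tr$epistasis <- as_tibble(tr$epistasis %||%
      tibble(site_a = character(), site_b = character(), gamma = numeric()))
    tr$shared_loading <- tr$shared_loading %||% 0
    for (fld in c("resid_sd", "rep_sd")) {
      if (!is.null(tr[[fld]]) && !is.na(tr[[fld]]) && tr[[fld]] < 0) {
        abort_arg(sprintf("noise sd `%s` must be >= 0 (trait %s)", fld, tr$trait))
      }
    }
    tr$resid_sd <- tr$resid_sd %||% NA_real_
    tr$rep_sd <- tr$rep_sd %||% NA_real_
    tr
  })
  names(traits) <- vapply(traits, `[[`, character(1), "trait")
  if (anyDuplicated(names(traits))) abort_arg("trait names must be unique")
  structure(list(traits = traits), class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture: %d traits>\n", length(x$traits)))
  for (tr in x$traits) {
    cat(sprintf(
      "  %s: %d additive, %d dominance, %d epistatic; loading %.3g; resid_sd %.3g; rep_sd %.3g\n",
      tr$trait, nrow(tr$additive), nrow(tr$dominance), nrow(tr$epistasis),
      tr$shared_loading, tr$resid_sd, tr$rep_sd))
  }
  invisible(x)
}

#' Draw a random multi-trait architecture
#'
#' Samples a correlated multi-trait architecture emulating a densely phenotyped
#' hybrid panel: each trait receives `n_qtl` additive sites drawn from a common
#' pool, with per-trait effects mixing a pool-wide effect vector (weight
#' `rho`, drawn per trait from `cor_range`) with idiosyncratic effects — the
#' shared sites and shared effects induce the spread of pairwise trait
#' correlations seen in multi-environment growth panels. Effect sizes decay
#' geometrically so that a few loci dominate; the strongest loci also receive
#' dominance, a small number of site pairs receive epistatic coefficients, and
#' every trait loads on one latent non-additive factor shared across traits.
#' Effects are drawn on a nominal scale; [calibrate_architecture()] rescales
#' the non-additive parts and solves for the noise standard deviations so that
#' each trait realizes the requested narrow-sense heritability and
#' repeatability on a given genotype matrix.
#'
#' @param map A site map (see [simulate_genetic_map()]).
#' @param n_traits Number of traits (default 9).
#' @param n_qtl Additive causal sites per trait; a vector is recycled across
#'   traits. The default mixes two near-monogenic traits (3 loci) with
#'   polygenic ones (25 loci), as in multi-environment growth panels where a
#'   couple of environments are dominated by single large-effect loci.
#' @param pool_size Size of the shared causal-site pool.
#' @param h2 Target narrow-sense heritability of the replicate-mean phenotype.
#' @param H2 Target repeatability (broad-sense heritability) of the mean.
#' @param dom_frac,epi_frac,shared_frac Fractions of the stable
#'   between-individual variance assigned to dominance, epistasis and the
#'   shared latent factor for polygenic traits. The additive fraction is
#'   `h2 / H2`; the remainder is stable individual residual. Their sum must
#'   leave that remainder >= 0.
#' @param mono_dom_frac,mono_shared_frac Dominance and shared-factor fractions
#'   for near-monogenic traits (fewer than 10 loci), whose non-additive
#'   variance sits mostly in dominance at the major loci rather than in the
#'   shared component.
#' @param n_epi_pairs Epistatic pairs per trait.
#' @param effect_decay Geometric decay rate of additive effect-size standard
#'   deviations across a trait's loci.
#' @param cor_range Range of the per-trait mixing weight on the shared pool
#'   effects; higher values give stronger genetic correlation between traits.
#' @param seed Integer seed.
#' @return An uncalibrated `trait_architecture` carrying the variance-share
#'   targets; pass through [calibrate_architecture()] before simulating.
#' @export
sample_architecture <- function(map, n_traits = 9, n_qtl = NULL, pool_size = 30,
                                h2 = 0.80, H2 = 0.94,
                                dom_frac = 0.02, epi_frac = 0.015,
                                shared_frac = 0.10,
                                mono_dom_frac = 0.10, mono_shared_frac = 0.04,
                                n_epi_pairs = 2,
                                effect_decay = 0.85, cor_range = c(0.4, 0.95),
                                seed = 1) {
  stopifnot(h2 > 0, H2 >= h2, H2 <= 1)
  add_frac <- h2 / H2
  if (add_frac + max(dom_frac + epi_frac + shared_frac,
                     mono_dom_frac + mono_shared_frac) > 1 + 1e-12) {
    abort_arg("variance fractions exceed 1: lower dom/epi/shared fractions")
  }
  pool_size <- min(pool_size, nrow(map))
  if (is.null(n_qtl)) {
    n_qtl <- if (n_traits >= 3) c(3L, 3L, rep(25L, n_traits - 2)) else 25L
  }
  n_qtl <- pmin(rep_len(as.integer(n_qtl), n_traits), pool_size)
  with_seed(derive_seed(seed, "architecture"), {
    pool <- sample(map$site_id, pool_size)
    pool_beta <- rnorm(pool_size) * sqrt(effect_decay^(seq_len(pool_size) - 1))
    traits <- lapply(seq_len(n_traits), function(t) {
      n_qtl <- n_qtl[t]
      mono <- n_qtl < 10
      if (mono) {
        # near-monogenic traits carry their own major loci (outside the
        # shared pool) with strong dominance, like single-pathway growth
        # traits
        sites <- sample(setdiff(map$site_id, pool), n_qtl)
        beta <- rnorm(n_qtl) * sqrt(effect_decay^(seq_len(n_qtl) - 1))
        dom_frac <- mono_dom_frac; shared_frac <- mono_shared_frac
        epi_frac <- 0
      } else {
        take <- sample(seq_len(pool_size), n_qtl)
        sites <- pool[take]
        rho <- runif(1, cor_range[1], cor_range[2])
        own <- rnorm(n_qtl) * sqrt(effect_decay^(seq_len(n_qtl) - 1))
        beta <- sqrt(rho) * pool_beta[take] + sqrt(1 - rho) * own
      }
      ord <- order(abs(beta), decreasing = TRUE)
      sites <- sites[ord]; beta <- beta[ord]
      n_dom <- if (dom_frac > 0) min(2L, n_qtl) else 0L
      dominance <- tibble(
        site_id = sites[seq_len(n_dom)],
        delta = abs(beta[seq_len(n_dom)]) * sample(c(-1, 1), n_dom, TRUE))
      n_ep <- if (epi_frac > 0) min(n_epi_pairs, floor(n_qtl / 2)) else 0L
      epistasis <- tibble(
        site_a = sites[seq_len(max(n_ep, 0))],
        site_b = sites[n_qtl + 1 - seq_len(max(n_ep, 0))],
        gamma = rnorm(n_ep))
      list(trait = paste0("trait", t),
           additive = tibble(site_id = sites, beta = beta),
           dominance = dominance,
           epistasis = epistasis,
           shared_loading = sample(c(-1, 1), 1, prob = c(0.2, 0.8)),
           resid_sd = NA_real_, rep_sd = NA_real_,
           targets = list(h2 = h2, H2 = H2, dom_frac = dom_frac,
                          epi_frac = epi_frac, shared_frac = shared_frac))
    })
    trait_architecture(traits)
  })
}

# genetic component values for one trait on a dosage matrix
trait_components <- function(tr, G) {
  n <- nrow(G)
  add <- rep(0, n); dom <- rep(0, n); epi <- rep(0, n)
  check_sites <- function(ids) {
    bad <- setdiff(ids, colnames(G))
    if (length(bad)) {
      abort_consistency(sprintf(
        "architecture for %s references unknown sites: %s",
        tr$trait, paste(head(bad, 3), collapse = ", ")))
    }
  }
  if (nrow(tr$additive)) {
    check_sites(tr$additive$site_id)
    add <- as.vector(G[, tr$additive$site_id, drop = FALSE] %*% tr$additive$beta)
  }
  if (nrow(tr$dominance)) {
    check_sites(tr$dominance$site_id)
    H <- (G[, tr$dominance$site_id, drop = FALSE] == 1) + 0
    dom <- as.vector(H %*% tr$dominance$delta)
  }
  if (nrow(tr$epistasis)) {
    check_sites(c(tr$epistasis$site_a, tr$epistasis$site_b))
    for (k in seq_len(nrow(tr$epistasis))) {
      epi <- epi + tr$epistasis$gamma[k] *
        G[, tr$epistasis$site_a[k]] * G[, tr$epistasis$site_b[k]]
    }
  }
  list(additive = add, dominance = dom, epistasis = epi)
}

#' Calibrate an architecture to target heritabilities on a genotype matrix
#'
#' Rescales each trait's dominance, epistatic and shared-factor contributions
#' to their target fractions of stable between-individual variance and solves
#' for the stable residual and replicate noise standard deviations so that the
#' replicate-mean phenotype realizes the trait's target narrow-sense
#' heritability `h2` (additive variance fraction) and repeatability `H2`
#' (stable variance fraction). With `V_a` the realized additive variance, total
#' stable variance is `S = V_a * H2 / h2` and the replicate noise variance is
#' `n_rep * S * (1 - H2) / H2`.
#'
#' @param arch A `trait_architecture` from [sample_architecture()] (or manual,
#'   with `targets` set per trait).
#' @param G Dosage matrix (individuals x sites, values 0/1/2) used to measure
#'   realized variances.
#' @param n_rep Number of replicate measurements the phenotypes will have.
#' @return The calibrated `trait_architecture`, with a `realized` tibble
#'   attached (`trait`, `h2`, `H2`, `H2_single`, variance components).
#' @export
calibrate_architecture <- function(arch, G, n_rep = 4) {
  stopifnot(inherits(arch, "trait_architecture"))
  assert_scalar_count(n_rep, "n_rep")
  realized <- list()
  arch$traits <- lapply(arch$traits, function(tr) {
    tg <- tr$targets
    if (is.null(tg)) {
      abort_arg(sprintf("trait %s has no calibration targets", tr$trait))
    }
    comp <- trait_components(tr, G)
    v_a <- pvar(comp$additive)
    if (v_a <= 0) abort_arg(sprintf("trait %s has zero additive variance", tr$trait))
    s_tot <- v_a * tg$H2 / tg$h2
    # scale each non-additive component so that it adds exactly its share of
    # the stable variance on top of the current genetic value, accounting for
    # covariance with it (dominance sits at the strongest additive loci):
    # solve f^2 var(x) + 2 f cov(base, x) = share * S for f >= 0
    add_component <- function(base, x, share) {
      vx <- pvar(x - mean(x))
      if (share <= 0 || vx <= 0) return(list(f = 0, base = base))
      cv <- mean((base - mean(base)) * (x - mean(x)))
      f <- (-cv + sqrt(cv^2 + vx * share * s_tot)) / vx
      list(f = f, base = base + f * x)
    }
    dm <- add_component(comp$additive, comp$dominance, tg$dom_frac)
    ep <- add_component(dm$base, comp$epistasis, tg$epi_frac)
    tr$dominance$delta <- tr$dominance$delta * dm$f
    tr$epistasis$gamma <- tr$epistasis$gamma * ep$f
    tr$shared_loading <- sign(tr$shared_loading) * sqrt(s_tot * tg$shared_frac)
    resid_var <- s_tot - pvar(ep$base) - tr$shared_loading^2
    if (resid_var < -1e-8 * s_tot) {
      abort_arg(sprintf(
        "trait %s: non-additive variance exceeds the stable budget; lower dom/epi/shared fractions",
        tr$trait))
    }
    tr$resid_sd <- sqrt(max(resid_var, 0))
    rep_var <- n_rep * s_tot * (1 - tg$H2) / tg$H2
    tr$rep_sd <- sqrt(rep_var)
    p_mean <- s_tot + rep_var / n_rep
    realized[[tr$trait]] <<- tibble(
      trait = tr$trait, h2 = v_a / p_mean, H2 = s_tot / p_mean,
      H2_single = s_tot / (s_tot + rep_var),
      v_additive = v_a, v_stable = s_tot, v_rep = rep_var)
    tr
  })
  attr(arch, "realized") <- bind_rows(realized)
  attr(arch, "n_rep") <- n_rep
  arch
}

#' Realized heritabilities of a calibrated architecture
#'
#' @param arch A calibrated `trait_architecture`.
#' @return Tibble with per-trait realized `h2`, `H2`, `H2_single` and variance
#'   components.
#' @export
realized_heritability <- function(arch) {
  out <- attr(arch, "realized")
  if (is.null(out)) abort_arg("architecture has not been calibrated")
  out
}
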