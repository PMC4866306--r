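# Synthetic diallel populations: genetic map, recombinant haploid panels,
# all-against-all mating, founder filtering and phenotype simulation.

#' Simulate a genetic map
#'
#' Places `sites_per_chrom` segregating sites uniformly at random on each of
#' `n_chrom` chromosomes of genetic length `chrom_length_cM`, sorted by
#' position. All sites are biallelic and segregating by construction (two
#' founder alleles at ~50% frequency in the derived panels).
#'
#' @param n_chrom Number of chromosomes (the emulated design uses 16).
#' @param sites_per_chrom Segregating sites per chromosome.
#' @param chrom_length_cM Genetic length of each chromosome in centimorgans.
#' @param seed Integer seed; identical seeds give identical maps.
#' @return A tibble with columns `site_id`, `chrom`, `pos_cM`, positions
#'   strictly increasing within each chromosome.
#' @export
simulate_genetic_map <- function(n_chrom = 16, sites_per_chrom = 50,
                                 chrom_length_cM = 100, seed = 1) {
  assert_scalar_count(n_chrom, "n_chrom")
  assert_scalar_count(sites_per_chrom, "sites_per_chrom")
  if (!is.numeric(chrom_length_cM) || chrom_length_cM <= 0) {
    abort_arg("`chrom_length_cM` must be > 0")
  }
  with_seed(derive_seed(seed, "map"), {
    map <- purrr::map(seq_len(n_chrom), function(ch) {
      pos <- sort(runif(sites_per_chrom, 0, chrom_length_cM))
      # enforce strict increase in the (measure-zero) event of ties
      while (anyDuplicated(pos)) pos <- sort(runif(sites_per_chrom, 0, chrom_length_cM))
      tibble(chrom = ch, pos_cM = pos)
    }) |> bind_rows()
    map |>
      mutate(site_id = sprintf("s%02d_%03d", .data$chrom,
                               ave(.data$chrom, .data$chrom, FUN = seq_along))) |>
      select("site_id", "chrom", "pos_cM")
  })
}

# one haploid founder mosaic over one chromosome's site positions:
# random founder phase at the left end, origin alternating at each crossover
# of a Poisson process with n_meioses-fold expanded map
mosaic_chromosome <- function(pos, chrom_length_cM, n_meioses) {
  n_xo <- rpois(1, n_meioses * chrom_length_cM / 100)
  phase <- rbinom(1, 1, 0.5)
  if (n_xo == 0) return(rep(phase, length(pos)))
  breaks <- sort(runif(n_xo, 0, chrom_length_cM))
  (phase + findInterval(pos, breaks)) %% 2
}

#' Simulate two panels of recombinant haploid segregants
#'
#' Each segregant genome is a mosaic of the two founder haplotypes (allele 0 =
#' first founder, 1 = second founder). Advanced-intercross (F12-style)
#' recombination is emulated marginally: each chromosome receives Poisson
#' crossovers at `n_meioses` times the base map rate (one expected crossover
#' per 100 cM per round), founder origin alternating at each breakpoint from a
#' random starting phase. Segregants are mutually independent, and every site
#' has allele frequency 1/2 in expectation.
#'
#' @param map Site map from [simulate_genetic_map()].
#' @param n_a,n_alpha Panel sizes for the two mating types (the emulated study
#'   panel is 86 + 86).
#' @param n_meioses Rounds of recombination; 12 emulates an F12 panel.
#' @param seed Integer seed.
#' @return A list of class `haplotype_panel_pair` with binary haplotype
#'   matrices `a` (rows `A01`, ...) and `alpha` (rows `L01`, ...), columns the
#'   map's sites, and the `map` itself.
#' @export
simulate_segregant_panel <- function(map, n_a = 86, n_alpha = 86,
                                     n_meioses = 12, seed = 1) {
  if (!is.data.frame(map) || nrow(map) == 0) abort_arg("`map` must be a non-empty site map")
  assert_scalar_count(n_a, "n_a"); assert_scalar_count(n_alpha, "n_alpha")
  assert_scalar_count(n_meioses, "n_meioses")
  chroms <- split(map, map$chrom)
  lens <- vapply(chroms, function(d) max(d$pos_cM), numeric(1))
  # chromosome genetic length: use the span implied by the map's scale; the
  # crossover process runs over [0, chrom_length], taken as the max position
  # rounded up to the map's nominal length when available
  chrom_len <- attr(map, "chrom_length_cM") %||% max(map$pos_cM)
  one_panel <- function(n, prefix, panel_seed) {
    with_seed(panel_seed, {
      H <- matrix(0L, n, nrow(map),
                  dimnames = list(sprintf("%s%03d", prefix, seq_len(n)), map$site_id))
      for (i in seq_len(n)) {
        H[i, ] <- unlist(lapply(chroms, function(d) {
          mosaic_chromosome(d$pos_cM, chrom_len, n_meioses)
        }), use.names = FALSE)
      }
      H
    })
  }
  structure(list(
    a = one_panel(n_a, "A", derive_seed(seed, "panel", "a")),
    alpha = one_panel(n_alpha, "L", derive_seed(seed, "panel", "alpha")),
    map = map), class = "haplotype_panel_pair")
}

#' Mate two haploid panels in all pairwise combinations
#'
#' Produces one diploid hybrid per ordered (MatA, MatAlpha) parent pair; the
#' hybrid dosage at each site is the sum of the two parental alleles (count of
#' second-founder alleles, 0/1/2).
#'
#' @param panels A `haplotype_panel_pair` from [simulate_segregant_panel()],
#'   or a haplotype matrix for the MatA panel if `panel_alpha` is given.
#' @param panel_alpha Optional MatAlpha haplotype matrix.
#' @return A list with `pedigree` (tibble: `hybrid_id`, `parent_a`,
#'   `parent_alpha`) and `G` (dosage matrix, hybrids x sites).
#' @export
mate_diallel <- function(panels, panel_alpha = NULL) {
  if (inherits(panels, "haplotype_panel_pair")) {
    Ha <- panels$a; Hl <- panels$alpha
  } else {
    Ha <- panels; Hl <- panel_alpha
  }
  if (is.null(Ha) || is.null(Hl) || nrow(Ha) == 0 || nrow(Hl) == 0) {
    abort_arg("both panels must be non-empty")
  }
  if (!identical(colnames(Ha), colnames(Hl))) {
    abort_consistency("panels have mismatched site maps")
  }
  pa <- rownames(Ha) %||% sprintf("A%03d", seq_len(nrow(Ha)))
  pl <- rownames(Hl) %||% sprintf("L%03d", seq_len(nrow(Hl)))
  ped <- expand_grid(parent_a = pa, parent_alpha = pl) |>
    mutate(hybrid_id = paste0(.data$parent_a, "x", .data$parent_alpha)) |>
    select("hybrid_id", "parent_a", "parent_alpha")
  G <- Ha[ped$parent_a, , drop = FALSE] + Hl[ped$parent_alpha, , drop = FALSE]
  rownames(G) <- ped$hybrid_id
  storage.mode(G) <- "integer"
  list(pedigree = ped, G = G)
}

#' Remove hybrids descending from excluded founders
#'
#' Drops every hybrid with any parent in either exclusion list, emulating the
#' removal of contaminated or aneuploid haploid founders from a diallel.
#'
#' @param ped Pedigree tibble.
#' @param G Dosage matrix (rows matching `ped$hybrid_id`), or `NULL`.
#' @param excluded_a,excluded_alpha Character vectors of parent ids to drop.
#' @return A list with the filtered `pedigree` and `G`.
#' @export
remove_founders <- function(ped, G = NULL, excluded_a = character(),
                            excluded_alpha = character()) {
  bad_a <- setdiff(excluded_a, ped$parent_a)
  bad_l <- setdiff(excluded_alpha, ped$parent_alpha)
  if (length(bad_a) || length(bad_l)) {
    abort_arg(sprintf("unknown founder ids in exclusion list: %s",
                      paste(c(bad_a, bad_l), collapse = ", ")))
  }
  keep <- !(ped$parent_a %in% excluded_a | ped$parent_alpha %in% excluded_alpha)
  ped2 <- ped[keep, , drop = FALSE]
  if (!is.null(G)) G <- G[ped2$hybrid_id, , drop = FALSE]
  list(pedigree = ped2, G = G)
}

#' Simulate replicated phenotypes from a trait architecture
#'
#' Each replicate value is the sum of the trait's additive term, dominance term
#' (on the heterozygote indicator), epistatic terms, its loading times a latent
#' per-individual factor shared across traits, a stable per-individual
#' residual, and per-replicate Gaussian noise. The latent factor and stable
#' residual are constant across replicates, so they contribute to repeatability
#' but not to narrow-sense heritability.
#'
#' @param G Dosage matrix (individuals x sites).
#' @param arch A calibrated `trait_architecture`.
#' @param n_rep Replicates per individual and trait (the emulated study uses 4).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A long tibble `(hybrid_id, trait, replicate, value)`.
#' @export
simulate_phenotypes <- function(G, arch, n_rep = 4, seed = 1) {
  stopifnot(inherits(arch, "trait_architecture"))
  assert_scalar_count(n_rep, "n_rep")
  n <- nrow(G); ids <- rownames(G)
  with_seed(derive_seed(seed, "phenotypes"), {
    latent <- rnorm(n)
    purrr::imap(arch$traits, function(tr, name) {
      if (is.na(tr$resid_sd) || is.na(tr$rep_sd)) {
        abort_arg(sprintf("trait %s has unset noise sds; calibrate the architecture first", name))
      }
      comp <- trait_components(tr, G)
      stable <- comp$additive + comp$dominance + comp$epistasis +
        tr$shared_loading * latent + rnorm(n, sd = tr$resid_sd)
      tibble(hybrid_id = rep(ids, each = n_rep),
             trait = name,
             replicate = rep(seq_len(n_rep), times = n),
             value = rep(stable, each = n_rep) + rnorm(n * n_rep, sd = tr$rep_sd))
    }) |> bind_rows()
  })
}

#' Replicate-mean phenotypes
#'
#' @param pheno Long phenotype tibble from [simulate_phenotypes()].
#' @return A tibble `(hybrid_id, trait, value)` of replicate averages.
#' @export
phenotype_means <- function(pheno) {
  pheno |>
    group_by(.data$hybrid_id, .data$trait) |>
    summarise(value = mean(.data$value), .groups = "drop")
}

#' Wide matrix of replicate-mean phenotypes
#'
#' @param pheno Long phenotype tibble.
#' @param ids Optional row order (hybrid ids).
#' @return A numeric matrix, individuals x traits.
#' @export
phenotype_matrix <- function(pheno, ids = NULL) {
  wide <- phenotype_means(pheno) |>
    pivot_wider(names_from = "trait", values_from = "value")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  rownames(Y) <- wide$hybrid_id
  if (!is.null(ids)) Y <- Y[ids, , drop = FALSE]
  Y
}

#' Simulate a complete diallel dataset
#'
#' Convenience wrapper running the full generator: genetic map, two recombinant
#' haploid panels, all-against-all mating, architecture calibration and
#' replicated phenotypes. Defaults emulate the study design this package
#' models: 16 chromosomes, two 86-segregant F12 panels, nine correlated traits
#' with median narrow-sense heritability ~0.80 and repeatability ~0.94, four
#' replicates.
#'
#' @inheritParams simulate_genetic_map
#' @inheritParams simulate_segregant_panel
#' @inheritParams simulate_phenotypes
#' @param arch Optional pre-built (uncalibrated) `trait_architecture`; by
#'   default one is drawn with [sample_architecture()].
#' @param ... Passed on to [sample_architecture()].
#' @return A list of class `diallel_data` with `map`, `panels`, `pedigree`,
#'   `G`, `phenotypes`, `arch` (calibrated) and `truth` (realized
#'   heritabilities).
#' @export
simulate_diallel <- function(n_a = 86, n_alpha = 86, n_chrom = 16,
                             sites_per_chrom = 50, chrom_length_cM = 100,
                             n_meioses = 12, n_rep = 4, arch = NULL,
                             seed = 1, ...) {
  map <- simulate_genetic_map(n_chrom, sites_per_chrom, chrom_length_cM,
                              seed = derive_seed(seed, "sim", "map"))
  attr(map, "chrom_length_cM") <- chrom_length_cM
  panels <- simulate_segregant_panel(map, n_a, n_alpha, n_meioses,
                                     seed = derive_seed(seed, "sim", "panel"))
  cross <- mate_diallel(panels)
  if (is.null(arch)) {
    arch <- sample_architecture(map, seed = derive_seed(seed, "sim", "arch"), ...)
  }
  arch <- calibrate_architecture(arch, cross$G, n_rep = n_rep)
  pheno <- simulate_phenotypes(cross$G, arch, n_rep = n_rep,
                               seed = derive_seed(seed, "sim", "pheno"))
  structure(list(map = map, panels = panels, pedigree = cross$pedigree,
                 G = cross$G, phenotypes = pheno, arch = arch,
                 truth = realized_heritability(arch), seed = seed),
            class = "diallel_data")
}

#' @export
print.diallel_data <- function(x, ...) {
  cat(sprintf("<diallel_data: %d hybrids (%d x %d parents), %d sites, %d traits>\n",
              nrow(x$pedigree), nrow(x$panels$a), nrow(x$panels$alpha),
              ncol(x$G), length(x$arch$traits)))
  invisible(x)
}
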