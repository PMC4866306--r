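# Kinship structure: realized relatedness matrix, identity-by-state fractions
# and pedigree-based close/distant classification.

#' Compute the realized genomic relatedness matrix
#'
#' `K = X X^T / c` from the raw dosage matrix `X`, with the scaling constant
#' `c` the average diagonal value of `X X^T`, so that `mean(diag(K)) = 1`.
#' Dosages are used as-is by default (no column centring or standardization);
#' the prediction models carry an explicit fitted mean, and in a two-founder
#' diallel allele frequencies are close to 1/2 anyway. Centring is available
#' behind `center = TRUE`.
#'
#' @param G Dosage matrix (individuals x sites, values 0/1/2).
#' @param center If `TRUE`, subtract column means from `X` first.
#' @return An object of class `grm`: list with `K` (symmetric PSD matrix with
#'   individual ids as dimnames), `c` (scaling constant) and `ids`.
#' @export
compute_grm <- function(G, center = FALSE) {
  if (is.null(dim(G)) || nrow(G) == 0 || ncol(G) == 0) {
    abort_arg("`G` must be a non-empty matrix")
  }
  if (anyNA(G)) abort_arg("`G` must have no missing dosages")
  X <- G
  storage.mode(X) <- "double"
  if (center) X <- sweep(X, 2, colMeans(X))
  XXt <- tcrossprod(X)
  c0 <- mean(diag(XXt))
  if (c0 <= 0) abort(paste0("degenerate genotype matrix: mean diagonal of ",
                            "XX^T is zero"), class = "dgp_degenerate_error")
  K <- XXt / c0
  structure(list(K = K, c = c0, ids = rownames(G)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm: %d individuals, c = %.4g, mean diag = %.6g>\n",
              nrow(x$K), x$c, mean(diag(x$K))))
  invisible(x)
}

#' Identity-by-state fraction between two genotype vectors
#'
#' Fraction of sites at which the two individuals carry the same unordered
#' diploid genotype (equal dosage). For two independent hybrids of a
#' two-founder diallel the expectation is
#' \eqn{(1/4)^2 + (1/2)^2 + (1/4)^2 = 0.375}; for hybrids sharing one haploid
#' parent it is 0.5.
#'
#' @param g_i,g_j Dosage vectors of equal positive length.
#' @return A number in `[0, 1]`.
#' @export
ibs_fraction <- function(g_i, g_j) {
  if (length(g_i) == 0 || length(g_i) != length(g_j)) {
    abort_arg("genotype vectors must have equal positive length")
  }
  mean(g_i == g_j)
}

#' Pairwise IBS fractions for all pairs of individuals
#'
#' @param G Dosage matrix (individuals x sites).
#' @return A symmetric matrix of IBS fractions.
#' @export
ibs_matrix <- function(G) {
  if (is.null(dim(G)) || nrow(G) < 1) abort_arg("`G` must be a matrix")
  M <- ncol(G)
  S <- matrix(0, nrow(G), nrow(G), dimnames = list(rownames(G), rownames(G)))
  for (d in 0:2) {
    Ind <- (G == d) + 0
    S <- S + tcrossprod(Ind)
  }
  S / M
}

#' Classify a pair of hybrids by shared parentage
#'
#' `self` for identical ids, `close` for exactly one shared haploid parent
#' (expected genotype-IBS fraction 0.5), `distant` for none (expected 0.375).
#' Sharing both parents is impossible in a diallel with unique parent pairs
#' and raises a consistency error.
#'
#' @param ped Pedigree tibble (`hybrid_id`, `parent_a`, `parent_alpha`).
#' @param i,j Hybrid ids.
#' @return One of `"self"`, `"close"`, `"distant"`.
#' @export
classify_pair <- function(ped, i, j) {
  ri <- ped[ped$hybrid_id == i, ]; rj <- ped[ped$hybrid_id == j, ]
  if (nrow(ri) != 1 || nrow(rj) != 1) {
    abort_arg(sprintf("unknown hybrid id(s): %s",
                      paste(setdiff(c(i, j), ped$hybrid_id), collapse = ", ")))
  }
  if (i == j) return("self")
  shared <- (ri$parent_a == rj$parent_a) + (ri$parent_alpha == rj$parent_alpha)
  if (shared == 2) {
    abort_consistency("two distinct hybrids share both parents; not a valid diallel pedigree")
  }
  if (shared == 1) "close" else "distant"
}

# vectorized pair classes against a fixed reference set of hybrids:
# for each hybrid, "close" if it shares >= 1 parent with any reference hybrid
shares_parent_with <- function(ped, ref_ids) {
  ref <- ped[ped$hybrid_id %in% ref_ids, ]
  ped$parent_a %in% ref$parent_a | ped$parent_alpha %in% ref$parent_alpha
}

#' Count close and distant relatives of a hybrid in a full diallel
#'
#' In a complete `n_a x n_alpha` diallel each hybrid has
#' `(n_a - 1) + (n_alpha - 1)` close relatives (one shared haploid parent) and
#' `(n_a - 1)(n_alpha - 1)` distant ones.
#'
#' @param ped Full-diallel pedigree tibble.
#' @param i Hybrid id.
#' @return A named list `(n_close, n_distant)`.
#' @export
count_relatives <- function(ped, i) {
  ri <- ped[ped$hybrid_id == i, ]
  if (nrow(ri) != 1) abort_arg(sprintf("unknown hybrid id: %s", i))
  others <- ped[ped$hybrid_id != i, ]
  shared <- (others$parent_a == ri$parent_a) +
    (others$parent_alpha == ri$parent_alpha)
  list(n_close = sum(shared == 1), n_distant = sum(shared == 0))
}

#' IBS fractions annotated with pedigree pair class
#'
#' Computes the genotype-IBS fraction for every unordered pair of hybrids and
#' labels each pair `close` or `distant` from the pedigree. The distribution
#' over all pairs of a full diallel is bimodal, with modes near 0.5 (close)
#' and 0.375 (distant).
#'
#' @param G Dosage matrix.
#' @param ped Pedigree tibble covering the rows of `G`.
#' @return A tibble `(id_i, id_j, ibs, class)` over unordered pairs.
#' @export
ibs_pairs <- function(G, ped) {
  ped <- ped[match(rownames(G), ped$hybrid_id), ]
  if (anyNA(ped$hybrid_id)) abort_arg("pedigree does not cover all rows of `G`")
  S <- ibs_matrix(G)
  n <- nrow(G)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  shared <- (ped$parent_a[idx[, 1]] == ped$parent_a[idx[, 2]]) +
    (ped$parent_alpha[idx[, 1]] == ped$parent_alpha[idx[, 2]])
  tibble(id_i = rownames(G)[idx[, 1]],
         id_j = rownames(G)[idx[, 2]],
         ibs = S[idx],
         class = c("distant", "close", "invalid")[shared + 1])
}

#' Histogram of pairwise IBS fractions by relatedness class
#'
#' @param pairs Tibble from [ibs_pairs()].
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_ibs_histogram <- function(pairs, binwidth = 0.005) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$ibs, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(0.375, 0.5), linetype = "dashed") +
    ggplot2::labs(x = "fraction of sites identical by genotype state",
                  y = "hybrid pairs", fill = "pair class")
}
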