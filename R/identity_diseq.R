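#' g2 estimator of identity disequilibrium
#'
#' Two-locus identity-disequilibrium parameter measuring the excess
#' covariance in heterozygosity across locus pairs, positive when
#' inbreeding varies among individuals. For a complete 0/1 heterozygosity
#' matrix `h` (n individuals x L loci),
#' \deqn{\hat g_2 = A/B - 1,\quad
#'   A = \frac{1}{nL(L-1)} \sum_i \sum_{k \ne l} h_{ik} h_{il},\quad
#'   B = \frac{1}{n(n-1)L(L-1)} \sum_{i \ne j} \sum_{k \ne l} h_{ik} h_{jl}.}
#' With missing cells the sums run over observed pairs only, each with its
#' own denominator (the count of observed index pairs); this reduces
#' exactly to the complete-data formula when nothing is missing.
#'
#' @param h numeric matrix of 0/1 heterozygosity indicators, `NA` allowed
#'   (see [slh_matrix()] with `normalize = FALSE`); `n >= 3`, `L >= 2`.
#' @return the g2 estimate (finite scalar).
#' @export
g2_estimate <- function(h) {
  h <- as.matrix(h)
  n <- nrow(h); L <- ncol(h)
  if (L < 2) stop("g2 needs at least 2 loci")
  if (n < 3) stop("g2 needs at least 3 individuals")
  if (!all(h %in% c(0, 1) | is.na(h)))
    stop("h must contain only 0, 1 or NA")
  m <- !is.na(h) * 1
  x <- h; x[is.na(x)] <- 0
  # within-individual cross-locus products and their observed-pair counts
  S_A <- sum(rowSums(x)^2 - rowSums(x * x))
  C_A <- sum(rowSums(m)^2 - rowSums(m * m))
  cx <- colSums(x); cm <- colSums(m)
  tot_x <- sum(cx)^2 - sum(cx^2)   # over all (i,j), k != l
  tot_m <- sum(cm)^2 - sum(cm^2)
  S_B <- tot_x - S_A               # restrict to i != j
  C_B <- tot_m - C_A
  if (C_A == 0 || C_B == 0 || S_B == 0)
    stop("g2 undefined: too few heterozygous cells or observed pairs")
  (S_A / C_A) / (S_B / C_B) - 1
}

#' Permutation test for identity disequilibrium
#'
#' Tests whether g2 exceeds its value under no identity disequilibrium.
#' The null distribution is generated by independently permuting each locus
#' column among individuals, which destroys across-locus correlation while
#' preserving each locus' heterozygosity frequency (and missingness
#' pattern marginally). Identity disequilibrium predicts a positive
#' deviation, so the default test is one-sided (greater);
#' `p = (1 + #(g2_perm >= g2_obs)) / (B + 1)`.
#'
#' @param h 0/1/`NA` heterozygosity matrix as in [g2_estimate()].
#' @param B number of permutations (>= 100; the conventional default is
#'   1000 iterations).
#' @param seed optional integer seed (identical seeds give identical
#'   results).
#' @param alternative `"greater"` (default) or `"two.sided"` (doubles the
#'   smaller tail, capped at 1).
#' @return object of class `g2_test`: list with `g2_hat`, `p_value`, `B`,
#'   `n`, `L`, `seed`, `alternative`.
#' @export
g2_test <- function(h, B = 1000, seed = NULL,
                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (B < 100) stop("B must be >= 100")
  h <- as.matrix(h)
  obs <- g2_estimate(h)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(h); L <- ncol(h)
  ge <- 0L; le <- 0L
  hp <- h
  for (b in seq_len(B)) {
    for (j in seq_len(L)) hp[, j] <- h[sample.int(n), j]
    gp <- tryCatch(g2_estimate(hp), error = function(e) NA_real_)
    if (is.na(gp)) next
    if (gp >= obs - 1e-12) ge <- ge + 1L
    if (gp <= obs + 1e-12) le <- le + 1L
  }
  p_g <- (1 + ge) / (B + 1)
  p <- if (alternative == "greater") p_g else
    min(1, 2 * min(p_g, (1 + le) / (B + 1)))
  structure(list(g2_hat = obs, p_value = p, B = B, n = n, L = L,
                 seed = seed, alternative = alternative),
            class = "g2_test")
}

#' @export
print.g2_test <- function(x, ...) {
  cat(sprintf("g2 identity-disequilibrium test (%s)\n", x$alternative))
  cat(sprintf("  g2_hat = %.6f, p = %.4g (B = %d permutations)\n",
              x$g2_hat, x$p_value, x$B))
  cat(sprintf("  n = %d individuals, L = %d loci\n", x$n, x$L))
  invisible(x)
}

#' Per-year g2 estimates by marker subset
#'
#' Computes the g2 estimate and permutation p-value for the individuals
#' breeding in each year, for the total, neutral and functional marker
#' subsets (the year x subset layout of a supplementary ID table).
#'
#' @param G a [genotype_matrix()].
#' @param individuals individual table with `individual_id` and `year`.
#' @param panel marker panel data.frame.
#' @param B permutations per test.
#' @param seed integer seed; each year x subset test uses a seed derived
#'   from it so the full table is reproducible.
#' @return data.frame with columns `year`, `subset`, `g2_hat`, `p_value`,
#'   `n`, `L`, `B`.
#' @export
g2_by_year <- function(G, individuals, panel, B = 1000, seed = 1) {
  subsets <- list(
    total = G$loci,
    neutral = intersect(G$loci, panel$locus_name[panel$category == "neutral"]),
    functional = intersect(G$loci, panel$locus_name[panel$category == "functional"]))
  years <- sort(unique(individuals$year))
  res <- list(); k <- 0L
  for (y in years) {
    ids <- unique(individuals$individual_id[individuals$year == y])
    idx <- match(intersect(ids, G$ids), G$ids)
    for (s in names(subsets)) {
      j <- match(subsets[[s]], G$loci)
      h <- is_het(G)[idx, j, drop = FALSE]
      k <- k + 1L
      tst <- tryCatch(
        g2_test(h, B = B, seed = derive_seed(seed, k)),
        error = function(e) NULL)
      res[[k]] <- data.frame(
        year = y, subset = s,
        g2_hat = if (is.null(tst)) NA_real_ else tst$g2_hat,
        p_value = if (is.null(tst)) NA_real_ else tst$p_value,
        n = length(idx), L = length(j), B = B)
    }
  }
  do.call(rbind, res)
}
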