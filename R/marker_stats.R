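#' Per-locus diversity statistics
#'
#' For each locus: number of typed individuals, allelic richness `A_R`
#' (raw count of distinct allele codes; all loci are typed on the same
#' individuals so no rarefaction is applied by default), observed
#' heterozygosity `H_O` (fraction of typed individuals with two different
#' alleles) and expected heterozygosity `E_l = 1 - sum(p_a^2)` with allele
#' frequencies estimated from all typed allele copies.
#'
#' @param G a [genotype_matrix()].
#' @param rarefaction_size optional number of gene copies; when given, an
#'   `A_R_rarefied` column holds the expected allele count in samples of
#'   that size (hypergeometric rarefaction). Off by default since all loci
#'   are typically typed on the same individuals.
#' @return data.frame of class `marker_stats` with columns `locus`,
#'   `n_typed`, `A_R`, `H_O`, `E_l` (and `A_R_rarefied` on request).
#' @export
marker_summary <- function(G, rarefaction_size = NULL) {
  L <- length(G$loci)
  out <- data.frame(locus = G$loci, n_typed = NA_integer_,
                    A_R = NA_integer_, H_O = NA_real_, E_l = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(rarefaction_size)) out$A_R_rarefied <- NA_real_
  for (j in seq_len(L)) {
    typed <- !is.na(G$a1[, j])
    n <- sum(typed)
    if (n == 0L) stop("locus with zero typed individuals: ", G$loci[j])
    alleles <- c(G$a1[typed, j], G$a2[typed, j])
    cnt <- as.numeric(table(alleles))
    p <- cnt / (2 * n)
    out$n_typed[j] <- n
    out$A_R[j] <- length(unique(alleles))
    out$H_O[j] <- mean(G$a1[typed, j] != G$a2[typed, j])
    out$E_l[j] <- 1 - sum(p^2)
    if (!is.null(rarefaction_size)) {
      g <- min(rarefaction_size, 2 * n)
      N <- 2 * n
      # expected alleles among g copies drawn without replacement
      out$A_R_rarefied[j] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
    }
  }
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Monte Carlo Hardy-Weinberg test for one locus
#'
#' Exact-style Monte Carlo test by random re-pairing of the observed allele
#' pool: the observed heterozygote count is compared with counts obtained by
#' shuffling the `2n` allele copies into random pairs. The two-sided p-value
#' doubles the smaller tail (each tail computed with the add-one rule
#' `(1 + #{extreme}) / (B + 1)`) and is capped at 1.
#'
#' @param G a [genotype_matrix()].
#' @param locus locus name.
#' @param B number of Monte Carlo pairings (>= 100).
#' @param seed optional integer seed.
#' @return p-value in `[1/(B+1), 1]`.
#' @export
hwe_test <- function(G, locus, B = 999, seed = NULL) {
  j <- match(locus, G$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  if (B < 100) stop("B must be >= 100")
  typed <- !is.na(G$a1[, j])
  n <- sum(typed)
  if (n < 5) stop("fewer than 5 typed individuals at locus ", locus)
  a <- c(G$a1[typed, j], G$a2[typed, j])
  if (length(unique(a)) == 1L) {
    warning("monomorphic locus ", locus, ": HWE test undefined, p = 1")
    return(1)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- sum(G$a1[typed, j] != G$a2[typed, j])
  odd <- seq(1, 2 * n, by = 2)
  perm <- vapply(seq_len(B), function(b) {
    s <- sample(a)
    sum(s[odd] != s[odd + 1L])
  }, numeric(1))
  p_low <- (1 + sum(perm <= obs)) / (B + 1)
  p_high <- (1 + sum(perm >= obs)) / (B + 1)
  min(1, 2 * min(p_low, p_high))
}

# G-test statistic of a contingency table (0 cells ignored)
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / E[idx]))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' The statistic is the G-test statistic of the two-locus genotype
#' contingency table; the null is generated by permuting the genotypes of
#' the second locus among individuals typed at both loci.
#'
#' @param G a [genotype_matrix()].
#' @param locus1,locus2 locus names.
#' @param B number of permutations (>= 100).
#' @param seed optional integer seed.
#' @return p-value `(1 + #{G_perm >= G_obs}) / (B + 1)`.
#' @export
ld_test <- function(G, locus1, locus2, B = 999, seed = NULL) {
  j1 <- match(locus1, G$loci); j2 <- match(locus2, G$loci)
  if (is.na(j1) || is.na(j2)) stop("unknown locus name")
  if (B < 100) stop("B must be >= 100")
  both <- !is.na(G$a1[, j1]) & !is.na(G$a1[, j2])
  if (sum(both) < 5) stop("fewer than 5 individuals typed at both loci")
  geno <- function(j) paste(pmin(G$a1[both, j], G$a2[both, j]),
                            pmax(G$a1[both, j], G$a2[both, j]), sep = "/")
  g1 <- geno(j1); g2 <- geno(j2)
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    warning("fewer than 2 distinct genotypes at a locus: LD test undefined, p = 1")
    return(1)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- g_statistic(table(g1, g2))
  perm <- vapply(seq_len(B), function(b)
    g_statistic(table(g1, sample(g2))), numeric(1))
  (1 + sum(perm >= obs - 1e-12)) / (B + 1)
}

#' One-way ANOVA of a marker statistic on marker category
#'
#' Compares neutral vs functional loci on allelic richness (`A_R`) or
#' observed heterozygosity (`H_O`) with a standard one-way ANOVA
#' (`df1 = 1`, `df2 = L - 2`).
#'
#' @param stats output of [marker_summary()].
#' @param panel marker panel data.frame with `locus_name`, `category`.
#' @param response `"A_R"` or `"H_O"`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
category_anova <- function(stats, panel, response = c("A_R", "H_O")) {
  response <- match.arg(response)
  d <- merge(as.data.frame(stats), panel,
             by.x = "locus", by.y = "locus_name")
  cnt <- table(d$category)
  if (length(cnt) < 2 || any(cnt < 2))
    stop("each marker category needs at least 2 loci")
  fit <- lm(d[[response]] ~ factor(d$category))
  a <- anova(fit)
  F <- a[["F value"]][1]
  p <- a[["Pr(>F)"]][1]
  if (a[["Sum Sq"]][1] < 1e-14) { F <- 0; p <- 1 }  # identical groups
  list(F = F, df1 = a$Df[1], df2 = a$Df[2], p = p)
}
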