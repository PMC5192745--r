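#' Body condition as mass residuals
#'
#' Body condition is the residual of an ordinary least-squares regression
#' of body mass on laying date, wing length and tarsus length, correcting
#' mass for timing of breeding and structural size. Fitted within year by
#' default.
#'
#' @param ind individual table (see [read_individuals()]).
#' @param by_year fit the regression separately within each year?
#' @return numeric vector aligned with the rows of `ind` (`NA` where any
#'   predictor or mass is missing).
#' @export
body_condition <- function(ind, by_year = TRUE) {
  out <- rep(NA_real_, nrow(ind))
  groupings <- if (by_year) split(seq_len(nrow(ind)), ind$year)
               else list(seq_len(nrow(ind)))
  for (idx in groupings) {
    d <- ind[idx, c("body_mass", "laying_date", "wing", "tarsus")]
    cc <- stats::complete.cases(d)
    if (sum(cc) < 5) stop("body_condition needs >= 5 complete rows per fit")
    P <- as.matrix(d[cc, c("laying_date", "wing", "tarsus")])
    cm <- suppressWarnings(cor(P))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (any(abs(cm) > 1 - 1e-10)) {
      w <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      stop(sprintf("collinear predictors in body-condition regression: %s and %s",
                   colnames(P)[w[1]], colnames(P)[w[2]]))
    }
    fit <- lm(body_mass ~ laying_date + wing + tarsus, data = d[cc, ])
    out[idx[cc]] <- residuals(fit)
  }
  out
}

#' Assemble a per-year modeling dataset
#'
#' Joins heterozygosity estimates onto the individual table, adds body
#' condition, restricts to one year (or all years when `year = NULL`), and
#' performs row-wise deletion of rows with missing model variables
#' (logging the count).
#'
#' @param ind individual table with a `recruited` column (see
#'   [derive_recruitment()]).
#' @param het output of [het_estimates()].
#' @param year the focal year, or `NULL` to keep all years with defined
#'   recruitment (pooled analysis).
#' @return data.frame with recruitment, het estimates and covariates;
#'   attribute `"n_deleted"` records the rows dropped.
#' @export
year_dataset <- function(ind, het, year = NULL) {
  if (!"recruited" %in% names(ind))
    stop("individual table has no recruited column; run derive_recruitment()")
  ind$body_condition <- body_condition(ind)
  d <- merge(ind, het, by = "individual_id", sort = FALSE)
  d <- if (is.null(year)) d[!is.na(d$recruited), , drop = FALSE]
       else d[d$year == year & !is.na(d$recruited), , drop = FALSE]
  need <- c("recruited", "het_total", "het_neutral", "het_functional",
            "plot", "sex", "origin", "age", "body_condition",
            "fledging_success", "pair_id")
  cc <- stats::complete.cases(d[, setdiff(need, "pair_id")])
  n_del <- sum(!cc)
  if (n_del) hf_log("year_dataset(%s): %d row(s) dropped by row-wise deletion",
                    if (is.null(year)) "pooled" else year, n_del)
  d <- d[cc, , drop = FALSE]
  d$year_f <- factor(d$year)
  attr(d, "n_deleted") <- n_del
  d
}

#' Multilocus heterozygosity-fitness model for one year (or pooled)
#'
#' Runs the per-year multimodel inference: binomial logit models of
#' recruitment with a mating-pair random intercept, all-subsets AICc
#' selection over the genetic and condition terms, and model averaging of
#' the equivalent (`delta AICc <= 2`) models. Heterozygosity enters either
#' as 1 - HL over all loci (`family = "total"`) or as the two subset
#' heterozygosities together (`family = "neutral_plus_functional"`).
#' Plot, sex and origin are carried in every candidate model; body
#' condition, fledging success, age and the heterozygosity term(s) are
#' enumerated. The pooled analysis stacks all years and adds year as a
#' forced fixed factor.
#'
#' @param yd dataset from [year_dataset()].
#' @param family `"total"` or `"neutral_plus_functional"`.
#' @param pooled logical; pooled all-year analysis (requires `yd` built
#'   with `year = NULL`).
#' @param min_rows minimum modeled rows (default 20).
#' @param random include the pair random intercept? (default `TRUE`).
#' @param always_terms fixed factors forced into every model.
#' @return a `hetfit_avg` table (see [model_average()]) with the model set
#'   in attribute `"modelset"`.
#' @export
run_multilocus_hfc <- function(yd,
                               family = c("total", "neutral_plus_functional"),
                               pooled = FALSE, min_rows = 20, random = TRUE,
                               always_terms = c("plot", "sex", "origin")) {
  family <- match.arg(family)
  if (nrow(yd) < min_rows)
    stop(sprintf("only %d modeled rows (< %d)", nrow(yd), min_rows))
  het_terms <- if (family == "total") "het_total"
               else c("het_neutral", "het_functional")
  cand <- c(het_terms, "body_condition", "fledging_success", "age")
  if (pooled) always_terms <- c(always_terms, "year_f")
  ms <- model_selection(yd, "recruited", candidate_terms = cand,
                        always_terms = always_terms,
                        group = if (random) "pair_id" else NULL)
  avg <- model_average(ms)
  attr(avg, "modelset") <- ms
  attr(avg, "year") <- if (pooled) "pooled" else unique(yd$year)
  avg
}

#' Univariate heterozygosity-only logistic regression
#'
#' Logistic regression of recruitment on a single heterozygosity measure,
#' with no other covariates (the simple per-year association underlying
#' recruit vs non-recruit heterozygosity comparisons).
#'
#' @param yd dataset from [year_dataset()].
#' @param het_col heterozygosity column name (default `"het_total"`).
#' @return list with `estimate`, `se`, `z`, `p`.
#' @export
univariate_hfc <- function(yd, het_col = "het_total") {
  fit <- fit_logistic(yd$recruited,
                      matrix(yd[[het_col]], ncol = 1,
                             dimnames = list(NULL, het_col)))
  est <- unname(fit$coefficients[het_col])
  se <- unname(fit$se[het_col])
  list(estimate = est, se = se, z = est / se,
       p = 2 * pnorm(-abs(est / se)))
}

#' Holm (sequential Bonferroni) step-down thresholds and flags
#'
#' Orders the m p-values ascending and compares the i-th smallest with
#' `alpha / (m - i + 1)`, stopping at the first failure. Flags match
#' `stats::p.adjust(p, "holm") <= alpha`.
#'
#' @param p numeric vector of raw p-values.
#' @param alpha family-wise error level.
#' @return list with `threshold` (per-element rank threshold, in input
#'   order) and `significant` (logical, input order).
#' @export
holm_stepdown <- function(p, alpha = 0.05) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  list(threshold = alpha / (m - rk + 1),
       significant = p.adjust(p, method = "holm") <= alpha)
}

#' Single-locus heterozygosity scan
#'
#' Fits one recruitment model per locus: the locus' 0/1 heterozygosity
#' indicator plus (by default) the same nongenetic covariates as the
#' multilocus models, with the mating-pair random intercept. Effect size is
#' the partial correlation approximation `r = z / sqrt(n)`. Sequential
#' Bonferroni (Holm) correction is applied across the scanned loci by
#' default; set `scope = "none"` to return raw p-values only and correct
#' externally (e.g. across all year x locus tests).
#'
#' @param yd dataset from [year_dataset()].
#' @param h raw 0/1 SLH matrix ([slh_matrix()] with `normalize = FALSE`)
#'   with rownames matching `individual_id`.
#' @param loci locus names to scan (default: all columns of `h`).
#' @param alpha family-wise error level for the Holm correction.
#' @param covariates include the nongenetic covariate set? (`FALSE` gives
#'   heterozygosity-only models).
#' @param random include the pair random intercept?
#' @param scope `"loci"` (Holm across this scan) or `"none"`.
#' @return data.frame of class `locus_scan` with columns `year`, `locus`,
#'   `estimate`, `z`, `p_raw`, `p_holm_rank_threshold`,
#'   `significant_after_correction`, `effect_size_r`, `n`.
#' @export
single_locus_scan <- function(yd, h, loci = colnames(h), alpha = 0.05,
                              covariates = TRUE, random = TRUE,
                              scope = c("loci", "none")) {
  scope <- match.arg(scope)
  idx <- match(yd$individual_id, rownames(h))
  if (anyNA(idx)) stop("individuals missing from the SLH matrix")
  base <- if (covariates) {
    mm <- model.matrix(~ plot + sex + origin + age + body_condition +
                         fledging_success, data = yd)
    mm[, -1, drop = FALSE]
  } else NULL
  rows <- list()
  for (loc in loci) {
    hv <- h[idx, loc]
    keep <- !is.na(hv)
    if (length(unique(hv[keep])) < 2) {
      warning("monomorphic heterozygosity at locus ", loc, ": skipped")
      next
    }
    X <- cbind(slh = hv, base)[keep, , drop = FALSE]
    fit <- tryCatch(
      fit_logistic(yd$recruited[keep], X,
                   groups = if (random) yd$pair_id[keep] else NULL),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("model for locus ", loc, " did not converge: skipped")
      next
    }
    est <- unname(fit$coefficients["slh"])
    z <- est / unname(fit$se["slh"])
    rows[[loc]] <- data.frame(
      year = unique(yd$year)[1], locus = loc, estimate = est, z = z,
      p_raw = 2 * pnorm(-abs(z)),
      effect_size_r = z / sqrt(fit$n_obs), n = fit$n_obs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no locus could be scanned")
  if (scope == "loci") {
    hs <- holm_stepdown(out$p_raw, alpha)
    out$p_holm_rank_threshold <- hs$threshold
    out$significant_after_correction <- hs$significant
  } else {
    out$p_holm_rank_threshold <- NA_real_
    out$significant_after_correction <- NA
  }
  rownames(out) <- NULL
  class(out) <- c("locus_scan", "data.frame")
  out
}

#' Post-hoc heterozygosity interaction checks
#'
#' Fits the heterozygosity-by-plot and heterozygosity-by-sex interactions
#' as separate models (each: full covariate set plus one interaction),
#' outside the all-subsets enumeration. A nonsignificant het x plot
#' interaction argues against population stratification driving the HFC;
#' a nonsignificant het x sex interaction means the association does not
#' differ between males and females.
#'
#' @param yd dataset from [year_dataset()].
#' @param het_col heterozygosity column (default `"het_total"`).
#' @param random include the pair random intercept?
#' @return data.frame with one row per interaction: `interaction`,
#'   `estimate`, `se`, `z`, `p`.
#' @export
hfc_interactions <- function(yd, het_col = "het_total", random = TRUE) {
  yd$het <- yd[[het_col]]
  rows <- lapply(c("plot", "sex"), function(fac) {
    mm <- model.matrix(as.formula(paste(
      "~ het *", fac, "+ origin + body_condition + fledging_success + age")),
      data = yd)
    X <- mm[, -1, drop = FALSE]
    fit <- fit_logistic(yd$recruited, X,
                        groups = if (random) yd$pair_id else NULL)
    iname <- grep("^het:", names(fit$coefficients), value = TRUE)[1]
    est <- unname(fit$coefficients[iname])
    se <- unname(fit$se[iname])
    data.frame(interaction = paste0(het_col, " x ", fac),
               estimate = est, se = se, z = est / se,
               p = 2 * pnorm(-abs(est / se)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Marker-variability model for single-locus effect sizes
#'
#' Ordinary linear model of the absolute single-locus effect sizes on
#' marker variability (allelic richness and observed heterozygosity as
#' covariates) and marker category (neutral vs functional) as a fixed
#' factor.
#'
#' @param scan a `locus_scan` (or row-bound scans).
#' @param stats [marker_summary()] output.
#' @param panel marker panel data.frame.
#' @return data.frame coefficient table with `term`, `estimate`, `se`,
#'   `t`, `p`.
#' @export
effect_size_model <- function(scan, stats, panel) {
  d <- merge(data.frame(locus = scan$locus, abs_r = abs(scan$effect_size_r)),
             as.data.frame(stats)[, c("locus", "A_R", "H_O")], by = "locus")
  d <- merge(d, panel[, c("locus_name", "category")],
             by.x = "locus", by.y = "locus_name")
  cnt <- table(unique(d[, c("locus", "category")])$category)
  if (length(cnt) < 2 || any(cnt < 3))
    stop("effect-size model needs >= 3 loci per category")
  fit <- lm(abs_r ~ A_R + H_O + category, data = d)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}
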