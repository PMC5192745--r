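#' Fit a logistic (optionally random-intercept) regression
#'
#' Binomial error, logit link. Without `groups` this is an ordinary
#' maximum-likelihood logistic regression; with `groups` a random-intercept
#' binomial mixed model is fitted by maximum likelihood with 20-node
#' adaptive Gauss-Hermite quadrature. Standard errors come from the
#' observed information. Aliased (rank-deficient) columns are dropped with
#' a warning before fitting.
#'
#' @param y 0/1 response vector.
#' @param X numeric design matrix of predictors (no intercept column; an
#'   intercept is always added), or `NULL` for an intercept-only model.
#' @param groups optional cluster identifiers (e.g. mating-pair ids) for a
#'   random intercept.
#' @return object of class `hetfit_fit`: list with `terms`, `coefficients`
#'   (including `(Intercept)`), `se`, `loglik`, `k_params` (coefficients
#'   plus one for the random-intercept variance when present), `n_obs`,
#'   `deviance`, `random_intercept_sd` (`NULL` for fixed-effect fits),
#'   `converged`, and the underlying fitted `model`.
#' @export
fit_logistic <- function(y, X = NULL, groups = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != n) stop("nrow(X) != length(y)")
    # drop aliased columns
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1L) {
      keep <- q$pivot[seq_len(q$rank)] - 1L
      keep <- keep[keep > 0L]
      dropped <- setdiff(colnames(X), colnames(X)[keep])
      warning("aliased column(s) dropped: ", paste(dropped, collapse = ", "))
      X <- X[, sort(keep), drop = FALSE]
      if (ncol(X) == 0L) X <- NULL
    }
  }
  k_fixed <- 1L + if (is.null(X)) 0L else ncol(X)
  if (n < k_fixed + 1L) stop("too few observations for the requested model")

  if (is.null(groups)) {
    d <- if (is.null(X)) data.frame(y = y) else data.frame(y = y, X,
                                                           check.names = FALSE)
    fit <- suppressWarnings(
      glm(y ~ ., data = d, family = binomial(),
          control = list(epsilon = 1e-12, maxit = 100)))
    if (fit$deviance < 1e-7 && n > 0) {
      cf <- coef(fit)
      stop("complete separation detected (term '",
           names(which.max(abs(cf[-1])))[1] %||% "(Intercept)", "')")
    }
    sm <- summary(fit)
    cf <- coef(fit)
    names(cf) <- gsub("^`|`$", "", names(cf))
    se <- sm$coefficients[, "Std. Error"]
    names(se) <- gsub("^`|`$", "", names(se))
    structure(list(
      terms = setdiff(names(cf), "(Intercept)"),
      coefficients = cf,
      se = se,
      loglik = as.numeric(logLik(fit)),
      k_params = length(coef(fit)),
      n_obs = n,
      deviance = fit$deviance,
      random_intercept_sd = NULL,
      converged = isTRUE(fit$converged),
      model = fit), class = "hetfit_fit")
  } else {
    if (length(groups) != n) stop("length(groups) != length(y)")
    d <- if (is.null(X)) data.frame(y = y) else data.frame(y = y, X,
                                                           check.names = FALSE)
    d$.grp <- factor(groups)
    form <- as.formula(paste(
      "y ~", if (is.null(X)) "1" else
        paste(sprintf("`%s`", colnames(X)), collapse = " + "),
      "+ (1 | .grp)"))
    # primary: 20-node AGQ with a fast optimizer; fall back to the default
    # optimizer, then to the Laplace approximation, before giving up
    attempts <- list(
      function() lme4::glmer(form, data = d, family = binomial(), nAGQ = 20,
                             control = lme4::glmerControl(
                               calc.derivs = FALSE, optimizer = "nloptwrap",
                               check.conv.singular = "ignore")),
      function() lme4::glmer(form, data = d, family = binomial(), nAGQ = 20),
      function() lme4::glmer(form, data = d, family = binomial(), nAGQ = 1))
    fit <- NULL
    for (a in attempts) {
      fit <- tryCatch(suppressWarnings(suppressMessages(a())),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("random-intercept logistic fit failed (possible separation)")
    ll <- logLik(fit)
    fe <- lme4::fixef(fit)
    names(fe) <- gsub("^`|`$", "", names(fe))
    se <- sqrt(diag(as.matrix(vcov(fit))))
    conv <- length(fit@optinfo$conv$lme4) == 0 &&
      (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0) &&
      all(is.finite(se)) && max(se) < 1e3   # absurd SEs = degenerate information
    structure(list(
      terms = setdiff(names(fe), "(Intercept)"),
      coefficients = fe,
      se = setNames(se, names(fe)),
      loglik = as.numeric(ll),
      k_params = attr(ll, "df"),
      n_obs = n,
      deviance = as.numeric(-2 * ll),
      random_intercept_sd = sqrt(lme4::VarCorr(fit)$.grp[1, 1]),
      converged = conv,
      model = fit), class = "hetfit_fit")
  }
}

#' @export
print.hetfit_fit <- function(x, ...) {
  cat(sprintf("logistic fit (%s): n = %d, logLik = %.3f, k = %d\n",
              if (is.null(x$random_intercept_sd)) "fixed effects"
              else sprintf("random intercept, sd = %.3f",
                           x$random_intercept_sd),
              x$n_obs, x$loglik, x$k_params))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.hetfit_fit <- function(object, ...) object$coefficients

#' @export
logLik.hetfit_fit <- function(object, ...) {
  structure(object$loglik, df = object$k_params,
            nobs = object$n_obs, class = "logLik")
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts all
#' estimated parameters (intercept, slopes and the random-intercept
#' variance when present) and `n` is the number of observations.
#'
#' @param object a `hetfit_fit`, or a numeric log-likelihood.
#' @param k,n parameter count and sample size (required when `object` is
#'   numeric).
#' @return the AICc value.
#' @export
aicc <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "hetfit_fit")) {
    ll <- object$loglik; k <- object$k_params; n <- object$n_obs
  } else {
    ll <- as.numeric(object)
    if (is.null(k) || is.null(n)) stop("k and n required")
  }
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return list with `delta` and `weights` (weights sum to 1).
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weights = w / sum(w))
}

#' All-subsets AICc model selection for binomial (mixed) models
#'
#' Fits every subset of `candidate_terms` (always including the intercept,
#' `always_terms`, and a random intercept when `group` is given), ranks the
#' models by AICc and computes Akaike weights over the full retained set.
#' Models that fail to converge are excluded with a warning. Factor terms
#' are expanded through `model.matrix`, and all columns belonging to a term
#' enter or leave together.
#'
#' @param data data.frame holding the response and all terms.
#' @param response name of the 0/1 response column.
#' @param candidate_terms character vector of term names to enumerate.
#' @param always_terms character vector of term names forced into every
#'   model.
#' @param group optional name of a cluster-id column for the random
#'   intercept.
#' @param cap maximum number of models (error above; default 4096).
#' @return object of class `hetfit_modelset`: list with `table` (one row
#'   per fitted model: terms, k, loglik, aicc, delta, weight), `fits`,
#'   `top_set` (indices with delta <= 2), plus the call ingredients.
#' @export
model_selection <- function(data, response, candidate_terms,
                            always_terms = character(), group = NULL,
                            cap = 4096) {
  if (length(candidate_terms) < 1) stop("need at least 1 candidate term")
  m <- length(candidate_terms)
  if (2^m > cap) stop(sprintf("all-subsets enumeration (%d models) exceeds cap %d",
                              2^m, cap))
  y <- data[[response]]
  groups <- if (is.null(group)) NULL else data[[group]]

  term_matrix <- function(terms) {
    if (!length(terms)) return(NULL)
    mm <- model.matrix(as.formula(paste("~", paste(terms, collapse = " + "))),
                       data = data)
    asn <- attr(mm, "assign")
    X <- mm[, asn > 0, drop = FALSE]
    attr(X, "term_of") <- terms[asn[asn > 0]]
    X
  }

  fits <- vector("list", 2^m)
  rows <- vector("list", 2^m)
  for (s in seq_len(2^m) - 1L) {
    inc <- candidate_terms[bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) > 0L]
    terms <- c(always_terms, inc)
    X <- term_matrix(terms)
    fit <- tryCatch(
      suppressWarnings(fit_logistic(y, X, groups)),
      error = function(e) e)
    ok <- inherits(fit, "hetfit_fit") && isTRUE(fit$converged)
    if (ok) {
      fit$term_of <- c("(Intercept)",
                       if (is.null(X)) character() else attr(X, "term_of"))
      fits[[s + 1L]] <- fit
    }
    rows[[s + 1L]] <- data.frame(
      model = s + 1L,
      terms = paste(c("1", terms), collapse = " + "),
      k = if (ok) fit$k_params else NA_integer_,
      loglik = if (ok) fit$loglik else NA_real_,
      converged = ok)
  }
  tab <- do.call(rbind, rows)
  if (any(!tab$converged))
    warning(sum(!tab$converged), " model(s) failed to converge and were excluded")
  keep <- which(tab$converged)
  if (!length(keep)) stop("no model converged")
  tab <- tab[keep, , drop = FALSE]
  fits <- fits[keep]
  tab$aicc <- vapply(fits, aicc, numeric(1))
  aw <- akaike_weights(tab$aicc)
  tab$delta <- aw$delta
  tab$weight <- aw$weights
  o <- order(tab$delta)
  tab <- tab[o, , drop = FALSE]
  fits <- fits[o]
  structure(list(table = tab, fits = fits,
                 top_set = which(tab$delta <= 2),
                 response = response,
                 candidate_terms = candidate_terms,
                 always_terms = always_terms, group = group),
            class = "hetfit_modelset")
}

#' @export
print.hetfit_modelset <- function(x, ...) {
  cat(sprintf("AICc model set: %d models (%d with delta <= 2)\n",
              nrow(x$table), length(x$top_set)))
  print(head(data.frame(terms = x$table$terms, k = x$table$k,
                        AICc = round(x$table$aicc, 2),
                        delta = round(x$table$delta, 2),
                        weight = round(x$table$weight, 4)), 10),
        row.names = FALSE)
  invisible(x)
}

#' Natural model averaging with unconditional standard errors
#'
#' Averages estimates over the models containing each term, weighting by
#' Akaike weights: `estimate = sum w_i theta_i` and
#' `USE = sum w_i sqrt(SE_i^2 + (theta_i - estimate)^2)` (the
#' between-model variance enters the unconditional SE). Weights are
#' normalized over the models that contain the term.
#'
#' @param est,se,w numeric vectors: per-model estimate, standard error and
#'   weight for one term.
#' @return list with `estimate` and `use`.
#' @export
unconditional_average <- function(est, se, w) {
  w <- w / sum(w)
  estimate <- sum(w * est)
  list(estimate = estimate,
       use = sum(w * sqrt(se^2 + (est - estimate)^2)))
}

#' Model-averaged coefficient table over the top model set
#'
#' Restricts a model set to the equivalent models (`delta AICc <= 2`),
#' renormalizes their Akaike weights, and produces a coefficient table in
#' the conventional layout: model-averaged estimate, unconditional standard
#' error (USE), the sum of (renormalized) Akaike weights of top-set models
#' containing the term, and the normal-approximation 95% CI
#' (`estimate +/- 1.96 USE`). A term is flagged significant when the CI
#' excludes zero. Terms absent from every top-set model are omitted; rows
#' are sorted by weight sum (relative importance) descending.
#'
#' @param ms a `hetfit_modelset` from [model_selection()].
#' @param include_intercept include the intercept row? (default `FALSE`).
#' @return data.frame of class `hetfit_avg` with columns `term`,
#'   `estimate`, `use`, `sum_weights`, `ci_low`, `ci_high`, `significant`.
#' @export
model_average <- function(ms, include_intercept = FALSE) {
  stopifnot(inherits(ms, "hetfit_modelset"))
  top <- ms$top_set
  if (!length(top)) stop("empty top model set")
  fits <- ms$fits[top]
  w <- ms$table$weight[top]
  w <- w / sum(w)
  coefs <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  if (!include_intercept) coefs <- setdiff(coefs, "(Intercept)")
  rows <- lapply(coefs, function(cn) {
    inm <- vapply(fits, function(f) cn %in% names(f$coefficients), logical(1))
    est <- vapply(fits[inm], function(f) unname(f$coefficients[cn]), numeric(1))
    se <- vapply(fits[inm], function(f) unname(f$se[cn]), numeric(1))
    avg <- unconditional_average(est, se, w[inm])
    data.frame(term = cn, estimate = avg$estimate, use = avg$use,
               sum_weights = sum(w[inm]),
               ci_low = avg$estimate - 1.96 * avg$use,
               ci_high = avg$estimate + 1.96 * avg$use,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  out <- out[order(-out$sum_weights, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hetfit_avg", "data.frame")
  out
}

#' @export
print.hetfit_avg <- function(x, ...) {
  d <- as.data.frame(x)
  d$estimate <- sprintf("%.2f ± %.2f", d$estimate, d$use)
  d$use <- NULL
  d$CI95 <- sprintf("(%.2f, %.2f)%s", x$ci_low, x$ci_high,
                    ifelse(x$significant, " *", ""))
  d$ci_low <- d$ci_high <- d$significant <- NULL
  names(d) <- c("term", "estimate ± USE", "sum(w)", "95% CI")
  print(d, row.names = FALSE)
  invisible(x)
}

#' F-ratio test of multilocus vs single-locus heterozygosity
#'
#' Compares a linear model of the outcome on the base covariates plus
#' multilocus heterozygosity (MLH) with one in which MLH is replaced by the
#' normalized single-locus heterozygosities (SLH) at all markers:
#' \deqn{F = \frac{(RSS_{MLH} - RSS_{SLH}) / (L - 1)}
#'   {RSS_{SLH} / (n - p_{base} - L - 1)}}
#' A significant F means some loci carry information beyond the single
#' multilocus summary (local effects); a nonsignificant F is consistent
#' with a genomewide (general) effect.
#'
#' @param y numeric outcome (the 0/1 recruitment indicator; the default
#'   test is formulated on linear-model residual sums of squares, as in
#'   the variance-decomposition method it follows).
#' @param base_X numeric matrix of base covariates (no intercept), or
#'   `NULL`.
#' @param mlh numeric vector of multilocus heterozygosity.
#' @param slh numeric matrix of normalized single-locus heterozygosities.
#' @param type `"rss"` (linear-model residual sums of squares, default)
#'   or `"deviance"` (binomial-deviance analogue).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
mlh_vs_slh_ftest <- function(y, base_X, mlh, slh, type = c("rss", "deviance")) {
  type <- match.arg(type)
  slh <- as.matrix(slh)
  v <- apply(slh, 2, var)
  if (any(v == 0 | is.na(v))) {
    warning("zero-variance SLH column(s) dropped: ",
            paste(colnames(slh)[v == 0 | is.na(v)], collapse = ", "))
    slh <- slh[, !(v == 0 | is.na(v)), drop = FALSE]
  }
  L <- ncol(slh)
  if (L < 2) stop("F-ratio test needs >= 2 SLH loci (df1 = L - 1 would be 0)")
  p_base <- if (is.null(base_X)) 0L else ncol(as.matrix(base_X))
  n <- length(y)
  if (n <= p_base + L + 1) stop("too few observations for the SLH model")
  rss <- if (type == "rss") {
    function(X) sum(lm.fit(cbind(1, X), y)$residuals^2)
  } else {
    function(X) suppressWarnings(
      glm.fit(cbind(1, X), y, family = binomial())$deviance)
  }
  rss1 <- rss(if (is.null(base_X)) as.matrix(mlh) else cbind(base_X, mlh))
  rss2 <- rss(if (is.null(base_X)) slh else cbind(base_X, slh))
  if (rss2 < 1e-12) stop("saturated SLH fit (RSS = 0)")
  df1 <- L - 1
  df2 <- n - p_base - L - 1
  F <- ((rss1 - rss2) / df1) / (rss2 / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}
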