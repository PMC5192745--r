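#' Homozygosity by locus (HL)
#'
#' Individual homozygosity index weighting each locus by its expected
#' heterozygosity, so that more informative (variable) loci contribute more:
#' \deqn{HL_i = \frac{\sum_{l \in hom_i} E_l}{\sum_{l \in hom_i} E_l +
#'   \sum_{l \in het_i} E_l}}
#' where the sums run over the loci at which individual *i* is typed and
#' homozygous / heterozygous, and `E_l` is the expected heterozygosity of
#' locus *l*. Missing loci are excluded from both sums. `HL = 1` iff the
#' individual is homozygous at all typed subset loci, `0` iff heterozygous
#' at all.
#'
#' @param G a [genotype_matrix()].
#' @param weights named numeric vector of per-locus `E_l` weights; by
#'   default taken from [marker_summary()] on `G` (pooled sample).
#' @param loci optional subset of locus names (default: all loci in `G`).
#' @return named numeric vector of HL values in `[0, 1]`; `NA` (with a
#'   warning) for individuals with no typed locus in the subset or whose
#'   typed subset loci all have zero weight.
#' @export
compute_hl <- function(G, weights = NULL, loci = NULL) {
  if (is.null(weights)) {
    ms <- marker_summary(G)
    weights <- setNames(ms$E_l, ms$locus)
  }
  loci <- loci %||% G$loci
  missing_w <- setdiff(loci, names(weights))
  if (length(missing_w))
    stop("no weight for locus: ", paste(missing_w, collapse = ", "))
  j <- match(loci, G$loci)
  if (anyNA(j)) stop("unknown locus: ",
                     paste(loci[is.na(j)], collapse = ", "))
  w <- weights[loci]
  hom <- (G$a1[, j, drop = FALSE] == G$a2[, j, drop = FALSE]) * 1
  typed <- !is.na(hom)
  wm <- matrix(w, nrow = nrow(hom), ncol = length(w), byrow = TRUE)
  num <- rowSums(wm * (hom == 1), na.rm = TRUE)
  den <- rowSums(wm * typed, na.rm = TRUE)
  hl <- ifelse(rowSums(typed) == 0L | den == 0, NA_real_, num / den)
  if (anyNA(hl))
    warning("HL undefined for individual(s): ",
            paste(G$ids[is.na(hl)], collapse = ", "))
  setNames(hl, G$ids)
}

#' Per-individual heterozygosity estimates (1 - HL) by marker subset
#'
#' Computes HL and its inverse 1 - HL for all typed markers and separately
#' for the neutral and functional subsets defined by the marker panel.
#' 1 - HL is the heterozygosity measure used in all downstream fitness
#' models.
#'
#' @param G a [genotype_matrix()].
#' @param panel marker panel data.frame (`locus_name`, `category`).
#' @param weights optional named `E_l` weights; default pooled
#'   [marker_summary()] on `G` (weight source is recorded in the
#'   `"weight_source"` attribute).
#' @param exclude optional locus names to drop from every subset.
#' @return data.frame with columns `individual_id`, `hl_total`,
#'   `hl_neutral`, `hl_functional`, `het_total`, `het_neutral`,
#'   `het_functional`, `n_typed_total`, `n_typed_neutral`,
#'   `n_typed_functional`.
#' @export
het_estimates <- function(G, panel, weights = NULL, exclude = character()) {
  src <- if (is.null(weights)) "pooled marker_summary(G)" else "user-supplied"
  if (is.null(weights)) {
    ms <- marker_summary(G)
    weights <- setNames(ms$E_l, ms$locus)
  }
  use <- setdiff(intersect(G$loci, panel$locus_name), exclude)
  subsets <- list(
    total = use,
    neutral = intersect(use, panel$locus_name[panel$category == "neutral"]),
    functional = intersect(use, panel$locus_name[panel$category == "functional"]))
  out <- data.frame(individual_id = G$ids, stringsAsFactors = FALSE)
  for (s in names(subsets)) {
    loci <- subsets[[s]]
    if (!length(loci)) stop("no loci in subset ", s)
    hl <- suppressWarnings(compute_hl(G, weights, loci))
    out[[paste0("hl_", s)]] <- unname(hl)
    out[[paste0("het_", s)]] <- 1 - unname(hl)
    j <- match(loci, G$loci)
    out[[paste0("n_typed_", s)]] <-
      rowSums(!is.na(G$a1[, j, drop = FALSE]))
  }
  attr(out, "weight_source") <- src
  out
}

#' Single-locus heterozygosity matrix
#'
#' Raw 0/1 heterozygosity indicators per individual and locus, optionally
#' standardized per locus. Standardization ("normalized SLH") z-scores each
#' column over typed individuals using the n-1 variance; columns with zero
#' variance are dropped with a warning (they carry no contrast for the
#' models). A mean-scaling alternative (`h / mean(h)`) is available.
#'
#' @param G a [genotype_matrix()].
#' @param loci optional locus subset.
#' @param normalize logical; return standardized columns?
#' @param method `"z"` (z-score, default) or `"mean"` (divide by column
#'   mean).
#' @return numeric matrix (individuals x loci) with `NA` for untyped cells;
#'   dropped locus names are recorded in the `"dropped"` attribute.
#' @export
slh_matrix <- function(G, loci = NULL, normalize = FALSE,
                       method = c("z", "mean")) {
  method <- match.arg(method)
  loci <- loci %||% G$loci
  j <- match(loci, G$loci)
  if (anyNA(j)) stop("unknown locus: ", paste(loci[is.na(j)], collapse = ", "))
  h <- is_het(G)[, j, drop = FALSE]
  if (!normalize) return(h)
  if (any(colSums(!is.na(h)) < 2))
    stop("normalization needs >= 2 typed individuals per locus")
  hz <- matrix(NA_real_, nrow(h), ncol(h), dimnames = dimnames(h))
  drop <- logical(ncol(h))
  for (k in seq_len(ncol(h))) {
    x <- h[, k]
    if (method == "z") {
      s <- sd(x, na.rm = TRUE)
      if (is.na(s) || s == 0) { drop[k] <- TRUE; next }
      hz[, k] <- (x - mean(x, na.rm = TRUE)) / s
    } else {
      m <- mean(x, na.rm = TRUE)
      if (is.na(m) || m == 0) { drop[k] <- TRUE; next }
      hz[, k] <- x / m
    }
  }
  if (any(drop))
    warning("zero-variance SLH column(s) dropped: ",
            paste(colnames(h)[drop], collapse = ", "))
  out <- hz[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(h)[drop]
  out
}
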