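# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive quantities from their definitions (quadruple
# sums, step-down enumeration) so the package implementations are checked
# against something that shares no code with them.

# definitional g2: explicit sums over observed index pairs
g2_brute <- function(h) {
  n <- nrow(h); L <- ncol(h)
  sa <- 0; ca <- 0; sb <- 0; cb <- 0
  for (i in seq_len(n)) for (k in seq_len(L)) for (l in seq_len(L)) {
    if (k == l) next
    if (!is.na(h[i, k]) && !is.na(h[i, l])) {
      sa <- sa + h[i, k] * h[i, l]; ca <- ca + 1
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (k in seq_len(L)) for (l in seq_len(L)) {
      if (k == l) next
      if (!is.na(h[i, k]) && !is.na(h[j, l])) {
        sb <- sb + h[i, k] * h[j, l]; cb <- cb + 1
      }
    }
  }
  (sa / ca) / (sb / cb) - 1
}

# step-down sequential Bonferroni by direct enumeration
holm_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  sig <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) sig[o[i]] <- TRUE else break
  }
  sig
}

# genotype_matrix from literal allele pair strings, e.g. c("1/1", "1/2")
gm_from_strings <- function(..., loci = NULL) {
  rows <- list(...)
  L <- length(strsplit(rows[[1]], " ")[[1]])
  a1 <- matrix(NA_integer_, length(rows), L)
  a2 <- matrix(NA_integer_, length(rows), L)
  for (i in seq_along(rows)) {
    cells <- strsplit(rows[[i]], " ")[[1]]
    for (j in seq_len(L)) {
      if (cells[j] != "./.") {
        ab <- as.integer(strsplit(cells[j], "/")[[1]])
        a1[i, j] <- ab[1]; a2[i, j] <- ab[2]
      }
    }
  }
  genotype_matrix(paste0("i", seq_along(rows)), a1, a2,
                  loci %||% paste0("loc", seq_len(L)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random 0/1 heterozygosity matrix with optional missingness mask
rand_h <- function(n, L, p = NULL, miss = 0) {
  if (is.null(p)) p <- runif(L, 0.3, 0.8)
  h <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
  if (miss > 0) h[matrix(runif(n * L) < miss, n, L)] <- NA
  h
}

# minimal valid individual table for io tests
toy_individuals <- function() {
  data.frame(
    individual_id = c("a", "b", "c", "a", "b", "d"),
    year = c(2010, 2010, 2010, 2011, 2011, 2011),
    plot = c("A", "A", "B", "B", "A", "B"),
    sex = c("M", "F", "M", "M", "F", "F"),
    age = c(1, 1, 2, 2, 2, 1),
    origin = c("local", "immigrant", "local", "local", "immigrant", "local"),
    body_mass = c(11, 10.5, 11.2, 11.1, 10.4, 10.9),
    tarsus = c(16.5, 16.1, 17.0, 16.5, 16.1, 16.4),
    wing = c(67, 64, 68, 67.5, 64.2, 63.9),
    laying_date = c(98, 102, 95, 101, 99, 97),
    fledging_success = c(5, 6, 4, 7, 3, 5),
    pair_id = c("p1", "p1", "p2", "p3", "p4", "p3"),
    stringsAsFactors = FALSE)
}

write_temp_csv <- function(df, ...) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, f, row.names = FALSE, quote = FALSE, ...)
  f
}
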