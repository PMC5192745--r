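#' Construct a genotype matrix
#'
#' Container for individuals x loci microsatellite genotypes: two positive
#' integer allele codes per locus, with missing data allowed only as a whole
#' genotype (both alleles `NA` together). Allele codes are opaque labels
#' (fragment lengths or arbitrary integers); no size information is used.
#'
#' @param ids character vector of individual identifiers (unique).
#' @param a1,a2 integer matrices (individuals x loci) of allele codes;
#'   `NA` marks a missing genotype and must occur in both matrices at the
#'   same cells.
#' @param loci character vector of locus names (unique), one per column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ids, a1, a2, loci) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (length(ids) != nrow(a1)) stop("length(ids) != nrow(a1)")
  if (length(loci) != ncol(a1)) stop("length(loci) != ncol(a1)")
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  if (anyDuplicated(loci)) stop("duplicated locus names")
  half <- which(is.na(a1) != is.na(a2))
  if (length(half)) {
    i <- ((half[1] - 1L) %% nrow(a1)) + 1L
    j <- ((half[1] - 1L) %/% nrow(a1)) + 1L
    stop(sprintf(
      "half-missing genotype for individual '%s' at locus '%s': both alleles must be present or both missing",
      ids[i], loci[j]))
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers")
  all_missing <- rowSums(!is.na(a1)) == 0L
  if (any(all_missing))
    stop("individual(s) with no typed locus: ",
         paste(ids[all_missing], collapse = ", "))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = as.character(ids), loci = as.character(loci),
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d missing genotypes)\n",
              length(x$ids), length(x$loci), sum(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ids), length(x$loci))

# 0/1/NA heterozygosity indicator matrix (individuals x loci)
#' Raw heterozygosity indicators
#'
#' @param G a [genotype_matrix()].
#' @return integer matrix with 1 = heterozygous, 0 = homozygous, `NA` = untyped.
#' @export
is_het <- function(G) {
  h <- (G$a1 != G$a2) * 1L
  dimnames(h) <- list(G$ids, G$loci)
  h
}

#' Read a marker panel table
#'
#' CSV with columns `locus_name`, `chromosome`, `category`
#' (`neutral`/`functional`).
#'
#' @param path file path.
#' @return data.frame with validated columns.
#' @export
read_marker_panel <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_name", "chromosome", "category")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("marker panel lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(p$locus_name))
    stop("duplicated locus names in marker panel")
  if (any(is.na(p$category)) || !all(p$category %in% c("neutral", "functional")))
    stop("category must be 'neutral' or 'functional' for every locus")
  if (nrow(p) < 2) stop("marker panel must contain at least 2 loci")
  p
}

#' Read a genotype CSV
#'
#' Expected header: `id` plus two columns per locus named `<locus>.a1` and
#' `<locus>.a2`. Missing genotypes may be empty cells or `NA` (both alleles
#' missing together).
#'
#' @param path file path.
#' @param panel marker panel data.frame (see [read_marker_panel()]); every
#'   locus column in the file must appear in the panel.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(d)) stop("genotype file must have an 'id' column")
  cols <- setdiff(names(d), "id")
  bad <- cols[!grepl("\\.a[12]$", cols)]
  if (length(bad)) stop("malformed genotype column(s): ",
                        paste(bad, collapse = ", "))
  loci <- unique(sub("\\.a[12]$", "", cols))
  orphan <- setdiff(loci, panel$locus_name)
  if (length(orphan))
    stop("locus column(s) absent from marker panel: ",
         paste(orphan, collapse = ", "))
  incomplete <- loci[!(paste0(loci, ".a1") %in% cols &
                       paste0(loci, ".a2") %in% cols)]
  if (length(incomplete))
    stop("locus with a single allele column: ",
         paste(incomplete, collapse = ", "))
  # keep panel order for loci present in the file
  loci <- panel$locus_name[panel$locus_name %in% loci]
  a1 <- as.matrix(d[, paste0(loci, ".a1"), drop = FALSE])
  a2 <- as.matrix(d[, paste0(loci, ".a2"), drop = FALSE])
  G <- genotype_matrix(d$id, a1, a2, loci)
  hf_log("read_genotypes: %d individuals x %d loci from %s",
         nrow(d), length(loci), path)
  G
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [read_genotypes()]; missing genotypes are written as `NA`.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @export
write_genotypes <- function(G, path) {
  out <- data.frame(id = G$ids, stringsAsFactors = FALSE)
  for (j in seq_along(G$loci)) {
    out[[paste0(G$loci[j], ".a1")]] <- G$a1[, j]
    out[[paste0(G$loci[j], ".a2")]] <- G$a2[, j]
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.ind_required <- c("individual_id", "year", "plot", "sex", "age", "origin",
                   "body_mass", "tarsus", "wing", "laying_date",
                   "fledging_success", "pair_id")

validate_individuals <- function(d) {
  miss <- setdiff(.ind_required, names(d))
  if (length(miss)) stop("individual table lacks column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(d$individual_id, d$year, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("duplicated (individual_id, year): ",
         gsub("\r", ", year ", k))
  }
  badsex <- which(!(d$sex %in% c("M", "F")))
  if (length(badsex))
    stop(sprintf("invalid sex value '%s' in row %d (must be M or F)",
                 d$sex[badsex[1]], badsex[1]))
  badplot <- which(!(d$plot %in% c("A", "B")))
  if (length(badplot))
    stop(sprintf("invalid plot value '%s' in row %d (must be A or B)",
                 d$plot[badplot[1]], badplot[1]))
  badorig <- which(!is.na(d$origin) & !(d$origin %in% c("local", "immigrant")))
  if (length(badorig))
    stop(sprintf("invalid origin value '%s' in row %d", d$origin[badorig[1]],
                 badorig[1]))
  if (any(d$fledging_success < 0, na.rm = TRUE))
    stop("negative fledging_success")
  if ("recruited" %in% names(d) &&
      !all(d$recruited %in% c(0L, 1L, NA)))
    stop("recruited must be 0, 1 or NA")
  # a pair is at most two individuals in a given year
  pk <- paste(d$pair_id, d$year)
  tab <- table(pk[!is.na(d$pair_id)])
  if (any(tab > 2))
    stop("pair_id shared by more than 2 individuals in a year: ",
         names(tab)[which(tab > 2)[1]])
  d$year <- as.integer(d$year)
  d$age <- as.integer(d$age)
  d
}

#' Read the individual/phenotype table
#'
#' CSV with per-individual, per-year phenotypes and covariates:
#' `individual_id`, `year`, `plot` (A/B), `sex` (M/F), `age`, `origin`
#' (local/immigrant), `body_mass`, `tarsus`, `wing`, `laying_date`,
#' `fledging_success`, `pair_id`, and optionally `recruited` (0/1, `NA` in
#' the final study year).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_individuals <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d <- validate_individuals(d)
  hf_log("read_individuals: %d rows, years %s from %s", nrow(d),
         paste(range(d$year), collapse = "-"), path)
  d
}

#' Derive recruitment outcomes from capture histories
#'
#' Codes `recruited(id, t) = 1` if the individual was captured breeding in
#' year `t + 1` in any study plot, `0` otherwise, and `NA` for the final
#' observed year (no `t + 1` data exist). Plot changes between years do not
#' affect the coding. Requires consecutive study years.
#'
#' @param captures individual table (with or without a `recruited` column;
#'   any existing column is recomputed).
#' @return the table with a `recruited` column.
#' @export
derive_recruitment <- function(captures) {
  d <- validate_individuals(captures)
  years <- sort(unique(d$year))
  if (length(years) < 2)
    stop("recruitment is undefined for single-year data (no year t+1)")
  if (any(diff(years) != 1L))
    stop("study years must be consecutive; gap after ",
         years[which(diff(years) != 1L)[1]])
  ids_by_year <- split(d$individual_id, d$year)
  last <- max(years)
  d$recruited <- ifelse(
    d$year == last, NA_integer_,
    vapply(seq_len(nrow(d)), function(i) {
      as.integer(d$individual_id[i] %in% ids_by_year[[as.character(d$year[i] + 1L)]])
    }, integer(1)))
  hf_log("derive_recruitment: %d rows coded; final year %d left undefined",
         sum(!is.na(d$recruited)), last)
  d
}

#' Read a daily weather series
#'
#' CSV with columns `date` (ISO), `tmin`, `tmax` (degrees C), `precip`
#' (mm/day). Returned sorted by date.
#'
#' @param path file path.
#' @return data.frame sorted ascending by date.
#' @export
read_weather <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "precip")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("weather table lacks column(s): ",
                         paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  if (any(is.na(d$date))) stop("unparseable date in weather table")
  validate_weather(d)
}

validate_weather <- function(d) {
  if (anyDuplicated(d$date))
    stop("duplicated date in weather table: ",
         as.character(d$date[duplicated(d$date)][1]))
  bad <- which(d$tmax < d$tmin)
  if (length(bad))
    stop(sprintf("tmax < tmin on %s", as.character(d$date[bad[1]])))
  if (any(d$precip < 0, na.rm = TRUE)) stop("negative precipitation")
  d[order(d$date), , drop = FALSE]
}

#' Write a weather series to CSV
#' @param w weather data.frame.
#' @param path output file path.
#' @export
write_weather <- function(w, path) {
  write.csv(w, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML file giving input paths, marker-subset definitions, model-term
#' lists, permutation counts and seeds. Only light validation is done here;
#' each pipeline step validates the pieces it consumes.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  for (f in intersect(c("genotypes", "individuals", "weather", "panel"),
                      names(cfg$files %||% list()))) {
    if (!file.exists(cfg$files[[f]]))
      stop("config file path does not exist: ", cfg$files[[f]])
  }
  if (!is.null(cfg$seed) && !is.numeric(cfg$seed))
    stop("config seed must be numeric")
  cfg
}
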