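#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the simulated study: a
#' multi-year nestbox population genotyped at microsatellite loci, with
#' variance in inbreeding generating identity disequilibrium, recruitment
#' probabilities logistic in heterozygosity with a year slope modulated by
#' winter precipitation, and daily Mediterranean weather.
#'
#' Defaults emulate the study design the pipeline targets: 26 loci
#' (14 neutral + 12 functional) on 10 chromosomes, 7 monitored years
#' (6 recruitment intervals), ~100 breeders per year, a two-point
#' inbreeding mixture (a fraction `pi` of individuals from consanguineous
#' matings with `f = f_high`, the rest outbred with `f = 0`), baseline
#' recruitment around 35% and stronger selection on heterozygosity in
#' wetter years, and weather calibrated to a meso-Mediterranean climate
#' (July means 24-26 C, January 4-6 C, 300-600 mm annual rainfall with
#' large interannual variance).
#'
#' @param n_per_year breeders per year.
#' @param years integer vector of consecutive study years.
#' @param n_loci,n_neutral total loci and how many are labelled neutral
#'   (the rest functional; labels carry no generative difference).
#' @param alleles_per_locus integer scalar or vector (>= 2) of allele
#'   counts per locus.
#' @param inbreeding list: `model` (`"mixture"`, `"constant"` or
#'   `"beta"`), `pi`, `f_high` (mixture), `f` (constant),
#'   `shape1`, `shape2` (beta).
#' @param recruitment list: `beta0` (baseline log-odds of recruiting at
#'   population-average heterozygosity), `beta0_precip_slope` (shift of
#'   the baseline with standardized winter precipitation; negative =
#'   lower survival after wet, harsh winters), `beta1_base` and
#'   `beta1_precip_slope` (logit slope on centered heterozygosity is
#'   `beta1_base + beta1_precip_slope * z(precip)`), optional
#'   `het_center` (reference heterozygosity; defaults to the expected
#'   population mean).
#' @param weather list of seasonal weather parameters: `tmean_jan`,
#'   `tmean_jul` (C), `dhr_winter`, `dhr_summer` (half tmin-tmax range in
#'   midwinter/midsummer; continental summers spread further around the
#'   mean), `temp_sd` (daily noise, C), `rain_prob` (daily occurrence),
#'   `rain_shape`, `rain_scale` (gamma magnitude, mm), `rain_year_sd`
#'   (lognormal sd of the yearly wetness factor).
#' @param functional_allele_factor multiplier (in (0, 1]) applied to the
#'   allele counts of functional loci, to emulate panels whose
#'   EST-derived loci are less variable than the neutral ones; 1 (the
#'   default) makes the category labels carry no generative difference.
#' @param missing_rate per-cell genotype missingness probability.
#' @param prop_immigrant probability a new breeder is an immigrant.
#' @param seed integer root seed (mandatory); all sub-generators derive
#'   their streams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_year = 100,
                       years = 2008:2014,
                       n_loci = 26, n_neutral = 14,
                       alleles_per_locus = round(seq(4, 20,
                         length.out = n_loci))[order(rep_len(1:2, n_loci))],
                       inbreeding = list(model = "mixture", pi = 0.2,
                                         f_high = 0.25),
                       recruitment = list(beta0 = -0.6,
                                          beta0_precip_slope = -0.4,
                                          beta1_base = 2,
                                          beta1_precip_slope = 4),
                       weather = list(tmean_jan = 5, tmean_jul = 25,
                                      dhr_winter = 5, dhr_summer = 9,
                                      temp_sd = 2.5,
                                      rain_prob = 0.24, rain_shape = 0.8,
                                      rain_scale = 8.5, rain_year_sd = 0.35),
                       functional_allele_factor = 1,
                       missing_rate = 0, prop_immigrant = 0.4,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  alleles_per_locus <- rep_len(as.integer(alleles_per_locus), n_loci)
  if (functional_allele_factor <= 0 || functional_allele_factor > 1)
    stop("functional_allele_factor must be in (0, 1]")
  if (functional_allele_factor < 1) {
    fun <- (n_neutral + 1):n_loci
    alleles_per_locus[fun] <-
      pmax(2L, as.integer(round(alleles_per_locus[fun] *
                                  functional_allele_factor)))
  }
  if (any(alleles_per_locus < 2)) stop("alleles_per_locus must be >= 2")
  if (n_neutral < 1 || n_neutral >= n_loci)
    stop("need at least 1 neutral and 1 functional locus")
  im <- inbreeding$model %||% "mixture"
  if (im == "mixture") {
    if (inbreeding$pi < 0 || inbreeding$pi > 1) stop("pi must be in [0, 1]")
    if (inbreeding$f_high < 0 || inbreeding$f_high >= 1)
      stop("f_high must be in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  structure(list(n_per_year = n_per_year, years = as.integer(years),
                 n_loci = n_loci, n_neutral = n_neutral,
                 alleles_per_locus = alleles_per_locus,
                 inbreeding = inbreeding, recruitment = recruitment,
                 weather = weather, missing_rate = missing_rate,
                 prop_immigrant = prop_immigrant,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic stream splitting: sub-seed k from the root seed
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629) + 1L
}

#' Closed-form expected g2 for the configured inbreeding model
#'
#' Under the generative model (loci independent given an individual's
#' inbreeding coefficient f, heterozygosity probability `(1 - f) E_l`),
#' the expected identity disequilibrium is
#' `g2 = Var(f) / (1 - E(f))^2`; 0 for constant f.
#'
#' @param cfg a [sim_config()].
#' @return the expected g2 value.
#' @export
expected_g2 <- function(cfg) {
  ib <- cfg$inbreeding
  switch(ib$model %||% "mixture",
    constant = 0,
    mixture = {
      m <- ib$pi * ib$f_high
      v <- ib$pi * (1 - ib$pi) * ib$f_high^2
      v / (1 - m)^2
    },
    beta = {
      a <- ib$shape1; b <- ib$shape2
      m <- a / (a + b)
      v <- a * b / ((a + b)^2 * (a + b + 1))
      v / (1 - m)^2
    },
    stop("unknown inbreeding model"))
}

# mean inbreeding coefficient implied by the configured model
mean_f <- function(cfg) {
  ib <- cfg$inbreeding
  switch(ib$model %||% "mixture",
    constant = ib$f %||% 0,
    mixture = ib$pi * ib$f_high,
    beta = ib$shape1 / (ib$shape1 + ib$shape2),
    stop("unknown inbreeding model"))
}

# draw per-individual inbreeding coefficients
draw_inbreeding <- function(n, cfg) {
  ib <- cfg$inbreeding
  switch(ib$model %||% "mixture",
    constant = rep(ib$f %||% 0, n),
    mixture = ifelse(runif(n) < ib$pi, ib$f_high, 0),
    beta = stats::rbeta(n, ib$shape1, ib$shape2),
    stop("unknown inbreeding model"))
}

# flat composition prior on allele frequencies, one vector per locus
draw_allele_freqs <- function(cfg) {
  lapply(cfg$alleles_per_locus, function(k) {
    p <- stats::rexp(k)
    p / sum(p)
  })
}

#' Simulate microsatellite genotypes under partial autozygosity
#'
#' For each individual and locus: with probability `f_i` the locus is
#' autozygous (one allele drawn from the locus' frequency distribution and
#' duplicated), otherwise two alleles are drawn independently.
#'
#' @param n number of individuals.
#' @param freqs list of allele-frequency vectors (one per locus), e.g.
#'   from a [sim_config()] via [simulate_dataset()]; if `NULL`, drawn from
#'   the flat composition prior of `cfg`.
#' @param f inbreeding coefficient, scalar or per-individual vector.
#' @param cfg a [sim_config()] (used for locus count / allele counts and
#'   missingness when `freqs` is `NULL`).
#' @param seed optional integer seed.
#' @param ids individual identifiers.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, freqs = NULL, f = 0, cfg = NULL,
                               seed = NULL,
                               ids = sprintf("ind%05d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) {
    if (is.null(cfg)) stop("need freqs or cfg")
    freqs <- draw_allele_freqs(cfg)
  }
  L <- length(freqs)
  f <- rep_len(f, n)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    p <- freqs[[j]]
    x1 <- sample.int(length(p), n, replace = TRUE, prob = p)
    x2 <- sample.int(length(p), n, replace = TRUE, prob = p)
    auto <- runif(n) < f
    x2[auto] <- x1[auto]
    a1[, j] <- x1; a2[, j] <- x2
  }
  mr <- if (is.null(cfg)) 0 else cfg$missing_rate
  if (mr > 0) {
    miss <- matrix(runif(n * L) < mr, n, L)
    # keep every individual typed somewhere
    miss[rowSums(!miss) == 0L, 1L] <- FALSE
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  loci <- sprintf("L%02d", seq_len(L))
  genotype_matrix(ids, a1, a2, loci)
}

#' Simulate daily weather
#'
#' Daily minimum and maximum temperatures follow a seasonal sinusoid
#' (peak mid-July) plus Gaussian noise, with `tmax >= tmin` enforced.
#' Rain occurrence is Bernoulli and magnitudes gamma; a lognormal yearly
#' wetness factor (applied per July-June season) creates the large
#' interannual precipitation variance typical of Mediterranean climates.
#'
#' @param cfg a [sim_config()].
#' @param years years to cover; the series runs 1 January of the first
#'   year through 31 March of the year after the last (so every
#'   July-March harshness window is complete).
#' @param seed integer seed (default derived from `cfg$seed`).
#' @return weather data.frame (`date`, `tmin`, `tmax`, `precip`).
#' @export
simulate_weather <- function(cfg, years = cfg$years,
                             seed = derive_seed(cfg$seed, 1)) {
  set.seed(seed)
  wp <- cfg$weather
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-03-31", max(years) + 1)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  mid <- (wp$tmean_jan + wp$tmean_jul) / 2
  amp <- (wp$tmean_jul - wp$tmean_jan) / 2
  season_cos <- cos(2 * pi * (doy - 196) / 365.25)   # +1 mid-July, -1 mid-Jan
  tmean <- mid + amp * season_cos
  dhr <- wp$dhr_winter + (wp$dhr_summer - wp$dhr_winter) * (1 + season_cos) / 2
  tmin <- tmean - dhr + rnorm(length(dates), 0, wp$temp_sd)
  tmax <- tmean + dhr + rnorm(length(dates), 0, wp$temp_sd)
  swap <- tmax < tmin + 0.2
  tmax[swap] <- tmin[swap] + 0.2
  # yearly wetness factor per July-June season
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  season <- yr - (mo < 7)
  seasons <- sort(unique(season))
  fac <- setNames(rlnorm(length(seasons),
                         meanlog = -wp$rain_year_sd^2 / 2,
                         sdlog = wp$rain_year_sd), seasons)
  wet <- runif(length(dates)) < wp$rain_prob
  precip <- numeric(length(dates))
  precip[wet] <- rgamma(sum(wet), shape = wp$rain_shape,
                        scale = wp$rain_scale) *
    fac[as.character(season[wet])]
  data.frame(date = dates, tmin = round(tmin, 1), tmax = round(tmax, 1),
             precip = round(precip, 1))
}

#' Simulate recruitment outcomes
#'
#' Bernoulli draws with
#' `P(recruit) = plogis(beta0 + beta0_precip_slope * precip_z
#'   + beta1 * (het - het_center))` where
#' `beta1 = beta1_base + beta1_precip_slope * precip_z` and `precip_z` is
#' the year's accumulated winter precipitation standardized across the
#' study years. Wet (harsh) winters thus lower overall survival while
#' strengthening selection on heterozygosity; the heterozygosity term is
#' centered so that changing the selection slope does not by itself move
#' the yearly recruitment rate.
#'
#' @param het numeric heterozygosity vector (1 - HL scale).
#' @param precip_z standardized accumulated precipitation of the focal
#'   year (scalar).
#' @param cfg a [sim_config()]; `cfg$recruitment$het_center` defaults to
#'   `mean(het)`.
#' @param seed optional integer seed.
#' @return integer 0/1 vector.
#' @export
simulate_recruitment <- function(het, precip_z, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rc <- cfg$recruitment
  beta1 <- rc$beta1_base + rc$beta1_precip_slope * precip_z
  eta <- rc$beta0 + (rc$beta0_precip_slope %||% 0) * precip_z +
    beta1 * (het - (rc$het_center %||% mean(het)))
  rbinom(length(het), 1, plogis(eta))
}

#' Simulate a complete multi-year study dataset
#'
#' Generates a study with known truth: weather, allele frequencies,
#' individuals with inbreeding coefficients from the configured mixture,
#' genotypes under the autozygosity rule, pair structure, phenotypic
#' covariates, and recruitment outcomes in which surviving individuals
#' reappear the following year (so [derive_recruitment()] reproduces the
#' generated outcomes) and the population is replenished with new breeders
#' each year. Heterozygosity driving recruitment is 1 - HL computed with
#' the true-frequency locus weights `E_l = 1 - sum(p^2)`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` ([genotype_matrix()]), `panel`,
#'   `individuals` (with `recruited`; `NA` in the final year), `weather`,
#'   and `truth` (per-individual `f` and true heterozygosity, per-year
#'   `beta1` and precipitation z-scores, `expected_g2`, allele
#'   frequencies).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  weather <- simulate_weather(cfg, seed = derive_seed(cfg$seed, 1))
  years <- cfg$years
  ryears <- years[-length(years)]   # years with a defined outcome
  harsh <- harshness_series(weather, ryears)
  pz <- if (length(ryears) > 1)
    as.numeric(scale(harsh$accumulated_precip)) else 0
  beta1 <- cfg$recruitment$beta1_base +
    cfg$recruitment$beta1_precip_slope * pz

  set.seed(derive_seed(cfg$seed, 2))
  freqs <- draw_allele_freqs(cfg)
  w_true <- vapply(freqs, function(p) 1 - sum(p^2), numeric(1))
  # expected population mean of 1 - HL under the true weights: centers the
  # selection term so beta1 does not move the yearly recruitment rate
  het_center <- cfg$recruitment$het_center %||%
    ((1 - mean_f(cfg)) * sum(w_true^2) / sum(w_true))
  rc <- cfg$recruitment

  set.seed(derive_seed(cfg$seed, 3))
  pool <- data.frame(individual_id = character(), f = numeric(),
                     sex = character(), plot = character(),
                     origin = character(), tarsus = numeric(),
                     wing = numeric(), entry_year = integer(),
                     entry_age = integer(), het = numeric(),
                     stringsAsFactors = FALSE)
  a1_all <- NULL; a2_all <- NULL
  n_created <- 0L

  new_entrants <- function(k, year) {
    ids <- sprintf("ind%05d", n_created + seq_len(k))
    f <- draw_inbreeding(k, cfg)
    sex <- sample(rep_len(c("M", "F"), k))
    plot <- sample(rep_len(c("A", "B"), k))
    origin <- ifelse(runif(k) < cfg$prop_immigrant, "immigrant", "local")
    tarsus <- rnorm(k, 16.5, 0.5)
    wing <- rnorm(k, 66, 2) + 1.5 * (sex == "M")
    G <- simulate_genotypes(k, freqs = freqs, f = f, cfg = cfg, ids = ids)
    hl <- suppressWarnings(compute_hl(G, weights = setNames(w_true, G$loci)))
    list(df = data.frame(individual_id = ids, f = f, sex = sex, plot = plot,
                         origin = origin, tarsus = tarsus, wing = wing,
                         entry_year = year,
                         entry_age = ifelse(origin == "immigrant",
                                            sample(1:2, k, replace = TRUE), 1L),
                         het = 1 - unname(hl), stringsAsFactors = FALSE),
         a1 = G$a1, a2 = G$a2)
  }

  rows <- list()
  current <- integer(0)  # row indices into pool of this year's breeders
  for (t in seq_along(years)) {
    y <- years[t]
    n_new <- cfg$n_per_year - length(current)
    if (n_new > 0) {
      ne <- new_entrants(n_new, y)
      pool <- rbind(pool, ne$df)
      a1_all <- rbind(a1_all, ne$a1)
      a2_all <- rbind(a2_all, ne$a2)
      n_created <- n_created + n_new
      current <- c(current, nrow(pool) - n_new + seq_len(n_new))
    }
    d <- pool[current, , drop = FALSE]
    # pair males and females within plot; leftovers breed unpaired
    pair_id <- rep(NA_character_, nrow(d))
    np <- 0L
    for (pl in c("A", "B")) {
      males <- sample(which(d$sex == "M" & d$plot == pl))
      females <- sample(which(d$sex == "F" & d$plot == pl))
      k <- min(length(males), length(females))
      if (k > 0) {
        pid <- sprintf("P%d_%03d", y, np + seq_len(k))
        pair_id[males[seq_len(k)]] <- pid
        pair_id[females[seq_len(k)]] <- pid
        np <- np + k
      }
    }
    solo <- which(is.na(pair_id))
    pair_id[solo] <- sprintf("P%d_s%03d", y, seq_along(solo))
    laying <- round(rnorm(nrow(d), 100, 7))
    mass <- 5.4 + 0.15 * d$tarsus + 0.04 * d$wing + 0.005 * laying +
      rnorm(nrow(d), 0, 0.35)
    fledged <- rpois(nrow(d), 5)
    if (t < length(years)) {
      eta <- rc$beta0 + (rc$beta0_precip_slope %||% 0) * pz[t] +
        beta1[t] * (d$het - het_center)
      recruited <- rbinom(nrow(d), 1, plogis(eta))
    } else {
      recruited <- rep(NA_integer_, nrow(d))
    }
    rows[[t]] <- data.frame(
      individual_id = d$individual_id, year = y, plot = d$plot,
      sex = d$sex, age = d$entry_age + (y - d$entry_year),
      origin = d$origin, body_mass = round(mass, 2),
      tarsus = round(d$tarsus, 2), wing = round(d$wing, 1),
      laying_date = laying, fledging_success = fledged,
      pair_id = pair_id, recruited = recruited,
      stringsAsFactors = FALSE)
    current <- current[recruited == 1L & !is.na(recruited)]
  }

  individuals <- validate_individuals(do.call(rbind, rows))
  G <- genotype_matrix(pool$individual_id, a1_all, a2_all,
                       sprintf("L%02d", seq_len(cfg$n_loci)))
  panel <- data.frame(
    locus_name = G$loci,
    chromosome = sprintf("chr%d", rep_len(1:10, cfg$n_loci)),
    category = c(rep("neutral", cfg$n_neutral),
                 rep("functional", cfg$n_loci - cfg$n_neutral)),
    stringsAsFactors = FALSE)
  list(genotypes = G, panel = panel, individuals = individuals,
       weather = weather,
       truth = list(f = setNames(pool$f, pool$individual_id),
                    het_true = setNames(pool$het, pool$individual_id),
                    beta1 = setNames(beta1, ryears),
                    precip_z = setNames(pz, ryears),
                    expected_g2 = expected_g2(cfg),
                    het_center = het_center,
                    allele_freqs = freqs))
}
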