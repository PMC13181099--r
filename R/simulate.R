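# Seeded synthetic-data generators emulating the statistical structure of
# the three experiments: a cure-fraction (physically dormant) germination
# process observed at weekly censuses, an ordered-logit latent scale for
# the 0-5 establishment score across soils, and pH x DAS organ-length
# distributions with a missing-organ mechanism.

.default_soils <- c("BV", "COPMO", "COPSA", "MBG3", "MEC")

# Latent-scale species x soil means for the ordinal generator, chosen to
# mirror the qualitative soil ranking seen in the multi-soil trial:
# BV depressed despite fertility, MBG3/COPMO permissive, COPSA good for
# albus, MEC restrictive especially for luteus/angustifolius.
.default_mu_species_soil <- function() {
  soil_eff <- c(BV = -1.5, COPMO = 1.0, COPSA = 0.3, MBG3 = 1.5, MEC = -0.8)
  sp_eff <- c(albus = 0.4, angustifolius = -0.3, luteus = 0)
  mu <- outer(sp_eff, soil_eff, "+")
  mu["albus", "COPSA"] <- mu["albus", "COPSA"] + 0.7
  mu["albus", "MEC"] <- mu["albus", "MEC"] + 0.8
  mu["luteus", "MEC"] <- mu["luteus", "MEC"] - 0.5
  mu["luteus", "MBG3"] <- mu["luteus", "MBG3"] + 0.5
  mu["angustifolius", "MEC"] <- mu["angustifolius", "MEC"] - 0.5
  mu
}

# Organ-length cell means (mm) per pH x DAS; rows are pH levels.
# DAS dominates elongation (~ +14 mm hypocotyl, ~ +12 mm epicotyl between
# DAS7 and DAS14 pooled over pH), pH 7.0 is most permissive, and epicotyl
# growth collapses under alkaline conditions at DAS14.
.default_mu_organ <- function() {
  list(
    hypocotyl = matrix(c(12, 15, 9, 26, 29, 23), nrow = 3,
                       dimnames = list(c("5.5", "7", "8.5"), c("7", "14"))),
    epicotyl = matrix(c(2, 4, 1, 16, 18, 6), nrow = 3,
                      dimnames = list(c("5.5", "7", "8.5"), c("7", "14")))
  )
}

# Dormant fractions for the germination panel: most accessions nearly
# non-dormant, a few intermediate and strongly dormant, mirroring a panel
# in which a small subset shows measurable physical dormancy.
.default_dormant_fraction <- function(n) {
  base <- c(rep(0.05, 12), 0.5, 0.6, 0.9, 0.95)
  rep_len(base, n)
}

#' Build a validated simulation configuration
#'
#' Collects the parameters of the three experiment generators in one
#' object. Defaults reproduce the designs of the trials being emulated:
#' a 16-accession germination panel with 5 seeds per treatment censused
#' weekly to day 365; a 48-accession (three species) x 5 soils x 2
#' scarification treatments x 3 blocks x 5 seeds ordinal trial; and a
#' 48-accession x 3 pH x 2 DAS x 3 replicates x 5 seeds growth trial.
#'
#' @param rng_seed Integer seed; every generator stream derives from it.
#' @param n_accessions Size of the multi-species panel (experiments 2-3).
#' @param seeds_per_unit Seeds per experimental unit.
#' @param exp1,exp2,exp3 Named lists overriding per-experiment defaults;
#'   see Details.
#'
#' @details
#' `exp1`: `n_accessions` (16), `dormant_fraction` (per-accession
#' probability of an impermeable seed coat under NS, recycled),
#' `germ_time_mean` (gamma mean germination day for permeable seeds, 12),
#' `germ_time_shape` (gamma shape, 4), `release_hazard` (per-census
#' dormancy-release probability, 0.005), `scar_time_factor`
#' (multiplicative rescaling of the mean germination time under
#' scarification, 0.7; scarification also sets the dormant fraction to 0),
#' `horizon_days` (365), `census_interval` (7).
#'
#' `exp2`: `mu` (species x soil latent means), `beta_scar` (latent shift
#' under scarification, 1.0), `sigma_accession` (accession random
#' intercept SD, 0.5), `cutpoints` (5 strictly increasing ordered-logit
#' cutpoints), `n_blocks` (3).
#'
#' `exp3`: `mu_hypocotyl`, `mu_epicotyl` (pH x DAS cell-mean matrices,
#' mm), `sigma` (residual SD, 4 mm), `missing_prob` (independent
#' per-organ missingness, 0.108), `accession_sd` (SD of the lognormal
#' per-accession length multiplier, 0.08), `n_replicates` (3).
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_accessions = 48L, seeds_per_unit = 5L,
                       exp1 = list(), exp2 = list(), exp3 = list()) {
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L,
            n_accessions >= 1L, seeds_per_unit >= 1L)
  e1 <- utils::modifyList(list(
    n_accessions = 16L,
    dormant_fraction = NULL,
    germ_time_mean = 12,
    germ_time_shape = 4,
    release_hazard = 0.005,
    scar_time_factor = 0.7,
    horizon_days = 365L,
    census_interval = 7L
  ), exp1)
  if (is.null(e1$dormant_fraction))
    e1$dormant_fraction <- .default_dormant_fraction(e1$n_accessions)
  e1$dormant_fraction <- rep_len(e1$dormant_fraction, e1$n_accessions)

  e2 <- utils::modifyList(list(
    mu = .default_mu_species_soil(),
    beta_scar = 1.0,
    sigma_accession = 0.5,
    cutpoints = c(-2.5, -1.5, -0.5, 0.5, 1.5),
    n_blocks = 3L
  ), exp2)

  e3 <- utils::modifyList(list(
    mu_hypocotyl = .default_mu_organ()$hypocotyl,
    mu_epicotyl = .default_mu_organ()$epicotyl,
    sigma = 4,
    missing_prob = 0.108,
    accession_sd = 0.08,
    n_replicates = 3L
  ), exp3)

  if (any(e1$dormant_fraction < 0 | e1$dormant_fraction > 1))
    stop("dormant_fraction must lie in [0, 1]", call. = FALSE)
  if (e1$release_hazard < 0 || e1$release_hazard > 1)
    stop("release_hazard must lie in [0, 1]", call. = FALSE)
  if (e1$germ_time_mean <= 0 || e1$germ_time_shape <= 0)
    stop("germination-time parameters must be > 0", call. = FALSE)
  if (e1$horizon_days < e1$census_interval)
    stop("horizon_days must cover at least one census interval", call. = FALSE)
  if (length(e2$cutpoints) != 5L || any(diff(e2$cutpoints) <= 0))
    stop("cutpoints must be 5 strictly increasing values", call. = FALSE)
  if (e2$sigma_accession < 0) stop("sigma_accession must be >= 0", call. = FALSE)
  if (e3$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (e3$missing_prob < 0 || e3$missing_prob > 1)
    stop("missing_prob must lie in [0, 1]", call. = FALSE)

  structure(list(rng_seed = as.integer(rng_seed),
                 n_accessions = as.integer(n_accessions),
                 seeds_per_unit = as.integer(seeds_per_unit),
                 exp1 = e1, exp2 = e2, exp3 = e3),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("lupinest simulation config\n")
  cat(sprintf("  seed %d; panel %d accessions; %d seeds per unit\n",
              x$rng_seed, x$n_accessions, x$seeds_per_unit))
  cat(sprintf("  exp1: %d accessions, horizon %d d, census every %d d\n",
              x$exp1$n_accessions, x$exp1$horizon_days, x$exp1$census_interval))
  cat(sprintf("  exp2: beta_scar %.2f, sigma_a %.2f, %d blocks\n",
              x$exp2$beta_scar, x$exp2$sigma_accession, x$exp2$n_blocks))
  cat(sprintf("  exp3: sigma %.1f mm, missing prob %.3f, %d replicates\n",
              x$exp3$sigma, x$exp3$missing_prob, x$exp3$n_replicates))
  invisible(x)
}

# panel identifiers and species assignment shared by exp2/exp3; the
# angustifolius subset heads the germination panel so dormancy metrics can
# be joined to soil outcomes by accession id.
.panel_accessions <- function(n) {
  ids <- sprintf("ACC%03d", seq_len(n))
  species <- rep_len(rep(.lupinest_species, each = ceiling(n / 3)), n)
  data.frame(accession_id = ids, species = species, stringsAsFactors = FALSE)
}

.exp1_accessions <- function(config) {
  panel <- .panel_accessions(config$n_accessions)
  ang <- panel$accession_id[panel$species == "angustifolius"]
  n1 <- config$exp1$n_accessions
  if (length(ang) >= n1) ang[seq_len(n1)] else sprintf("ANG%03d", seq_len(n1))
}

#' Simulate weekly germination censuses with a dormant fraction
#'
#' Each non-scarified seed is physically dormant (impermeable) with the
#' accession's dormant fraction; scarification sets that probability to
#' zero and rescales the germination-time distribution. Permeable seeds
#' draw a gamma germination time; dormant seeds are released at each
#' weekly census with a constant hazard and then germinate immediately.
#' Events are recorded at the first census on which they are observable;
#' trials are truncated at the horizon.
#'
#' Draw order is fixed (accessions in panel order, NS before S, seeds in
#' index order: one dormancy draw, then one time or release draw per
#' seed), so a given seed yields byte-identical output across runs.
#'
#' @param config A [sim_config()].
#' @return Long data frame in the `germination` schema.
#' @export
simulate_germination <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 101L)
  e1 <- config$exp1
  census_days <- seq(e1$census_interval, e1$horizon_days, by = e1$census_interval)
  ids <- .exp1_accessions(config)
  n_seeds <- config$seeds_per_unit
  out <- vector("list", length(ids) * 2L)
  k <- 0L
  for (i in seq_along(ids)) {
    for (trt in c("NS", "S")) {
      pi_d <- if (trt == "NS") e1$dormant_fraction[i] else 0
      mean_t <- e1$germ_time_mean * if (trt == "S") e1$scar_time_factor else 1
      scale_t <- mean_t / e1$germ_time_shape
      event_day <- rep(NA_real_, n_seeds)
      for (s in seq_len(n_seeds)) {
        if (stats::runif(1) < pi_d) {
          # dormant: geometric release over censuses, then germination at
          # the releasing census
          if (e1$release_hazard > 0) {
            rel <- stats::rgeom(1, e1$release_hazard) + 1L
            if (rel <= length(census_days)) event_day[s] <- census_days[rel]
          }
        } else {
          t <- stats::rgamma(1, shape = e1$germ_time_shape, scale = scale_t)
          idx <- which(census_days >= t)
          if (length(idx) > 0L) event_day[s] <- census_days[idx[1L]]
        }
      }
      cum <- vapply(census_days,
                    function(d) sum(!is.na(event_day) & event_day <= d), 0L)
      k <- k + 1L
      out[[k]] <- data.frame(accession_id = ids[i], treatment = trt,
                             n_sown = n_seeds, n_viable = n_seeds,
                             census_day = as.integer(census_days),
                             cum_germinated = as.integer(cum),
                             stringsAsFactors = FALSE)
    }
  }
  validate_table(do.call(rbind, out), "germination")
}

#' Simulate the multi-soil ordinal establishment trial
#'
#' Generates the full factorial accession x soil x treatment x block x
#' seed layout. Each seed's latent establishment propensity is
#' mu(species, soil) + accession intercept + beta_scar under scarification
#' plus standard logistic noise, thresholded through the ordered cutpoints
#' into a 0-5 score.
#'
#' @param config A [sim_config()].
#' @return Data frame in the `ordinal` schema.
#' @export
simulate_soil_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 202L)
  e2 <- config$exp2
  panel <- .panel_accessions(config$n_accessions)
  soils <- colnames(e2$mu)
  a_int <- stats::rnorm(nrow(panel), 0, e2$sigma_accession)
  grid <- expand.grid(seed_index = seq_len(config$seeds_per_unit),
                      block = seq_len(e2$n_blocks),
                      treatment = c("NS", "S"),
                      soil_code = soils,
                      acc = seq_len(nrow(panel)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eta <- e2$mu[cbind(panel$species[grid$acc], grid$soil_code)] +
    a_int[grid$acc] + e2$beta_scar * (grid$treatment == "S") +
    stats::rlogis(nrow(grid))
  score <- vapply(eta, function(v) sum(v > e2$cutpoints), 0L)
  df <- data.frame(accession_id = panel$accession_id[grid$acc],
                   species = panel$species[grid$acc],
                   soil_code = grid$soil_code,
                   block = as.integer(grid$block),
                   treatment = grid$treatment,
                   seed_index = as.integer(grid$seed_index),
                   score = as.integer(score),
                   stringsAsFactors = FALSE)
  validate_table(df[order(df$accession_id, df$soil_code, df$treatment,
                          df$block, df$seed_index), ], "ordinal")
}

#' Simulate the substrate pH x DAS seedling growth trial
#'
#' Hypocotyl and epicotyl lengths are drawn around pH x DAS cell means
#' scaled by a per-accession lognormal vigour multiplier, with normal
#' residual noise left-censored at zero; each organ is then independently
#' set missing with the configured probability, emulating seedlings
#' lacking one of the two measurements.
#'
#' @param config A [sim_config()].
#' @return Data frame in the `growth` schema (one row per seedling).
#' @export
simulate_ph_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 303L)
  e3 <- config$exp3
  panel <- .panel_accessions(config$n_accessions)
  vig <- exp(stats::rnorm(nrow(panel), 0, e3$accession_sd))
  sp_mult <- c(albus = 1.1, angustifolius = 0.95, luteus = 1.0)
  grid <- expand.grid(seedling = seq_len(config$seeds_per_unit),
                      replicate = seq_len(e3$n_replicates),
                      das = .lupinest_das_levels,
                      ph_level = .lupinest_ph_levels,
                      acc = seq_len(nrow(panel)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ph_key <- as.character(grid$ph_level)
  das_key <- as.character(grid$das)
  mult <- vig[grid$acc] * sp_mult[panel$species[grid$acc]]
  mu_h <- e3$mu_hypocotyl[cbind(ph_key, das_key)] * mult
  mu_e <- e3$mu_epicotyl[cbind(ph_key, das_key)] * mult
  n <- nrow(grid)
  hyp <- pmax(stats::rnorm(n, mu_h, e3$sigma), 0)
  epi <- pmax(stats::rnorm(n, mu_e, e3$sigma), 0)
  hyp[stats::runif(n) < e3$missing_prob] <- NA_real_
  epi[stats::runif(n) < e3$missing_prob] <- NA_real_
  df <- data.frame(accession_id = panel$accession_id[grid$acc],
                   species = panel$species[grid$acc],
                   ph_level = grid$ph_level,
                   das = as.integer(grid$das),
                   replicate = as.integer(grid$replicate),
                   hypocotyl_mm = round(hyp, 2),
                   epicotyl_mm = round(epi, 2),
                   stringsAsFactors = FALSE)
  validate_table(df[order(df$accession_id, df$ph_level, df$das,
                          df$replicate), ], "growth")
}
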