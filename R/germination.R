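# Germination and physical-dormancy analytics for long-duration weekly
# censuses: FGP, MGT, Maguire IVG, interpolated DDS50, PD, Kaplan-Meier
# curves, log-rank tests, and dormancy classification.

#' Construct a single germination trial
#'
#' One accession x treatment census series. Enforces the trial
#' invariants: strictly increasing census days in 1..365, non-decreasing
#' cumulative counts never exceeding the number of viable seeds.
#'
#' @param accession_id Accession identifier.
#' @param treatment `"NS"` (intact) or `"S"` (scarified).
#' @param n_sown Seeds sown.
#' @param n_viable Viable seeds (non-germinated seeds are
#'   viability-checked at the end of the assay).
#' @param census_days Ascending census days since sowing.
#' @param cum_germinated Cumulative germinated counts aligned to
#'   `census_days`.
#' @return Object of class `germination_trial`.
#' @export
germination_trial <- function(accession_id, treatment, n_sown, n_viable,
                              census_days, cum_germinated) {
  treatment <- match.arg(treatment, c("NS", "S"))
  stopifnot(length(census_days) == length(cum_germinated),
            length(census_days) >= 1L)
  if (n_viable > n_sown || n_viable < 0L)
    stop("need 0 <= n_viable <= n_sown", call. = FALSE)
  if (any(census_days < 1) || any(diff(census_days) <= 0))
    stop("census_days must be strictly increasing and >= 1", call. = FALSE)
  if (any(cum_germinated < 0) || any(diff(cum_germinated) < 0) ||
      any(cum_germinated > n_viable))
    stop("cum_germinated must be non-decreasing and <= n_viable", call. = FALSE)
  structure(list(accession_id = as.character(accession_id),
                 treatment = treatment,
                 n_sown = as.integer(n_sown), n_viable = as.integer(n_viable),
                 census_days = as.numeric(census_days),
                 cum_germinated = as.integer(cum_germinated)),
            class = "germination_trial")
}

#' Split a germination table into trials
#'
#' @param df Data frame in the `germination` schema.
#' @return Named list of [germination_trial()] objects
#'   (`accession_id.treatment`).
#' @export
as_germination_trials <- function(df) {
  df <- validate_table(df, "germination")
  key <- interaction(df$accession_id, df$treatment, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$census_day), ]
    germination_trial(d$accession_id[1L], d$treatment[1L], d$n_sown[1L],
                      d$n_viable[1L], d$census_day, d$cum_germinated)
  })
}

# per-census newly germinated counts
.new_events <- function(trial) diff(c(0L, trial$cum_germinated))

# event day for each germinated seed (census day of first observation)
.event_days <- function(trial) rep(trial$census_days, .new_events(trial))

#' Final germination percentage
#'
#' 100 x (final cumulative germinated) / (viable seeds).
#'
#' @param trial A [germination_trial()].
#' @return Percentage in \\[0, 100\\].
#' @export
compute_fgp <- function(trial) {
  stopifnot(inherits(trial, "germination_trial"))
  if (trial$n_viable == 0L)
    stop("FGP undefined: no viable seeds", call. = FALSE)
  100 * utils::tail(trial$cum_germinated, 1L) / trial$n_viable
}

#' Mean germination time
#'
#' Average event day over germinated seeds only; `NA` when no seed
#' germinated (an undefined mean, not an error).
#'
#' @param trial A [germination_trial()].
#' @return Days, or `NA_real_`.
#' @export
compute_mgt <- function(trial) {
  stopifnot(inherits(trial, "germination_trial"))
  ev <- .event_days(trial)
  if (length(ev) == 0L) return(NA_real_)
  mean(ev)
}

#' Germination velocity index (Maguire)
#'
#' Sum over censuses of newly germinated seeds divided by the census day:
#' higher for faster, more synchronous germination.
#'
#' @param trial A [germination_trial()].
#' @return Per-day index, >= 0.
#' @export
compute_ivg <- function(trial) {
  stopifnot(inherits(trial, "germination_trial"))
  sum(.new_events(trial) / trial$census_days)
}

#' Days to 50 percent cumulative germination
#'
#' First crossing of 50% of the viable seeds on the cumulative census
#' curve, linearly interpolated between the bracketing censuses (the
#' curve starts at 0 on day 0). When the final cumulative fraction never
#' reaches 50%, the value is right-censored at the horizon.
#'
#' @param trial A [germination_trial()].
#' @param horizon Censoring horizon in days (default 365).
#' @return List with `days` (interpolated crossing day, or the horizon
#'   when censored) and `censored` (logical).
#' @export
compute_dds50 <- function(trial, horizon = 365) {
  stopifnot(inherits(trial, "germination_trial"))
  frac <- trial$cum_germinated / trial$n_viable
  if (utils::tail(frac, 1L) < 0.5)
    return(list(days = as.numeric(horizon), censored = TRUE))
  i <- which(frac >= 0.5)[1L]
  if (frac[i] == 0.5) return(list(days = trial$census_days[i], censored = FALSE))
  d0 <- if (i == 1L) 0 else trial$census_days[i - 1L]
  f0 <- if (i == 1L) 0 else frac[i - 1L]
  days <- d0 + (trial$census_days[i] - d0) * (0.5 - f0) / (frac[i] - f0)
  list(days = days, censored = FALSE)
}

#' Physical dormancy percentage
#'
#' PD = 100 - FGP of the non-scarified treatment, i.e. the percentage of
#' viable intact seeds that failed to germinate within the assay.
#'
#' @param ns_trial A non-scarified [germination_trial()].
#' @return Percentage in \\[0, 100\\].
#' @export
compute_pd <- function(ns_trial) {
  stopifnot(inherits(ns_trial, "germination_trial"))
  if (ns_trial$treatment != "NS")
    stop("PD is defined for the non-scarified (NS) treatment only",
         call. = FALSE)
  100 - compute_fgp(ns_trial)
}

#' Per-trial germination metrics table
#'
#' Computes FGP, MGT, IVG, DDS50 (with censoring flag) for every
#' accession x treatment trial, and PD for NS trials.
#'
#' @param df Data frame in the `germination` schema.
#' @param horizon Censoring horizon for DDS50 (days).
#' @return Data frame with one row per accession x treatment.
#' @export
germination_metrics <- function(df, horizon = 365) {
  trials <- as_germination_trials(df)
  rows <- lapply(trials, function(tr) {
    d50 <- compute_dds50(tr, horizon)
    data.frame(accession_id = tr$accession_id, treatment = tr$treatment,
               n_viable = tr$n_viable,
               fgp = compute_fgp(tr), mgt = compute_mgt(tr),
               ivg = compute_ivg(tr),
               dds50 = d50$days, dds50_censored = d50$censored,
               pd = if (tr$treatment == "NS") compute_pd(tr) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$accession_id, out$treatment), ]
}

#' Germination event/censoring times of a trial
#'
#' Germinated seeds contribute their first-observation census day as an
#' event; seeds still ungerminated at the last census are right-censored
#' there.
#'
#' @param trial A [germination_trial()].
#' @return List with numeric `events` and `censored` day vectors.
#' @export
trial_event_times <- function(trial) {
  stopifnot(inherits(trial, "germination_trial"))
  ev <- .event_days(trial)
  n_cens <- trial$n_viable - utils::tail(trial$cum_germinated, 1L)
  list(events = ev,
       censored = rep(utils::tail(trial$census_days, 1L), n_cens))
}

#' Kaplan-Meier curve of time to germination
#'
#' Product-limit estimate of the probability of remaining ungerminated,
#' with the number of seeds still at risk and events at each event time.
#'
#' @param event_days Germination days (events).
#' @param censored_days Right-censoring days (seeds never germinating
#'   within the horizon).
#' @return Object of class `survival_curve`: list with `times`,
#'   `survival`, `at_risk`, `n_events`.
#' @export
km_estimate <- function(event_days, censored_days = numeric()) {
  if (length(event_days) + length(censored_days) == 0L)
    stop("no observations", call. = FALSE)
  if (any(c(event_days, censored_days) < 1))
    stop("all days must be >= 1", call. = FALSE)
  time <- c(event_days, censored_days)
  status <- rep(c(1L, 0L), c(length(event_days), length(censored_days)))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_events = fit$n.event[keep]),
            class = "survival_curve")
}

#' Log-rank test across labelled germination-time groups
#'
#' Standard log-rank chi-square comparing the time-to-germination
#' distributions of two or more groups, with df = groups - 1.
#'
#' @param groups Named list; each element a list with numeric `events`
#'   and `censored` day vectors (as from [trial_event_times()]).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, function(g) length(g$events) + length(g$censored), 0L)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  time <- unlist(lapply(groups, function(g) c(g$events, g$censored)))
  status <- unlist(lapply(groups, function(g)
    rep(c(1L, 0L), c(length(g$events), length(g$censored)))))
  grp <- rep(names(groups), sizes)
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  df <- length(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Classify accessions into dormancy classes from NS metrics
#'
#' Standardizes the four non-scarified germination metrics with dormancy
#' as the positive direction (MGT and DDS50 as-is, FGP and IVG
#' sign-flipped), takes the first principal axis of the standardized
#' matrix as a continuous dormancy score (oriented so the score increases
#' with dormancy), and splits the score at its tertiles into ordered
#' classes low < intermediate < high. Undefined MGT (no germination) is
#' treated as the horizon; censored DDS50 enters at the horizon value.
#' When all accessions have identical metrics every accession is assigned
#' `low` (documented tie rule).
#'
#' @param metrics_ns NS rows of [germination_metrics()] (>= 3 accessions).
#' @return Data frame `accession_id`, `dormancy_score`, `dormancy_class`
#'   (ordered factor).
#' @export
classify_dormancy <- function(metrics_ns) {
  stopifnot(all(c("accession_id", "fgp", "mgt", "ivg", "dds50")
                %in% names(metrics_ns)))
  if (any(metrics_ns$treatment != "NS"))
    stop("dormancy classification uses NS metrics only", call. = FALSE)
  if (nrow(metrics_ns) < 3L) stop("need >= 3 accessions", call. = FALSE)
  horizon <- max(365, metrics_ns$dds50, na.rm = TRUE)
  x <- cbind(mgt = ifelse(is.na(metrics_ns$mgt), horizon, metrics_ns$mgt),
             dds50 = metrics_ns$dds50,
             fgp = -metrics_ns$fgp, ivg = -metrics_ns$ivg)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  lev <- c("low", "intermediate", "high")
  if (!any(keep)) {
    score <- rep(0, nrow(x))
  } else {
    z <- scale(x[, keep, drop = FALSE])
    if (sum(keep) == 1L) {
      score <- as.numeric(z)
    } else {
      pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
      score <- as.numeric(pc$x[, 1L])
      # orient: score must increase with the dormancy-positive inputs
      if (sum(pc$rotation[, 1L]) < 0) score <- -score
    }
  }
  if (stats::sd(score) == 0) {
    cls <- factor(rep("low", length(score)), levels = lev, ordered = TRUE)
  } else {
    br <- unique(stats::quantile(score, c(0, 1 / 3, 2 / 3, 1)))
    cls_idx <- findInterval(score, br, rightmost.closed = TRUE,
                            all.inside = TRUE)
    # map the (possibly collapsed) tertile bins onto the ordered labels
    cls <- factor(lev[pmin(cls_idx, 3L)], levels = lev, ordered = TRUE)
  }
  data.frame(accession_id = metrics_ns$accession_id,
             dormancy_score = score, dormancy_class = cls,
             stringsAsFactors = FALSE)
}
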