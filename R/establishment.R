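# Multi-soil ordinal establishment analytics: outcome derivation from the
# 0-5 score, group rates with Wilson binomial intervals, the accession x
# soil establishment matrix, a self-contained IRLS logistic fit, and the
# dormancy-vs-establishment correlation test.

#' Derive the three nested binary outcomes from an ordinal score
#'
#' On the 0-5 establishment scale (0 = no change, 1 = seed coat rupture,
#' 2 = radicle emergence, 3 = cotyledon emergence, 4 = arrested growth or
#' fungal damage, 5 = fully established): germination is score >= 1,
#' cotyledon emergence is score >= 3, establishment is score = 5. Score 4
#' therefore counts toward germination and cotyledon emergence but never
#' toward establishment: it is a failure mode, not a stage.
#'
#' @param score Integer vector of scores in 0..5.
#' @return Data frame with logical columns `germinated`, `cotyledon`,
#'   `established`.
#' @export
derive_outcomes <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 5 | score != round(score)))
    stop("score must be an integer in 0..5", call. = FALSE)
  data.frame(germinated = score >= 1, cotyledon = score >= 3,
             established = score == 5)
}

#' Wilson score interval for a binomial proportion
#'
#' Boundary-safe score interval; at x = 0 the lower bound is 0 and at
#' x = n the upper bound is 1.
#'
#' @param x Successes.
#' @param n Trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Matrix with columns `low`, `high` (one row per input).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # boundary cases are exact: [0, .] at x = 0 and [., 1] at x = n
  cbind(low = ifelse(x == 0, 0, pmax(centre - half, 0)),
        high = ifelse(x == n, 1, pmin(centre + half, 1)))
}

#' Outcome rates by group with 95 percent Wilson intervals
#'
#' Aggregates the three nested outcomes over any grouping of the ordinal
#' records (accession, species, soil, treatment, ...). Rates preserve the
#' nesting establishment <= cotyledon <= germination within every group.
#'
#' @param records Data frame in the `ordinal` schema.
#' @param group_by Character vector of grouping columns.
#' @param conf Confidence level.
#' @return Data frame with `n`, the three rates, and `*_low` / `*_high`
#'   Wilson bounds per rate.
#' @export
aggregate_rates <- function(records, group_by = c("soil_code", "treatment"),
                            conf = 0.95) {
  records <- validate_table(records, "ordinal")
  stopifnot(all(group_by %in% names(records)))
  oc <- derive_outcomes(records$score)
  key <- interaction(records[group_by], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(ii) {
    n <- length(ii)
    out <- records[ii[1L], group_by, drop = FALSE]
    out$n <- n
    for (nm in c("germinated", "cotyledon", "established")) {
      x <- sum(oc[[nm]][ii])
      ci <- wilson_ci(x, n, conf)
      rate_nm <- sub("germinated", "germination",
                     sub("established", "establishment", nm))
      out[[paste0(rate_nm, "_rate")]] <- x / n
      out[[paste0(rate_nm, "_low")]] <- ci[, "low"]
      out[[paste0(rate_nm, "_high")]] <- ci[, "high"]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accession x soil matrix of percent establishment
#'
#' Cell value = establishment rate (score 5) computed per treatment and
#' averaged over the treatments present, expressed as a percentage.
#' Accession x soil cells with no observations stay `NA` (flagged, never
#' zero-filled).
#'
#' @param records Data frame in the `ordinal` schema.
#' @return Numeric matrix, rows = accessions, columns = soils.
#' @export
establishment_matrix <- function(records) {
  records <- validate_table(records, "ordinal")
  est <- derive_outcomes(records$score)$established
  accs <- sort(unique(records$accession_id))
  soils <- sort(unique(records$soil_code))
  m <- matrix(NA_real_, length(accs), length(soils),
              dimnames = list(accs, soils))
  key <- paste(records$accession_id, records$soil_code, records$treatment,
               sep = "\r")
  rate_by_trt <- tapply(est, key, mean)
  parts <- strsplit(names(rate_by_trt), "\r", fixed = TRUE)
  cell <- paste(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
                sep = "\r")
  cell_mean <- tapply(rate_by_trt, cell, mean)
  cp <- strsplit(names(cell_mean), "\r", fixed = TRUE)
  m[cbind(vapply(cp, `[`, "", 1L), vapply(cp, `[`, "", 2L))] <-
    100 * as.numeric(cell_mean)
  m
}

# IRLS fit of a binomial logistic regression; X must be full rank.
.irls_logistic <- function(X, y, max_iter = 100L, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    wX <- X * sqrt(w)
    beta_new <- qr.solve(qr(wX), sqrt(w) * z)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (delta < tol * (1 + max(abs(beta))) || max(abs(beta)) > 30) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmin(pmax(mu * (1 - mu), 1e-12), 0.25)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  list(coef = beta, cov = cov, fitted = mu, deviance = dev, iter = it)
}

#' Fixed-effects logistic regression of a derived outcome
#'
#' Fits a binomial logistic model by iteratively reweighted least squares
#' to one of the three nested outcomes derived from the ordinal score.
#' Accession-level clustering is handled by aggregation elsewhere, not by
#' random intercepts; coefficients are population-level fixed effects and
#' the output metadata records this approximation.
#'
#' @param records Data frame in the `ordinal` schema.
#' @param outcome One of `"germinated"`, `"cotyledon"`, `"established"`.
#' @param design Model formula in the record columns (right-hand side),
#'   default `~ species * soil_code + treatment`.
#' @param conf Confidence level for Wald intervals.
#' @return List with `coefficients` (term, estimate, se, z, p, odds
#'   ratio with Wald CI), `deviance`, `n`, and `meta` (fixed-effects
#'   approximation note).
#' @export
fit_logistic <- function(records, outcome = c("germinated", "cotyledon",
                                              "established"),
                         design = ~ species * soil_code + treatment,
                         conf = 0.95) {
  records <- validate_table(records, "ordinal")
  outcome <- match.arg(outcome)
  y <- as.numeric(derive_outcomes(records$score)[[outcome]])
  if (length(unique(y)) < 2L)
    stop(sprintf("outcome '%s' is constant: degenerate fit", outcome),
         call. = FALSE)
  X <- stats::model.matrix(design, data = records)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank deficient; aliased term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- .irls_logistic(X, y)
  if (is.null(fit$cov) || any(abs(fit$coef) > 15) ||
      any(!is.finite(fit$coef)))
    stop("complete or quasi-complete separation detected: estimates diverge",
         call. = FALSE)
  se <- sqrt(diag(fit$cov))
  z <- fit$coef / se
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  coefs <- data.frame(term = colnames(X), estimate = fit$coef, se = se,
                      z = z, p = 2 * stats::pnorm(-abs(z)),
                      or = exp(fit$coef),
                      or_low = exp(fit$coef - zc * se),
                      or_high = exp(fit$coef + zc * se),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  list(coefficients = coefs, deviance = fit$deviance, n = length(y),
       iterations = fit$iter,
       meta = paste("fixed-effects logistic (IRLS);",
                    "accession clustering handled by aggregation,",
                    "not random intercepts"))
}

#' Correlate dormancy (DDS50) with establishment, per soil
#'
#' Pearson correlation between per-accession days-to-50%-germination and
#' per-accession establishment percentage within each soil, with
#' Fisher-z 95% confidence intervals and two-sided p-values. Accessions
#' whose DDS50 is right-censored are excluded and counted.
#'
#' @param dds50 Data frame with `accession_id`, `dds50`,
#'   `dds50_censored` (NS metrics).
#' @param est_matrix Accession x soil percent matrix from
#'   [establishment_matrix()].
#' @param conf Confidence level.
#' @return Data frame per soil: `n`, `n_censored_excluded`, `r`,
#'   `ci_low`, `ci_high`, `p` (`r` is `NA` with a note when a variable
#'   has zero variance).
#' @export
correlate_dormancy_establishment <- function(dds50, est_matrix, conf = 0.95) {
  stopifnot(all(c("accession_id", "dds50", "dds50_censored") %in% names(dds50)))
  usable <- dds50[!dds50$dds50_censored, , drop = FALSE]
  n_censored <- sum(dds50$dds50_censored)
  rows <- lapply(colnames(est_matrix), function(soil) {
    est <- est_matrix[, soil]
    common <- intersect(usable$accession_id, rownames(est_matrix)[!is.na(est)])
    x <- usable$dds50[match(common, usable$accession_id)]
    y <- est[common]
    n <- length(common)
    if (n < 4L)
      stop(sprintf("soil %s: need >= 4 accessions with both values", soil),
           call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(soil_code = soil, n = n,
                        n_censored_excluded = n_censored,
                        r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, note = "zero variance",
                        stringsAsFactors = FALSE))
    r <- stats::cor(x, y)
    zc <- stats::qnorm(1 - (1 - conf) / 2)
    fz <- atanh(r)
    se <- 1 / sqrt(n - 3)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(soil_code = soil, n = n, n_censored_excluded = n_censored,
               r = r, ci_low = tanh(fz - zc * se), ci_high = tanh(fz + zc * se),
               p = 2 * stats::pt(-abs(tt), n - 2), note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
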