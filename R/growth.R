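# Substrate-pH x developmental-time growth analytics: trait derivation
# and the missing-organ exclusion rule, two-way factorial ANOVA (type II),
# seeded permutation max-|t| pairwise contrasts, polynomial pH response,
# and logit-allocation regression.

#' Derive growth and allocation traits per seedling
#'
#' Adds, for every record with both organs measured: total length
#' (hypocotyl + epicotyl, mm), hypocotyl-to-epicotyl ratio with the 1 mm
#' stabilizing constant (hypocotyl / (epicotyl + 1)), hypocotyl
#' allocation (hypocotyl / total), and the establishment flag
#' (total >= 30 mm, inclusive). Records lacking either organ are retained
#' with `valid = FALSE` and no traits, and are excluded from growth and
#' allocation analyses downstream.
#'
#' @param records Data frame in the `growth` schema.
#' @return The records with added columns `valid`, `total_mm`, `ratio`,
#'   `allocation`, `established`.
#' @export
derive_growth_traits <- function(records) {
  records <- validate_table(records, "growth")
  valid <- !is.na(records$hypocotyl_mm) & !is.na(records$epicotyl_mm)
  total <- ifelse(valid, records$hypocotyl_mm + records$epicotyl_mm, NA_real_)
  records$valid <- valid
  records$total_mm <- total
  records$ratio <- ifelse(valid, records$hypocotyl_mm / (records$epicotyl_mm + 1),
                          NA_real_)
  records$allocation <- ifelse(valid & total > 0, records$hypocotyl_mm / total,
                               ifelse(valid, 0.5, NA_real_))
  records$established <- ifelse(valid, total >= 30, NA)
  records
}

#' Apply the missing-organ exclusion rule
#'
#' Retains seedlings with both organs measured and reports how many were
#' excluded, overall and per pH x DAS stratum.
#'
#' @param traits Output of [derive_growth_traits()].
#' @return List: `retained` (valid records), `n_excluded`, and
#'   `excluded_by_stratum` (pH x DAS counts).
#' @export
filter_valid <- function(traits) {
  stopifnot("valid" %in% names(traits))
  excl <- traits[!traits$valid, , drop = FALSE]
  by_stratum <- as.data.frame(table(ph_level = excl$ph_level, das = excl$das),
                              stringsAsFactors = FALSE)
  names(by_stratum)[3L] <- "n_excluded"
  list(retained = traits[traits$valid, , drop = FALSE],
       n_excluded = nrow(excl),
       excluded_by_stratum = by_stratum)
}

#' Two-way factorial ANOVA with interaction (type II sums of squares)
#'
#' Fits `response ~ A * B` and reports type-II sums of squares, F and
#' upper-tail p per source plus the residual line. In the balanced
#' designs generated here type I and type II coincide. Empty factor
#' cells raise an explicit design-imbalance error naming the cell.
#'
#' @param data Data frame of valid trait records.
#' @param response Response column name.
#' @param factors Length-2 character vector of factor column names
#'   (default pH level and DAS).
#' @return Data frame with rows `A`, `B`, `A:B`, `Residuals` and columns
#'   `ss`, `df`, `f`, `p`.
#' @export
anova_two_way <- function(data, response,
                          factors = c("ph_level", "das")) {
  stopifnot(length(factors) == 2L, all(c(response, factors) %in% names(data)))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  a <- factor(data[[factors[1L]]])
  b <- factor(data[[factors[2L]]])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("each factor needs >= 2 observed levels", call. = FALSE)
  tab <- table(a, b)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", factors[1L],
                 rownames(tab)[empty[1L]], factors[2L],
                 colnames(tab)[empty[2L]]), call. = FALSE)
  }
  if (nrow(data) - nlevels(a) * nlevels(b) < 1L)
    stop("no residual degrees of freedom", call. = FALSE)
  d <- data.frame(y = data[[response]], A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = d)
  an <- car::Anova(fit, type = 2)
  src <- c("A", "B", "A:B", "Residuals")
  out <- data.frame(source = c(factors, paste(factors, collapse = ":"),
                               "Residuals"),
                    ss = an[src, "Sum Sq"], df = an[src, "Df"],
                    f = c(an[src[1:3], "F value"], NA),
                    p = c(an[src[1:3], "Pr(>F)"], NA),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pairwise contrasts with seeded permutation max-|t| adjustment
#'
#' For every pair of groups: mean difference and pooled-variance
#' two-sample t statistic. Family-wise adjusted p-values come from a
#' seeded permutation null of the maximum |t| over all pairs (group
#' labels permuted), which controls the family-wise error rate without
#' the studentized-range distribution. With exactly two groups the
#' adjusted p equals the unadjusted permutation p.
#'
#' @param data Data frame of valid trait records.
#' @param response Response column name.
#' @param group Grouping column name (a factor or factor combination).
#' @param n_perm Number of label permutations (default 999).
#' @param rng_seed Seed for the permutation stream.
#' @return Data frame per pair: `group1`, `group2`, `diff`, `t`,
#'   `p_adjusted`.
#' @export
pairwise_contrasts <- function(data, response, group, n_perm = 999L,
                               rng_seed = 1L) {
  stopifnot(all(c(response, group) %in% names(data)))
  y <- data[[response]]
  g <- factor(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs >= 2 observations", call. = FALSE)
  pair_t <- function(y, g) {
    lev <- levels(g)
    ns <- tabulate(g)
    means <- tapply(y, g, mean)
    vars <- tapply(y, g, stats::var)
    pairs <- utils::combn(seq_along(lev), 2L)
    apply(pairs, 2L, function(ij) {
      i <- ij[1L]; j <- ij[2L]
      sp2 <- ((ns[i] - 1) * vars[i] + (ns[j] - 1) * vars[j]) /
        (ns[i] + ns[j] - 2)
      (means[i] - means[j]) / sqrt(sp2 * (1 / ns[i] + 1 / ns[j]))
    })
  }
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2L)
  t_obs <- pair_t(y, g)
  means <- tapply(y, g, mean)
  set.seed(rng_seed)
  exceed <- rep(0L, length(t_obs))
  for (b in seq_len(n_perm)) {
    t_b <- pair_t(y, sample(g))
    m <- max(abs(t_b))
    exceed <- exceed + (m >= abs(t_obs))
  }
  p_adj <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(group1 = lev[pairs[1L, ]], group2 = lev[pairs[2L, ]],
                    diff = as.numeric(means[pairs[1L, ]] - means[pairs[2L, ]]),
                    t = as.numeric(t_obs), p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Polynomial regression of a trait on the pH gradient
#'
#' Least-squares polynomial in centered pH (raw polynomial basis), with
#' R-squared. A fit whose degree equals the number of distinct pH levels
#' minus one is saturated in the level means and is flagged as
#' interpolating.
#'
#' @param data Data frame of valid trait records.
#' @param response Response column name.
#' @param degree Polynomial degree, 1 or 2 (default 2: three design
#'   levels).
#' @return List with `coefficients` (term, estimate, se, t, p),
#'   `r_squared`, `center` (pH centering constant), `saturated`.
#' @export
polynomial_ph_response <- function(data, response, degree = 2L) {
  stopifnot(response %in% names(data), degree >= 1L)
  d <- data[!is.na(data[[response]]) & !is.na(data$ph_level), , drop = FALSE]
  levs <- sort(unique(d$ph_level))
  if (length(levs) < degree + 1L)
    stop(sprintf("degree %d needs >= %d distinct pH levels (have %d)",
                 degree, degree + 1L, length(levs)), call. = FALSE)
  centre <- mean(levs)
  ph_c <- d$ph_level - centre
  X <- stats::poly(ph_c, degree = degree, raw = TRUE)
  fit <- stats::lm(d[[response]] ~ X)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  out <- data.frame(term = c("(Intercept)", paste0("ph_c^", seq_len(degree))),
                    estimate = cf[, 1L], se = cf[, 2L], t = cf[, 3L],
                    p = cf[, 4L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(coefficients = out, r_squared = sm$r.squared, center = centre,
       saturated = degree == length(levs) - 1L)
}

#' Linear regression of logit-transformed hypocotyl allocation
#'
#' Clamps the allocation proportion to [eps, 1 - eps] (eps = 0.005 by
#' default), applies the logit, and fits ordinary least squares on the
#' stated predictors. Emits a degenerate-response warning when every
#' value sits at a single clamped bound.
#'
#' @param traits Valid trait records with an `allocation` column.
#' @param design Right-hand-side model formula in the trait columns
#'   (default `~ ph_level * das`).
#' @param eps Clamping constant.
#' @return List with `coefficients` (term, estimate, se, t, p) and
#'   `r_squared`.
#' @export
logit_allocation_regression <- function(traits, design = ~ ph_level * das,
                                        eps = 0.005) {
  stopifnot("allocation" %in% names(traits), eps > 0, eps < 0.5)
  d <- traits[!is.na(traits$allocation), , drop = FALSE]
  if (any(d$allocation < 0 | d$allocation > 1))
    stop("allocation must lie in [0, 1]", call. = FALSE)
  a <- pmin(pmax(d$allocation, eps), 1 - eps)
  if (length(unique(a)) == 1L && (a[1L] %in% c(eps, 1 - eps)))
    warning("degenerate response: all allocations at a clamped bound")
  y <- stats::qlogis(a)
  X <- stats::model.matrix(design, data = d)
  fit <- stats::lm.fit(X, y)
  res <- y - drop(X %*% fit$coefficients)
  rdf <- length(y) - fit$rank
  s2 <- sum(res^2) / rdf
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXi) * s2)
  tval <- fit$coefficients / se
  tss <- sum((y - mean(y))^2)
  out <- data.frame(term = colnames(X), estimate = fit$coefficients,
                    se = se, t = tval,
                    p = 2 * stats::pt(-abs(tval), rdf),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(coefficients = out, r_squared = 1 - sum(res^2) / tss)
}
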