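# Shared fixture builders: all fixtures are generated in code.

make_trial <- function(census_days, cum, n_viable = max(cum), n_sown = n_viable,
                       treatment = "NS", accession_id = "A1") {
  germination_trial(accession_id, treatment, n_sown, n_viable,
                    census_days, cum)
}

# long-format germination table from per-trial event days
germ_table <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(accession_id = tr$accession_id, treatment = tr$treatment,
               n_sown = tr$n_sown, n_viable = tr$n_viable,
               census_day = as.integer(tr$census_days),
               cum_germinated = tr$cum_germinated,
               stringsAsFactors = FALSE)
  }))
}

# minimal ordinal records with given scores in one group
ordinal_records <- function(scores, accession_id = "A1", species = "albus",
                            soil_code = "BV", block = 1L, treatment = "NS") {
  data.frame(accession_id = accession_id, species = species,
             soil_code = soil_code, block = block, treatment = treatment,
             seed_index = seq_along(scores), score = as.integer(scores),
             stringsAsFactors = FALSE)
}

growth_records <- function(hyp, epi, accession_id = "A1", species = "albus",
                           ph_level = 7.0, das = 14L, replicate = 1L) {
  data.frame(accession_id = accession_id, species = species,
             ph_level = ph_level, das = as.integer(das),
             replicate = as.integer(replicate),
             hypocotyl_mm = hyp, epicotyl_mm = epi, stringsAsFactors = FALSE)
}

# hand-coded product-limit estimator (independent of the survival package)
km_oracle <- function(events, censored) {
  time <- c(events, censored)
  status <- rep(c(1, 0), c(length(events), length(censored)))
  ts <- sort(unique(events))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_, at_risk = NA_real_,
                    d = NA_real_)
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(events == ts[i])
    s <- s * (1 - d_i / n_i)
    out$surv[i] <- s; out$at_risk[i] <- n_i; out$d[i] <- d_i
  }
  out
}

# type-II sums of squares by explicit least-squares projections
anova2_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  X_a <- stats::model.matrix(~a); X_b <- stats::model.matrix(~b)
  X_ab <- stats::model.matrix(~ a + b)
  X_full <- stats::model.matrix(~ a * b)
  ss_a <- rss(X_b) - rss(X_ab)
  ss_b <- rss(X_a) - rss(X_ab)
  ss_int <- rss(X_ab) - rss(X_full)
  ss_res <- rss(X_full)
  df <- c(nlevels(a) - 1, nlevels(b) - 1,
          (nlevels(a) - 1) * (nlevels(b) - 1),
          length(y) - nlevels(a) * nlevels(b))
  ms_res <- ss_res / df[4]
  data.frame(ss = c(ss_a, ss_b, ss_int, ss_res), df = df,
             f = c(ss_a / df[1], ss_b / df[2], ss_int / df[3], NA) / ms_res)
}

# brute-force Ward.D2 agglomeration via the Lance-Williams recurrence
ward_oracle <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), function(i) i)
  merges <- list(); heights <- numeric()
  id <- seq_len(n) * -1  # hclust convention: negatives are leaves
  cur <- d2
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- c(NA, NA); best_v <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      v <- cur[active[i], active[j]]
      if (v < best_v - 1e-12) { best_v <- v; best <- c(active[i], active[j]) }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1L]] <- sort(c(members[[i]], members[[j]]))
    heights <- c(heights, sqrt(best_v))
    ni <- sizes[i]; nj <- sizes[j]
    for (m in setdiff(active, c(i, j))) {
      nm <- sizes[m]
      cur[i, m] <- cur[m, i] <-
        ((ni + nm) * cur[i, m] + (nj + nm) * cur[j, m] - nm * best_v) /
        (ni + nj + nm)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(leaf_sets = merges, heights = heights)
}

# leaf sets of an hclust object in merge order
hclust_leaf_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  sets
}

# Benjamini-Hochberg step-up by direct enumeration
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}
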