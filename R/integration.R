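# Cross-experiment synthesis: z-score standardization, PCA, Ward.D2
# clustering with silhouette and bootstrap co-clustering support, a
# Spearman/Benjamini-Hochberg correlation screen, the Integrated
# Selection Index, and soil-matched accession recommendations.

#' Z-score standardize an accession x trait table
#'
#' Centers and scales every trait column to mean 0 and SD 1 (sample SD,
#' n - 1 denominator). Constant or all-missing columns cannot be
#' standardized and are dropped with a warning.
#'
#' @param x Numeric matrix or data frame with accessions as rows
#'   (rownames kept).
#' @return Standardized numeric matrix.
#' @export
zscore_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need >= 2 rows", call. = FALSE)
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  bad <- is.na(sds) | sds == 0
  if (any(bad)) {
    warning(sprintf("dropping constant or all-missing column(s): %s",
                    paste(colnames(x)[bad], collapse = ", ")))
    x <- x[, !bad, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no non-constant columns left", call. = FALSE)
  scale(x)[, , drop = FALSE]
}

#' Principal component analysis with deterministic sign convention
#'
#' Eigendecomposition of the covariance of the (already standardized)
#' input; components are ordered by decreasing variance and each loading
#' column's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param x Standardized matrix from [zscore_matrix()].
#' @return List with `loadings` (trait x component), `scores`
#'   (accession x component), `var_explained` (percent per component,
#'   summing to 100).
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  if (all(apply(x, 2L, stats::sd) == 0))
    stop("matrix has no variance", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  list(loadings = loadings, scores = scores,
       var_explained = 100 * pc$sdev^2 / sum(pc$sdev^2))
}

# leaf sets of every internal node of an hclust tree, as sorted label keys
.clade_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
    sets[[i]] <- c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L]))
  }
  sets
}

#' Ward.D2 hierarchical clustering with silhouette and bootstrap support
#'
#' Agglomerates accessions by Ward.D2 on Euclidean distances, cuts at
#' `k` clusters, reports the mean silhouette width at that cut, and
#' attaches an ordinary-bootstrap co-clustering support to every internal
#' node: rows are resampled with replacement, the resample is
#' re-clustered, and a node counts as recovered when its member
#' accessions present in the resample appear together as a clade (with no
#' outside accession). Resamples in which fewer than two distinct members
#' or no non-member survive are uninformative for that node and are not
#' counted in its denominator.
#'
#' @param x Standardized matrix from [zscore_matrix()] (rownames =
#'   accessions).
#' @param k Number of clusters, 2 <= k <= n - 1.
#' @param bootstrap_reps Bootstrap resamples (default 100).
#' @param rng_seed Seed for the resampling stream.
#' @return List with `hclust`, `labels` (cluster per accession),
#'   `mean_silhouette`, `node_support` (per internal node: size and
#'   support proportion).
#' @export
ward_cluster <- function(x, k, bootstrap_reps = 100L, rng_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(n))
  if (k < 2L || k > n - 1L) stop("need 2 <= k <= n - 1", call. = FALSE)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  sil <- cluster::silhouette(labels, stats::dist(x))
  mean_sil <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
  sets <- .clade_sets(hc)
  hits <- rep(0L, length(sets))
  valid <- rep(0L, length(sets))
  if (bootstrap_reps > 0L) {
    set.seed(rng_seed)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      rownames(xb) <- make.unique(rownames(x)[idx])
      hb <- stats::hclust(stats::dist(xb), method = "ward.D2")
      labs_b <- rownames(x)[idx]
      present <- unique(labs_b)
      # clades of the bootstrap tree, reduced to distinct original labels
      orig_of <- function(v) unique(sub("\\.\\d+$", "", v))
      keys_b <- unique(vapply(.clade_sets(hb), function(s)
        paste(sort(orig_of(s)), collapse = "\r"), ""))
      for (i in seq_along(sets)) {
        s <- sets[[i]]
        sp <- intersect(s, present)
        if (length(sp) < 2L || length(setdiff(present, s)) < 1L) next
        valid[i] <- valid[i] + 1L
        if (paste(sort(sp), collapse = "\r") %in% keys_b)
          hits[i] <- hits[i] + 1L
      }
    }
  }
  support <- ifelse(valid > 0L, hits / valid, NA_real_)
  list(hclust = hc, labels = labels, mean_silhouette = mean_sil,
       node_support = data.frame(node = seq_along(sets),
                                 size = lengths(sets),
                                 support = support))
}

#' Pairwise Spearman screen with bootstrap CIs and BH correction
#'
#' Spearman's rho on midranks for every trait pair, a percentile
#' bootstrap 95% confidence interval (rows resampled with replacement),
#' a two-sided p-value, and Benjamini-Hochberg step-up q-values over all
#' tested pairs. Pairs involving a constant trait are reported with an
#' undefined marker and skipped by the correction.
#'
#' @param x Accession x trait matrix or data frame.
#' @param bootstrap_reps Bootstrap resamples (default 500).
#' @param rng_seed Seed for the bootstrap stream.
#' @param conf Confidence level.
#' @return Data frame per pair: `trait1`, `trait2`, `n`, `rho`,
#'   `ci_low`, `ci_high`, `p`, `q`.
#' @export
spearman_screen <- function(x, bootstrap_reps = 500L, rng_seed = 1L,
                            conf = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 traits", call. = FALSE)
  pairs <- utils::combn(colnames(x), 2L)
  set.seed(rng_seed)
  alpha <- 1 - conf
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    t1 <- pairs[1L, j]; t2 <- pairs[2L, j]
    ok <- stats::complete.cases(x[, c(t1, t2)])
    u <- x[ok, t1]; v <- x[ok, t2]
    n <- sum(ok)
    if (n < 4L)
      stop(sprintf("pair %s/%s: need >= 4 complete pairs", t1, t2),
           call. = FALSE)
    if (stats::sd(u) == 0 || stats::sd(v) == 0)
      return(data.frame(trait1 = t1, trait2 = t2, n = n, rho = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        q = NA_real_, stringsAsFactors = FALSE))
    rho <- stats::cor(u, v, method = "spearman")
    p <- suppressWarnings(stats::cor.test(u, v, method = "spearman",
                                          exact = FALSE)$p.value)
    boot <- vapply(seq_len(bootstrap_reps), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      if (stats::sd(u[ii]) == 0 || stats::sd(v[ii]) == 0) return(NA_real_)
      stats::cor(u[ii], v[ii], method = "spearman")
    }, 0)
    qs <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
    data.frame(trait1 = t1, trait2 = t2, n = n, rho = rho,
               ci_low = unname(qs[1L]), ci_high = unname(qs[2L]), p = p,
               q = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  out
}

# min-max rescale to [0, 1]; a constant component is neutral at 0.5
.minmax <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0.5, length(v)))
  (v - rng[1L]) / diff(rng)
}

#' Integrated Selection Index from the pH experiment at DAS 14
#'
#' Three equally weighted components per accession, all from the pH
#' experiment at 14 days after sowing and restricted to pH 5.5 and 7.0
#' (alkaline 8.5 never enters): mean establishment proportion across the
#' two pH levels, mean total seedling length (mm), and stability
#' 1 / (|establishment(7.0) - establishment(5.5)| + 1). Establishment is
#' a proportion in \\[0, 1\\], so raw stability lies in (0.5, 1]. Each
#' component is min-max rescaled to \\[0, 1\\] across accessions (a
#' constant component is set to the neutral 0.5); the index is the
#' unweighted mean of the three rescaled components, and ranks are dense
#' with ties broken by accession identifier.
#'
#' @param ph_summary Data frame per accession: `accession_id`, `est_55`,
#'   `est_70` (establishment proportions at DAS 14), `length_mean`
#'   (mean total length across pH 5.5 and 7.0 at DAS 14, mm).
#' @return Data frame with raw components, normalized components, `isi`,
#'   and `rank` (1 = best).
#' @export
compute_isi <- function(ph_summary) {
  need <- c("accession_id", "est_55", "est_70", "length_mean")
  stopifnot(all(need %in% names(ph_summary)))
  d <- ph_summary
  miss <- is.na(d$est_55) | is.na(d$est_70) | is.na(d$length_mean)
  if (any(miss)) {
    warning(sprintf("excluding %d accession(s) missing a pH level: %s",
                    sum(miss),
                    paste(d$accession_id[miss], collapse = ", ")))
    d <- d[!miss, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no complete accessions", call. = FALSE)
  if (any(d$est_55 < 0 | d$est_55 > 1 | d$est_70 < 0 | d$est_70 > 1))
    stop("establishment must be a proportion in [0, 1]", call. = FALSE)
  est_mean <- (d$est_55 + d$est_70) / 2
  stability <- 1 / (abs(d$est_70 - d$est_55) + 1)
  out <- data.frame(accession_id = d$accession_id,
                    est_mean = est_mean, length_mean = d$length_mean,
                    stability = stability,
                    norm_est = .minmax(est_mean),
                    norm_length = .minmax(d$length_mean),
                    norm_stability = .minmax(stability),
                    stringsAsFactors = FALSE)
  out$isi <- (out$norm_est + out$norm_length + out$norm_stability) / 3
  ord <- order(-out$isi, out$accession_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), ]
}

#' Summarize the pH experiment for the selection index
#'
#' Per-accession DAS 14 establishment proportions (total >= 30 mm) at pH
#' 5.5 and 7.0, and mean total length across the two pH levels, computed
#' from valid seedlings only.
#'
#' @param traits Output of [derive_growth_traits()].
#' @return Data frame `accession_id`, `est_55`, `est_70`, `length_mean`
#'   ready for [compute_isi()].
#' @export
isi_inputs <- function(traits) {
  d <- filter_valid(traits)$retained
  d <- d[d$das == 14L & d$ph_level %in% c(5.5, 7.0), , drop = FALSE]
  accs <- sort(unique(traits$accession_id))
  get_cell <- function(acc, ph, col, fun) {
    v <- d[[col]][d$accession_id == acc & d$ph_level == ph]
    if (length(v) == 0L) NA_real_ else fun(v)
  }
  est_55 <- vapply(accs, get_cell, 0, ph = 5.5, col = "established", fun = mean)
  est_70 <- vapply(accs, get_cell, 0, ph = 7.0, col = "established", fun = mean)
  len <- vapply(accs, function(acc) {
    v <- d$total_mm[d$accession_id == acc]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, 0)
  data.frame(accession_id = accs, est_55 = est_55, est_70 = est_70,
             length_mean = len, stringsAsFactors = FALSE, row.names = NULL)
}

#' Soil-matched accession recommendations
#'
#' Combines the per-soil establishment ranking (multi-soil experiment)
#' with the pH-performance ranking (Integrated Selection Index).
#' Accessions in both top-`top_n` sets come first, ordered by their rank
#' within the soil, flagged `overlap`; the list is then completed with
#' the next best accessions from the soil ranking, flagged `fill`, until
#' `top_n` entries are reached.
#'
#' @param est_matrix Accession x soil percent matrix from
#'   [establishment_matrix()].
#' @param isi [compute_isi()] output (or any data frame with
#'   `accession_id` and `rank`).
#' @param soil_code Soil column to recommend for.
#' @param top_n List length (default 5).
#' @return Data frame `accession_id`, `source` (`overlap`/`fill`),
#'   `soil_rank`, `isi_rank`, `establishment_pct`.
#' @export
recommend_accessions <- function(est_matrix, isi, soil_code, top_n = 5L) {
  stopifnot(soil_code %in% colnames(est_matrix),
            all(c("accession_id", "rank") %in% names(isi)))
  est <- est_matrix[, soil_code]
  est <- est[!is.na(est)]
  if (length(est) == 0L) stop("empty performance table", call. = FALSE)
  soil_order <- names(est)[order(-est, names(est))]
  soil_rank <- stats::setNames(seq_along(soil_order), soil_order)
  isi_rank <- stats::setNames(isi$rank, isi$accession_id)
  top_soil <- utils::head(soil_order, top_n)
  top_isi <- isi$accession_id[isi$rank <= top_n]
  overlap <- top_soil[top_soil %in% top_isi]
  fill <- setdiff(soil_order, overlap)
  picks <- utils::head(c(overlap, fill), top_n)
  data.frame(accession_id = picks,
             source = ifelse(picks %in% overlap, "overlap", "fill"),
             soil_rank = unname(soil_rank[picks]),
             isi_rank = unname(isi_rank[picks]),
             establishment_pct = unname(est[picks]),
             stringsAsFactors = FALSE)
}
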