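#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' positive counts in every sample, of the ratio between the sample's count
#' and the gene's geometric mean across samples. Factors are rescaled to
#' geometric mean 1, so they are comparable across runs.
#'
#' @param counts Non-negative integer matrix, genes x samples (>= 2 samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in all samples; consider adding a pseudocount")
  }
  lg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - lg))
  })
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion `alpha` in `Var = mu + alpha * mu^2`, estimated on
#' size-factor-normalized counts: within each condition,
#' `alpha_c = (s^2 - mu) / mu^2` from the sample moments, then averaged
#' across conditions and truncated at zero. Genes with zero counts
#' everywhere get `alpha = 0` and are flagged untestable. No shrinkage is
#' applied: the estimator is intentionally simple and its calibration is
#' validated by simulation rather than by matching any particular package.
#'
#' @param counts Count matrix, genes x samples.
#' @param size_factors Per-sample factors, e.g. from [size_factors()].
#' @param condition Character/factor of per-sample condition labels,
#'   at least 2 samples per condition.
#' @return Numeric vector of dispersions with attribute `untestable`
#'   (logical, all-zero genes).
#' @export
estimate_dispersion <- function(counts, size_factors, condition) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(ncol(counts) == length(condition),
            length(size_factors) == ncol(counts))
  if (any(table(condition) < 2L)) stop("need >= 2 samples per condition")
  norm <- sweep(counts, 2L, size_factors, "/")
  levs <- unique(condition)
  per_cond <- sapply(levs, function(lv) {
    x <- norm[, condition == lv, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- 0
    pmax(a, 0)
  })
  alpha <- rowMeans(as.matrix(per_cond))
  untestable <- rowSums(counts) == 0
  alpha[untestable] <- 0
  attr(alpha, "untestable") <- unname(untestable)
  alpha
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in rank, capped at 1), delegating to
#' [stats::p.adjust()] after validating the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Negative-binomial Wald test for tumor-vs-normal differential expression
#'
#' Per gene: the log2 fold change of normalized condition means (with a
#' pseudocount to handle zeros), a delta-method standard error under
#' `Var(K) = mu + alpha * mu^2`, and a two-sided Wald p-value referenced to
#' a t distribution with `n1 + n2 - 2` degrees of freedom (the plug-in
#' dispersion makes the normal reference anticonservative at small n).
#' q-values are BH-adjusted; the direction call requires all three of
#' `|log2FC| > lfc_threshold`, `p < p_threshold`, `q < q_threshold`.
#'
#' @param counts Count matrix, genes x samples.
#' @param condition Per-sample labels; `numerator` vs `denominator` contrast.
#' @param size_factors Optional; computed by [size_factors()] when `NULL`.
#' @param dispersions Optional; computed by [estimate_dispersion()] when
#'   `NULL`.
#' @param numerator,denominator Condition labels contrasted as
#'   log2(numerator / denominator); defaults tumor vs normal.
#' @param lfc_threshold,p_threshold,q_threshold Direction-call thresholds.
#' @param pseudocount Added to both normalized means in the fold change.
#' @return Data frame with `gene_id`, `base_mean`, `log2_fold_change`,
#'   `p_value`, `q_value`, `direction` (`up`/`down`/`ns`).
#' @export
de_test <- function(counts, condition, size_factors = NULL,
                    dispersions = NULL, numerator = "tumor",
                    denominator = "normal", lfc_threshold = 1,
                    p_threshold = 0.05, q_threshold = 0.05,
                    pseudocount = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  it <- condition == numerator
  in_ <- condition == denominator
  if (sum(it) < 2L || sum(in_) < 2L) {
    stop("each condition needs at least 2 samples")
  }
  if (is.null(size_factors)) size_factors <- .size_factors_fn(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, size_factors, condition)
  }
  norm <- sweep(counts, 2L, size_factors, "/")
  mt <- rowMeans(norm[, it, drop = FALSE])
  mn <- rowMeans(norm[, in_, drop = FALSE])
  lfc <- log2((mt + pseudocount) / (mn + pseudocount))
  a <- pmax(as.numeric(dispersions), 0)
  # Var(mean_c) = (1/n_c^2) * sum_j (m_c / s_j + a * m_c^2)
  st <- size_factors[it]; sn <- size_factors[in_]
  vt <- (mt * sum(1 / st) + a * mt^2 * length(st)) / length(st)^2
  vn <- (mn * sum(1 / sn) + a * mn^2 * length(sn)) / length(sn)^2
  se <- sqrt(vt / (mt + pseudocount)^2 + vn / (mn + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  df <- sum(it) + sum(in_) - 2L
  p <- 2 * stats::pt(-abs(z), df = df)
  allzero <- rowSums(counts) == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  q <- bh_adjust(p)
  direction <- rep("ns", length(p))
  sig <- abs(lfc) > lfc_threshold & p < p_threshold & q < q_threshold
  direction[sig & lfc > 0] <- "up"
  direction[sig & lfc < 0] <- "down"
  data.frame(gene_id = rownames(counts) %||% as.character(seq_along(p)),
             base_mean = (mt + mn) / 2, log2_fold_change = lfc,
             p_value = p, q_value = q, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# callable from scopes where an argument named `size_factors` shadows the
# exported function
.size_factors_fn <- function(counts) size_factors(counts)

#' Hierarchical clustering of samples and features on correlation distance
#'
#' Average-linkage clustering on `1 - Pearson` distance, computed over both
#' samples and features of a (typically differential-expression-filtered)
#' matrix. Rows and columns are sorted lexicographically before clustering
#' so leaf order is deterministic; constant features are dropped with a
#' warning because their correlation is undefined.
#'
#' @param mat Numeric matrix, features x samples.
#' @return List with `samples` and `features` (`hclust` objects; `features`
#'   is `NULL` for a single feature) and the corresponding leaf orders.
#' @export
cluster_samples <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  keep <- apply(mat, 1L, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant feature(s) dropped (correlation undefined)")
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 1L) stop("no non-constant features left")
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  # with a single feature the between-sample correlation is undefined;
  # fall back to Euclidean distance on that feature
  sample_dist <- if (nrow(mat) >= 2L) {
    stats::as.dist(1 - stats::cor(mat))
  } else {
    stats::dist(t(mat))
  }
  hc_s <- stats::hclust(sample_dist, method = "average")
  if (nrow(mat) >= 2L) {
    hc_f <- stats::hclust(stats::as.dist(1 - stats::cor(t(mat))),
                          method = "average")
    forder <- rownames(mat)[hc_f$order]
  } else {
    hc_f <- NULL
    forder <- rownames(mat)
  }
  list(samples = hc_s, features = hc_f,
       sample_order = colnames(mat)[hc_s$order], feature_order = forder)
}
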