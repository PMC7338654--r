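#' Rank genes by a signal-to-noise tumor-vs-normal metric
#'
#' Per gene, `(mean_tumor - mean_normal) / (sd_tumor + sd_normal)` with
#' each group's standard deviation floored at `0.2 * |mean| + 1e-8` (the
#' usual signal-to-noise regularization), sorted descending; ties are
#' broken lexicographically by gene id. Genes constant in both groups get
#' metric 0 with a warning.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Per-sample condition labels.
#' @param numerator,denominator The two contrasted labels.
#' @return A `ranked_list` data frame with `gene` and `metric`, sorted
#'   descending by metric.
#' @export
rank_genes <- function(expr, labels, numerator = "tumor",
                       denominator = "normal") {
  expr <- as.matrix(expr)
  labels <- as.character(labels)
  it <- labels == numerator; in_ <- labels == denominator
  if (!any(it) || !any(in_)) stop("both labels must be present")
  xt <- expr[, it, drop = FALSE]; xn <- expr[, in_, drop = FALSE]
  mt <- rowMeans(xt); mn <- rowMeans(xn)
  st <- apply(xt, 1L, stats::sd); sn <- apply(xn, 1L, stats::sd)
  const <- st == 0 & sn == 0 & mt == mn
  st <- pmax(st, 0.2 * abs(mt) + 1e-8)
  sn <- pmax(sn, 0.2 * abs(mn) + 1e-8)
  metric <- (mt - mn) / (st + sn)
  if (any(const)) {
    warning(sum(const), " gene(s) constant in both groups; metric set to 0")
    metric[const] <- 0
  }
  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  ord <- order(-metric, ids)
  structure(data.frame(gene = ids[ord], metric = metric[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list accumulating `|metric|^weight_exponent`
#' (normalized over the gene set's hits) at set members and subtracting
#' `1 / (N - Nh)` at non-members; the enrichment score is the signed
#' maximum deviation of this running sum from zero. A positive ES means
#' the set is concentrated at the top of the list.
#'
#' @param ranked A `ranked_list` from [rank_genes()] (or a data frame with
#'   `gene` and `metric` sorted descending).
#' @param gene_set Character vector; must intersect the list but not cover
#'   it.
#' @param weight_exponent Metric weighting (0 gives the unweighted
#'   Kolmogorov-Smirnov-style statistic; default 1).
#' @return An `enrichment_result`: list with `es`, `running_sum` (length
#'   N), `leading_edge` (set members at or before the extremum) and
#'   `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == N) stop("gene set covers the entire ranked list")
  w <- abs(ranked$metric)^weight_exponent
  denom <- sum(w[hit])
  inc <- numeric(N)
  if (denom > 0) {
    inc[hit] <- w[hit] / denom
  } else {
    inc[hit] <- 1 / nh  # all hit metrics zero: fall back to equal weights
  }
  inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  i_max <- which.max(abs(rs))
  es <- rs[i_max]
  leading <- if (es >= 0) genes[seq_len(i_max)][hit[seq_len(i_max)]]
             else genes[i_max:N][hit[i_max:N]]
  structure(list(es = es, running_sum = rs, leading_edge = leading,
                 n_hits = nh),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> ES = %.4f (%d hits, %d leading-edge)\n",
              x$es, x$n_hits, length(x$leading_edge)))
  invisible(x)
}

# evaluate code under a given seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Phenotype-permutation p-value for an enrichment score
#'
#' Recomputes the ranking and ES under label permutations and returns the
#' add-one permutation p-value
#' `(1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`, reproducible for a
#' given seed. When the number of distinct label assignments is at most
#' `n_perm`, all of them are enumerated instead of sampling.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Per-sample labels (two groups).
#' @param gene_set Character vector.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param weight_exponent Passed to [enrichment_score()].
#' @param numerator,denominator Contrast labels.
#' @return List with `p_value`, `es_observed`, `es_permuted` (vector),
#'   `n_perm_used`, `exhaustive`.
#' @export
permutation_p <- function(expr, labels, gene_set, n_perm = 1000, seed = 1,
                          weight_exponent = 1, numerator = "tumor",
                          denominator = "normal") {
  if (n_perm < 100) stop("n_perm must be at least 100")
  labels <- as.character(labels)
  obs <- enrichment_score(rank_genes(expr, labels, numerator, denominator),
                          gene_set, weight_exponent)$es
  ns <- length(labels)
  nt <- sum(labels == numerator)
  n_distinct <- choose(ns, nt)
  es_of <- function(lab) {
    enrichment_score(rank_genes(expr, lab, numerator, denominator),
                     gene_set, weight_exponent)$es
  }
  if (n_distinct <= n_perm) {
    combos <- utils::combn(ns, nt)
    es_perm <- apply(combos, 2L, function(idx) {
      lab <- rep(denominator, ns)
      lab[idx] <- numerator
      es_of(lab)
    })
    exhaustive <- TRUE
  } else {
    es_perm <- .with_seed(seed, {
      vapply(seq_len(n_perm), function(i) es_of(sample(labels)), 0)
    })
    exhaustive <- FALSE
  }
  p <- (1 + sum(abs(es_perm) >= abs(obs) - 1e-12)) / (length(es_perm) + 1)
  list(p_value = p, es_observed = obs, es_permuted = es_perm,
       n_perm_used = length(es_perm), exhaustive = exhaustive)
}

#' Write a ranked list in RNK format
#' @param ranked A `ranked_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rnk <- function(ranked, path) {
  writeLines(sprintf("%s\t%.10g", ranked$gene, ranked$metric), path)
  invisible(path)
}
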