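#' Build the coexpression graph from pairwise expression correlations
#'
#' Scores every gene pair by Pearson correlation across samples, converts
#' correlations to two-sided p-values via the t transform, BH-adjusts over
#' all pairs, and keeps edges with adjusted p below `p_cutoff`. Markov
#' clustering expects similarity weights, so the adjusted p is mapped to
#' `weight = -log10(q)` (larger = stronger), floored at a small positive
#' constant; q-values are clamped away from zero before the log.
#'
#' @param expr Expression matrix, genes x samples (>= 3 samples).
#' @param nodes Gene ids to include (default all rows). Constant genes are
#'   excluded with a warning.
#' @param p_cutoff Adjusted-p edge cutoff.
#' @param weight_floor Minimum edge weight.
#' @return A `coexpression_graph`: list with `nodes` (data frame `id`) and
#'   `edges` (data frame `node1`, `node2`, `pcc`, `q_value`, `weight`).
#' @export
correlation_graph <- function(expr, nodes = rownames(expr), p_cutoff = 0.01,
                              weight_floor = 1e-3) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing)) stop("nodes absent from expr: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  mat <- expr[nodes, , drop = FALSE]
  keep <- apply(mat, 1L, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant gene(s) excluded from the graph")
    mat <- mat[keep, , drop = FALSE]
  }
  ids <- sort(rownames(mat))
  mat <- mat[ids, , drop = FALSE]
  n <- ncol(mat)
  if (nrow(mat) < 2L) {
    return(structure(list(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                          edges = data.frame(node1 = character(),
                                             node2 = character(),
                                             pcc = double(), q_value = double(),
                                             weight = double())),
                     class = "coexpression_graph"))
  }
  C <- stats::cor(t(mat))
  iu <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[iu]
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- bh_adjust(p)
  sel <- q < p_cutoff
  edges <- data.frame(node1 = ids[iu[sel, 1L]], node2 = ids[iu[sel, 2L]],
                      pcc = r[sel], q_value = q[sel],
                      weight = pmax(-log10(pmax(q[sel], 1e-300)), weight_floor),
                      stringsAsFactors = FALSE)
  swap <- edges$node1 > edges$node2
  tmp <- edges$node1[swap]; edges$node1[swap] <- edges$node2[swap]
  edges$node2[swap] <- tmp
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                 edges = edges),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("<coexpression_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Markov clustering parameters
#'
#' @param inflation Entrywise inflation exponent (> 1); larger values give
#'   finer clusters.
#' @param expansion Matrix-power expansion exponent (integer >= 2).
#' @param pruning Entries below this are zeroed after each inflation.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute change.
#' @return An `mcl_params` list.
#' @export
mcl_params <- function(inflation = 2, expansion = 2, pruning = 1e-5,
                       max_iter = 100, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, pruning >= 0, max_iter >= 1)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 pruning = pruning, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "mcl_params")
}

.colnorm <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2L, cs, "/")
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Flow simulation on the column-stochastic transition matrix built from
#' the edge weights: alternate expansion (matrix power) and inflation
#' (entrywise power plus renormalization) with pruning of small entries
#' until the matrix stops changing. Self-loops (value: the node's maximum
#' incident weight, 1 for isolated nodes) are added before iterating, the
#' standard regularization. Clusters are read off the attractor structure;
#' a node attracted by several attractors joins the one receiving the
#' largest flow, ties broken lexicographically. The procedure is fully
#' deterministic.
#'
#' @param graph A `coexpression_graph` (or list with `nodes`/`edges`).
#' @param params An [mcl_params()] object.
#' @return A `cluster_set`: list with `clusters` (list of character
#'   vectors, sorted by decreasing size then lexicographically), `sizes`,
#'   `converged`, `iterations`, and `dropped` (empty here; filled by
#'   [filter_clusters()]).
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  ids <- sort(graph$nodes$id)
  nn <- length(ids)
  if (nn == 0L) stop("graph is empty")
  A <- matrix(0, nn, nn, dimnames = list(ids, ids))
  e <- graph$edges
  if (nrow(e)) {
    i <- match(e$node1, ids); j <- match(e$node2, ids)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- .colnorm(A)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    Mexp <- M
    for (k in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    # inflate and renormalize before pruning: pruning the un-normalized
    # entrywise powers would underflow whole columns at high inflation
    Minf <- .colnorm(Mexp^params$inflation)
    Minf[Minf < params$pruning] <- 0
    Minf <- .colnorm(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < params$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iter,
            " iterations; interpreting current flow matrix")
  }
  clusters <- .interpret_mcl(M, ids)
  structure(list(clusters = clusters,
                 sizes = lengths(clusters),
                 converged = converged, iterations = iter,
                 dropped = character()),
            class = "cluster_set")
}

# read clusters off a converged MCL flow matrix: attractors are rows with
# positive diagonal flow; attractors that exchange flow form one attractor
# system (union-find); every column joins the system receiving its largest
# flow, ties broken lexicographically by node id
.interpret_mcl <- function(M, ids) {
  nn <- length(ids)
  att <- which(diag(M) > 0)
  if (!length(att)) att <- unique(apply(M, 2L, which.max))
  att <- sort(att)
  parent <- seq_len(nn)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (a in att) {
    for (b in att) {
      if (a < b && (M[a, b] > 0 || M[b, a] > 0)) union_(a, b)
    }
  }
  owner <- integer(nn)
  for (j in seq_len(nn)) {
    flows <- M[att, j]
    if (all(flows == 0)) {
      # no attractor flow (cannot happen after self-loop regularization,
      # kept as a safe fallback): singleton
      owner[j] <- -j
    } else {
      best <- att[flows == max(flows)]
      owner[j] <- find(best[1L])  # ids sorted, so first = lexicographic tie-break
    }
  }
  groups <- split(ids, owner)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, `[[`, "", 1L))
  unname(groups[ord])
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s); sizes: %s%s\n",
              length(x$clusters),
              paste(utils::head(x$sizes, 10), collapse = ", "),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Drop clusters below a minimum size
#'
#' @param cluster_set A `cluster_set` from [mcl_cluster()].
#' @param min_size Minimum retained cluster size (default 45).
#' @return A `cluster_set` with small clusters removed and their members
#'   recorded in `dropped`.
#' @export
filter_clusters <- function(cluster_set, min_size = 45) {
  keep <- cluster_set$sizes >= min_size
  dropped <- sort(unlist(cluster_set$clusters[!keep], use.names = FALSE))
  out <- cluster_set
  out$clusters <- cluster_set$clusters[keep]
  out$sizes <- cluster_set$sizes[keep]
  out$dropped <- c(cluster_set$dropped, dropped)
  out
}

#' Hypergeometric term enrichment of a cluster
#'
#' One-sided hypergeometric tail `P(X >= k)` for the overlap `k` between
#' the cluster and each annotation term, against the given gene background;
#' BH-adjusted across terms.
#'
#' @param cluster_genes Non-empty character vector, a subset of
#'   `background`.
#' @param term_table Named list mapping term id to gene set.
#' @param background Character vector, the gene universe.
#' @return Data frame `term`, `overlap`, `term_size`, `cluster_size`,
#'   `p_value`, `q_value`, sorted by `p_value`.
#' @export
hypergeom_enrich <- function(cluster_genes, term_table, background) {
  if (!length(cluster_genes)) stop("empty cluster")
  cluster_genes <- unique(cluster_genes)
  background <- unique(background)
  if (!all(cluster_genes %in% background)) {
    stop("cluster genes must be a subset of the background")
  }
  N <- length(background)
  n <- length(cluster_genes)
  rows <- lapply(names(term_table), function(tm) {
    term <- intersect(term_table[[tm]], background)
    K <- length(term)
    if (!K) return(NULL)
    k <- length(intersect(cluster_genes, term))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, cluster_size = n,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no term intersects the background")
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (term, description, genes...).
#' @return Named list of character gene sets.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT line ", which(bad)[1L], " has fewer than 3 fields")
  setNames(lapply(fields, function(f) f[-(1:2)]),
           vapply(fields, `[[`, "", 1L))
}

#' Write a GMT gene-set file
#' @param sets Named list of character gene sets.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Write a coexpression graph as an edge-list TSV
#' @param graph A `coexpression_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
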