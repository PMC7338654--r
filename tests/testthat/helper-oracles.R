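# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately naive (per-base enumeration, plain
# loops) and independent of the package's implementation paths.

# random small transcript on a short chromosome, gene body <= ~2000 nt
random_small_tx <- function(id, chrom = "chrX", max_pos = 2000,
                            strand = NULL) {
  n_ex <- sample(1:3, 1)
  starts <- sort(sample(0:(max_pos - 60), n_ex))
  exons <- NULL
  cur <- -1
  for (s in starts) {
    s <- max(s, cur + 1)
    e <- s + sample(10:50, 1)
    if (!is.null(exons) && s <= cur) next
    exons <- rbind(exons, c(s, e))
    cur <- e
  }
  transcript_model(id, paste0(id, "G"), chrom,
                   if (is.null(strand)) sample(c("+", "-"), 1) else strand,
                   exons)
}

# per-base membership oracle for exonic overlap
oracle_exonic_overlap <- function(a, b, strand_mode) {
  if (a$chrom != b$chrom) return(0)
  if (strand_mode == "same" &&
      (a$strand == "*" || b$strand == "*" || a$strand != b$strand)) return(0)
  if (strand_mode == "opposite" &&
      (a$strand == "*" || b$strand == "*" || a$strand == b$strand)) return(0)
  bases_a <- unlist(apply(a$exons, 1, function(e) seq(e[1], e[2] - 1)))
  bases_b <- unlist(apply(b$exons, 1, function(e) seq(e[1], e[2] - 1)))
  length(intersect(bases_a, bases_b))
}

# per-base oracle for gene-body distance (touching bodies -> 0)
oracle_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  ba <- seq(min(a$exons[, 1]), max(a$exons[, 2]) - 1)
  bb <- seq(min(b$exons[, 1]), max(b$exons[, 2]) - 1)
  d <- min(vapply(ba, function(x) min(abs(x - bb)), 0))
  max(0, d - 1)  # adjacent bases belong to touching bodies: distance 0
}

# independent dense-matrix MCL following the textbook iteration
oracle_mcl <- function(ids, edges, inflation = 2, expansion = 2,
                       pruning = 1e-5, max_iter = 100, tol = 1e-8,
                       check_stochastic = FALSE) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- match(edges$node1[r], ids); j <- match(edges$node2[r], ids)
      A[i, j] <- edges$weight[r]; A[j, i] <- edges$weight[r]
    }
  }
  for (i in seq_len(n)) {
    mx <- max(A[i, ])
    A[i, i] <- if (mx > 0) mx else 1
  }
  normalize <- function(M) {
    for (j in seq_len(ncol(M))) {
      s <- sum(M[, j])
      if (s > 0) M[, j] <- M[, j] / s
    }
    M
  }
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    Me <- M
    for (k in seq_len(expansion - 1)) Me <- Me %*% M
    Mi <- normalize(Me^inflation)
    Mi[Mi < pruning] <- 0
    Mi <- normalize(Mi)
    if (check_stochastic) {
      stopifnot(all(abs(colSums(Mi) - 1) < 1e-9))
    }
    d <- max(abs(Mi - M))
    M <- Mi
    if (d < tol) break
  }
  att <- which(diag(M) > 0)
  if (!length(att)) att <- unique(apply(M, 2, which.max))
  att <- sort(att)
  # attractor systems: merge attractors that exchange flow
  sys <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in att) for (b in att) {
      if ((M[a, b] > 0 || M[b, a] > 0) && sys[a] != sys[b]) {
        sys[sys == max(sys[a], sys[b])] <- min(sys[a], sys[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  owner <- integer(n)
  for (j in seq_len(n)) {
    fl <- M[att, j]
    best <- att[fl == max(fl)][1]
    owner[j] <- sys[best]
  }
  parts <- split(ids, owner)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[[`, "", 1))])
}

# canonical form of a partition for comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[[`, "", 1))]
}

# independent running-sum ES oracle
oracle_es <- function(genes, metric, set, w = 1) {
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  wts <- abs(metric)^w
  denom <- sum(wts[hit])
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) {
      if (denom > 0) wts[i] / denom else 1 / nh
    } else -1 / (N - nh)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# random weighted graph in coexpression_graph shape
random_graph <- function(n, p_edge = 0.4) {
  ids <- sprintf("g%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      edges <- rbind(edges, data.frame(node1 = ids[i], node2 = ids[j],
                                       pcc = NA, q_value = NA,
                                       weight = stats::runif(1, 0.5, 3),
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(node1 = character(), node2 = character(),
                        pcc = double(), q_value = double(),
                        weight = double(), stringsAsFactors = FALSE)
  }
  list(nodes = data.frame(id = ids, stringsAsFactors = FALSE), edges = edges)
}

# shared small simulated study for the expensive integration tests; built
# once per test run
sim_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "lncscout-sim-fixture")
      man <- simulate_all(dir, seed = 20240901)
      cache <<- list(dir = dir, manifest = man)
    }
    cache
  }
})
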