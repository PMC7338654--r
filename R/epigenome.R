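#' Methylation table constructor
#'
#' @param sites Data frame with `cpg_id`, `chrom`, `pos` (0-based position
#'   of the CpG base).
#' @param beta Numeric matrix of beta values in `[0, 1]`, CpGs x samples,
#'   rownames matching `cpg_id`.
#' @return A `methylation_table` (list of `sites` and `beta`).
#' @export
methylation_table <- function(sites, beta) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(sites)),
            is.matrix(beta), nrow(beta) == nrow(sites),
            identical(rownames(beta), sites$cpg_id))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  structure(list(sites = sites, beta = beta), class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat(sprintf("<methylation_table> %d CpG sites x %d samples\n",
              nrow(x$sites), ncol(x$beta)))
  invisible(x)
}

#' CpG sites in a gene's promoter
#'
#' The promoter is the window strictly upstream of the TSS (the TSS base
#' itself is excluded): positions `[TSS - window, TSS)` on the plus strand,
#' `(TSS, TSS + window]` on the minus strand.
#'
#' @param gene A stranded `transcript_model`.
#' @param methylation A [methylation_table()].
#' @param window_nt Promoter window size, nt (default 2000).
#' @return Character vector of CpG ids falling in the promoter.
#' @export
promoter_cpgs <- function(gene, methylation, window_nt = 2000) {
  if (gene$strand == "*") stop("promoter undefined for unstranded gene")
  p <- tss(gene)
  s <- methylation$sites
  on_chrom <- s$chrom == gene$chrom
  inside <- if (gene$strand == "+") {
    s$pos >= p - window_nt & s$pos < p
  } else {
    s$pos > p & s$pos <= p + window_nt
  }
  s$cpg_id[on_chrom & inside]
}

#' Screen DE genes for promoter methylation anti-correlated with expression
#'
#' For every differentially expressed gene, Pearson correlation between its
#' expression and the beta value of each promoter CpG across the shared
#' samples; pairs with `pcc < threshold` are retained. The per-gene summary
#' flags the most negative CpG (`is_best`). Pairs with a zero-variance
#' expression or beta vector are skipped with a warning.
#'
#' @param expr Expression matrix, genes x samples.
#' @param methylation A [methylation_table()].
#' @param de_genes [de_test()]-shaped table; rows with direction `up`/`down`
#'   are screened.
#' @param annotation [annotation_set()] supplying TSS and strand per gene.
#' @param threshold Retention threshold on the correlation (default -0.3).
#' @param window_nt Promoter window, nt.
#' @return Data frame `gene_id`, `cpg_id`, `pcc`, `n`, `direction`,
#'   `is_best`, sorted by `pcc`.
#' @export
methylation_expression_screen <- function(expr, methylation, de_genes,
                                          annotation, threshold = -0.3,
                                          window_nt = 2000) {
  stopifnot(nrow(de_genes) > 0)
  de <- de_genes[de_genes$direction %in% c("up", "down"), , drop = FALSE]
  samples <- intersect(colnames(expr), colnames(methylation$beta))
  if (length(samples) < 3L) stop("need >= 3 shared samples")
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(de))) {
    g <- de$gene_id[i]
    tx_ids <- annotation$tx$transcript_id[annotation$tx$gene_id == g]
    if (!length(tx_ids) || !g %in% rownames(expr)) next
    cpgs <- unique(unlist(lapply(tx_ids, function(id) {
      promoter_cpgs(get_transcript(annotation, id), methylation, window_nt)
    })))
    if (!length(cpgs)) next
    e <- as.numeric(expr[g, samples])
    if (stats::sd(e) == 0) { n_skipped <- n_skipped + length(cpgs); next }
    for (cg in cpgs) {
      b <- as.numeric(methylation$beta[cg, samples])
      if (stats::sd(b) == 0) { n_skipped <- n_skipped + 1L; next }
      r <- stats::cor(e, b)
      if (r < threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, cpg_id = cg, pcc = r, n = length(samples),
          direction = de$direction[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " gene-CpG pair(s) skipped: zero-variance vector")
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), cpg_id = character(),
                      pcc = double(), n = integer(), direction = character(),
                      is_best = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pcc, out$gene_id, out$cpg_id), , drop = FALSE]
  best <- tapply(out$pcc, out$gene_id, min)
  out$is_best <- out$pcc == best[out$gene_id] & !duplicated(out$gene_id)
  rownames(out) <- NULL
  out
}

#' Annotate DE genes with overlapping significant CNV segments
#'
#' A gene is annotated with every significant (`q_value < q_max`) segment
#' its gene body intersects; the `concordant` flag marks the expected
#' dosage relationship (deletion with down-regulation, amplification with
#' up-regulation).
#'
#' @param de_genes [de_test()]-shaped table.
#' @param segments Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `kind` (`amplification`/`deletion`), `q_value`.
#' @param annotation [annotation_set()] giving gene bodies.
#' @param q_max Significance cutoff on the segment q-value (default 0.25).
#' @return Data frame `gene_id`, `direction`, `kind`, `q_value`,
#'   `concordant`; genes intersecting no significant segment are absent.
#' @export
cnv_overlap <- function(de_genes, segments, annotation, q_max = 0.25) {
  stopifnot(all(c("chrom", "start", "end", "kind", "q_value") %in%
                names(segments)))
  sig <- segments[segments$q_value < q_max, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(de_genes))) {
    g <- de_genes$gene_id[i]
    tx <- annotation$tx[annotation$tx$gene_id == g, , drop = FALSE]
    if (!nrow(tx)) next
    gs <- min(tx$start); ge <- max(tx$end); gc <- tx$chrom[1L]
    hit <- sig$chrom == gc & sig$start < ge & gs < sig$end
    for (j in which(hit)) {
      dir <- de_genes$direction[i]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, direction = dir, kind = sig$kind[j],
        q_value = sig$q_value[j],
        concordant = (sig$kind[j] == "deletion" && dir == "down") ||
                     (sig$kind[j] == "amplification" && dir == "up"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), direction = character(),
                      kind = character(), q_value = double(),
                      concordant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean ChIP signal profile around transcription start sites
#'
#' Accumulates peak signal into strand-oriented offset bins spanning
#' `[-flank, flank)` around each transcript's TSS (negative offsets are
#' upstream) and averages the binned signal over transcripts. A peak
#' spreads its signal value uniformly over its bases (density
#' `signal / width`), so a bin receives `density x overlap` from each peak.
#' On the minus strand the base `[g, g+1)` maps to the reflected offset
#' interval `[tss - g - 1, tss - g)`, which makes a strand flip mirror the
#' binned profile exactly.
#'
#' @param peaks Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `signal` (non-negative).
#' @param transcripts Non-empty list of stranded `transcript_model`s (one
#'   class of transcripts).
#' @param flank Half-window around the TSS, nt (default 7000).
#' @param bin_width Bin width, nt (must divide `2 * flank`).
#' @return Data frame `offset_start`, `offset_end`, `mean_signal` with
#'   `2 * flank / bin_width` rows.
#' @export
tss_signal_profile <- function(peaks, transcripts, flank = 7000,
                               bin_width = 100) {
  if (length(transcripts) == 0L) stop("transcript list is empty")
  if ((2 * flank) %% bin_width != 0) stop("bin_width must divide 2 * flank")
  nbins <- as.integer(2 * flank / bin_width)
  total <- numeric(nbins)
  for (t in transcripts) {
    if (t$strand == "*") stop("transcripts must be stranded")
    p <- tss(t)
    pk <- peaks[peaks$chrom == t$chrom & peaks$signal > 0, , drop = FALSE]
    if (!nrow(pk)) next
    # offset interval of each peak in TSS-oriented coordinates
    if (t$strand == "+") {
      os <- pk$start - p; oe <- pk$end - p
    } else {
      os <- p - pk$end; oe <- p - pk$start
    }
    dens <- pk$signal / (pk$end - pk$start)
    for (k in seq_len(nrow(pk))) {
      a <- max(os[k], -flank); b <- min(oe[k], flank)
      if (a >= b) next
      b0 <- floor((a + flank) / bin_width)
      b1 <- floor((b - 1e-9 + flank) / bin_width)
      for (bin in b0:b1) {
        lo <- -flank + bin * bin_width
        hi <- lo + bin_width
        ov <- min(b, hi) - max(a, lo)
        if (ov > 0) total[bin + 1L] <- total[bin + 1L] + dens[k] * ov
      }
    }
  }
  offs <- -flank + (seq_len(nbins) - 1L) * bin_width
  data.frame(offset_start = offs, offset_end = offs + bin_width,
             mean_signal = total / length(transcripts))
}

#' Mean conservation score over exonic and intronic bases, by class
#'
#' Aggregates a per-base score track (bedGraph-style intervals) over the
#' exonic and intronic bases of each transcript class. Bases not covered by
#' the track are skipped and reported through the coverage fraction.
#'
#' @param track Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `score`.
#' @param transcripts List of `transcript_model`s.
#' @param classes Character vector of class labels, parallel to
#'   `transcripts`.
#' @return Data frame `class`, `region` (`exon`/`intron`), `mean_score`
#'   (`NA` when the class has no bases of that region type), `covered_bp`,
#'   `total_bp`, `coverage`.
#' @export
conservation_by_region <- function(track, transcripts, classes) {
  stopifnot(length(transcripts) == length(classes))
  track_gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1, track$end))
  region_stats <- function(df) {
    # df: chrom/start/end 0-based half-open intervals
    if (!nrow(df)) {
      return(c(sum = NA_real_, covered = 0, total = 0))
    }
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1, df$end))
    total <- sum(BiocGenerics::width(gr))
    hits <- GenomicRanges::findOverlaps(gr, track_gr)
    if (!length(hits)) return(c(sum = NA_real_, covered = 0, total = total))
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    track_gr[S4Vectors::subjectHits(hits)])
    w <- BiocGenerics::width(ov)
    sc <- track$score[S4Vectors::subjectHits(hits)]
    c(sum = sum(w * sc), covered = sum(w), total = total)
  }
  out <- list()
  for (cl in unique(classes)) {
    sel <- transcripts[classes == cl]
    exon_df <- do.call(rbind, lapply(sel, function(t) {
      data.frame(chrom = t$chrom, start = t$exons[, "start"],
                 end = t$exons[, "end"], stringsAsFactors = FALSE)
    }))
    intron_df <- do.call(rbind, lapply(sel, function(t) {
      ex <- t$exons
      if (nrow(ex) < 2L) return(NULL)
      data.frame(chrom = t$chrom, start = ex[-nrow(ex), "end"],
                 end = ex[-1L, "start"], stringsAsFactors = FALSE)
    }))
    if (is.null(intron_df)) {
      intron_df <- data.frame(chrom = character(), start = double(),
                              end = double(), stringsAsFactors = FALSE)
    }
    for (reg in c("exon", "intron")) {
      st <- region_stats(if (reg == "exon") exon_df else intron_df)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, region = reg,
        mean_score = if (st["covered"] > 0) st["sum"] / st["covered"] else NA_real_,
        covered_bp = st["covered"], total_bp = st["total"],
        coverage = if (st["total"] > 0) st["covered"] / st["total"] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
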