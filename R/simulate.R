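# Synthetic multi-omic data with a planted ground truth. Every generator is
# a pure function of (seed, parameters); all randomness flows from one root
# seed through named substreams so adding a generator never perturbs the
# draws of another.

.sub_seed <- function(root, name) {
  u <- utf8ToInt(name)
  (as.numeric(root) * 1009 + sum(u * seq_along(u)) * 7919) %% 2147483629
}

# uniform random sequence guaranteed to contain no ATG (hence no ORF)
.random_seq_noatg <- function(len) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  while (grepl("ATG", s, fixed = TRUE)) {
    s <- gsub("ATG", "ATC", s, fixed = TRUE)
  }
  s
}

# sequence of given length whose central ORF covers ~orf_frac of it
.coding_seq <- function(len, orf_frac = 0.8) {
  orf_nt <- 3 * max(12L, floor(orf_frac * len / 3))
  orf_nt <- min(orf_nt, 3 * ((len - 6) %/% 3))
  ncod <- orf_nt / 3 - 2L
  non_stop <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1L, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  body <- paste(sample(non_stop, ncod, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")
  u5 <- max(0L, floor((len - orf_nt) / 2))
  u3 <- len - orf_nt - u5
  paste0(if (u5 > 0) .random_seq_noatg(u5) else "", orf,
         if (u3 > 0) .random_seq_noatg(u3) else "")
}

#' Simulate a reference annotation
#'
#' Places non-overlapping multi-exon protein-coding and lncRNA genes on a
#' small synthetic genome using a fixed slot layout (genes occupy every
#' other slot, leaving guaranteed intergenic room for planted candidates).
#' Coding genes have 3-6 exons of 100-300 nt separated by introns of
#' 1,200-2,500 nt (so every coding gene has an intron large enough to host
#' an intronic candidate); lncRNA genes have 1-3 exons. One transcript per
#' gene. Deterministic given the seed.
#'
#' @param seed RNG seed.
#' @param n_coding,n_lncRNA Number of genes of each biotype.
#' @param genome_size Chromosome length, nt.
#' @param n_chrom Number of chromosomes.
#' @param slot_nt Slot size of the placement grid.
#' @return An [annotation_set()].
#' @export
simulate_annotation <- function(seed, n_coding = 30, n_lncRNA = 15,
                                genome_size = 2e6, n_chrom = 2,
                                slot_nt = 30000) {
  stopifnot(n_coding >= 1, n_lncRNA >= 1)
  .with_seed(seed, {
    slots_per_chrom <- (genome_size %/% slot_nt) %/% 2L
    total_slots <- n_chrom * slots_per_chrom
    n_genes <- n_coding + n_lncRNA
    if (n_genes > total_slots) {
      stop("infeasible packing: ", n_genes, " genes but only ", total_slots,
           " gene slots; increase genome_size")
    }
    biotypes <- c(rep("protein_coding", n_coding),
                  rep("annotated_lncRNA", n_lncRNA))
    biotypes <- sample(biotypes)  # interleave biotypes along the genome
    models <- vector("list", n_genes)
    ic <- il <- 0L
    for (i in seq_len(n_genes)) {
      chrom <- sprintf("chr%d", ((i - 1L) %/% slots_per_chrom) + 1L)
      slot0 <- (((i - 1L) %% slots_per_chrom)) * 2L * slot_nt
      offset <- sample(2000:4000, 1L)
      pos <- slot0 + offset
      if (biotypes[i] == "protein_coding") {
        ic <- ic + 1L
        gid <- sprintf("REFC%03d", ic)
        nex <- sample(3:6, 1L)
        exon_len <- sample(100:300, nex, replace = TRUE)
        intron_len <- sample(1200:2500, nex - 1L, replace = TRUE)
      } else {
        il <- il + 1L
        gid <- sprintf("REFL%03d", il)
        nex <- sample(1:3, 1L)
        exon_len <- sample(150:400, nex, replace = TRUE)
        intron_len <- if (nex > 1L) sample(500:1500, nex - 1L, replace = TRUE)
                      else integer()
      }
      starts <- pos + cumsum(c(0, exon_len[-nex] + intron_len))
      exons <- cbind(start = starts, end = starts + exon_len)
      strand <- sample(c("+", "-"), 1L)
      models[[i]] <- transcript_model(paste0(gid, ".1"), gid, chrom, strand,
                                      exons, biotypes[i])
    }
    annotation_set(models)
  })
}

# deterministic apportionment of n into classes by proportions, guaranteeing
# at least one per class when n >= number of classes
.apportion_classes <- function(n, props) {
  props <- props / sum(props)
  cnt <- floor(n * props)
  frac <- n * props - cnt
  for (k in seq_len(n - sum(cnt))) {
    j <- order(-frac)[k]
    cnt[j] <- cnt[j] + 1L
  }
  if (n >= length(props)) {
    while (any(cnt == 0L)) {
      give <- which(cnt == 0L)[1L]
      take <- which.max(cnt)
      cnt[give] <- cnt[give] + 1L
      cnt[take] <- cnt[take] - 1L
    }
  }
  cnt
}

# free placement cells: intervals well clear (>= margin) of every reference
# gene body, tiled into fixed-size cells, ordered by chrom then position
.far_cells <- function(reference, margin = 2600, cell = 7000) {
  out <- list()
  for (ch in unique(reference$tx$chrom)) {
    tx <- reference$tx[reference$tx$chrom == ch, , drop = FALSE]
    tx <- tx[order(tx$start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(tx$start, tx$end)), max(tx$end) + 60000)
    for (i in seq(1L, length(bounds) - 1L, by = 2L)) {
      gs <- bounds[i]; ge <- bounds[i + 1L]
      lo <- gs + margin; hi <- ge - margin
      k <- 0L
      while (lo + (k + 1L) * cell <= hi) {
        out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                              start = lo + k * cell,
                                              stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate an assembled transcriptome with planted candidates and decoys
#'
#' Plants `n_true_candidates` novel lncRNAs spanning all four positional
#' classes (counts apportioned from `class_props`, at least one per class)
#' plus `decoys_per_filter` decoys per screening filter, each violating
#' exactly one filter: length <= 200 nt; same-strand exonic overlap with
#' the reference; mono-exonic within 2,000 nt of a reference gene;
#' mono-exonic with max FPKM <= 0.5 (flagged for the count simulator); and
#' a long ORF (coding). Emits transcript sequences: planted candidates and
#' non-coding decoys are ATG-free (no ORF by construction), coding decoys
#' carry an ORF covering ~80% of the sequence.
#'
#' @param reference [annotation_set()] from [simulate_annotation()].
#' @param seed RNG seed.
#' @param n_true_candidates Number of planted candidates (>= 4).
#' @param decoys_per_filter Decoys per filter.
#' @param class_props Named proportions for intergenic/antisense/sense/
#'   intronic (defaults mirror the typical genomic distribution of novel
#'   lncRNAs, 83.4/15.2/1.3/0.1).
#' @return List with `assembly` ([annotation_set()]), `sequences` (named
#'   character), and `manifest` (candidates, decoys, expected audit counts,
#'   low-expression ids).
#' @export
simulate_assembly <- function(reference, seed, n_true_candidates = 12,
                              decoys_per_filter = 2,
                              class_props = c(intergenic = 0.834,
                                              antisense = 0.152,
                                              sense = 0.013,
                                              intronic = 0.001)) {
  stopifnot(nrow(reference$tx) > 0, n_true_candidates >= 4)
  .with_seed(seed, {
    cells <- .far_cells(reference)
    cell_i <- 0L
    next_cell <- function() {
      cell_i <<- cell_i + 1L
      if (cell_i > nrow(cells)) stop("infeasible placement: out of free cells")
      cells[cell_i, ]
    }
    coding_tx <- reference$tx[reference$tx$biotype == "protein_coding", ,
                              drop = FALSE]
    coding_ids <- coding_tx$transcript_id
    ref_i <- 0L
    next_coding <- function() {
      ref_i <<- ref_i + 1L
      reference$transcripts[[coding_ids[((ref_i - 1L) %% length(coding_ids)) + 1L]]]
    }
    counts <- .apportion_classes(n_true_candidates, class_props)
    names(counts) <- names(class_props)

    models <- list()
    seqs <- character()
    cand_rows <- list()
    decoy_rows <- list()
    idx <- 0L
    add_candidate <- function(m, class) {
      models[[length(models) + 1L]] <<- m
      seqs[m$transcript_id] <<- .random_seq_noatg(m$length_nt)
      cand_rows[[length(cand_rows) + 1L]] <<- data.frame(
        transcript_id = m$transcript_id, gene_id = m$gene_id,
        positional_class = class, monoexonic = nrow(m$exons) == 1L,
        stringsAsFactors = FALSE)
    }

    for (k in seq_len(counts["intergenic"])) {
      idx <- idx + 1L
      cl <- next_cell()
      pos <- cl$start + sample(0:500, 1L)
      strand <- sample(c("+", "-"), 1L)
      if (k %% 2L == 1L) {  # multi-exonic
        e1 <- sample(250:500, 1L); gap <- sample(300:700, 1L)
        e2 <- sample(250:500, 1L)
        exons <- cbind(start = c(pos, pos + e1 + gap),
                       end = c(pos + e1, pos + e1 + gap + e2))
      } else {              # mono-exonic (exercises distance + FPKM branch)
        exons <- cbind(start = pos, end = pos + sample(400:900, 1L))
      }
      add_candidate(transcript_model(sprintf("CAND%03d.1", idx),
                                     sprintf("CANDG%03d", idx), cl$chrom,
                                     strand, exons), "intergenic")
    }
    for (k in seq_len(counts["antisense"])) {
      idx <- idx + 1L
      ref <- next_coding()
      ex <- ref$exons[1L, ]
      strand <- if (ref$strand == "+") "-" else "+"
      a_start <- ex["start"] + 10
      a_end <- min(ex["end"], a_start + 140)
      b_start <- a_end + sample(300:500, 1L)
      exons <- cbind(start = c(a_start, b_start),
                     end = c(a_end, b_start + 160))
      add_candidate(transcript_model(sprintf("CAND%03d.1", idx),
                                     sprintf("CANDG%03d", idx), ref$chrom,
                                     strand, exons), "antisense")
    }
    for (k in seq_len(counts["sense"])) {
      idx <- idx + 1L
      ref <- next_coding()
      body_end <- max(ref$exons[, "end"])
      gap <- sample(300:1200, 1L)
      pos <- body_end + gap
      exons <- cbind(start = c(pos, pos + 150 + 300),
                     end = c(pos + 150, pos + 150 + 300 + 150))
      add_candidate(transcript_model(sprintf("CAND%03d.1", idx),
                                     sprintf("CANDG%03d", idx), ref$chrom,
                                     ref$strand, exons), "sense")
    }
    for (k in seq_len(counts["intronic"])) {
      idx <- idx + 1L
      ref <- next_coding()
      i_s <- ref$exons[1L, "end"]; i_e <- ref$exons[2L, "start"]
      pos <- i_s + 100
      exons <- cbind(start = c(pos, pos + 150 + 200),
                     end = c(pos + 150, pos + 150 + 200 + 150))
      stopifnot(max(exons[, "end"]) <= i_e - 50)
      add_candidate(transcript_model(sprintf("CAND%03d.1", idx),
                                     sprintf("CANDG%03d", idx), ref$chrom,
                                     ref$strand, exons), "intronic")
    }

    add_decoy <- function(m, filter, sequence) {
      models[[length(models) + 1L]] <<- m
      seqs[m$transcript_id] <<- sequence
      decoy_rows[[length(decoy_rows) + 1L]] <<- data.frame(
        transcript_id = m$transcript_id, gene_id = m$gene_id,
        filter = filter, monoexonic = nrow(m$exons) == 1L,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(decoys_per_filter)) {
      # fails length only
      cl <- next_cell()
      len <- sample(120:200, 1L)
      m <- transcript_model(sprintf("DEC_LEN%d.1", k),
                            sprintf("DECG_LEN%d", k), cl$chrom,
                            sample(c("+", "-"), 1L),
                            cbind(start = cl$start, end = cl$start + len))
      add_decoy(m, "length", .random_seq_noatg(len))

      # fails same-strand annotation overlap only
      ref <- next_coding()
      ex <- ref$exons[nrow(ref$exons), ]
      a_start <- ex["start"] + 5
      a_end <- min(ex["end"], a_start + 120)
      b_start <- a_end + 350
      m <- transcript_model(sprintf("DEC_OVL%d.1", k),
                            sprintf("DECG_OVL%d", k), ref$chrom, ref$strand,
                            cbind(start = c(a_start, b_start),
                                  end = c(a_end, b_start + 180)))
      add_decoy(m, "overlap", .random_seq_noatg(m$length_nt))

      # mono-exonic, fails the 2,000 nt distance rule only
      ref <- next_coding()
      gap <- sample(400:1500, 1L)
      pos <- max(ref$exons[, "end"]) + gap
      len <- sample(300:700, 1L)
      m <- transcript_model(sprintf("DEC_DST%d.1", k),
                            sprintf("DECG_DST%d", k), ref$chrom,
                            sample(c("+", "-"), 1L),
                            cbind(start = pos, end = pos + len))
      add_decoy(m, "distance", .random_seq_noatg(len))

      # mono-exonic far from genes, fails the FPKM rule only (count
      # simulator gives it near-zero expression)
      cl <- next_cell()
      m <- transcript_model(sprintf("DEC_FPK%d.1", k),
                            sprintf("DECG_FPK%d", k), cl$chrom,
                            sample(c("+", "-"), 1L),
                            cbind(start = cl$start, end = cl$start + 1200))
      add_decoy(m, "fpkm", .random_seq_noatg(1200))

      # multi-exonic far from genes, fails the coding-potential rule only
      cl <- next_cell()
      pos <- cl$start
      m <- transcript_model(sprintf("DEC_CPC%d.1", k),
                            sprintf("DECG_CPC%d", k), cl$chrom,
                            sample(c("+", "-"), 1L),
                            cbind(start = c(pos, pos + 600 + 400),
                                  end = c(pos + 600, pos + 600 + 400 + 600)))
      add_decoy(m, "coding", .coding_seq(m$length_nt, 0.8))
    }

    candidates <- do.call(rbind, cand_rows)
    decoys <- do.call(rbind, decoy_rows)
    n_cand <- nrow(candidates)
    dpf <- decoys_per_filter
    mono_cand <- sum(candidates$monoexonic)
    multi_cand <- n_cand - mono_cand
    # expected audit: every decoy fails exactly its own filter
    n0 <- n_cand + nrow(decoys)
    n1 <- n0 - dpf                                   # length decoys out
    n2 <- n1 - dpf                                   # overlap decoys out
    mono3 <- mono_cand + 2L * dpf                    # distance + fpkm decoys
    multi3 <- multi_cand + dpf                       # coding decoys
    mono4 <- mono3 - dpf
    mono5 <- mono4 - dpf
    novel <- mono5 + multi3
    final <- novel - dpf
    audit_expected <- data.frame(
      step = c("merged_transcriptome", "length_strand", "annotation_overlap",
               "exon_number", "distance", "expression", "novel_transcripts",
               "coding_potential"),
      n_mono = c(NA, NA, NA, mono3, mono4, mono5, NA, NA),
      n_multi = c(NA, NA, NA, multi3, multi3, multi3, NA, NA),
      n_total = c(n0, n1, n2, mono3 + multi3, mono4 + multi3,
                  mono5 + multi3, novel, final),
      stringsAsFactors = FALSE)
    list(assembly = annotation_set(models), sequences = seqs,
         manifest = list(candidates = candidates, decoys = decoys,
                         audit_expected = audit_expected,
                         low_expression_ids =
                           decoys$gene_id[decoys$filter == "fpkm"],
                         class_counts = as.list(counts)))
  })
}

#' Simulate paired tumor/normal NB counts and derived FPKM
#'
#' Negative-binomial counts for `n_tumor` tumor and `n_normal` normal
#' samples with planted fold changes on a subset of genes, optional planted
#' per-sample library-size factors, and FPKM derived from the counts,
#' transcript lengths and library sizes (plus a constant background library
#' standing in for the unsimulated remainder of the transcriptome).
#'
#' @param genes Data frame with `gene_id`, `transcript_id`, `length_nt`.
#' @param seed RNG seed.
#' @param n_tumor,n_normal Samples per condition.
#' @param dispersion NB dispersion alpha.
#' @param de_fraction Fraction of genes given a fold change.
#' @param log2fc Planted |log2 fold change| (tumor over normal).
#' @param size_factors Optional per-sample multipliers (length
#'   `n_tumor + n_normal`); default all 1.
#' @param base_mean_range Range of baseline normalized means (log-uniform).
#' @param low_expression_ids Gene ids forced to near-zero expression.
#' @param force_de Optional list with `up`/`down` gene id vectors that must
#'   be differentially expressed, at `force_lfc`.
#' @param force_lfc |log2FC| for `force_de` genes.
#' @param background_lib Constant added to each library size for FPKM.
#' @return List with `counts` (gene rows), `fpkm` (transcript rows),
#'   `expr_gene` (FPKM re-keyed by gene id), `condition`, `samples` and
#'   `manifest` (`de`, `size_factor_truth`).
#' @export
simulate_counts <- function(genes, seed, n_tumor = 8, n_normal = 8,
                            dispersion = 0.2, de_fraction = 0.15,
                            log2fc = 2.5, size_factors = NULL,
                            base_mean_range = c(30, 400),
                            low_expression_ids = character(),
                            force_de = list(), force_lfc = 3.5,
                            background_lib = 4e6) {
  stopifnot(n_tumor >= 2, n_normal >= 2, dispersion >= 0,
            all(c("gene_id", "transcript_id", "length_nt") %in% names(genes)))
  .with_seed(seed, {
    ns <- n_tumor + n_normal
    if (is.null(size_factors)) size_factors <- rep(1, ns)
    stopifnot(length(size_factors) == ns, all(size_factors > 0))
    samples <- c(sprintf("T%02d", seq_len(n_tumor)),
                 sprintf("N%02d", seq_len(n_normal)))
    condition <- c(rep("tumor", n_tumor), rep("normal", n_normal))
    g <- genes$gene_id
    q <- exp(stats::runif(length(g), log(base_mean_range[1]),
                          log(base_mean_range[2])))
    names(q) <- g
    q[intersect(low_expression_ids, g)] <- 0.005
    lfc <- setNames(rep(0, length(g)), g)
    forced_up <- intersect(force_de$up %||% character(), g)
    forced_down <- intersect(force_de$down %||% character(), g)
    lfc[forced_up] <- force_lfc
    lfc[forced_down] <- -force_lfc
    n_extra <- max(0L, round(de_fraction * length(g)) -
                     length(forced_up) - length(forced_down))
    pool <- setdiff(g, c(forced_up, forced_down, low_expression_ids))
    extra <- if (n_extra > 0L && length(pool)) {
      sample(pool, min(n_extra, length(pool)))
    } else character()
    lfc[extra] <- ifelse(seq_along(extra) %% 2L == 1L, log2fc, -log2fc)
    mu <- outer(q, rep(1, ns))
    mu[, condition == "tumor"] <- mu[, condition == "tumor"] *
      2^lfc[rownames(mu) %||% g]
    mu <- sweep(mu, 2L, size_factors, "*")
    counts <- matrix(
      if (dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(length(mu), lambda = mu)
      },
      nrow = nrow(mu), dimnames = list(g, samples))
    len_kb <- setNames(genes$length_nt / 1000, g)
    lib <- colSums(counts) + background_lib
    fpkm <- sweep(sweep(counts, 1L, len_kb, "/"), 2L, lib / 1e6, "/")
    rownames(fpkm) <- genes$transcript_id[match(rownames(counts),
                                                genes$gene_id)]
    expr_gene <- fpkm
    rownames(expr_gene) <- g
    de <- data.frame(gene_id = names(lfc)[lfc != 0],
                     true_log2fc = unname(lfc[lfc != 0]),
                     stringsAsFactors = FALSE)
    list(counts = counts, fpkm = fpkm, expr_gene = expr_gene,
         condition = condition, samples = samples,
         manifest = list(de = de,
                         size_factor_truth = setNames(size_factors, samples)))
  })
}

#' Simulate promoter CpG methylation anti-correlated with expression
#'
#' For each planted gene, one CpG is placed 300-1,500 nt strictly upstream
#' of its TSS and its beta values are a logistic transform of the gene's
#' standardized expression mixed with noise at latent correlation `rho`
#' (negative: methylation suppresses expression). Background CpGs carry
#' independent Beta(2, 2) values.
#'
#' @param expr Gene-level expression matrix (the 16-sample design).
#' @param annotation Merged [annotation_set()] covering the planted genes.
#' @param planted_genes Gene ids to anti-correlate.
#' @param seed RNG seed.
#' @param rho Latent correlation (default -0.7).
#' @param n_background Number of background CpGs.
#' @return List with `methylation` ([methylation_table()]) and `manifest`
#'   (data frame `gene_id`, `cpg_id`, `rho`).
#' @export
simulate_methylation <- function(expr, annotation, planted_genes, seed,
                                 rho = -0.7, n_background = 40) {
  stopifnot(abs(rho) <= 1)
  planted_genes <- intersect(planted_genes, rownames(expr))
  .with_seed(seed, {
    ns <- ncol(expr)
    cgn <- 0L
    sites <- list(); beta <- list(); man <- list()
    for (g in planted_genes) {
      tx_ids <- annotation$tx$transcript_id[annotation$tx$gene_id == g]
      if (!length(tx_ids)) next
      t <- get_transcript(annotation, tx_ids[1L])
      if (t$strand == "*") next
      p <- tss(t)
      up <- sample(300:1500, 1L)
      pos <- if (t$strand == "+") p - up else p + up
      cgn <- cgn + 1L
      id <- sprintf("cg%08d", cgn)
      sx <- as.numeric(scale(expr[g, ]))
      if (any(!is.finite(sx))) sx <- rep(0, ns)
      latent <- rho * sx + sqrt(1 - rho^2) * stats::rnorm(ns)
      b <- stats::plogis(0.9 * latent)
      sites[[cgn]] <- data.frame(cpg_id = id, chrom = t$chrom, pos = pos,
                                 stringsAsFactors = FALSE)
      beta[[cgn]] <- b
      man[[length(man) + 1L]] <- data.frame(gene_id = g, cpg_id = id,
                                            rho = rho, stringsAsFactors = FALSE)
    }
    chroms <- unique(annotation$tx$chrom)
    span <- max(annotation$tx$end)
    for (k in seq_len(n_background)) {
      cgn <- cgn + 1L
      sites[[cgn]] <- data.frame(cpg_id = sprintf("cg%08d", cgn),
                                 chrom = sample(chroms, 1L),
                                 pos = sample.int(span, 1L),
                                 stringsAsFactors = FALSE)
      beta[[cgn]] <- stats::rbeta(ns, 2, 2)
    }
    sites <- do.call(rbind, sites)
    bmat <- do.call(rbind, beta)
    dimnames(bmat) <- list(sites$cpg_id, colnames(expr))
    list(methylation = methylation_table(sites, bmat),
         manifest = if (length(man)) do.call(rbind, man) else
           data.frame(gene_id = character(), cpg_id = character(),
                      rho = double(), stringsAsFactors = FALSE))
  })
}

#' Simulate CNV segment calls with one planted deletion
#'
#' One significant deletion segment covering the given (down-regulated)
#' gene's body, one significant amplification in gene-free space, and a few
#' non-significant segments (q >= 0.25).
#'
#' @param annotation Merged [annotation_set()].
#' @param deletion_gene Gene id the deletion must cover.
#' @param seed RNG seed.
#' @return List with `segments` (data frame) and `manifest`.
#' @export
simulate_cnv <- function(annotation, deletion_gene, seed) {
  tx <- annotation$tx[annotation$tx$gene_id == deletion_gene, , drop = FALSE]
  if (!nrow(tx)) stop("deletion_gene not found in annotation: ", deletion_gene)
  .with_seed(seed, {
    del <- data.frame(chrom = tx$chrom[1L],
                      start = max(0, min(tx$start) - 3000),
                      end = max(tx$end) + 3000,
                      kind = "deletion", q_value = 0.01,
                      stringsAsFactors = FALSE)
    span <- max(annotation$tx$end)
    amp <- data.frame(chrom = annotation$tx$chrom[1L],
                      start = span + 20000, end = span + 60000,
                      kind = "amplification", q_value = 0.05,
                      stringsAsFactors = FALSE)
    ns <- lapply(1:3, function(k) {
      s <- sample.int(span, 1L)
      data.frame(chrom = sample(unique(annotation$tx$chrom), 1L),
                 start = s, end = s + sample(5000:20000, 1L),
                 kind = sample(c("amplification", "deletion"), 1L),
                 q_value = stats::runif(1, 0.3, 0.9),
                 stringsAsFactors = FALSE)
    })
    segments <- rbind(del, amp, do.call(rbind, ns))
    list(segments = segments,
         manifest = list(deletion_gene = deletion_gene,
                         deletion_q = 0.01))
  })
}

#' Simulate TSS-centered ChIP peaks with class-ordered intensity
#'
#' Each transcript gets one peak centered on its TSS whose signal is the
#' class intensity (protein-coding > annotated lncRNA > candidate) times
#' log-normal noise; background peaks are scattered at low signal. Two
#' marks are emitted (the promoter mark at full intensity, the enhancer
#' mark at 80%).
#'
#' @param transcripts List of stranded `transcript_model`s.
#' @param classes Class label per transcript (names of `intensities`).
#' @param seed RNG seed.
#' @param intensities Named mean signal per class.
#' @param peak_halfwidth Half-width of TSS peaks, nt.
#' @param n_background Background peaks per mark.
#' @return List with `h3k4me3`, `h3k27ac` (peak data frames) and
#'   `manifest` (the intensity ordering).
#' @export
simulate_chip <- function(transcripts, classes, seed,
                          intensities = c(protein_coding = 10,
                                          annotated_lncRNA = 5,
                                          candidate = 2),
                          peak_halfwidth = 300, n_background = 40) {
  stopifnot(length(transcripts) == length(classes),
            all(classes %in% names(intensities)))
  .with_seed(seed, {
    mk <- function(scale_f) {
      rows <- lapply(seq_along(transcripts), function(i) {
        t <- transcripts[[i]]
        p <- tss(t)
        data.frame(chrom = t$chrom, start = max(0, p - peak_halfwidth),
                   end = p + peak_halfwidth,
                   signal = intensities[classes[i]] * scale_f *
                     exp(stats::rnorm(1, 0, 0.15)),
                   stringsAsFactors = FALSE)
      })
      span <- max(vapply(transcripts, function(t) max(t$exons[, "end"]), 0))
      chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
      bg <- lapply(seq_len(n_background), function(k) {
        s <- sample.int(span, 1L)
        data.frame(chrom = sample(chroms, 1L), start = s, end = s + 400,
                   signal = stats::runif(1, 0.2, 1),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, c(rows, bg))
      out <- out[order(out$chrom, out$start), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    list(h3k4me3 = mk(1), h3k27ac = mk(0.8),
         manifest = list(intensities = as.list(intensities)))
  })
}

#' Simulate a conservation score track over gene bodies
#'
#' Per-region scores: exons of protein-coding genes are most conserved,
#' introns least, lncRNA (annotated or candidate) exons/introns in between,
#' with small Gaussian noise. The track covers every exonic and intronic
#' base of the given transcripts.
#'
#' @param transcripts List of `transcript_model`s.
#' @param classes Class label per transcript.
#' @param seed RNG seed.
#' @param exon_means,intron_means Named per-class means.
#' @return List with `track` (bedGraph-like data frame) and `manifest`.
#' @export
simulate_conservation <- function(transcripts, classes, seed,
                                  exon_means = c(protein_coding = 0.75,
                                                 annotated_lncRNA = 0.35,
                                                 candidate = 0.35),
                                  intron_means = c(protein_coding = 0.30,
                                                   annotated_lncRNA = 0.12,
                                                   candidate = 0.12)) {
  stopifnot(length(transcripts) == length(classes))
  .with_seed(seed, {
    rows <- list()
    for (i in seq_along(transcripts)) {
      t <- transcripts[[i]]
      ex <- t$exons
      for (j in seq_len(nrow(ex))) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = t$chrom, start = ex[j, "start"], end = ex[j, "end"],
          score = min(1, max(0, stats::rnorm(1, exon_means[classes[i]], 0.02))),
          stringsAsFactors = FALSE)
      }
      if (nrow(ex) > 1L) {
        for (j in seq_len(nrow(ex) - 1L)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = t$chrom, start = ex[j, "end"], end = ex[j + 1L, "start"],
            score = min(1, max(0, stats::rnorm(1, intron_means[classes[i]],
                                               0.02))),
            stringsAsFactors = FALSE)
        }
      }
    }
    track <- do.call(rbind, rows)
    track <- track[order(track$chrom, track$start), , drop = FALSE]
    rownames(track) <- NULL
    list(track = track,
         manifest = list(exon_means = as.list(exon_means),
                         intron_means = as.list(intron_means)))
  })
}

#' Simulate a validation cohort with survival follow-up
#'
#' Log-scale expression for all genes in `n_tumor` tumor and `n_normal`
#' normal samples, reproducing the planted fold changes at 80% strength
#' (an independent cohort rarely shows the full discovery effect). For the
#' tumor patients, exponential survival times with hazard ratio `hr` for
#' patients whose expression of `prognostic_gene` exceeds its median;
#' roughly `censor_frac` of patients are censored uniformly within their
#' follow-up.
#'
#' @param genes Data frame with `gene_id`.
#' @param de Data frame `gene_id`, `true_log2fc` (planted fold changes).
#' @param prognostic_gene Gene id carrying the survival signal.
#' @param seed RNG seed.
#' @param n_tumor,n_normal Cohort sizes.
#' @param hr Planted hazard ratio (high vs low expression).
#' @param censor_frac Expected censoring fraction.
#' @param baseline_median_days Median survival of the low-risk arm.
#' @return List with `expr` (genes x samples), `labels`, `cohort` (tumor
#'   patients: `patient_id`, `time_days`, `event`, gene columns) and
#'   `manifest`.
#' @export
simulate_cohort <- function(genes, de, prognostic_gene, seed,
                            n_tumor = 170, n_normal = 28, hr = 3,
                            censor_frac = 0.15,
                            baseline_median_days = 900) {
  stopifnot(prognostic_gene %in% genes$gene_id)
  .with_seed(seed, {
    g <- genes$gene_id
    ns <- n_tumor + n_normal
    samples <- c(sprintf("VC_T%03d", seq_len(n_tumor)),
                 sprintf("VC_N%03d", seq_len(n_normal)))
    labels <- c(rep("tumor", n_tumor), rep("normal", n_normal))
    mu <- stats::runif(length(g), 4, 8)
    expr <- matrix(stats::rnorm(length(g) * ns, mean = mu, sd = 1),
                   nrow = length(g), dimnames = list(g, samples))
    lfc <- setNames(rep(0, length(g)), g)
    hit <- intersect(de$gene_id, g)
    lfc[hit] <- de$true_log2fc[match(hit, de$gene_id)]
    expr[, labels == "tumor"] <- expr[, labels == "tumor"] + 0.8 * lfc
    tumor_expr <- expr[, labels == "tumor", drop = FALSE]
    x <- tumor_expr[prognostic_gene, ]
    high <- x > stats::median(x)
    rate <- log(2) / baseline_median_days * ifelse(high, hr, 1)
    t_true <- stats::rexp(n_tumor, rate = rate)
    censored <- stats::runif(n_tumor) < censor_frac
    time <- ifelse(censored, t_true * stats::runif(n_tumor, 0.1, 0.9), t_true)
    time <- pmax(1, round(time))
    event <- as.integer(!censored)
    cohort <- data.frame(patient_id = sprintf("P%03d", seq_len(n_tumor)),
                         time_days = time, event = event,
                         stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(t(tumor_expr), check.names = FALSE))
    rownames(cohort) <- NULL
    list(expr = expr, labels = labels, cohort = cohort,
         manifest = list(prognostic_gene = prognostic_gene, hr = hr,
                         high_group = cohort$patient_id[high],
                         censor_frac = censor_frac))
  })
}

#' Generate the full synthetic study and write it to a directory
#'
#' Runs every generator off named substreams of one root seed and writes
#' the complete input bundle the pipeline consumes: reference and assembled
#' GTFs, transcript sequences, count/FPKM matrices with sample labels,
#' methylation table, CNV segments, two ChIP peak tracks, a conservation
#' track, term sets, a validation cohort and `manifest.json` with the full
#' ground truth.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Root seed; all generators derive named sub-seeds from it.
#' @param n_coding,n_lncRNA,n_true_candidates,decoys_per_filter,n_cohort
#'   Principal sizes of the study.
#' @param ... Passed through to [simulate_counts()].
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
simulate_all <- function(outdir, seed, n_coding = 30, n_lncRNA = 15,
                         n_true_candidates = 12, decoys_per_filter = 2,
                         n_cohort = 170, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_annotation(.sub_seed(seed, "annotation"),
                             n_coding = n_coding, n_lncRNA = n_lncRNA)
  asm <- simulate_assembly(ref, .sub_seed(seed, "assembly"),
                           n_true_candidates = n_true_candidates,
                           decoys_per_filter = decoys_per_filter)
  merged <- annotation_set(c(unname(ref$transcripts),
                             unname(asm$assembly$transcripts)))
  gene_table <- data.frame(
    gene_id = merged$tx$gene_id, transcript_id = merged$tx$transcript_id,
    length_nt = merged$tx$length_nt, stringsAsFactors = FALSE)

  cand <- asm$manifest$candidates
  intergenic <- cand$gene_id[cand$positional_class == "intergenic"]
  up_cand <- intergenic[seq_len(min(2L, length(intergenic)))]
  down_pool <- setdiff(cand$gene_id, up_cand)
  down_cand <- down_pool[seq_len(min(2L, length(down_pool)))]
  cnt <- simulate_counts(gene_table, .sub_seed(seed, "counts"),
                         low_expression_ids = asm$manifest$low_expression_ids,
                         force_de = list(up = up_cand, down = down_cand), ...)
  de_man <- cnt$manifest$de

  meth <- simulate_methylation(cnt$expr_gene, merged,
                               planted_genes = de_man$gene_id[
                                 seq_len(min(6L, nrow(de_man)))],
                               seed = .sub_seed(seed, "methylation"))
  cnv <- simulate_cnv(merged, deletion_gene = down_cand[1L],
                      seed = .sub_seed(seed, "cnv"))

  tx_models <- unname(merged$transcripts)
  tx_classes <- ifelse(merged$tx$biotype == "unannotated", "candidate",
                       merged$tx$biotype)
  chip <- simulate_chip(tx_models, tx_classes, .sub_seed(seed, "chip"))
  cons <- simulate_conservation(tx_models, tx_classes,
                                .sub_seed(seed, "conservation"))
  cohort <- simulate_cohort(gene_table, de_man,
                            prognostic_gene = up_cand[1L],
                            seed = .sub_seed(seed, "cohort"),
                            n_tumor = n_cohort)

  # term sets over protein-coding genes: one per planted direction + noise
  coding_genes <- sort(merged$tx$gene_id[merged$tx$biotype == "protein_coding"])
  up_coding <- intersect(de_man$gene_id[de_man$true_log2fc > 0], coding_genes)
  down_coding <- intersect(de_man$gene_id[de_man$true_log2fc < 0], coding_genes)
  terms <- .with_seed(.sub_seed(seed, "terms"), {
    ts <- list(upregulated_program = up_coding,
               downregulated_program = down_coding)
    for (k in 1:6) {
      ts[[sprintf("random_term_%d", k)]] <-
        sort(sample(coding_genes, min(8L, length(coding_genes))))
    }
    ts[lengths(ts) > 0]
  })

  paths <- list(
    reference_gtf = file.path(outdir, "reference.gtf"),
    assembly_gtf = file.path(outdir, "assembly.gtf"),
    sequences_fa = file.path(outdir, "sequences.fa"),
    counts_tsv = file.path(outdir, "counts.tsv"),
    fpkm_tsv = file.path(outdir, "fpkm.tsv"),
    samples_tsv = file.path(outdir, "samples.tsv"),
    methylation_tsv = file.path(outdir, "methylation.tsv"),
    cnv_bed = file.path(outdir, "cnv.bed"),
    peaks_h3k4me3_bed = file.path(outdir, "peaks_h3k4me3.bed"),
    peaks_h3k27ac_bed = file.path(outdir, "peaks_h3k27ac.bed"),
    conservation_bedgraph = file.path(outdir, "conservation.bedgraph"),
    terms_gmt = file.path(outdir, "terms.gmt"),
    cohort_expression_tsv = file.path(outdir, "cohort_expression.tsv"),
    cohort_labels_tsv = file.path(outdir, "cohort_labels.tsv"),
    cohort_survival_tsv = file.path(outdir, "cohort_survival.tsv"),
    manifest_json = file.path(outdir, "manifest.json"))

  write_gtf(ref, paths$reference_gtf)
  write_gtf(asm$assembly, paths$assembly_gtf)
  write_fasta_sequences(asm$sequences, paths$sequences_fa)
  write_expression_tsv(cnt$counts, paths$counts_tsv)
  write_expression_tsv(cnt$fpkm, paths$fpkm_tsv)
  utils::write.table(data.frame(sample = cnt$samples,
                                condition = cnt$condition),
                     paths$samples_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_methylation_tsv(meth$methylation, paths$methylation_tsv)
  utils::write.table(cnv$segments, paths$cnv_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(chip$h3k4me3, paths$peaks_h3k4me3_bed, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(chip$h3k27ac, paths$peaks_h3k27ac_bed, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cons$track, paths$conservation_bedgraph, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gmt(terms, paths$terms_gmt)
  write_expression_tsv(cohort$expr, paths$cohort_expression_tsv)
  utils::write.table(data.frame(sample = colnames(cohort$expr),
                                condition = cohort$labels),
                     paths$cohort_labels_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$cohort, paths$cohort_survival_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(seed = seed,
                   samples = list(tumor = sum(cnt$condition == "tumor"),
                                  normal = sum(cnt$condition == "normal")),
                   candidates = asm$manifest$candidates,
                   decoys = asm$manifest$decoys,
                   audit_expected = asm$manifest$audit_expected,
                   class_counts = asm$manifest$class_counts,
                   low_expression_ids = asm$manifest$low_expression_ids,
                   de = de_man,
                   size_factor_truth = as.list(cnt$manifest$size_factor_truth),
                   methylation = meth$manifest,
                   cnv = cnv$manifest,
                   chip = chip$manifest,
                   conservation = cons$manifest,
                   cohort = cohort$manifest[c("prognostic_gene", "hr",
                                              "censor_frac")],
                   files = paths)
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
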