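test_that("annotation generator is deterministic and well-formed", {
  a1 <- simulate_annotation(99, n_coding = 10, n_lncRNA = 5)
  a2 <- simulate_annotation(99, n_coding = 10, n_lncRNA = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(a1, f1); write_gtf(a2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  expect_equal(sum(a1$tx$biotype == "protein_coding"), 10)
  expect_equal(sum(a1$tx$biotype == "annotated_lncRNA"), 5)
  # round trip through the parser preserves every invariant
  back <- parse_gtf(f1)
  expect_setequal(transcript_ids(back), transcript_ids(a1))
  for (id in transcript_ids(back)) {
    m <- get_transcript(back, id)
    expect_true(all(m$exons[, "end"] > m$exons[, "start"]))
    expect_equal(m$length_nt, sum(m$exons[, "end"] - m$exons[, "start"]))
  }
  expect_error(simulate_annotation(1, n_coding = 500, n_lncRNA = 500,
                                   genome_size = 2e5),
               "infeasible")
})

test_that("every decoy fails exactly its intended filter", {
  sim <- sim_bundle()
  man <- sim$manifest
  asm <- parse_gtf(man$files$assembly_gtf)
  ref <- parse_gtf(man$files$reference_gtf)
  fpkm <- read_expression_tsv(man$files$fpkm_tsv)
  seqs <- read_fasta_sequences(man$files$sequences_fa)

  fails <- function(id) {
    m <- get_transcript(asm, id)
    ov <- sum(vapply(ref$transcripts, function(r)
      exonic_overlap_bp(m, r, "same"), 0))
    d <- min(vapply(ref$transcripts, function(r)
      transcript_distance(m, r), 0))
    maxf <- if (id %in% rownames(fpkm)) max(fpkm[id, ]) else 0
    mono <- nrow(m$exons) == 1
    c(length = m$length_nt <= 200 || m$strand == "*",
      overlap = ov > 0,
      distance = mono && d <= 2000,
      fpkm = mono && maxf <= 0.5,
      coding = coding_potential_score(seqs[[id]]) > 0)
  }
  for (i in seq_len(nrow(man$decoys))) {
    f <- fails(man$decoys$transcript_id[i])
    expect_equal(unname(which(f)),
                 match(man$decoys$filter[i], names(f)),
                 info = man$decoys$transcript_id[i])
  }
  # planted candidates fail nothing
  for (id in man$candidates$transcript_id) {
    expect_false(any(fails(id)), info = id)
  }
  # planted antisense candidates have opposite-strand overlap by construction
  anti <- man$candidates$transcript_id[
    man$candidates$positional_class == "antisense"]
  for (id in anti) {
    m <- get_transcript(asm, id)
    ov <- sum(vapply(ref$transcripts, function(r)
      exonic_overlap_bp(m, r, "opposite"), 0))
    expect_gt(ov, 0)
  }
  # emitted class counts match the apportionment recorded in the manifest
  expect_equal(as.list(table(man$candidates$positional_class))[
    names(man$class_counts)], man$class_counts)
})

test_that("count generator: determinism, null mode, NB moments", {
  genes <- data.frame(gene_id = sprintf("G%03d", 1:300),
                      transcript_id = sprintf("G%03d.1", 1:300),
                      length_nt = 1000)
  c1 <- simulate_counts(genes, seed = 5)
  c2 <- simulate_counts(genes, seed = 5)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$fpkm, c2$fpkm)

  c0 <- simulate_counts(genes, seed = 6, de_fraction = 0)
  expect_equal(nrow(c0$manifest$de), 0)

  # sample moments consistent with NB(mu, alpha): pooled over genes the
  # variance/mean relationship var = mu + alpha mu^2 must hold
  set.seed(7)
  big <- simulate_counts(genes, seed = 7, de_fraction = 0, dispersion = 0.3,
                         n_tumor = 250, n_normal = 250)
  m <- rowMeans(big$counts)
  v <- apply(big$counts, 1, stats::var)
  alpha_hat <- stats::median((v - m) / m^2, na.rm = TRUE)
  expect_gt(alpha_hat, 0.2)
  expect_lt(alpha_hat, 0.4)
})

test_that("planted methylation pairs carry the intended anti-correlation", {
  sim <- sim_bundle()
  man <- sim$manifest
  meth <- read_methylation_tsv(man$files$methylation_tsv)
  fpkm <- read_expression_tsv(man$files$fpkm_tsv)
  merged <- annotation_set(c(
    unname(parse_gtf(man$files$reference_gtf)$transcripts),
    unname(parse_gtf(man$files$assembly_gtf)$transcripts)))
  expr <- fpkm
  rownames(expr) <- merged$tx$gene_id[match(rownames(fpkm),
                                            merged$tx$transcript_id)]
  for (i in seq_len(nrow(man$methylation))) {
    g <- man$methylation$gene_id[i]; cg <- man$methylation$cpg_id[i]
    r <- stats::cor(as.numeric(expr[g, ]), as.numeric(meth$beta[cg, ]))
    expect_lt(r, -0.3)
    # and the CpG really sits in the gene's promoter
    txid <- merged$tx$transcript_id[merged$tx$gene_id == g][1]
    expect_true(cg %in% promoter_cpgs(get_transcript(merged, txid), meth))
  }
})

test_that("the planted deletion covers its down-regulated target gene", {
  sim <- sim_bundle()
  man <- sim$manifest
  segs <- read_cnv_bed(man$files$cnv_bed)
  del <- segs[segs$kind == "deletion" & segs$q_value < 0.25, ]
  g <- man$cnv$deletion_gene
  merged <- annotation_set(c(
    unname(parse_gtf(man$files$reference_gtf)$transcripts),
    unname(parse_gtf(man$files$assembly_gtf)$transcripts)))
  tx <- merged$tx[merged$tx$gene_id == g, ]
  hit <- any(del$chrom == tx$chrom & del$start < tx$end & tx$start < del$end)
  expect_true(hit)
  # the target is planted as down-regulated
  expect_lt(man$de$true_log2fc[man$de$gene_id == g], 0)
})

test_that("cohort generator: planted hazard ratio and null calibration", {
  genes <- data.frame(gene_id = c("PG", sprintf("X%02d", 1:10)),
                      transcript_id = c("PG.1", sprintf("X%02d.1", 1:10)),
                      length_nt = 800)
  de <- data.frame(gene_id = "PG", true_log2fc = 3)
  co <- simulate_cohort(genes, de, "PG", seed = 31, n_tumor = 170)
  expect_equal(nrow(co$cohort), 170)
  expect_true(all(co$cohort$time_days > 0))
  expect_true(all(co$cohort$event %in% 0:1))
  # the planted high-expression arm dies faster
  high <- co$cohort$patient_id %in% co$manifest$high_group
  lr <- logrank_test(co$cohort$time_days[high], co$cohort$event[high],
                     co$cohort$time_days[!high], co$cohort$event[!high])
  expect_lt(lr$p_value, 0.01)

  # HR = 1: log-rank p approximately uniform over replicates
  set.seed(808)
  ps <- vapply(1:100, function(r) {
    co0 <- simulate_cohort(genes, de, "PG", seed = 1000 + r, n_tumor = 60,
                           hr = 1)
    high0 <- co0$cohort$patient_id %in% co0$manifest$high_group
    logrank_test(co0$cohort$time_days[high0], co0$cohort$event[high0],
                 co0$cohort$time_days[!high0],
                 co0$cohort$event[!high0])$p_value
  }, 0)
  expect_gt(mean(ps > 0.05), 0.80)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("manifest ids all exist in the emitted files", {
  sim <- sim_bundle()
  man <- sim$manifest
  asm_ids <- transcript_ids(parse_gtf(man$files$assembly_gtf))
  expect_true(all(man$candidates$transcript_id %in% asm_ids))
  expect_true(all(man$decoys$transcript_id %in% asm_ids))
  seqs <- read_fasta_sequences(man$files$sequences_fa)
  expect_setequal(names(seqs), asm_ids)
  counts <- read_expression_tsv(man$files$counts_tsv)
  expect_true(all(man$de$gene_id %in% rownames(counts)))
  cohort <- read_survival_tsv(man$files$cohort_survival_tsv)
  expect_true(man$cohort$prognostic_gene %in% colnames(cohort))
  expect_true(file.exists(man$files$manifest_json))
})
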