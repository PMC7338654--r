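# small hand-built screen fixture: one reference coding gene, assembled
# transcripts probing each filter boundary
make_screen_fixture <- function() {
  ref <- annotation_set(list(
    transcript_model("REF1.1", "REF1", "chr1", "+",
                     rbind(c(10000, 10300), c(12000, 12400)),
                     "protein_coding")))
  asm <- list(
    # exactly 200 nt: boundary fails the exclusive length filter
    len200 = transcript_model("len200", "g_len200", "chr1", "+",
                              rbind(c(50000, 50200))),
    len201 = transcript_model("len201", "g_len201", "chr1", "+",
                              rbind(c(60000, 60201))),
    # mono-exonic 1,500 nt from the reference gene: distance filter
    near1500 = transcript_model("near1500", "g_near", "chr1", "-",
                                rbind(c(13900, 14400))),
    unstranded = transcript_model("nostrand", "g_ns", "chr1", "*",
                                  rbind(c(70000, 70500))),
    far_ok = transcript_model("far_ok", "g_far", "chr1", "+",
                              rbind(c(90000, 90600))))
  list(ref = ref, asm = annotation_set(asm))
}

test_that("filter cascade boundaries: length, strand, mono-exon distance", {
  fx <- make_screen_fixture()
  fpkm <- matrix(5, nrow = 5, ncol = 2,
                 dimnames = list(transcript_ids(fx$asm), c("s1", "s2")))
  seqs <- setNames(vapply(transcript_ids(fx$asm), function(id) {
    paste(rep("C", get_transcript(fx$asm, id)$length_nt), collapse = "")
  }, ""), transcript_ids(fx$asm))
  res <- screen_candidates(fx$asm, fx$ref, fpkm, sequences = seqs)
  expect_false("len200" %in% res$candidates)    # length > 200 is exclusive
  expect_true("len201" %in% res$candidates)
  expect_false("nostrand" %in% res$candidates)  # unstranded removed at step 1
  expect_false("near1500" %in% res$candidates)  # 1,500 nt < 2,000 nt
  expect_true("far_ok" %in% res$candidates)
  # audit counts are non-increasing step over step (within each branch)
  tot <- res$audit$n_total
  expect_true(all(diff(tot[-4]) <= 0))
  mono <- res$audit$n_mono[!is.na(res$audit$n_mono)]
  expect_true(all(diff(mono) <= 0))
})

test_that("mono-exonic expression filter is exclusive at max FPKM 0.5", {
  fx <- make_screen_fixture()
  ids <- transcript_ids(fx$asm)
  fpkm <- matrix(5, nrow = length(ids), ncol = 2,
                 dimnames = list(ids, c("s1", "s2")))
  fpkm["far_ok", ] <- c(0.5, 0.2)  # max exactly 0.5 must fail
  seqs <- setNames(vapply(ids, function(id) {
    paste(rep("C", get_transcript(fx$asm, id)$length_nt), collapse = "")
  }, ""), ids)
  res <- screen_candidates(fx$asm, fx$ref, fpkm, sequences = seqs)
  expect_false("far_ok" %in% res$candidates)
  fpkm["far_ok", 1] <- 0.51
  res2 <- screen_candidates(fx$asm, fx$ref, fpkm, sequences = seqs)
  expect_true("far_ok" %in% res2$candidates)
})

test_that("screen recovers exactly the planted candidates with matching audit", {
  sim <- sim_bundle()
  man <- sim$manifest
  asm <- parse_gtf(man$files$assembly_gtf)
  ref <- parse_gtf(man$files$reference_gtf)
  fpkm <- read_expression_tsv(man$files$fpkm_tsv)
  seqs <- read_fasta_sequences(man$files$sequences_fa)
  res <- screen_candidates(asm, ref, fpkm, sequences = seqs)
  expect_setequal(res$candidates, man$candidates$transcript_id)
  expect_length(intersect(res$candidates, man$decoys$transcript_id), 0)
  expect_equal(res$audit$n_total, man$audit_expected$n_total)
  expect_equal(res$audit$n_mono, man$audit_expected$n_mono)
  # post hoc: no survivor retains same-strand exonic overlap with reference
  for (id in res$candidates) {
    cand <- get_transcript(asm, id)
    ov <- vapply(ref$transcripts, function(r)
      exonic_overlap_bp(cand, r, "same"), 0)
    expect_equal(sum(ov), 0)
  }
})

test_that("length/strand and annotation-overlap filters commute", {
  sim <- sim_bundle()
  man <- sim$manifest
  asm <- parse_gtf(man$files$assembly_gtf)
  ref <- parse_gtf(man$files$reference_gtf)
  ids <- transcript_ids(asm)
  pass1 <- vapply(ids, function(id) {
    m <- get_transcript(asm, id)
    m$length_nt > 200 && m$strand != "*"
  }, TRUE)
  pass2 <- vapply(ids, function(id) {
    m <- get_transcript(asm, id)
    sum(vapply(ref$transcripts, function(r)
      exonic_overlap_bp(m, r, "same"), 0)) == 0
  }, TRUE)
  expect_setequal(ids[pass1][pass2[pass1]], ids[pass2][pass1[pass2]])
})

test_that("coding potential: ORF-free, ORF-rich and random sequences", {
  set.seed(77)
  # no ATG-initiated ORF >= 30 nt: always negative
  no_orf <- paste(rep(c("C", "A", "T", "C"), 50), collapse = "")
  expect_false(grepl("ATG", no_orf))
  expect_lt(coding_potential_score(no_orf), 0)
  # 900 nt in-frame ORF covering 75% of a 1,200 nt transcript: positive
  non_stop <- setdiff(apply(expand.grid(B1 = c("A", "C", "G", "T"),
                                        B2 = c("A", "C", "G", "T"),
                                        B3 = c("A", "C", "G", "T")),
                            1, paste, collapse = ""),
                      c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(non_stop, 298, TRUE), collapse = ""), "TAA")
  expect_equal(nchar(orf), 900)
  flank <- function(n) paste(sample(c("C", "A", "T"), n, TRUE), collapse = "")
  seq75 <- paste0(flank(150), orf, flank(150))
  expect_gt(coding_potential_score(seq75), 0)
  # random uniform 300 nt sequences are called non-coding >= 95% of the time
  scores <- replicate(500, coding_potential_score(
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")))
  expect_gte(mean(scores < 0), 0.95)
  expect_error(coding_potential_score(""), "empty")
  expect_error(coding_potential_score("ACGU"), "outside")
})

test_that("positional classification follows the documented precedence", {
  ref <- annotation_set(list(
    transcript_model("C1.1", "C1", "chr1", "+",
                     rbind(c(10000, 10300), c(12000, 12400)),
                     "protein_coding"),
    transcript_model("L1.1", "L1", "chr1", "-", rbind(c(40000, 40500)),
                     "annotated_lncRNA")))
  # exon overlaps a coding exon on the opposite strand -> antisense
  anti <- transcript_model("anti", "ga", "chr1", "-",
                           rbind(c(10100, 10250), c(10600, 10800)))
  expect_equal(classify_position(anti, ref), "antisense")
  # gene body fully inside the intron, same strand, no exonic overlap
  intr <- transcript_model("intr", "gi", "chr1", "+",
                           rbind(c(10400, 10550), c(10800, 10950)))
  expect_equal(classify_position(intr, ref), "intronic")
  # same strand, within 2,000 nt of the coding body -> sense
  sens <- transcript_model("sens", "gs", "chr1", "+",
                           rbind(c(13000, 13200), c(13500, 13700)))
  expect_equal(classify_position(sens, ref), "sense")
  # > 2,000 nt from everything -> intergenic (lncRNA neighbors don't count
  # for the sense class)
  inter <- transcript_model("inter", "gx", "chr1", "+",
                            rbind(c(41000, 41400)))
  expect_equal(classify_position(inter, ref), "intergenic")
  # overlap with the annotated lncRNA on the opposite strand is antisense too
  anti2 <- transcript_model("anti2", "ga2", "chr1", "+",
                            rbind(c(40100, 40300)))
  expect_equal(classify_position(anti2, ref), "antisense")
})

test_that("planted positional classes are recovered exactly", {
  sim <- sim_bundle()
  man <- sim$manifest
  asm <- parse_gtf(man$files$assembly_gtf)
  ref <- parse_gtf(man$files$reference_gtf)
  cls <- classify_positions(asm, man$candidates$transcript_id, ref)
  m <- merge(cls, man$candidates, by = "transcript_id")
  expect_equal(m$positional_class.x, m$positional_class.y)
  expect_setequal(unique(m$positional_class.x),
                  c("intergenic", "antisense", "sense", "intronic"))
})
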