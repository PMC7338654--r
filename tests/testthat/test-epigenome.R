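make_meth <- function(pos, chrom = "chr1", n_samples = 4) {
  sites <- data.frame(cpg_id = sprintf("cg%03d", seq_along(pos)),
                      chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  beta <- matrix(0.5, nrow = length(pos), ncol = n_samples,
                 dimnames = list(sites$cpg_id, sprintf("s%d", 1:n_samples)))
  methylation_table(sites, beta)
}

test_that("promoter CpGs are strictly upstream and strand-aware", {
  gp <- transcript_model("gp", "gp", "chr1", "+", rbind(c(10000, 10500)))
  meth <- make_meth(c(9500, 10000, 9999, 8000, 7999, 10100))
  got <- promoter_cpgs(gp, meth, 2000)
  # 500 upstream in; the TSS base itself excluded; boundary 2000 included
  expect_setequal(got, c("cg001", "cg003", "cg004"))
  gm <- transcript_model("gm", "gm", "chr1", "-", rbind(c(10000, 10500)))
  # minus-strand TSS base = 10499; none of these positions is above it
  expect_length(promoter_cpgs(gm, meth, 2000), 0)
  meth2 <- make_meth(c(10499, 10500, 12499, 12500))
  expect_setequal(promoter_cpgs(gm, meth2, 2000), c("cg002", "cg003"))
  expect_error(promoter_cpgs(
    transcript_model("u", "u", "chr1", "*", rbind(c(0, 10))), meth),
    "unstranded")
})

test_that("promoter membership matches a brute-force window oracle", {
  set.seed(501)
  for (k in 1:200) {
    strand <- sample(c("+", "-"), 1)
    s <- sample(3000:20000, 1)
    g <- transcript_model("g", "g", "chr1", strand, rbind(c(s, s + 300)))
    pos <- sample(0:25000, 30)
    meth <- make_meth(pos)
    got <- promoter_cpgs(g, meth, 2000)
    p <- tss(g)
    expected <- meth$sites$cpg_id[vapply(pos, function(x) {
      if (strand == "+") x >= p - 2000 && x < p else x > p && x <= p + 2000
    }, TRUE)]
    expect_setequal(got, expected)
  }
})

test_that("methylation screen: exact anti-correlation and planted signal", {
  ann <- annotation_set(list(
    transcript_model("G1.1", "G1", "chr1", "+", rbind(c(10000, 10800)))))
  expr <- matrix(seq(1, 16), nrow = 1,
                 dimnames = list("G1", sprintf("s%02d", 1:16)))
  sites <- data.frame(cpg_id = "cg001", chrom = "chr1", pos = 9400,
                      stringsAsFactors = FALSE)
  # beta is an affine decreasing transform of expression: pcc exactly -1
  beta <- matrix(1 - seq(1, 16) / 20, nrow = 1,
                 dimnames = list("cg001", colnames(expr)))
  meth <- methylation_table(sites, beta)
  de <- data.frame(gene_id = "G1", direction = "up", stringsAsFactors = FALSE)
  out <- methylation_expression_screen(expr, meth, de, ann)
  expect_equal(nrow(out), 1)
  expect_equal(out$pcc, -1)
  expect_true(out$is_best)

  # planted latent rho = -0.7 at n = 16 retained in >= 95% of datasets
  set.seed(502)
  kept <- replicate(300, {
    e <- stats::rnorm(16)
    b <- stats::plogis(0.9 * (-0.7 * scale(e)[, 1] +
                                sqrt(1 - 0.49) * stats::rnorm(16)))
    stats::cor(e, b) < -0.3
  })
  expect_gte(mean(kept), 0.95)

  # independent pairs rarely pass the -0.3 cut (null tail mass)
  set.seed(503)
  null_kept <- replicate(1000, stats::cor(stats::rnorm(16),
                                          stats::rnorm(16)) < -0.3)
  expect_lte(mean(null_kept), 0.25)
})

test_that("Pearson correlation is invariant under positive affine maps", {
  set.seed(504)
  for (k in 1:50) {
    x <- stats::rnorm(16); y <- stats::rnorm(16)
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1)
    expect_equal(stats::cor(a * x + b, y), stats::cor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("CNV overlap respects the q cutoff and flags concordance", {
  ann <- annotation_set(list(
    transcript_model("G1.1", "G1", "chr1", "+", rbind(c(1000, 2000))),
    transcript_model("G2.1", "G2", "chr1", "+", rbind(c(50000, 51000))),
    transcript_model("G3.1", "G3", "chr1", "-", rbind(c(8000, 9000)))))
  segs <- data.frame(chrom = "chr1",
                     start = c(500, 7000, 40000),
                     end = c(2500, 9500, 60000),
                     kind = c("deletion", "deletion", "amplification"),
                     q_value = c(0.01, 0.5, 0.2),
                     stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("G1", "G2", "G3"),
                   direction = c("down", "down", "down"),
                   stringsAsFactors = FALSE)
  out <- cnv_overlap(de, segs, ann)
  # G1: significant deletion + down -> concordant
  expect_true(out$concordant[out$gene_id == "G1"])
  # G3 overlaps only a q = 0.5 deletion: excluded by q < 0.25
  expect_false("G3" %in% out$gene_id)
  # G2 in a significant amplification but down-regulated: not concordant
  expect_false(out$concordant[out$gene_id == "G2"])
  # no overlap -> empty annotation
  out2 <- cnv_overlap(data.frame(gene_id = "G1", direction = "up"),
                      segs[3, ], ann)
  expect_equal(nrow(out2), 0)
})

test_that("CNV overlap equals a per-base intersection check", {
  set.seed(505)
  for (k in 1:200) {
    gs <- sample(0:5000, 1); ge <- gs + sample(50:400, 1)
    ann <- annotation_set(list(
      transcript_model("G.1", "G", "chr1", "+", rbind(c(gs, ge)))))
    ss <- sample(0:5000, 1); se <- ss + sample(50:400, 1)
    segs <- data.frame(chrom = "chr1", start = ss, end = se,
                       kind = "deletion", q_value = 0.01,
                       stringsAsFactors = FALSE)
    de <- data.frame(gene_id = "G", direction = "down",
                     stringsAsFactors = FALSE)
    hit <- nrow(cnv_overlap(de, segs, ann)) > 0
    brute <- length(intersect(seq(gs, ge - 1), seq(ss, se - 1))) > 0
    expect_identical(hit, brute)
  }
})

test_that("TSS profiles: empty input, centered peak, per-base oracle", {
  tp <- transcript_model("t", "g", "chr1", "+", rbind(c(50000, 50400)))
  no_peaks <- data.frame(chrom = character(), start = double(),
                         end = double(), signal = double())
  prof0 <- tss_signal_profile(no_peaks, list(tp))
  expect_true(all(prof0$mean_signal == 0))
  expect_equal(nrow(prof0), 140)
  expect_error(tss_signal_profile(no_peaks, list()), "empty")

  # a unit-signal 100 nt peak centered on the TSS: all mass in the two
  # central bins, total mass equal to the signal
  pk <- data.frame(chrom = "chr1", start = 49950, end = 50050, signal = 1)
  prof1 <- tss_signal_profile(pk, list(tp))
  central <- prof1$offset_start %in% c(-100, 0)
  expect_equal(sum(prof1$mean_signal[central]), 1, tolerance = 1e-9)
  expect_true(all(prof1$mean_signal[!central] == 0))

  # random peaks vs a per-base accumulation oracle
  set.seed(506)
  for (k in 1:25) {
    strand <- sample(c("+", "-"), 1)
    t1 <- transcript_model("t", "g", "chr1", strand,
                           rbind(c(20000, 20000 + sample(200:800, 1))))
    pkn <- do.call(rbind, lapply(1:6, function(i) {
      s <- sample(11000:29000, 1)
      data.frame(chrom = "chr1", start = s, end = s + sample(50:400, 1),
                 signal = stats::runif(1, 0.5, 4))
    }))
    prof <- tss_signal_profile(pkn, list(t1), flank = 2000, bin_width = 100)
    p <- tss(t1)
    brute <- numeric(40)
    for (r in seq_len(nrow(pkn))) {
      dens <- pkn$signal[r] / (pkn$end[r] - pkn$start[r])
      for (g in seq(pkn$start[r], pkn$end[r] - 1)) {
        off <- if (strand == "+") g - p else p - g - 1
        if (off >= -2000 && off < 2000) {
          bin <- floor((off + 2000) / 100) + 1
          brute[bin] <- brute[bin] + dens
        }
      }
    }
    expect_equal(prof$mean_signal, brute, tolerance = 1e-9)
  }
})

test_that("strand-flipping the input mirrors the TSS profile exactly", {
  set.seed(507)
  # single-base-exon transcripts keep their TSS under a strand flip, so the
  # flipped profile must be the exact bin reversal of the original
  txs <- lapply(1:5, function(i) {
    s <- sample(20000:40000, 1)
    transcript_model(paste0("t", i), paste0("g", i), "chr1", "+",
                     rbind(c(s, s + 1)))
  })
  flipped <- lapply(txs, function(t) {
    transcript_model(t$transcript_id, t$gene_id, t$chrom, "-", t$exons)
  })
  pk <- do.call(rbind, lapply(1:12, function(i) {
    s <- sample(13000:47000, 1)
    data.frame(chrom = "chr1", start = s, end = s + sample(30:500, 1),
               signal = stats::runif(1, 0.2, 3))
  }))
  a <- tss_signal_profile(pk, txs)
  b <- tss_signal_profile(pk, flipped)
  expect_equal(a$mean_signal, rev(b$mean_signal), tolerance = 1e-12)
})

test_that("conservation aggregation: uniform track and planted ordering", {
  t1 <- transcript_model("c.1", "c", "chr1", "+",
                         rbind(c(1000, 1200), c(2000, 2300)))
  t2 <- transcript_model("l.1", "l", "chr1", "-", rbind(c(5000, 5400)))
  # uniform track: exon and intron means both equal the constant
  uni <- data.frame(chrom = "chr1", start = 0, end = 10000, score = 0.42)
  out <- conservation_by_region(uni, list(t1, t2), c("coding", "lnc"))
  expect_equal(out$mean_score[out$class == "coding"], c(0.42, 0.42))
  expect_true(all(out$coverage[out$class == "coding"] == 1))
  # mono-exonic class has no intronic bases
  expect_true(is.na(out$mean_score[out$class == "lnc" &
                                   out$region == "intron"]))

  # exons scored 1, introns 0 by construction
  tr <- data.frame(chrom = "chr1",
                   start = c(1000, 1200, 2000),
                   end = c(1200, 2000, 2300),
                   score = c(1, 0, 1))
  out2 <- conservation_by_region(tr, list(t1), "coding")
  expect_equal(out2$mean_score[out2$region == "exon"], 1)
  expect_equal(out2$mean_score[out2$region == "intron"], 0)

  # synthetic class-dependent track recovers the planted ordering
  sim <- sim_bundle()
  man <- sim$manifest
  ref <- parse_gtf(man$files$reference_gtf)
  track <- read_bedgraph(man$files$conservation_bedgraph)
  models <- unname(ref$transcripts)
  classes <- ref$tx$biotype
  out3 <- conservation_by_region(track, models, classes)
  ex <- function(cl) out3$mean_score[out3$class == cl & out3$region == "exon"]
  expect_gt(ex("protein_coding"), ex("annotated_lncRNA"))
  inx <- function(cl) out3$mean_score[out3$class == cl & out3$region == "intron"]
  expect_gt(ex("protein_coding"), inx("protein_coding"))
})
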