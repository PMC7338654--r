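#' Screening thresholds for the candidate-lncRNA filter cascade
#'
#' Defaults follow the standard novel-lncRNA screen: transcripts must be
#' longer than 200 nt and stranded, show zero same-strand exonic overlap
#' with the reference annotation, mono-exonic transcripts must lie more than
#' 2,000 nt from any annotated transcript and exceed 0.5 FPKM in at least
#' one sample, and surviving transcripts with a positive coding-potential
#' score are removed. All thresholds are exclusive: boundary values fail.
#'
#' @param min_length_nt Minimum transcript length (exclusive), nt.
#' @param max_annotation_overlap_bp Maximum tolerated same-strand exonic
#'   overlap with the reference, bp.
#' @param monoexon_min_distance_nt Minimum gene-body distance (exclusive)
#'   from any reference transcript, applied to mono-exonic transcripts only.
#' @param min_max_fpkm Minimum of the per-transcript maximum FPKM across
#'   samples (exclusive), mono-exonic transcripts only.
#' @param coding_score_threshold Transcripts with coding score strictly
#'   above this are removed.
#' @return A `screen_params` list.
#' @export
screen_params <- function(min_length_nt = 200,
                          max_annotation_overlap_bp = 0,
                          monoexon_min_distance_nt = 2000,
                          min_max_fpkm = 0.5,
                          coding_score_threshold = 0) {
  p <- list(min_length_nt = min_length_nt,
            max_annotation_overlap_bp = max_annotation_overlap_bp,
            monoexon_min_distance_nt = monoexon_min_distance_nt,
            min_max_fpkm = min_max_fpkm,
            coding_score_threshold = coding_score_threshold)
  if (any(vapply(p[1:4], function(x) !is.numeric(x) || x < 0, TRUE))) {
    stop("screen thresholds must be non-negative numbers")
  }
  structure(p, class = "screen_params")
}

# summed same-strand exonic overlap (bp) of each assembly transcript with
# the whole reference exon index
.annotation_overlap_bp <- function(assembly, reference, ids) {
  out <- setNames(numeric(length(ids)), ids)
  if (!length(ids) || nrow(reference$tx) == 0L) return(out)
  q <- assembly$exon_gr[S4Vectors::mcols(assembly$exon_gr)$transcript_id %in% ids]
  hits <- GenomicRanges::findOverlaps(q, reference$exon_gr, ignore.strand = FALSE)
  if (!length(hits)) return(out)
  ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                  reference$exon_gr[S4Vectors::subjectHits(hits)])
  w <- BiocGenerics::width(ov)
  tid <- S4Vectors::mcols(q)$transcript_id[S4Vectors::queryHits(hits)]
  agg <- tapply(w, tid, sum)
  out[names(agg)] <- agg
  out
}

# gene-body distance (nt) of each assembly transcript to the nearest
# reference transcript, strand-blind; Inf when no reference shares the chrom
.nearest_reference_distance <- function(assembly, reference, ids) {
  out <- setNames(rep(Inf, length(ids)), ids)
  if (!length(ids) || nrow(reference$tx) == 0L) return(out)
  q <- assembly$body_gr[match(ids, S4Vectors::mcols(assembly$body_gr)$transcript_id)]
  hits <- GenomicRanges::distanceToNearest(q, reference$body_gr,
                                           ignore.strand = TRUE)
  if (length(hits)) {
    out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  out
}

#' Screen an assembled transcriptome for candidate lncRNAs
#'
#' Applies, in order: (1) length > `min_length_nt` and defined strand;
#' (2) same-strand exonic overlap with the reference (protein-coding or
#' annotated non-coding) not exceeding `max_annotation_overlap_bp`;
#' (3) split into mono-/multi-exonic branches; (4) mono-exonic only:
#' gene-body distance to the nearest reference transcript strictly greater
#' than `monoexon_min_distance_nt`; (5) mono-exonic only: maximum FPKM
#' across samples strictly greater than `min_max_fpkm`; (6) merge branches
#' into the novel-transcript set; (7) remove transcripts whose coding score
#' exceeds `coding_score_threshold`. Opposite-strand and intron-contained
#' transcripts pass step 2 by design, so antisense and intronic candidates
#' are retained for classification.
#'
#' @param assembly [annotation_set()] of assembled transcripts.
#' @param reference [annotation_set()] of the reference annotation.
#' @param fpkm Numeric matrix, transcripts x samples; assembled transcripts
#'   without a row are treated as unexpressed.
#' @param coding_scores Optional named numeric vector of precomputed coding
#'   scores (e.g. from an external coding-potential tool); transcripts not
#'   covered fall back to the built-in [coding_potential_score()] applied to
#'   `sequences`.
#' @param sequences Optional named character vector of transcript sequences
#'   used by the built-in scorer.
#' @param params A [screen_params()] object.
#' @return List with `candidates` (character vector of surviving transcript
#'   ids), `genes` (data frame mapping survivors to gene ids), `audit`
#'   (per-step data frame of remaining transcript counts, mono/multi split
#'   at the exon-number step) and `scores` (coding scores used at step 7).
#' @export
screen_candidates <- function(assembly, reference, fpkm,
                              coding_scores = NULL, sequences = NULL,
                              params = screen_params()) {
  tx <- assembly$tx
  audit <- data.frame(step = character(), n_mono = integer(),
                      n_multi = integer(), n_total = integer(),
                      stringsAsFactors = FALSE)
  add <- function(step, total, mono = NULL, multi = NULL) {
    rbind(audit, data.frame(step = step,
                            n_mono = if (is.null(mono)) NA_integer_ else length(mono),
                            n_multi = if (is.null(multi)) NA_integer_ else length(multi),
                            n_total = length(total),
                            stringsAsFactors = FALSE))
  }
  all_ids <- tx$transcript_id
  audit <- add("merged_transcriptome", all_ids)
  if (!length(all_ids)) {
    for (s in c("length_strand", "annotation_overlap", "distance",
                "expression")) audit <- add(s, character())
    audit <- rbind(audit[1:3, ],
                   data.frame(step = "exon_number", n_mono = 0L,
                              n_multi = 0L, n_total = 0L),
                   audit[4:5, ],
                   data.frame(step = c("novel_transcripts", "coding_potential"),
                              n_mono = NA_integer_, n_multi = NA_integer_,
                              n_total = 0L))
    return(list(candidates = character(),
                genes = data.frame(transcript_id = character(),
                                   gene_id = character()),
                audit = audit, scores = numeric()))
  }

  s1 <- tx$transcript_id[tx$length_nt > params$min_length_nt & tx$strand != "*"]
  audit <- add("length_strand", s1)

  ov <- .annotation_overlap_bp(assembly, reference, s1)
  s2 <- s1[ov[s1] <= params$max_annotation_overlap_bp]
  audit <- add("annotation_overlap", s2)

  nex <- setNames(tx$n_exons, tx$transcript_id)
  mono <- s2[nex[s2] == 1L]
  multi <- s2[nex[s2] > 1L]
  audit <- add("exon_number", s2, mono, multi)

  d <- .nearest_reference_distance(assembly, reference, mono)
  mono <- mono[d[mono] > params$monoexon_min_distance_nt]
  audit <- add("distance", c(mono, multi), mono, multi)

  maxf <- setNames(rep(0, length(mono)), mono)
  present <- intersect(mono, rownames(fpkm))
  if (length(present)) {
    maxf[present] <- apply(fpkm[present, , drop = FALSE], 1L, max)
  }
  mono <- mono[maxf[mono] > params$min_max_fpkm]
  audit <- add("expression", c(mono, multi), mono, multi)

  novel <- sort(c(mono, multi))
  audit <- add("novel_transcripts", novel)

  scores <- setNames(rep(NA_real_, length(novel)), novel)
  if (!is.null(coding_scores)) {
    hit <- intersect(novel, names(coding_scores))
    scores[hit] <- coding_scores[hit]
  }
  need <- names(scores)[is.na(scores)]
  if (length(need)) {
    if (is.null(sequences) || !all(need %in% names(sequences))) {
      stop("no coding score or sequence available for: ",
           paste(utils::head(setdiff(need, names(sequences)), 5), collapse = ", "))
    }
    scores[need] <- vapply(sequences[need], coding_potential_score, 0)
  }
  surv <- novel[scores[novel] <= params$coding_score_threshold]
  audit <- add("coding_potential", surv)

  list(candidates = surv,
       genes = data.frame(transcript_id = surv,
                          gene_id = setNames(tx$gene_id, tx$transcript_id)[surv],
                          row.names = NULL, stringsAsFactors = FALSE),
       audit = audit, scores = scores)
}

# longest ATG-initiated, stop-terminated ORF (nt, includes the stop codon)
# over the three forward frames; 0 when none
.longest_orf_nt <- function(chars) {
  n <- length(chars)
  best <- 0L
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    i1 <- f + seq.int(1L, ncod * 3L, 3L)
    cod <- paste0(chars[i1], chars[i1 + 1L], chars[i1 + 2L])
    starts <- which(cod == "ATG")
    stops <- which(cod %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    for (s in starts) {
      st <- stops[stops >= s]
      if (length(st)) {
        len <- (st[1L] - s + 1L) * 3L
        if (len > best) best <- len
      }
    }
  }
  best
}

# mean over A/C/G/T of the codon-position asymmetry (max+1)/(min+1) of the
# base's counts at the three frame-0 codon positions, each capped at 3
.position_bias <- function(chars) {
  pos <- (seq_along(chars) - 1L) %% 3L
  biases <- vapply(c("A", "C", "G", "T"), function(b) {
    cnt <- tabulate(pos[chars == b] + 1L, nbins = 3L)
    min((max(cnt) + 1) / (min(cnt) + 1), 3)
  }, 0)
  mean(biases)
}

#' Coding-potential score of a transcript sequence
#'
#' Deterministic score combining the longest-ORF fraction with a
#' Fickett-style codon-position asymmetry statistic; positive values are
#' coding-like. An ORF is an ATG-initiated, in-frame, stop-terminated run in
#' one of the three forward frames; ORFs shorter than 30 nt are ignored.
#' The score is `3 * (orf_fraction - 0.70) + 0.35 * (bias - 1.25)` with the
#' asymmetry `bias` capped at 3, calibrated on uniform-random sequence so
#' that sequences without a qualifying ORF always score negative and
#' sequences whose ORF covers most of their length score positive.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return Numeric score; `> 0` means coding-like.
#' @export
coding_potential_score <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (!nzchar(s)) stop("empty sequence")
  if (grepl("[^ACGTN]", s)) stop("sequence contains characters outside A/C/G/T/N")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  orf <- .longest_orf_nt(chars)
  if (orf < 30L) orf <- 0L
  frac <- orf / length(chars)
  3 * (frac - 0.70) + 0.35 * (.position_bias(chars) - 1.25)
}

#' Positional class of a candidate lncRNA
#'
#' Classifies a screened candidate relative to the reference annotation,
#' with precedence antisense > intronic > sense > intergenic:
#' `antisense` if any exon overlaps an exon of any reference transcript on
#' the opposite strand; `intronic` if the candidate's gene body lies
#' completely within one intron of a same-strand protein-coding transcript;
#' `sense` if a same-strand protein-coding transcript's gene body lies
#' within `window_nt`; otherwise `intergenic`.
#'
#' @param candidate A `transcript_model` that survived [screen_candidates()].
#' @param reference The reference [annotation_set()].
#' @param window_nt Body-to-body window for the sense class (default 2000).
#' @return One of `"antisense"`, `"intronic"`, `"sense"`, `"intergenic"`.
#' @export
classify_position <- function(candidate, reference, window_nt = 2000) {
  ref <- reference$tx[reference$tx$chrom == candidate$chrom, , drop = FALSE]
  if (!nrow(ref)) return("intergenic")
  for (id in ref$transcript_id) {
    if (exonic_overlap_bp(candidate, reference$transcripts[[id]],
                          "opposite") > 0) return("antisense")
  }
  cs <- min(candidate$exons[, "start"]); ce <- max(candidate$exons[, "end"])
  coding <- ref[ref$biotype == "protein_coding" &
                ref$strand == candidate$strand, , drop = FALSE]
  for (id in coding$transcript_id) {
    ex <- reference$transcripts[[id]]$exons
    if (nrow(ex) < 2L) next
    intron_start <- ex[-nrow(ex), "end"]
    intron_end <- ex[-1L, "start"]
    if (any(intron_start <= cs & ce <= intron_end)) return("intronic")
  }
  for (id in coding$transcript_id) {
    if (transcript_distance(candidate, reference$transcripts[[id]]) <
        window_nt) return("sense")
  }
  "intergenic"
}

#' Classify every candidate in an annotation set
#'
#' @param assembly [annotation_set()] holding the candidates.
#' @param candidate_ids Transcript ids to classify.
#' @param reference The reference [annotation_set()].
#' @param window_nt Sense-class window, nt.
#' @return Data frame with `transcript_id`, `gene_id`, `positional_class`,
#'   and the nearest reference transcript id and gene-body distance.
#' @export
classify_positions <- function(assembly, candidate_ids, reference,
                               window_nt = 2000) {
  cls <- character(length(candidate_ids))
  near_id <- character(length(candidate_ids))
  near_d <- numeric(length(candidate_ids))
  for (i in seq_along(candidate_ids)) {
    m <- get_transcript(assembly, candidate_ids[i])
    cls[i] <- classify_position(m, reference, window_nt)
    d <- vapply(reference$transcripts, function(r) transcript_distance(m, r), 0)
    if (length(d) && any(is.finite(d))) {
      j <- which.min(d)
      near_id[i] <- names(d)[j]
      near_d[i] <- d[j]
    } else {
      near_id[i] <- NA_character_
      near_d[i] <- Inf
    }
  }
  data.frame(transcript_id = candidate_ids,
             gene_id = assembly$tx$gene_id[match(candidate_ids,
                                                 assembly$tx$transcript_id)],
             positional_class = cls, nearest_reference = near_id,
             nearest_distance_nt = near_d,
             row.names = NULL, stringsAsFactors = FALSE)
}
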