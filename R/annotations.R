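#' Construct a transcript model
#'
#' A transcript model is a stranded, multi-exon transcript: the atomic unit
#' of the assembled and reference transcriptomes. Coordinates are 0-based
#' half-open throughout the package; GTF I/O converts from/to the 1-based
#' inclusive convention at the file boundary.
#'
#' @param transcript_id,gene_id Character scalars identifying the transcript
#'   and its gene grouping.
#' @param chrom Chromosome name (non-empty).
#' @param strand One of `"+"`, `"-"`, `"*"` (`"."` in a GTF is read as `"*"`,
#'   i.e. strand unknown).
#' @param exons Two-column matrix or data frame of exon `start`/`end`
#'   (0-based half-open). Exons are sorted and must not overlap.
#' @param biotype One of `"protein_coding"`, `"annotated_lncRNA"`,
#'   `"unannotated"`.
#' @return An object of class `transcript_model` with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (sorted matrix),
#'   `biotype` and `length_nt` (sum of exon widths).
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = "unannotated") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  if (identical(strand, ".")) strand <- "*"
  if (!strand %in% c("+", "-", "*")) {
    stop("unknown strand character: ", strand)
  }
  exons <- as.matrix(as.data.frame(exons)[, 1:2])
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript must have at least one exon")
  if (any(exons[, "end"] <= exons[, "start"])) {
    stop("exon end must be greater than exon start (0-based half-open)")
  }
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
    stop("exons of transcript ", transcript_id, " overlap")
  }
  biotype <- match.arg(biotype,
                       c("unannotated", "protein_coding", "annotated_lncRNA"))
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 biotype = biotype,
                 length_nt = sum(exons[, "end"] - exons[, "start"])),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s) %d exon(s), %d nt, %s\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons[, "start"]), max(x$exons[, "end"]), x$strand,
              nrow(x$exons), x$length_nt, x$biotype))
  invisible(x)
}

#' Bundle transcript models into an indexed annotation set
#'
#' Builds the per-chromosome, strand-separated exon and gene-body interval
#' indices (as [GenomicRanges::GRanges]) that every downstream overlap and
#' distance query uses.
#'
#' @param models List of [transcript_model()] objects with unique ids.
#' @return An object of class `annotation_set`: `transcripts` (named list),
#'   `tx` (summary data frame, one row per transcript), `exons` (data frame
#'   of all exons), `exon_gr` and `body_gr` (stranded `GRanges` indices whose
#'   `transcript_id` metadata maps every interval back to its transcript).
#' @export
annotation_set <- function(models) {
  if (length(models) == 0L) {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     start = double(), end = double(), n_exons = integer(),
                     length_nt = double(), biotype = character(),
                     stringsAsFactors = FALSE)
    ex <- data.frame(transcript_id = character(), chrom = character(),
                     start = double(), end = double(), strand = character(),
                     stringsAsFactors = FALSE)
    return(structure(list(transcripts = list(), tx = tx, exons = ex,
                          exon_gr = .intervals_to_gr(ex),
                          body_gr = .intervals_to_gr(ex)),
                     class = "annotation_set"))
  }
  stopifnot(all(vapply(models, inherits, TRUE, "transcript_model")))
  ids <- vapply(models, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(models) <- ids
  tx <- data.frame(
    transcript_id = ids,
    gene_id = vapply(models, `[[`, "", "gene_id"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    start = vapply(models, function(m) min(m$exons[, "start"]), 0),
    end = vapply(models, function(m) max(m$exons[, "end"]), 0),
    n_exons = vapply(models, function(m) nrow(m$exons), 0L),
    length_nt = vapply(models, `[[`, 0, "length_nt"),
    biotype = vapply(models, `[[`, "", "biotype"),
    row.names = NULL, stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = m$transcript_id, chrom = m$chrom,
               start = m$exons[, "start"], end = m$exons[, "end"],
               strand = m$strand, row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(transcripts = models, tx = tx, exons = ex,
                 exon_gr = .intervals_to_gr(ex),
                 body_gr = .intervals_to_gr(
                   data.frame(transcript_id = tx$transcript_id,
                              chrom = tx$chrom, start = tx$start,
                              end = tx$end, strand = tx$strand))),
            class = "annotation_set")
}

# 0-based half-open data.frame -> 1-based closed GRanges
.intervals_to_gr <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  gr
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcripts (%d genes) on %d chromosome(s)\n",
              nrow(x$tx), length(unique(x$tx$gene_id)),
              length(unique(x$tx$chrom))))
  if (nrow(x$tx)) print(table(x$tx$biotype))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) nrow(x$tx)

#' Retrieve one transcript model from an annotation set
#' @param aset An `annotation_set`.
#' @param id Transcript id.
#' @return The `transcript_model`.
#' @export
get_transcript <- function(aset, id) {
  m <- aset$transcripts[[id]]
  if (is.null(m)) stop("unknown transcript id: ", id)
  m
}

#' Transcript ids of an annotation set
#' @param aset An `annotation_set`.
#' @return Character vector of transcript ids.
#' @export
transcript_ids <- function(aset) aset$tx$transcript_id

.attr_value <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, '\\s+"([^"]*)"'), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

#' Parse a GTF file into an annotation set
#'
#' Reads the 9-column tab-separated GTF, keeps `exon` features, converts the
#' 1-based inclusive coordinates to the internal 0-based half-open
#' convention, and groups exons into transcripts via the `transcript_id`
#' attribute. The `gene_type` attribute, when present, sets the biotype
#' (`protein_coding` maps to itself, any other value to `annotated_lncRNA`);
#' transcripts without `gene_type` are `unannotated`. Strand `"."` is kept
#' as unstranded (downstream screening removes it).
#'
#' @param path Path to a GTF file.
#' @return An [annotation_set()].
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lnum <- which(keep)
  if (!length(lnum)) return(annotation_set(list()))
  fields <- strsplit(lines[lnum], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    b <- which(nf != 9L)[1L]
    stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, found %d",
                 lnum[b], nf[b]))
  }
  feat <- vapply(fields, `[[`, "", 3L)
  er <- which(feat == "exon")
  if (!length(er)) return(annotation_set(list()))
  chrom <- vapply(fields[er], `[[`, "", 1L)
  start1 <- suppressWarnings(as.numeric(vapply(fields[er], `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields[er], `[[`, "", 5L)))
  strand <- vapply(fields[er], `[[`, "", 7L)
  attrs <- vapply(fields[er], `[[`, "", 9L)
  if (anyNA(start1) || anyNA(end1)) {
    b <- which(is.na(start1) | is.na(end1))[1L]
    stop(sprintf("GTF parse error at line %d: non-numeric coordinates", lnum[er[b]]))
  }
  if (any(end1 < start1)) {
    b <- which(end1 < start1)[1L]
    stop(sprintf("GTF parse error at line %d: end (%d) < start (%d)",
                 lnum[er[b]], end1[b], start1[b]))
  }
  bad_strand <- !strand %in% c("+", "-", ".")
  if (any(bad_strand)) {
    b <- which(bad_strand)[1L]
    stop(sprintf("GTF parse error at line %d: unknown strand character '%s'",
                 lnum[er[b]], strand[b]))
  }
  tid <- .attr_value(attrs, "transcript_id")
  gid <- .attr_value(attrs, "gene_id")
  gtype <- .attr_value(attrs, "gene_type")
  if (anyNA(tid)) {
    stop(sprintf("GTF parse error at line %d: missing transcript_id attribute",
                 lnum[er[which(is.na(tid))[1L]]]))
  }
  if (anyNA(gid)) {
    stop(sprintf("GTF parse error at line %d: missing gene_id attribute",
                 lnum[er[which(is.na(gid))[1L]]]))
  }
  df <- data.frame(tid = tid, gid = gid, chrom = chrom, strand = strand,
                   start = start1 - 1, end = end1, gtype = gtype,
                   stringsAsFactors = FALSE)
  models <- lapply(split(df, df$tid), function(d) {
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L ||
        length(unique(d$gid)) != 1L) {
      stop("inconsistent chrom/strand/gene_id for transcript ", d$tid[1L])
    }
    gt <- d$gtype[!is.na(d$gtype)]
    biotype <- if (!length(gt)) "unannotated"
               else if (gt[1L] == "protein_coding") "protein_coding"
               else "annotated_lncRNA"
    transcript_model(d$tid[1L], d$gid[1L], d$chrom[1L], d$strand[1L],
                     cbind(start = d$start, end = d$end), biotype)
  })
  annotation_set(unname(models))
}

#' Write an annotation set as GTF
#'
#' Deterministic writer: one `exon` line per exon, sorted by chromosome,
#' gene-body start, then transcript id; coordinates converted back to
#' 1-based inclusive. Round-trips through [parse_gtf()] losslessly (up to
#' attribute ordering).
#'
#' @param aset An [annotation_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(aset, path) {
  tx <- aset$tx[order(aset$tx$chrom, aset$tx$start, aset$tx$transcript_id), ,
                drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(tx))) {
    m <- aset$transcripts[[tx$transcript_id[i]]]
    gt <- switch(m$biotype,
                 protein_coding = ' gene_type "protein_coding";',
                 annotated_lncRNA = ' gene_type "lincRNA";',
                 "")
    strand <- if (m$strand == "*") "." else m$strand
    writeLines(sprintf(
      '%s\tlncscout\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
      m$chrom, m$exons[, "start"] + 1, m$exons[, "end"], strand,
      m$gene_id, m$transcript_id, gt), con)
  }
  invisible(path)
}

#' Write candidate loci as BED6
#'
#' @param aset An [annotation_set()] (gene bodies are written).
#' @param path Output file path.
#' @param scores Optional numeric scores (default 0).
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(aset, path, scores = NULL) {
  tx <- aset$tx[order(aset$tx$chrom, aset$tx$start, aset$tx$transcript_id), ,
                drop = FALSE]
  if (is.null(scores)) scores <- rep(0, nrow(tx))
  strand <- ifelse(tx$strand == "*", ".", tx$strand)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", tx$chrom, as.integer(tx$start),
                     as.integer(tx$end), tx$transcript_id, scores, strand),
             path)
  invisible(path)
}

#' Exonic overlap between two transcripts, in base pairs
#'
#' Number of genomic bases shared between any exon of `a` and any exon of
#' `b`. `strand_mode = "same"` counts overlap only when both transcripts are
#' stranded and on the same strand, `"opposite"` only when stranded and on
#' different strands, `"ignore"` regardless of strand. Transcripts on
#' different chromosomes never overlap.
#'
#' @param a,b `transcript_model` objects.
#' @param strand_mode `"same"`, `"opposite"` or `"ignore"`.
#' @return Non-negative integer number of shared bases.
#' @export
exonic_overlap_bp <- function(a, b, strand_mode = c("same", "opposite", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  if (a$chrom != b$chrom) return(0)
  if (strand_mode == "same" &&
      (a$strand == "*" || b$strand == "*" || a$strand != b$strand)) return(0)
  if (strand_mode == "opposite" &&
      (a$strand == "*" || b$strand == "*" || a$strand == b$strand)) return(0)
  na <- nrow(a$exons); nb <- nrow(b$exons)
  as <- rep(a$exons[, "start"], times = nb); ae <- rep(a$exons[, "end"], times = nb)
  bs <- rep(b$exons[, "start"], each = na); be <- rep(b$exons[, "end"], each = na)
  sum(pmax(0, pmin(ae, be) - pmax(as, bs)))
}

#' Gap between two transcripts' gene bodies, in nucleotides
#'
#' The gene body spans from the first exon start to the last exon end.
#' Overlapping or touching bodies (`[0,100)` and `[100,200)`) have distance
#' 0; transcripts on different chromosomes have distance `Inf`.
#'
#' @param a,b `transcript_model` objects.
#' @return Non-negative number of bases separating the bodies (`Inf` across
#'   chromosomes).
#' @export
transcript_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  s1 <- min(a$exons[, "start"]); e1 <- max(a$exons[, "end"])
  s2 <- min(b$exons[, "start"]); e2 <- max(b$exons[, "end"])
  max(0, max(s1, s2) - min(e1, e2))
}

#' Transcription start site of a transcript
#'
#' The 0-based position of the 5'-most transcribed base: the smallest exon
#' start on the plus strand, the largest exon end minus one on the minus
#' strand. Undefined for unstranded transcripts.
#'
#' @param t A `transcript_model`.
#' @return 0-based genomic position of the TSS base.
#' @export
tss <- function(t) {
  if (t$strand == "+") return(min(t$exons[, "start"]))
  if (t$strand == "-") return(max(t$exons[, "end"]) - 1)
  stop("TSS undefined without strand")
}
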