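#' Build a pipeline configuration
#'
#' Collects input paths (defaulting to the file names [simulate_all()]
#' emits under `input_dir`) and every stage's tunable parameters, each
#' defaulting to the screening and testing thresholds the pipeline is
#' built around (length > 200 nt, mono-exon distance > 2,000 nt,
#' max FPKM > 0.5, coding score <= 0, |log2FC| > 1 with p and q < 0.05,
#' promoter window 2,000 nt with pcc < -0.3, CNV q < 0.25, TSS flank
#' 7,000 nt, minimum cluster size 45, 5-year survival horizon).
#'
#' @param input_dir Directory holding the input bundle.
#' @param outdir Output directory for stage reports.
#' @param seed Seed for the pipeline's stochastic steps (GSEA
#'   permutations).
#' @param ... Overrides for any config field (e.g. `min_cluster_size`,
#'   `de_top_lfc`, `mcl_inflation`, individual file paths).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, outdir, seed = 1, ...) {
  cfg <- list(
    reference_gtf = file.path(input_dir, "reference.gtf"),
    assembly_gtf = file.path(input_dir, "assembly.gtf"),
    sequences_fa = file.path(input_dir, "sequences.fa"),
    counts_tsv = file.path(input_dir, "counts.tsv"),
    fpkm_tsv = file.path(input_dir, "fpkm.tsv"),
    samples_tsv = file.path(input_dir, "samples.tsv"),
    methylation_tsv = file.path(input_dir, "methylation.tsv"),
    cnv_bed = file.path(input_dir, "cnv.bed"),
    peaks_h3k4me3_bed = file.path(input_dir, "peaks_h3k4me3.bed"),
    peaks_h3k27ac_bed = file.path(input_dir, "peaks_h3k27ac.bed"),
    conservation_bedgraph = file.path(input_dir, "conservation.bedgraph"),
    terms_gmt = file.path(input_dir, "terms.gmt"),
    cohort_expression_tsv = file.path(input_dir, "cohort_expression.tsv"),
    cohort_labels_tsv = file.path(input_dir, "cohort_labels.tsv"),
    cohort_survival_tsv = file.path(input_dir, "cohort_survival.tsv"),
    coding_scores_tsv = NULL,
    outdir = outdir, seed = seed,
    min_length_nt = 200, max_annotation_overlap_bp = 0,
    monoexon_min_distance_nt = 2000, min_max_fpkm = 0.5,
    coding_score_threshold = 0, classify_window_nt = 2000,
    lfc_threshold = 1, p_threshold = 0.05, q_threshold = 0.05,
    de_top_lfc = 3, de_top_n = 5,
    promoter_window_nt = 2000, methylation_pcc_threshold = -0.3,
    cnv_q_max = 0.25, tss_flank_nt = 7000, tss_bin_nt = 100,
    correlation_p_cutoff = 0.01, mcl_inflation = 2,
    min_cluster_size = 45, gsea_n_perm = 1000, gsea_weight = 1,
    survival_rule = "scan", survival_horizon_days = 1825)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML must provide `input_dir` and `outdir`; any other key overrides
#' the corresponding [pipeline_config()] field.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$input_dir), !is.null(y$outdir))
  args <- y[setdiff(names(y), c("input_dir", "outdir"))]
  do.call(pipeline_config, c(list(input_dir = y$input_dir,
                                  outdir = y$outdir), args))
}

.validate_config <- function(cfg) {
  path_fields <- c("reference_gtf", "assembly_gtf", "sequences_fa",
                   "counts_tsv", "fpkm_tsv", "samples_tsv",
                   "methylation_tsv", "cnv_bed", "peaks_h3k4me3_bed",
                   "peaks_h3k27ac_bed", "conservation_bedgraph",
                   "terms_gmt", "cohort_expression_tsv",
                   "cohort_labels_tsv", "cohort_survival_tsv")
  missing <- path_fields[!vapply(path_fields,
                                 function(f) file.exists(cfg[[f]]), TRUE)]
  if (length(missing)) {
    stop("config validation failed; missing input file(s): ",
         paste(vapply(missing, function(f) cfg[[f]], ""), collapse = ", "))
  }
  invisible(TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes screen -> classification -> differential expression ->
#' methylation/CNV/ChIP/conservation integration -> coexpression network
#' and enrichment -> cohort GSEA validation -> survival screening, writing
#' one TSV per stage plus a run log into `config$outdir`. Stage outputs
#' are pure functions of the inputs and the config (reruns are
#' byte-identical).
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  .validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("lncscout %s", as.character(utils::packageVersion("lncscout"))),
                 sprintf("seed: %d", cfg$seed))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines,
                   sprintf("FAILED at stage '%s': %s", name,
                           conditionMessage(e)),
                   "partial results only"),
                 file.path(cfg$outdir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-14s %6.2fs", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  inputs <- stage("load", {
    list(reference = parse_gtf(cfg$reference_gtf),
         assembly = parse_gtf(cfg$assembly_gtf),
         sequences = read_fasta_sequences(cfg$sequences_fa),
         counts = read_expression_tsv(cfg$counts_tsv),
         fpkm = read_expression_tsv(cfg$fpkm_tsv),
         samples = utils::read.delim(cfg$samples_tsv,
                                     stringsAsFactors = FALSE),
         methylation = read_methylation_tsv(cfg$methylation_tsv),
         cnv = read_cnv_bed(cfg$cnv_bed),
         peaks = list(h3k4me3 = read_peaks_bed(cfg$peaks_h3k4me3_bed),
                      h3k27ac = read_peaks_bed(cfg$peaks_h3k27ac_bed)),
         conservation = read_bedgraph(cfg$conservation_bedgraph),
         terms = read_gmt(cfg$terms_gmt),
         cohort_expr = read_expression_tsv(cfg$cohort_expression_tsv),
         cohort_labels = utils::read.delim(cfg$cohort_labels_tsv,
                                           stringsAsFactors = FALSE),
         cohort = read_survival_tsv(cfg$cohort_survival_tsv),
         coding_scores = if (!is.null(cfg$coding_scores_tsv)) {
           df <- utils::read.delim(cfg$coding_scores_tsv,
                                   stringsAsFactors = FALSE)
           setNames(df[[2]], df[[1]])
         } else NULL)
  })

  screen <- stage("screen", {
    res <- screen_candidates(
      inputs$assembly, inputs$reference, inputs$fpkm,
      coding_scores = inputs$coding_scores, sequences = inputs$sequences,
      params = screen_params(cfg$min_length_nt, cfg$max_annotation_overlap_bp,
                             cfg$monoexon_min_distance_nt, cfg$min_max_fpkm,
                             cfg$coding_score_threshold))
    .write_tsv(res$audit, file.path(cfg$outdir, "audit.tsv"))
    cand_set <- annotation_set(unname(inputs$assembly$transcripts[res$candidates]))
    write_gtf(cand_set, file.path(cfg$outdir, "candidates.gtf"))
    write_bed6(cand_set, file.path(cfg$outdir, "candidates.bed"))
    res
  })

  classification <- stage("classify", {
    cls <- classify_positions(inputs$assembly, screen$candidates,
                              inputs$reference, cfg$classify_window_nt)
    .write_tsv(cls, file.path(cfg$outdir, "classification.tsv"))
    cls
  })

  de <- stage("de", {
    condition <- inputs$samples$condition[match(colnames(inputs$counts),
                                                inputs$samples$sample)]
    sf <- size_factors(inputs$counts)
    disp <- estimate_dispersion(inputs$counts, sf, condition)
    tab <- de_test(inputs$counts, condition, sf, disp,
                   lfc_threshold = cfg$lfc_threshold,
                   p_threshold = cfg$p_threshold,
                   q_threshold = cfg$q_threshold)
    .write_tsv(tab, file.path(cfg$outdir, "de_table.tsv"))
    extremes <- tab[tab$direction != "ns" &
                    abs(tab$log2_fold_change) > cfg$de_top_lfc, , drop = FALSE]
    top <- do.call(rbind, lapply(c("up", "down"), function(d) {
      sub <- extremes[extremes$direction == d, , drop = FALSE]
      utils::head(sub[order(sub$p_value), , drop = FALSE], cfg$de_top_n)
    }))
    .write_tsv(top, file.path(cfg$outdir, "de_top.tsv"))
    tab
  })

  merged <- annotation_set(c(unname(inputs$reference$transcripts),
                             unname(inputs$assembly$transcripts)))
  gene_biotype <- tapply(merged$tx$biotype, merged$tx$gene_id,
                         function(b) b[1L])
  candidate_genes <- unique(screen$genes$gene_id)
  lnc_gene <- function(g) {
    g %in% candidate_genes | gene_biotype[g] %in% "annotated_lncRNA"
  }
  expr_gene <- inputs$fpkm
  rownames(expr_gene) <- merged$tx$gene_id[match(rownames(inputs$fpkm),
                                                 merged$tx$transcript_id)]

  integration <- stage("integrate", {
    de_called <- de[de$direction != "ns", , drop = FALSE]
    meth <- methylation_expression_screen(
      expr_gene, inputs$methylation, de_called, merged,
      threshold = cfg$methylation_pcc_threshold,
      window_nt = cfg$promoter_window_nt)
    .write_tsv(meth, file.path(cfg$outdir, "methylation_pairs.tsv"))
    cnv <- cnv_overlap(de_called, inputs$cnv, merged, q_max = cfg$cnv_q_max)
    .write_tsv(cnv, file.path(cfg$outdir, "cnv_annotation.tsv"))

    cls_of <- function(tx_ids) {
      b <- merged$tx$biotype[match(tx_ids, merged$tx$transcript_id)]
      ifelse(merged$tx$gene_id[match(tx_ids, merged$tx$transcript_id)] %in%
               candidate_genes, "candidate",
             ifelse(b == "protein_coding", "protein_coding",
                    "annotated_lncRNA"))
    }
    ref_ids <- inputs$reference$tx$transcript_id
    tx_ids <- c(ref_ids, screen$candidates)
    classes <- cls_of(tx_ids)
    models <- lapply(tx_ids, function(id) get_transcript(merged, id))
    prof <- do.call(rbind, unlist(lapply(names(inputs$peaks), function(mark) {
      lapply(unique(classes), function(cl) {
        p <- tss_signal_profile(inputs$peaks[[mark]],
                                models[classes == cl],
                                flank = cfg$tss_flank_nt,
                                bin_width = cfg$tss_bin_nt)
        cbind(mark = mark, class = cl, p)
      })
    }), recursive = FALSE))
    .write_tsv(prof, file.path(cfg$outdir, "tss_profiles.tsv"))
    cons <- conservation_by_region(inputs$conservation, models, classes)
    .write_tsv(cons, file.path(cfg$outdir, "conservation.tsv"))
    list(methylation = meth, cnv = cnv, tss_profiles = prof,
         conservation = cons)
  })

  network <- stage("network", {
    de_called <- de$gene_id[de$direction != "ns"]
    nodes <- intersect(de_called, rownames(expr_gene))
    if (length(nodes) < 3L) {
      log_lines <<- c(log_lines, "network skipped: fewer than 3 DE nodes")
      NULL
    } else {
      graph <- correlation_graph(expr_gene, nodes,
                                 p_cutoff = cfg$correlation_p_cutoff)
      write_graph_tsv(graph, file.path(cfg$outdir, "network_edges.tsv"))
      clusters <- mcl_cluster(graph,
                              mcl_params(inflation = cfg$mcl_inflation))
      kept <- filter_clusters(clusters, cfg$min_cluster_size)
      cl_df <- do.call(rbind, lapply(seq_along(kept$clusters), function(i) {
        g <- kept$clusters[[i]]
        data.frame(gene_id = g, cluster = i,
                   role = ifelse(lnc_gene(g), "lncRNA", "mRNA"),
                   stringsAsFactors = FALSE)
      }))
      if (is.null(cl_df)) {
        cl_df <- data.frame(gene_id = character(), cluster = integer(),
                            role = character(), stringsAsFactors = FALSE)
      }
      .write_tsv(cl_df, file.path(cfg$outdir, "clusters.tsv"))
      background <- sort(names(gene_biotype)[gene_biotype == "protein_coding"])
      enr <- do.call(rbind, lapply(seq_along(kept$clusters), function(i) {
        coding <- intersect(kept$clusters[[i]], background)
        if (!length(coding)) return(NULL)
        cbind(cluster = i,
              hypergeom_enrich(coding, inputs$terms, background))
      }))
      if (is.null(enr)) {
        enr <- data.frame(cluster = integer(), term = character(),
                          overlap = integer(), term_size = integer(),
                          cluster_size = integer(), p_value = double(),
                          q_value = double(), stringsAsFactors = FALSE)
      }
      .write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))
      list(graph = graph, clusters = kept, enrichment = enr)
    }
  })

  gsea <- stage("validate", {
    labels <- inputs$cohort_labels$condition[
      match(colnames(inputs$cohort_expr), inputs$cohort_labels$sample)]
    ranked <- rank_genes(inputs$cohort_expr, labels)
    write_rnk(ranked, file.path(cfg$outdir, "cohort_ranked.rnk"))
    sets <- list(
      up_lncRNA = de$gene_id[de$direction == "up" & lnc_gene(de$gene_id)],
      down_lncRNA = de$gene_id[de$direction == "down" & lnc_gene(de$gene_id)])
    rows <- lapply(names(sets), function(nm) {
      gs <- intersect(sets[[nm]], ranked$gene)
      if (!length(gs) || length(gs) >= nrow(ranked)) {
        return(data.frame(gene_set = nm, n_genes = length(gs),
                          es = NA_real_, p_value = NA_real_,
                          n_perm = 0L, stringsAsFactors = FALSE))
      }
      pp <- permutation_p(inputs$cohort_expr, labels, gs,
                          n_perm = cfg$gsea_n_perm, seed = cfg$seed,
                          weight_exponent = cfg$gsea_weight)
      data.frame(gene_set = nm, n_genes = length(gs),
                 es = pp$es_observed, p_value = pp$p_value,
                 n_perm = pp$n_perm_used, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    .write_tsv(out, file.path(cfg$outdir, "gsea.tsv"))
    out
  })

  surv <- stage("survive", {
    lnc_de <- de[de$direction != "ns" & lnc_gene(de$gene_id), , drop = FALSE]
    tab <- survival_screen(lnc_de, inputs$cohort, rule = cfg$survival_rule,
                           horizon = cfg$survival_horizon_days)
    .write_tsv(tab, file.path(cfg$outdir, "survival_screen.tsv"))
    tab
  })

  writeLines(c(log_lines, "status: complete"),
             file.path(cfg$outdir, "run_log.txt"))
  invisible(list(config = cfg, inputs = inputs, screen = screen,
                 classification = classification, de = de,
                 integration = integration, network = network,
                 gsea = gsea, survival = surv))
}
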