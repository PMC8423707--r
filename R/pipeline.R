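## End-to-end orchestration: read inputs, cluster, test differential
## splicing, classify cassette events, attach sequence/conservation/
## expression features where the corresponding inputs are given, and write
## TSV outputs plus a JSON stage summary. The thresholds default to the
## standard analysis settings and are logged verbatim into output headers.

#' Pipeline configuration
#'
#' Paths may be `NULL`; stages whose inputs are missing are skipped, except
#' the junction stage which is mandatory. All thresholds are fractions or
#' bases as documented in the stage functions.
#'
#' @param junction_files per-sample junction count files.
#' @param groups per-sample group labels.
#' @param dialect junction file dialect (see [readJunctionCounts()]).
#' @param control_group control group label.
#' @param gtf,fasta,conservation,de_table optional annotation, genome,
#'   bedGraph conservation and differential-expression inputs.
#' @param fdr,dpsi,psi_low,psi_high cluster-significance and classification
#'   thresholds.
#' @param max_exon,flank,min_event_reads,min_cluster_reads,min_prop,max_intron
#'   remaining stage parameters (see the stage functions for semantics).
#' @param scan_all scan all clusters for cassettes, not only significant
#'   ones.
#' @param seed integer seed recorded in outputs.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(junction_files, groups,
                           dialect = "plain_tsv",
                           control_group = "control",
                           gtf = NULL, fasta = NULL, conservation = NULL,
                           de_table = NULL,
                           fdr = 0.05, dpsi = 0.10, psi_low = 0.10,
                           psi_high = 0.90, max_exon = 250, flank = 100,
                           min_event_reads = 15, min_cluster_reads = 60,
                           min_prop = 0.001, max_intron = 200000,
                           scan_all = FALSE, seed = 1) {
    stopifnot(fdr > 0, fdr < 1, dpsi > 0, dpsi < 1,
              psi_low > 0, psi_low < 1, psi_high > 0, psi_high < 1)
    cfg <- as.list(environment())
    class(cfg) <- "PipelineConfig"
    cfg
}

threshold_header <- function(config) {
    keys <- c("fdr", "dpsi", "psi_low", "psi_high", "max_exon", "flank",
              "min_event_reads", "min_cluster_reads", "min_prop",
              "max_intron", "seed")
    paste0("# ", keys, " = ",
           vapply(keys, function(k) format(config[[k]],
                                           scientific = FALSE), ""))
}

write_tsv_with_header <- function(d, path, header) {
    con <- file(path, "w")
    writeLines(header, con)
    suppressWarnings(utils::write.table(d, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
}

#' Run the full pipeline
#'
#' Stages, in fixed order: read junction counts; cluster; Dirichlet-
#' multinomial differential splicing with BH control; cassette
#' classification (with novelty annotation when a GTF is given); exon
#' sequence extraction and frame preservation (when a genome FASTA is
#' given); per-exon mean conservation (when a bedGraph is given);
#' downregulation bias versus an expression-matched null (when a DE table
#' is given and at least 2 cryptic genes are found). Outputs one TSV per
#' stage plus `summary.json` with the stage counts. All outputs are
#' deterministic for fixed inputs; missing inputs for a requested stage
#' fail fast and no partial outputs are left behind.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @return invisibly, the summary list (also written to
#'   `outdir/summary.json`).
#' @export
runPipeline <- function(config, outdir) {
    for (p in c(config$junction_files, config$gtf, config$fasta,
                config$conservation, config$de_table))
        if (!file.exists(p)) stop("missing input file: ", p)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    on_fail <- function(e) {
        unlink(written)
        stop(e)
    }
    tryCatch({
        hdr <- threshold_header(config)
        x <- readJunctionCounts(config$junction_files, config$groups,
                                dialect = config$dialect)
        clusters <- clusterJunctions(
            x, min_cluster_reads = config$min_cluster_reads,
            min_prop = config$min_prop, max_intron = config$max_intron)
        cl_tab <- data.frame(cluster_id = clusterIds(clusters),
                             n_junctions = vapply(clusterMembers(clusters),
                                                  length, 1L),
                             span = as.character(clusterSpan(clusters)))
        f <- file.path(outdir, "clusters.tsv")
        write_tsv_with_header(cl_tab, f, hdr); written <- c(written, f)

        dm <- differentialSplicing(x, clusters, fdr = config$fdr)
        dm_out <- dm[, c("cluster_id", "loglik_null", "loglik_alt",
                         "lrt_stat", "df", "p_value", "q_value",
                         "significant", "failed")]
        f <- file.path(outdir, "differential_splicing.tsv")
        write_tsv_with_header(dm_out, f, hdr); written <- c(written, f)

        annotation <- if (!is.null(config$gtf)) readGTF(config$gtf)
                      else NULL
        events <- runClassification(
            x, clusters, dm, annotation = annotation,
            control_group = config$control_group, fdr = config$fdr,
            dpsi_threshold = config$dpsi, max_exon = config$max_exon,
            min_event_reads = config$min_event_reads,
            scan_all = config$scan_all)
        stage_counts <- attr(events, "summary")

        if (!is.null(config$fasta) && nrow(events)) {
            exons <- GenomicRanges::GRanges(
                events$exon_chrom,
                IRanges::IRanges(events$exon_start, events$exon_end),
                strand = events$exon_strand)
            seqs <- extractSequences(config$fasta, exons,
                                     flank = config$flank)
            events$frame_preserving <- framePreserving(events$exon_length)
            events$exon_seq <- seqs$exon_body
            events$upstream_seq <- seqs$upstream_flank
            events$downstream_seq <- seqs$downstream_flank
        }
        if (!is.null(config$conservation) && nrow(events)) {
            track <- readConservationTrack(config$conservation)
            exons <- GenomicRanges::GRanges(
                events$exon_chrom,
                IRanges::IRanges(events$exon_start, events$exon_end))
            events$mean_phylop <- meanConservation(track, exons)
        }
        f <- file.path(outdir, "cassette_events.tsv")
        write_tsv_with_header(events, f, hdr); written <- c(written, f)

        expr_res <- NULL
        if (!is.null(config$de_table)) {
            de <- readExpressionTable(config$de_table)
            cryptic_genes <- unique(stats::na.omit(
                events$gene[events$exon_set %in% "cryptic"]))
            spliced_genes <- unique(stats::na.omit(events$gene))
            if (length(cryptic_genes) >= 2) {
                null_genes <- matchExpressionNull(de, cryptic_genes,
                                                  spliced_genes)
                expr_res <- downregulationBias(de, cryptic_genes,
                                               null_genes,
                                               fdr = config$fdr)
                f <- file.path(outdir, "expression_overlap.tsv")
                write_tsv_with_header(
                    data.frame(metric = names(unlist(expr_res)),
                               value = unlist(expr_res)), f, hdr)
                written <- c(written, f)
            } else {
                message("fewer than 2 cryptic genes; ",
                        "expression overlap skipped")
            }
        }
        summary <- c(list(n_junctions = nrow(x),
                          n_clusters_tested = sum(!dm$failed),
                          n_significant = sum(dm$significant)),
                     as.list(stage_counts))
        if (!is.null(expr_res))
            summary$downregulation_p <- expr_res$p_value
        f <- file.path(outdir, "summary.json")
        jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        written <- c(written, f)
        invisible(summary)
    }, error = on_fail)
}
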