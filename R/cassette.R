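## Cassette-exon topology search, novelty annotation against a transcript
## reference, PSI / delta-PSI quantification and the cryptic/skiptic
## classification rules.

#' Enumerate cassette topologies within a cluster
#'
#' A cassette event is a junction triple `(j1, j2, skip)` with
#' `start(j1) == start(skip)`, `end(j2) == end(skip)` and
#' `end(j1) < start(j2)`: the two inclusion junctions flank a central exon
#' `[end(j1)+1, start(j2)-1]` and the skipping junction spans the whole
#' cluster of the triple. Putative exons longer than `max_exon` (default
#' 250 bp) are discarded. When several triples imply the same exon
#' coordinates, the triple with the highest pooled inclusion read count is
#' kept.
#'
#' @param cluster_members integer indices of the cluster's junctions (rows
#'   of `x`).
#' @param x a [JunctionExperiment-class].
#' @param max_exon maximum central-exon length in bases.
#' @param cluster_id identifier copied into the output.
#' @return a `data.frame`, one row per event: junction row indices
#'   (`inc1`, `inc2`, `skip`), `exon_chrom`, `exon_start`, `exon_end`,
#'   `exon_strand`, `exon_length`, and the skipping junction's intron
#'   (`intron_start`, `intron_end`).
#' @export
findCassetteEvents <- function(cluster_members, x, max_exon = 250,
                               cluster_id = NA_character_) {
    gr <- junctionRanges(x)[cluster_members]
    s <- IRanges::start(gr); e <- IRanges::end(gr)
    n <- length(gr)
    empty <- data.frame(cluster_id = character(), inc1 = integer(),
                        inc2 = integer(), skip = integer(),
                        exon_chrom = character(), exon_start = integer(),
                        exon_end = integer(), exon_strand = character(),
                        exon_length = integer(), intron_start = integer(),
                        intron_end = integer(), stringsAsFactors = FALSE)
    if (n < 3L) return(empty)
    pooled <- rowSums(junctionCounts(x))[cluster_members]
    chrom <- as.character(GenomicRanges::seqnames(gr))
    strand <- as.character(GenomicRanges::strand(gr))
    rows <- list()
    for (sk in seq_len(n)) {
        j1s <- which(s == s[sk] & e < e[sk])
        j2s <- which(e == e[sk] & s > s[sk])
        if (!length(j1s) || !length(j2s)) next
        for (a in j1s) for (b in j2s) {
            if (e[a] >= s[b]) next                    # need a central exon
            ex_len <- s[b] - e[a] - 1L
            if (ex_len > max_exon) next
            rows[[length(rows) + 1L]] <- data.frame(
                cluster_id = cluster_id,
                inc1 = cluster_members[a], inc2 = cluster_members[b],
                skip = cluster_members[sk],
                exon_chrom = chrom[sk],
                exon_start = e[a] + 1L, exon_end = s[b] - 1L,
                exon_strand = strand[sk], exon_length = ex_len,
                intron_start = s[sk], intron_end = e[sk],
                support = pooled[a] + pooled[b],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(empty)
    ev <- do.call(rbind, rows)
    # deduplicate identical exon coordinates, keeping max inclusion support
    key <- paste(ev$exon_chrom, ev$exon_start, ev$exon_end, ev$exon_strand)
    ev <- ev[order(key, -ev$support), ]
    ev <- ev[!duplicated(paste(ev$exon_chrom, ev$exon_start, ev$exon_end,
                               ev$exon_strand)), ]
    ev <- ev[order(ev$exon_start, ev$exon_end), ]
    ev$support <- NULL
    rownames(ev) <- NULL
    ev
}

#' Annotate event novelty against a transcript reference
#'
#' Compares the three junctions of each event with the reference junction
#' set: `both_annotated` when both inclusion junctions and the skipping
#' junction are known, `inclusion_novel` when the inclusion pair is not
#' fully annotated, `skipping_novel` when only the skipping junction is
#' unannotated, `fully_novel` when none match. Strand-unknown junctions
#' match annotated junctions of either strand. Events are "novel" for
#' downstream reporting whenever the status is not `both_annotated`.
#'
#' @param events output of [findCassetteEvents()] (possibly row-bound).
#' @param x the [JunctionExperiment-class] the events index into.
#' @param annotation a [TranscriptAnnotation-class].
#' @return `events` with columns `annot_status`, `novel` and `gene` added.
#' @export
annotateNovelty <- function(events, x, annotation) {
    gr <- junctionRanges(x)
    ref <- annotatedJunctions(annotation)
    ref_key_stranded <- paste(GenomicRanges::seqnames(ref),
                              IRanges::start(ref), IRanges::end(ref),
                              GenomicRanges::strand(ref))
    ref_key_plain <- paste(GenomicRanges::seqnames(ref), IRanges::start(ref),
                           IRanges::end(ref))
    is_annot <- function(idx) {
        g <- gr[idx]
        st <- as.character(GenomicRanges::strand(g))
        key_s <- paste(GenomicRanges::seqnames(g), IRanges::start(g),
                       IRanges::end(g), st)
        key_p <- paste(GenomicRanges::seqnames(g), IRanges::start(g),
                       IRanges::end(g))
        ifelse(st == "*", key_p %in% ref_key_plain,
               key_s %in% ref_key_stranded |
                   key_p %in% ref_key_plain[
                       as.character(GenomicRanges::strand(ref)) == "*"])
    }
    if (!nrow(events)) {
        events$annot_status <- character(0)
        events$novel <- logical(0)
        events$gene <- character(0)
        return(events)
    }
    inc_ok <- is_annot(events$inc1) & is_annot(events$inc2)
    skip_ok <- is_annot(events$skip)
    events$annot_status <- ifelse(inc_ok & skip_ok, "both_annotated",
                           ifelse(!inc_ok & skip_ok, "inclusion_novel",
                           ifelse(inc_ok & !skip_ok, "skipping_novel",
                                  "fully_novel")))
    events$novel <- events$annot_status != "both_annotated"
    # gene: carried over from any annotated junction of the triple
    g <- gr[events$skip]
    key_p <- paste(GenomicRanges::seqnames(g), IRanges::start(g),
                   IRanges::end(g))
    hit <- match(key_p, ref_key_plain)
    for (col in c("inc1", "inc2")) {
        g2 <- gr[events[[col]]]
        key2 <- paste(GenomicRanges::seqnames(g2), IRanges::start(g2),
                      IRanges::end(g2))
        hit[is.na(hit)] <- match(key2, ref_key_plain)[is.na(hit)]
    }
    events$gene <- ifelse(is.na(hit), NA_character_,
                          S4Vectors::mcols(ref)$gene_id[hit])
    events
}

#' Percent spliced in (PSI) per sample, group means and delta-PSI
#'
#' For each sample, let `m` be the mean of the two inclusion-junction read
#' counts and `s` the skipping-junction count. The bounded PSI is
#' `m / (m + s)` (in `[0,1]`); samples with `m + s < min_event_reads` are
#' treated as unquantifiable (missing). Group PSIs are means over
#' non-missing samples and `dpsi = psi_case - psi_control`. With
#' `literal_ratio = TRUE` the raw ratio `m / s` is computed instead and
#' capped at 1 for classification; the bounded form is the default because
#' it is the only form under which PSI thresholds such as "above 90%" are
#' coherent.
#'
#' @param events event table (from [findCassetteEvents()] or downstream).
#' @param x a [JunctionExperiment-class].
#' @param control_group label of the control group in `sampleGroups(x)`;
#'   the other label is the case group.
#' @param min_event_reads minimum `m + s` per sample (default 15).
#' @param literal_ratio use the unbounded `m / s` ratio (capped at 1).
#' @return `events` with a `psi` sample matrix attribute replaced by
#'   columns: `psi_control`, `psi_case`, `dpsi`, `quantifiable`, plus one
#'   `psi.<sample>` column per sample.
#' @export
computePsi <- function(events, x, control_group = "control",
                       min_event_reads = 15, literal_ratio = FALSE) {
    groups <- sampleGroups(x)
    if (!control_group %in% groups)
        stop("control group '", control_group, "' not present")
    cts <- junctionCounts(x)
    n_ev <- nrow(events)
    psi <- matrix(NA_real_, nrow = n_ev, ncol = ncol(cts),
                  dimnames = list(NULL, colnames(cts)))
    if (n_ev) {
        for (i in seq_len(n_ev)) {
            m <- (cts[events$inc1[i], ] + cts[events$inc2[i], ]) / 2
            s <- cts[events$skip[i], ]
            ok <- (m + s) >= min_event_reads
            v <- if (literal_ratio) pmin(m / s, 1) else m / (m + s)
            v[!ok | !is.finite(v)] <- NA_real_
            psi[i, ] <- v
        }
    }
    ctrl <- groups == control_group
    grp_mean <- function(rows) {
        if (!n_ev) return(numeric(0))
        apply(psi[, rows, drop = FALSE], 1, function(z)
            if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
    }
    events$psi_control <- grp_mean(ctrl)
    events$psi_case <- grp_mean(!ctrl)
    events$dpsi <- events$psi_case - events$psi_control
    events$quantifiable <- !is.na(events$psi_control) &
        !is.na(events$psi_case)
    if (n_ev)
        for (j in seq_len(ncol(psi)))
            events[[paste0("psi.", colnames(psi)[j])]] <- psi[, j]
    events
}

#' Classify a quantified cassette event
#'
#' Labels (mutually exclusive, checked in order):
#' \describe{
#'   \item{cryptic}{control PSI below `psi_low` and `dpsi` above
#'     `dpsi_threshold` — a normally repressed exon gaining inclusion.}
#'   \item{skiptic}{control PSI above `psi_high` and `dpsi` below
#'     `-dpsi_threshold` — a normally constitutive exon becoming skipped.}
#'   \item{included}{`dpsi >= dpsi_threshold`, not cryptic.}
#'   \item{skipped}{`dpsi <= -dpsi_threshold`, not skiptic.}
#'   \item{weak}{`|dpsi| < dpsi_threshold`.}
#' }
#' Defaults: `psi_low = 0.10`, `psi_high = 0.90`, `dpsi_threshold = 0.10`.
#'
#' @param psi_control,dpsi numeric vectors (group-mean PSI in controls and
#'   case-minus-control difference).
#' @param psi_low,psi_high,dpsi_threshold classification thresholds.
#' @return character vector of `exon_set` labels (`NA` where PSI missing).
#' @export
classifyEvent <- function(psi_control, dpsi, psi_low = 0.10,
                          psi_high = 0.90, dpsi_threshold = 0.10) {
    out <- rep(NA_character_, length(psi_control))
    ok <- !is.na(psi_control) & !is.na(dpsi)
    out[ok & psi_control < psi_low & dpsi > dpsi_threshold] <- "cryptic"
    out[ok & is.na(out) & psi_control > psi_high &
            dpsi < -dpsi_threshold] <- "skiptic"
    out[ok & is.na(out) & dpsi >= dpsi_threshold] <- "included"
    out[ok & is.na(out) & dpsi <= -dpsi_threshold] <- "skipped"
    out[ok & is.na(out)] <- "weak"
    out
}

#' Full cassette classification over significant clusters
#'
#' Scans the clusters deemed significant by [differentialSplicing()] (or all
#' clusters with `scan_all = TRUE`) for cassette topologies, annotates
#' novelty, quantifies PSI and assigns `exon_set` labels. The output mirrors
#' a per-event results table with `exon_coords` / `intron_coords` location
#' strings.
#'
#' @param x a [JunctionExperiment-class].
#' @param clusters a [JunctionClusters-class].
#' @param dm_results output of [differentialSplicing()] over `clusters`.
#' @param annotation optional [TranscriptAnnotation-class] for novelty.
#' @param control_group control group label.
#' @param fdr FDR threshold selecting clusters to scan.
#' @param dpsi_threshold effect-size threshold for classification and the
#'   summary counts.
#' @param max_exon maximum exon length in bases.
#' @param min_event_reads per-sample PSI coverage floor.
#' @param scan_all scan all clusters instead of significant ones only.
#' @return a `data.frame` of classified events with a `summary` attribute
#'   (named integer vector of stage counts: `n_cassette`, `n_effect`,
#'   `n_cryptic`, `n_novel_cryptic`, `n_skiptic`, `n_novel_skiptic`).
#' @export
runClassification <- function(x, clusters, dm_results, annotation = NULL,
                              control_group = "control", fdr = 0.05,
                              dpsi_threshold = 0.10, max_exon = 250,
                              min_event_reads = 15, scan_all = FALSE) {
    if (!setequal(dm_results$cluster_id, clusterIds(clusters)))
        stop("dm_results do not match the supplied clusters")
    take <- if (scan_all) rep(TRUE, length(clusters))
            else dm_results$significant[match(clusterIds(clusters),
                                              dm_results$cluster_id)]
    idx <- which(take)
    evs <- lapply(idx, function(i)
        findCassetteEvents(clusterMembers(clusters)[[i]], x,
                           max_exon = max_exon,
                           cluster_id = clusterIds(clusters)[i]))
    events <- do.call(rbind, c(evs, list(findCassetteEvents(integer(0), x))))
    if (!is.null(annotation)) {
        events <- annotateNovelty(events, x, annotation)
    } else {
        events$annot_status <- rep(NA_character_, nrow(events))
        events$novel <- rep(NA, nrow(events))
        events$gene <- rep(NA_character_, nrow(events))
    }
    events <- computePsi(events, x, control_group = control_group,
                         min_event_reads = min_event_reads)
    events$exon_set <- classifyEvent(events$psi_control, events$dpsi,
                                     dpsi_threshold = dpsi_threshold)
    events$exon_coords <- sprintf("%s:%d-%d", events$exon_chrom,
                                  events$exon_start, events$exon_end)
    events$intron_coords <- sprintf("%s:%d-%d", events$exon_chrom,
                                    events$intron_start, events$intron_end)
    eff <- !is.na(events$dpsi) & abs(events$dpsi) >= dpsi_threshold
    summary <- c(
        n_cassette = nrow(events),
        n_effect = sum(eff),
        n_cryptic = sum(events$exon_set == "cryptic", na.rm = TRUE),
        n_novel_cryptic = sum(events$exon_set == "cryptic" & events$novel,
                              na.rm = TRUE),
        n_skiptic = sum(events$exon_set == "skiptic", na.rm = TRUE),
        n_novel_skiptic = sum(events$exon_set == "skiptic" & events$novel,
                              na.rm = TRUE))
    attr(events, "summary") <- summary
    events
}
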