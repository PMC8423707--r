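## I/O for the standard formats feeding the pipeline. Everything is
## normalised on read to 1-based inclusive coordinates (the GTF/GRanges
## convention); BED-dialect inputs (0-based half-open) are converted here and
## nowhere else.

#' Harmonise chromosome names
#'
#' Maps `"1"`-style names to `"chr1"`-style (GENCODE/UCSC) or the reverse.
#' Mixed resources (GENCODE GTF vs UCSC conservation tracks) disagree on
#' this prefix; the pipeline harmonises every input with one call.
#'
#' @param chroms character vector of chromosome names.
#' @param style `"chr"` to add the prefix, `"plain"` to strip it.
#' @return character vector of harmonised names.
#' @export
harmonizeChroms <- function(chroms, style = c("chr", "plain")) {
    style <- match.arg(style)
    chroms <- as.character(chroms)
    if (style == "chr") {
        plain <- !startsWith(chroms, "chr")
        chroms[plain] <- paste0("chr", sub("^MT$", "M", chroms[plain]))
    } else {
        chroms <- sub("^chr", "", chroms)
        chroms[chroms == "M"] <- "MT"
    }
    chroms
}

#' Read a GTF and derive intron junctions
#'
#' Parses exon features (GENCODE dialect, 1-based inclusive) and derives the
#' intron junction of every pair of adjacent exons within a transcript:
#' exons at `[a,b]` and `[c,d]` (`b < c`) imply the intron `[b+1, c-1]`. The
#' junction set is deduplicated across transcripts; each junction keeps the
#' `gene_id` of (one of) its transcripts. Exon records without a
#' `transcript_id` attribute are skipped with a warning.
#'
#' @param path GTF file path.
#' @param feature_filter feature types to keep (default `"exon"`).
#' @return a [TranscriptAnnotation-class].
#' @export
readGTF <- function(path, feature_filter = "exon") {
    gr <- tryCatch(
        rtracklayer::import(path, format = "gtf"),
        error = function(e) stop("failed to parse GTF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    gr <- gr[as.character(gr$type) %in% feature_filter]
    mc <- S4Vectors::mcols(gr)
    if (!"transcript_id" %in% colnames(mc))
        mc$transcript_id <- NA_character_
    if (!"gene_id" %in% colnames(mc))
        mc$gene_id <- NA_character_
    missing_tx <- is.na(mc$transcript_id)
    if (any(missing_tx)) {
        warning(sum(missing_tx),
                " exon record(s) without transcript_id skipped")
        gr <- gr[!missing_tx]
        mc <- S4Vectors::mcols(gr)
    }
    exons <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr), IRanges::ranges(gr),
        strand = GenomicRanges::strand(gr),
        transcript_id = mc$transcript_id, gene_id = mc$gene_id)

    junctions <- derive_junctions(exons)
    methods::new("TranscriptAnnotation", exons = exons, junctions = junctions)
}

## adjacent-exon introns per transcript, deduplicated across transcripts
derive_junctions <- function(exons) {
    if (!length(exons))
        return(GenomicRanges::GRanges(gene_id = character()))
    o <- order(S4Vectors::mcols(exons)$transcript_id, IRanges::start(exons))
    ex <- exons[o]
    tx <- S4Vectors::mcols(ex)$transcript_id
    same_tx <- which(tx[-length(tx)] == tx[-1])
    if (!length(same_tx))
        return(GenomicRanges::GRanges(gene_id = character()))
    jstart <- IRanges::end(ex)[same_tx] + 1L
    jend <- IRanges::start(ex)[same_tx + 1L] - 1L
    ok <- jstart <= jend            # overlapping/adjacent exons give no intron
    j <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(ex)[same_tx][ok],
        IRanges::IRanges(jstart[ok], jend[ok]),
        strand = GenomicRanges::strand(ex)[same_tx][ok],
        gene_id = S4Vectors::mcols(ex)$gene_id[same_tx][ok])
    key <- paste(GenomicRanges::seqnames(j), IRanges::start(j),
                 IRanges::end(j), GenomicRanges::strand(j))
    j[!duplicated(key)]
}

#' Read per-sample junction counts
#'
#' Reads one junction file per sample and assembles the union of junctions
#' into a [JunctionExperiment-class]. Two dialects are supported:
#' \describe{
#'   \item{`regtools_bed12`}{regtools `junctions extract` output: BED12,
#'     0-based half-open, where the two block sizes flank the intron. The
#'     intron is `[chromStart + blockSize1 + 1, chromEnd - blockSize2]` in
#'     1-based inclusive coordinates; the score column is the read count.}
#'   \item{`plain_tsv`}{a headered TSV with columns `chrom`, `start`, `end`,
#'     `strand`, `count`; coordinates already 1-based inclusive.}
#' }
#' Junctions absent from a sample get count 0. Duplicate junction lines
#' within one file are summed (with a message). Counts must be
#' non-negative; mixing `"chr1"`- and `"1"`-style names across samples is an
#' error (harmonise first, see [harmonizeChroms()]).
#'
#' @param paths character vector of file paths, one per sample.
#' @param group per-sample group labels (same length as `paths`).
#' @param dialect input flavour, see Details.
#' @param sample_names optional sample names; default basenames.
#' @return a [JunctionExperiment-class].
#' @export
readJunctionCounts <- function(paths, group,
                               dialect = c("plain_tsv", "regtools_bed12"),
                               sample_names = NULL) {
    dialect <- match.arg(dialect)
    if (length(group) != length(paths))
        stop("one group label per file is required")
    if (is.null(sample_names))
        sample_names <- make.unique(sub("\\.[^.]*$", "", basename(paths)))
    per_sample <- lapply(paths, read_one_junction_file, dialect = dialect)

    styles <- vapply(per_sample, function(d)
        any(startsWith(d$chrom, "chr")), TRUE)
    if (length(unique(styles)) > 1L) {
        offending <- unique(unlist(lapply(per_sample, function(d)
            unique(d$chrom))))
        stop("inconsistent chromosome naming across samples: ",
             paste(sort(offending), collapse = ", "))
    }
    all_keys <- unique(unlist(lapply(per_sample, function(d) d$key)))
    cts <- matrix(0L, nrow = length(all_keys), ncol = length(paths),
                  dimnames = list(NULL, sample_names))
    for (i in seq_along(per_sample)) {
        d <- per_sample[[i]]
        cts[match(d$key, all_keys), i] <- as.integer(d$count)
    }
    parts <- do.call(rbind, strsplit(all_keys, "\031", fixed = TRUE))
    gr <- GenomicRanges::GRanges(parts[, 1],
                                 IRanges::IRanges(as.integer(parts[, 2]),
                                                  as.integer(parts[, 3])),
                                 strand = parts[, 4])
    o <- order_granges(gr)
    JunctionExperiment(cts[o, , drop = FALSE], gr[o], group = group)
}

order_granges <- function(gr) {
    order(as.character(GenomicRanges::seqnames(gr)), IRanges::start(gr),
          IRanges::end(gr), as.character(GenomicRanges::strand(gr)))
}

read_one_junction_file <- function(path, dialect) {
    if (dialect == "plain_tsv") {
        d <- utils::read.delim(path, stringsAsFactors = FALSE)
        need <- c("chrom", "start", "end", "strand", "count")
        if (!all(need %in% colnames(d)))
            stop("'", path, "': plain_tsv needs columns ",
                 paste(need, collapse = ", "))
        out <- data.frame(chrom = as.character(d$chrom),
                          start = as.integer(d$start),
                          end = as.integer(d$end),
                          strand = as.character(d$strand),
                          count = as.numeric(d$count),
                          stringsAsFactors = FALSE)
    } else {
        d <- utils::read.delim(path, header = FALSE,
                               stringsAsFactors = FALSE)
        if (ncol(d) < 12)
            stop("'", path, "': regtools_bed12 needs 12 columns")
        sizes <- strsplit(as.character(d[[11]]), ",")
        b1 <- vapply(sizes, function(s) as.integer(s[1]), 1L)
        b2 <- vapply(sizes, function(s) as.integer(s[2]), 1L)
        out <- data.frame(chrom = as.character(d[[1]]),
                          start = as.integer(d[[2]]) + b1 + 1L,
                          end = as.integer(d[[3]]) - b2,
                          strand = as.character(d[[6]]),
                          count = as.numeric(d[[5]]),
                          stringsAsFactors = FALSE)
    }
    if (any(out$count < 0))
        stop("'", path, "': negative junction count")
    if (any(out$start > out$end))
        stop("'", path, "': intron start > end")
    out$strand[!out$strand %in% c("+", "-")] <- "*"
    out$key <- paste(out$chrom, out$start, out$end, out$strand,
                     sep = "\031")
    if (anyDuplicated(out$key)) {
        message("'", basename(path), "': duplicate junction lines summed")
        agg <- rowsum(out$count, out$key)
        out <- out[!duplicated(out$key), ]
        out$count <- agg[match(out$key, rownames(agg)), 1]
    }
    out
}

#' Write a JunctionExperiment as one plain TSV per sample
#'
#' Inverse of [readJunctionCounts()] with `dialect = "plain_tsv"`; junctions
#' with zero count in a sample are still written so that a round trip is
#' exact.
#'
#' @param x a [JunctionExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeJunctionCounts <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gr <- junctionRanges(x)
    cts <- junctionCounts(x)
    paths <- file.path(dir, paste0(colnames(cts), ".tsv"))
    for (i in seq_len(ncol(cts))) {
        d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = IRanges::start(gr), end = IRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        count = cts[, i])
        utils::write.table(d, paths[i], sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(paths)
}

#' Extract exon-body and flanking sequences in transcript orientation
#'
#' For each interval, returns the exon body plus `flank` bases upstream and
#' downstream *with respect to the transcript strand*: on the minus strand
#' all three sequences are reverse-complemented and the genomic left/right
#' flanks swap roles so that "upstream" is always 5' of the exon.
#'
#' @param genome a FASTA path or a [Biostrings::DNAStringSet].
#' @param intervals a [GenomicRanges::GRanges]; strand must be `+` or `-`.
#' @param flank flank length in bases (default 100).
#' @return a `data.frame` with one row per interval and character columns
#'   `upstream_flank`, `exon_body`, `downstream_flank`.
#' @export
extractSequences <- function(genome, intervals, flank = 100L) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    str <- as.character(GenomicRanges::strand(intervals))
    if (any(!str %in% c("+", "-")))
        stop("strand must be '+' or '-' to orient flanks")
    chrom <- as.character(GenomicRanges::seqnames(intervals))
    if (any(!chrom %in% names(genome)))
        stop("interval chromosome(s) absent from genome: ",
             paste(setdiff(chrom, names(genome)), collapse = ", "))
    s <- IRanges::start(intervals); e <- IRanges::end(intervals)
    lens <- setNames(IRanges::width(genome), names(genome))
    if (any(s - flank < 1L) || any(e + flank > lens[chrom]))
        stop("interval with flank extends beyond contig end")
    n <- length(intervals)
    up <- body <- down <- character(n)
    for (i in seq_len(n)) {
        chr_seq <- genome[[chrom[i]]]
        left  <- as.character(Biostrings::subseq(chr_seq, s[i] - flank,
                                                 s[i] - 1L))
        mid   <- as.character(Biostrings::subseq(chr_seq, s[i], e[i]))
        right <- as.character(Biostrings::subseq(chr_seq, e[i] + 1L,
                                                 e[i] + flank))
        if (str[i] == "+") {
            up[i] <- left; body[i] <- mid; down[i] <- right
        } else {
            rc <- function(z) as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(z)))
            up[i] <- rc(right); body[i] <- rc(mid); down[i] <- rc(left)
        }
    }
    data.frame(upstream_flank = up, exon_body = body,
               downstream_flank = down, stringsAsFactors = FALSE)
}

#' Read a per-base conservation track from bedGraph
#'
#' bedGraph intervals are 0-based half-open and are converted to 1-based
#' inclusive. Overlapping intervals within a chromosome are an error;
#' positions outside coverage score `NA`.
#'
#' @param path bedGraph file path.
#' @return a `GRanges` with a numeric `score` column (the track).
#' @export
readConservationTrack <- function(path) {
    gr <- tryCatch(
        rtracklayer::import(path, format = "bedGraph"),
        error = function(e) stop("failed to parse bedGraph '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    # rtracklayer already converts to 1-based inclusive
    hits <- IRanges::findOverlaps(gr, gr)
    if (any(S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)))
        stop("overlapping intervals in conservation track '", path, "'")
    gr
}

#' Query a conservation track at single positions
#'
#' @param track a `GRanges` track from [readConservationTrack()].
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return numeric scores, `NA` where uncovered.
#' @export
trackScoreAt <- function(track, chrom, pos) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    # chromosomes absent from the track are legitimate queries (-> NA)
    hits <- suppressWarnings(
        IRanges::findOverlaps(q, track, ignore.strand = TRUE))
    out <- rep(NA_real_, length(q))
    out[S4Vectors::queryHits(hits)] <-
        S4Vectors::mcols(track)$score[S4Vectors::subjectHits(hits)]
    out
}
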