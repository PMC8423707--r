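#' @import methods
#' @importFrom stats optim pchisq p.adjust rpois runif rbinom rgamma rnorm
#'   complete.cases median cor.test wilcox.test sd rmultinom ave na.omit
#'   setNames
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits
#'   subjectHits
#' @importFrom IRanges IRanges findOverlaps pintersect width start end
#' @importFrom GenomicRanges GRanges seqnames strand granges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowRanges
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement subseq vcountPDict PDict
#'   mkAllStrings
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Junction-by-sample count container
#'
#' `JunctionExperiment` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are intron
#' intervals (1-based, inclusive, the GTF convention), columns are samples,
#' and the single `"counts"` assay holds non-negative integer split-read
#' counts. Each sample carries a `group` label in `colData` (exactly the
#' two-condition design expected by [differentialSplicing()]).
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [JunctionExperiment()], [readJunctionCounts()]
#' @export
setClass("JunctionExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("JunctionExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
        if (anyNA(cts))
            msg <- c(msg, "counts must not contain NA")
    }
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    rr <- SummarizedExperiment::rowRanges(object)
    key <- paste(GenomicRanges::seqnames(rr), IRanges::start(rr),
                 IRanges::end(rr), GenomicRanges::strand(rr))
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate junctions (chrom/start/end/strand) found")
    if (is.null(msg)) TRUE else msg
})

#' Construct a JunctionExperiment
#'
#' @param counts junction-by-sample matrix of non-negative integers.
#' @param junctions a [GenomicRanges::GRanges] of intron intervals (1-based,
#'   inclusive), one per row of `counts`. Strand `*` means unknown.
#' @param group character or factor of per-sample group labels (e.g.
#'   `"control"`, `"knockdown"`), recycled checkably to `ncol(counts)`.
#' @return a [JunctionExperiment-class] object.
#' @examples
#' jx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 400)),
#'                              strand = "+")
#' cts <- matrix(c(5L, 7L, 3L, 2L), nrow = 2,
#'               dimnames = list(NULL, c("s1", "s2")))
#' je <- JunctionExperiment(cts, jx, group = c("control", "knockdown"))
#' je
#' @export
JunctionExperiment <- function(counts, junctions, group) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (length(junctions) != nrow(counts))
        stop("length(junctions) must equal nrow(counts)")
    if (length(group) != ncol(counts))
        stop("one group label per sample is required")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = junctions,
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       row.names = colnames(counts)))
    methods::new("JunctionExperiment", se)
}

#' @describeIn JunctionExperiment the counts assay.
#' @param object,x a `JunctionExperiment`.
#' @export
junctionCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn JunctionExperiment intron intervals as `GRanges`.
#' @export
junctionRanges <- function(x) SummarizedExperiment::rowRanges(x)

#' @describeIn JunctionExperiment per-sample group labels.
#' @export
sampleGroups <- function(x) SummarizedExperiment::colData(x)$group

setMethod("show", "JunctionExperiment", function(object) {
    cat("JunctionExperiment with", nrow(object), "junctions and",
        ncol(object), "samples\n")
    grp <- table(sampleGroups(object))
    cat("groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
    methods::callNextMethod()
})

#' Transcript annotation: exons and derived intron junctions
#'
#' Built by [readGTF()]. `exons` holds exon intervals with `transcript_id`
#' and `gene_id` metadata; `junctions` holds the deduplicated set of intron
#' intervals derived from adjacent exons of each transcript, with a `gene_id`
#' metadata column.
#'
#' @slot exons a [GenomicRanges::GRanges] of exons.
#' @slot junctions a [GenomicRanges::GRanges] of introns.
#' @export
setClass("TranscriptAnnotation",
         representation(exons = "GRanges", junctions = "GRanges"))

setValidity("TranscriptAnnotation", function(object) {
    msg <- NULL
    if (length(object@exons) &&
        !all(c("transcript_id", "gene_id") %in%
             colnames(S4Vectors::mcols(object@exons))))
        msg <- c(msg, "exons need transcript_id and gene_id metadata")
    j <- object@junctions
    key <- paste(GenomicRanges::seqnames(j), IRanges::start(j),
                 IRanges::end(j), GenomicRanges::strand(j))
    if (anyDuplicated(key))
        msg <- c(msg, "junction set must be deduplicated")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn TranscriptAnnotation exon intervals.
#' @param x a `TranscriptAnnotation`.
#' @export
annotatedExons <- function(x) x@exons

#' @describeIn TranscriptAnnotation derived intron junctions.
#' @export
annotatedJunctions <- function(x) x@junctions

setMethod("show", "TranscriptAnnotation", function(object) {
    cat("TranscriptAnnotation:", length(object@exons), "exons,",
        length(object@junctions), "distinct junctions,",
        length(unique(S4Vectors::mcols(object@exons)$transcript_id)),
        "transcripts\n")
})

#' Junction clusters
#'
#' Result of [clusterJunctions()]: connected components of overlapping (or
#' splice-site-sharing) intron intervals that survived the read-support
#' filters. `members` indexes rows of the originating
#' [JunctionExperiment-class].
#'
#' @slot ids canonical cluster identifiers (see [clusterFingerprint()]).
#' @slot members list of integer vectors of junction row indices.
#' @slot span a [GenomicRanges::GRanges], one range covering each cluster.
#' @export
setClass("JunctionClusters",
         representation(ids = "character", members = "list",
                        span = "GRanges"))

setValidity("JunctionClusters", function(object) {
    msg <- NULL
    if (length(object@ids) != length(object@members) ||
        length(object@ids) != length(object@span))
        msg <- c(msg, "ids, members and span must have equal length")
    if (any(vapply(object@members, length, 1L) < 2L))
        msg <- c(msg, "every retained cluster needs >= 2 junctions")
    if (anyDuplicated(object@ids))
        msg <- c(msg, "cluster ids must be unique")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn JunctionClusters number of clusters.
#' @param x a `JunctionClusters`.
#' @export
setMethod("length", "JunctionClusters", function(x) length(x@ids))

#' @describeIn JunctionClusters cluster identifiers.
#' @export
clusterIds <- function(x) x@ids

#' @describeIn JunctionClusters list of junction index vectors.
#' @export
clusterMembers <- function(x) x@members

#' @describeIn JunctionClusters covering span per cluster.
#' @export
clusterSpan <- function(x) x@span

setMethod("show", "JunctionClusters", function(object) {
    sizes <- vapply(object@members, length, 1L)
    cat("JunctionClusters:", length(object@ids), "clusters;",
        "sizes", if (length(sizes)) paste0(min(sizes), "-", max(sizes))
                 else "-", "junctions\n")
})
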