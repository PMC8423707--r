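## Downstream feature statistics over exon sets: reading-frame preservation,
## per-exon mean conservation, rank tests between exon classes, and the
## presence-based k-mer enrichment contrast.

#' Is an exon length frame-preserving?
#'
#' An exon preserves the downstream reading frame iff its width is divisible
#' by 3. Under uniform random lengths about one third of exons are
#' frame-preserving, which is the null expectation the observed fraction is
#' compared against.
#'
#' @param exon_length integer vector of exon lengths (>= 1).
#' @return logical vector.
#' @export
framePreserving <- function(exon_length) {
    if (any(exon_length < 1)) stop("exon lengths must be >= 1")
    exon_length %% 3 == 0
}

#' Mean per-base conservation over an exon
#'
#' Arithmetic mean of the track score over the exon's covered bases only;
#' `NA` when nothing is covered (conservation tracks have gaps and an
#' uncovered base carries no information).
#'
#' @param track a `GRanges` score track from [readConservationTrack()].
#' @param exons a `GRanges` of exons.
#' @return numeric vector of per-exon means.
#' @export
meanConservation <- function(track, exons) {
    # exons on chromosomes the track does not cover simply come back NA
    hits <- suppressWarnings(
        IRanges::findOverlaps(exons, track, ignore.strand = TRUE))
    out <- rep(NA_real_, length(exons))
    if (!length(hits)) return(out)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- suppressWarnings(
        IRanges::pintersect(GenomicRanges::granges(exons)[qh],
                            GenomicRanges::granges(track)[sh],
                            ignore.strand = TRUE))
    w <- IRanges::width(ov)
    sc <- S4Vectors::mcols(track)$score[sh]
    num <- rowsum(w * sc, qh)
    den <- rowsum(w, qh)
    out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
    out
}

#' Rank test of conservation between two exon classes
#'
#' Two-sided Wilcoxon rank-sum test of mean conservation between two
#' `exon_set` classes, reporting group medians alongside the p-value. Groups
#' smaller than 3 trigger a warning but are still tested.
#'
#' @param summaries a `data.frame` with columns `mean_phylop` and `exon_set`.
#' @param group_a,group_b the two `exon_set` labels to compare.
#' @return a list: `p_value`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
conservationGroupTest <- function(summaries, group_a, group_b) {
    a <- summaries$mean_phylop[summaries$exon_set == group_a]
    b <- summaries$mean_phylop[summaries$exon_set == group_b]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    if (length(a) < 3 || length(b) < 3)
        warning("a conservation group has fewer than 3 exons")
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(p_value = wt$p.value, median_a = stats::median(a),
         median_b = stats::median(b), n_a = length(a), n_b = length(b))
}

## 2x2 chi-squared test of equal proportions, no continuity correction.
## x1/n1, x2/n2 successes; degenerate margins give p = 1.
chisq_equal_prop <- function(x1, n1, x2, n2) {
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
        return(list(stat = 0, p = 1))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Presence-based k-mer enrichment between two sequence sets
#'
#' For every k-mer of each length in `k_range`, computes the fraction of
#' sequences in each set containing the k-mer at least once and contrasts
#' the two fractions with a chi-squared test of equal proportions (no
#' continuity correction). Bonferroni adjustment is applied within each
#' k-mer-length family (`4^k` tests). `N` bases never match; sequences
#' shorter than `k` count as not containing the k-mer. The enrichment ratio
#' is `prop_a / prop_b`.
#'
#' @param set_a,set_b character vectors or [Biostrings::DNAStringSet]s of
#'   uppercase DNA sequences (e.g. included vs skipped exon bodies).
#' @param k_range integer k-mer lengths (default `2:4`).
#' @param region optional label copied into the output.
#' @return a `data.frame` sorted by adjusted p: `kmer`, `k`, `region`,
#'   `prop_a`, `prop_b`, `chi2_stat`, `p_value`, `p_bonferroni`,
#'   `enrichment_ratio`.
#' @export
kmerEnrichment <- function(set_a, set_b, k_range = 2:4, region = NA) {
    set_a <- Biostrings::DNAStringSet(set_a)
    set_b <- Biostrings::DNAStringSet(set_b)
    if (!length(set_a) || !length(set_b))
        stop("both sequence sets must be non-empty")
    res <- lapply(k_range, function(k) {
        kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
        pres_a <- kmer_presence(set_a, kmers, k)
        pres_b <- kmer_presence(set_b, kmers, k)
        prop_a <- rowMeans(pres_a)
        prop_b <- rowMeans(pres_b)
        tests <- mapply(function(xa, xb) {
            t <- chisq_equal_prop(xa, length(set_a), xb, length(set_b))
            c(t$stat, t$p)
        }, rowSums(pres_a), rowSums(pres_b))
        data.frame(kmer = kmers, k = k, region = region,
                   prop_a = prop_a, prop_b = prop_b,
                   chi2_stat = tests[1, ], p_value = tests[2, ],
                   p_bonferroni = pmin(1, tests[2, ] * length(kmers)),
                   enrichment_ratio = prop_a / prop_b,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out <- out[order(out$p_bonferroni, out$p_value, out$kmer), ]
    rownames(out) <- NULL
    out
}

## presence/absence matrix (kmers x sequences); N never matches and
## sequences shorter than k count as not containing any k-mer
kmer_presence <- function(seqs, kmers, k) {
    short <- IRanges::width(seqs) < k
    if (any(short))
        message(sum(short), " sequence(s) shorter than k = ", k,
                " counted as motif-free")
    cnt <- matrix(0L, nrow = length(kmers), ncol = length(seqs))
    if (any(!short)) {
        pd <- Biostrings::PDict(kmers)
        cnt[, !short] <- Biostrings::vcountPDict(pd, seqs[!short])
    }
    cnt > 0L
}

#' Fraction of sequences containing a bracket pattern
#'
#' A pattern such as `CCC[AT]` expands single-position bracket classes into
#' all concrete alternatives (`CCCA`, `CCCT`); a sequence matches if any
#' alternative occurs in it.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet].
#' @param pattern DNA pattern with optional `[..]` classes.
#' @return fraction of sequences with at least one match.
#' @export
patternPresence <- function(sequences, pattern) {
    sequences <- as.character(Biostrings::DNAStringSet(sequences))
    alts <- expand_bracket_pattern(pattern)
    hit <- rep(FALSE, length(sequences))
    for (a in alts)
        hit <- hit | grepl(a, sequences, fixed = TRUE)
    mean(hit)
}

expand_bracket_pattern <- function(pattern) {
    if (!grepl("^[ACGT\\[\\]]+$", pattern, perl = TRUE))
        stop("pattern may only contain A, C, G, T and brackets")
    chars <- strsplit(pattern, "")[[1]]
    if (sum(chars == "[") != sum(chars == "]"))
        stop("malformed brackets in pattern '", pattern, "'")
    pieces <- list()
    i <- 1L
    while (i <= length(chars)) {
        if (chars[i] == "[") {
            j <- i + 1L
            cls <- character()
            while (j <= length(chars) && chars[j] != "]") {
                if (chars[j] == "[") stop("nested brackets in pattern")
                cls <- c(cls, chars[j]); j <- j + 1L
            }
            if (j > length(chars) || !length(cls))
                stop("malformed brackets in pattern '", pattern, "'")
            pieces[[length(pieces) + 1L]] <- cls
            i <- j + 1L
        } else {
            pieces[[length(pieces) + 1L]] <- chars[i]
            i <- i + 1L
        }
    }
    alts <- ""
    for (p in pieces)
        alts <- as.vector(outer(alts, p, paste0))
    alts
}
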