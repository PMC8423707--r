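## Leafcutter-style clustering of intron intervals: connected components
## under overlap / splice-site sharing, with read-support and intron-length
## filters applied to counts pooled across all samples.

#' Cluster overlapping splice junctions
#'
#' Groups junctions into connected components where two junctions are
#' connected if their intron intervals share at least one base or a splice
#' site (with 1-based inclusive introns, sharing a donor or acceptor always
#' shares a base, so plain interval overlap realises both notions).
#' Filters, in order:
#' \enumerate{
#'   \item junctions with intron length greater than `max_intron` are removed;
#'   \item components are formed per chromosome (strand-unknown junctions may
#'     join either strand but never bridge a `+` and a `-` component);
#'   \item junctions contributing (pooled over all samples) less than
#'     `min_prop` of their cluster's total reads are dropped and components
#'     re-formed, iterated to a fixed point;
#'   \item clusters with pooled total below `min_cluster_reads`, and
#'     singleton clusters, are dropped.
#' }
#' Defaults are the standard short-read cassette-discovery settings
#' (minimum cluster reads 60, minimum proportional contribution 0.001,
#' maximum intron length 200,000 bp).
#'
#' @param x a [JunctionExperiment-class].
#' @param min_cluster_reads minimum pooled reads for a cluster to be kept.
#' @param min_prop minimum pooled proportional contribution of a junction to
#'   its cluster.
#' @param max_intron maximum intron length in bases.
#' @return a [JunctionClusters-class]; may be empty.
#' @export
clusterJunctions <- function(x, min_cluster_reads = 60, min_prop = 0.001,
                             max_intron = 200000) {
    gr <- junctionRanges(x)
    pooled <- rowSums(junctionCounts(x))
    keep <- which(IRanges::width(gr) <= max_intron)

    comps <- list()
    active <- keep
    for (iter in seq_len(100L)) {
        comps <- connected_components(gr, active)
        drop <- integer(0)
        for (cp in comps) {
            tot <- sum(pooled[cp])
            low <- cp[pooled[cp] < min_prop * tot]
            drop <- c(drop, low)
        }
        if (!length(drop)) break
        active <- setdiff(active, drop)
        if (!length(active)) break
    }
    comps <- Filter(function(cp) length(cp) >= 2L &&
                        sum(pooled[cp]) >= min_cluster_reads, comps)
    build_clusters(comps, gr)
}

## connected components among junction indices `idx`, per chromosome;
## '*' strand joins either strand but cannot bridge '+' and '-'.
connected_components <- function(gr, idx) {
    if (!length(idx)) return(list())
    sub <- gr[idx]
    hits <- IRanges::findOverlaps(sub, sub, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    str <- as.character(GenomicRanges::strand(sub))
    compatible <- str[qi] == "*" | str[si] == "*" | str[qi] == str[si]
    edges <- cbind(qi, si)[compatible & qi < si, , drop = FALSE]
    comp <- union_find(length(idx), edges)

    # split components that ended up containing both '+' and '-' members:
    # reassign each '*' junction to the stranded side it touches more, then
    # recompute within strand.
    out <- list()
    for (cid in unique(comp)) {
        mem <- which(comp == cid)
        st <- unique(str[mem])
        if (all(c("+", "-") %in% st)) {
            amb <- mem[str[mem] == "*"]
            eff <- str[mem]
            for (a in amb) {
                touch <- unique(c(si[qi == a], qi[si == a]))
                touch <- intersect(touch, mem)
                nplus <- sum(str[touch] == "+")
                nminus <- sum(str[touch] == "-")
                eff[match(a, mem)] <- if (nminus > nplus) "-" else "+"
            }
            for (s in c("+", "-")) {
                sm <- mem[eff == s]
                if (!length(sm)) next
                e2 <- edges[edges[, 1] %in% sm & edges[, 2] %in% sm, ,
                            drop = FALSE]
                relab <- match(e2, sm)
                dim(relab) <- dim(e2)
                sub_comp <- union_find(length(sm), relab)
                for (sc in unique(sub_comp))
                    out[[length(out) + 1L]] <- idx[sm[sub_comp == sc]]
            }
        } else {
            out[[length(out) + 1L]] <- idx[mem]
        }
    }
    out
}

union_find <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    if (length(edges))
        for (k in seq_len(nrow(edges))) {
            a <- find(edges[k, 1]); b <- find(edges[k, 2])
            if (a != b) parent[b] <- a
        }
    vapply(seq_len(n), find, 1L)
}

build_clusters <- function(comps, gr) {
    if (!length(comps))
        return(methods::new("JunctionClusters", ids = character(),
                            members = list(), span = GenomicRanges::GRanges()))
    comps <- lapply(comps, sort)
    chrom <- vapply(comps, function(cp)
        as.character(GenomicRanges::seqnames(gr))[cp[1]], "")
    s <- vapply(comps, function(cp) min(IRanges::start(gr)[cp]), 1L)
    e <- vapply(comps, function(cp) max(IRanges::end(gr)[cp]), 1L)
    str <- vapply(comps, function(cp) {
        st <- setdiff(unique(as.character(GenomicRanges::strand(gr))[cp]), "*")
        if (length(st) == 1L) st else "*"
    }, "")
    o <- order(chrom, s, e, str)
    comps <- comps[o]; chrom <- chrom[o]; s <- s[o]; e <- e[o]; str <- str[o]
    base <- paste0(chrom, ":", s, "-", e, ":", str)
    ids <- paste0(base, ":", stats::ave(seq_along(base), base,
                                        FUN = seq_along))
    span <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                   strand = str)
    methods::new("JunctionClusters", ids = ids, members = comps, span = span)
}

#' Canonical cluster fingerprint
#'
#' `chrom:minStart-maxEnd:strand:k` where `k` disambiguates clusters with an
#' identical span. Stable across runs and invariant to the input order of
#' member junctions.
#'
#' @param clusters a [JunctionClusters-class].
#' @return character vector of ids (identical to [clusterIds()]).
#' @export
clusterFingerprint <- function(clusters) clusterIds(clusters)

#' Re-express clusters as a JunctionExperiment
#'
#' Subsets a [JunctionExperiment-class] to the junctions retained in
#' `clusters` (used for idempotence checks and downstream stages).
#'
#' @param x a [JunctionExperiment-class].
#' @param clusters a [JunctionClusters-class] over `x`.
#' @return a [JunctionExperiment-class] containing only clustered junctions.
#' @export
clusteredExperiment <- function(x, clusters) {
    idx <- sort(unique(unlist(clusterMembers(clusters))))
    methods::new("JunctionExperiment", x[idx, ])
}
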