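# shared fixture builders and independent brute-force oracles

write_gtf_lines <- function(path, exons) {
    # exons: data.frame chrom, start, end, strand, gene, tx
    lines <- sprintf(
        "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        exons$chrom, exons$start, exons$end, exons$strand, exons$gene,
        exons$tx)
    writeLines(lines, path)
    path
}

write_junction_tsv <- function(path, chrom, start, end, strand, count) {
    d <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand, count = count)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

make_junction_experiment <- function(chrom, start, end, strand, counts,
                                     group) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    JunctionExperiment(counts, gr, group = group)
}

# brute-force clustering oracle: O(n^2) overlap matrix, transitive closure
# by repeated sweeps, then the same filters as the implementation. Fully
# independent of findOverlaps/union-find. Returns a list of sorted index
# vectors (sorted by first member). Assumes all junctions share one strand.
oracle_cluster <- function(start, end, pooled, min_cluster_reads = 60,
                           min_prop = 0.001, max_intron = 200000) {
    active <- which(end - start + 1 <= max_intron)
    repeat {
        n <- length(active)
        if (n == 0) return(list())
        comp <- seq_len(n)
        repeat {
            changed <- FALSE
            for (i in seq_len(n)) for (j in seq_len(n)) {
                if (comp[i] != comp[j] &&
                    start[active[i]] <= end[active[j]] &&
                    start[active[j]] <= end[active[i]]) {
                    comp[comp == comp[j]] <- comp[i]
                    changed <- TRUE
                }
            }
            if (!changed) break
        }
        drop <- integer(0)
        for (cid in unique(comp)) {
            mem <- active[comp == cid]
            tot <- sum(pooled[mem])
            drop <- c(drop, mem[pooled[mem] < min_prop * tot])
        }
        if (!length(drop)) break
        active <- setdiff(active, drop)
    }
    out <- list()
    for (cid in unique(comp)) {
        mem <- sort(active[comp == cid])
        if (length(mem) >= 2 && sum(pooled[mem]) >= min_cluster_reads)
            out[[length(out) + 1L]] <- mem
    }
    out[order(vapply(out, min, 1L))]
}

# brute-force cassette-triple oracle: enumerate all ordered triples
oracle_triples <- function(start, end, max_exon = 250) {
    n <- length(start)
    out <- NULL
    for (a in seq_len(n)) for (b in seq_len(n)) for (sk in seq_len(n)) {
        if (a == b || a == sk || b == sk) next
        if (start[a] != start[sk] || end[b] != end[sk]) next
        if (end[a] >= start[b]) next
        if (start[b] - end[a] - 1 > max_exon) next
        out <- rbind(out, c(exon_start = end[a] + 1,
                            exon_end = start[b] - 1))
    }
    if (is.null(out)) return(out)
    unique(as.data.frame(out))
}
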