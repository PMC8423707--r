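test_that("GTF exons yield adjacent-pair introns, strand-invariantly", {
    path <- withr::local_tempfile(fileext = ".gtf")
    write_gtf_lines(path, data.frame(
        chrom = "chr1", start = c(1, 201, 401), end = c(100, 300, 500),
        strand = "+", gene = "G1", tx = "T1"))
    ann <- readGTF(path)
    j <- annotatedJunctions(ann)
    expect_equal(IRanges::start(j), c(101, 301))
    expect_equal(IRanges::end(j), c(200, 400))

    # same exons on the minus strand: identical coordinates, strand recorded
    write_gtf_lines(path, data.frame(
        chrom = "chr1", start = c(1, 201, 401), end = c(100, 300, 500),
        strand = "-", gene = "G1", tx = "T1"))
    jm <- annotatedJunctions(readGTF(path))
    expect_equal(IRanges::start(jm), IRanges::start(j))
    expect_equal(IRanges::end(jm), IRanges::end(j))
    expect_equal(as.character(GenomicRanges::strand(jm)), c("-", "-"))

    # a single-exon transcript contributes no junctions
    write_gtf_lines(path, data.frame(
        chrom = "chr1", start = 10, end = 90, strand = "+",
        gene = "G2", tx = "T2"))
    expect_length(annotatedJunctions(readGTF(path)), 0)
})

test_that("junction sets are deduplicated across transcripts", {
    path <- withr::local_tempfile(fileext = ".gtf")
    write_gtf_lines(path, data.frame(
        chrom = "chr1", start = c(1, 201, 1, 201), end = c(100, 300, 100, 300),
        strand = "+", gene = "G1", tx = c("T1", "T1", "T2", "T2")))
    expect_length(annotatedJunctions(readGTF(path)), 1)
})

test_that("regtools BED12 blocks convert to 1-based inclusive introns", {
    # blocks [901,1001) and [2000,2050): intron [1001,2000) half-open,
    # i.e. [1002,2000] 1-based inclusive
    path <- withr::local_tempfile(fileext = ".bed")
    writeLines(paste("chr1", 901, 2050, "JUNC1", 12, "+", 901, 2050,
                     "255,0,0", 2, "100,50", "0,1099", sep = "\t"), path)
    x <- readJunctionCounts(path, group = "control",
                            dialect = "regtools_bed12")
    gr <- junctionRanges(x)
    expect_equal(IRanges::start(gr), 1002)
    expect_equal(IRanges::end(gr), 2000)
    expect_equal(unname(junctionCounts(x)[1, 1]), 12L)
})

test_that("multi-sample reads take the union with zero fill and sum dups", {
    d <- withr::local_tempdir()
    a <- write_junction_tsv(file.path(d, "a.tsv"), "chr1", 100, 200, "+", 7)
    b <- write_junction_tsv(file.path(d, "b.tsv"), "chr1", 500, 600, "+", 3)
    x <- readJunctionCounts(c(a, b), group = c("g1", "g2"))
    expect_equal(nrow(x), 2)
    m <- junctionCounts(x)
    key <- paste(IRanges::start(junctionRanges(x)))
    expect_equal(unname(m[key == "100", ]), c(7L, 0L))
    expect_equal(unname(m[key == "500", ]), c(0L, 3L))

    # duplicate lines in one file are summed
    dup <- write_junction_tsv(file.path(d, "dup.tsv"), "chr1",
                              c(100, 100, 100), c(200, 200, 200), "+",
                              c(5, 2, 1))
    expect_message(xd <- readJunctionCounts(dup, group = "g1"), "summed")
    expect_equal(unname(junctionCounts(xd)[1, 1]), 8L)
})

test_that("negative counts and mixed chromosome styles are rejected", {
    d <- withr::local_tempdir()
    neg <- write_junction_tsv(file.path(d, "neg.tsv"), "chr1", 1, 5, "+", -1)
    expect_error(readJunctionCounts(neg, group = "g"), "negative")
    a <- write_junction_tsv(file.path(d, "a.tsv"), "chr1", 1, 5, "+", 1)
    b <- write_junction_tsv(file.path(d, "b.tsv"), "1", 1, 5, "+", 1)
    expect_error(readJunctionCounts(c(a, b), group = c("g", "g")),
                 "chromosome naming")
})

test_that("plain TSV round trip is exact", {
    set.seed(42)
    x <- make_junction_experiment(
        "chr2", c(10, 50, 400), c(30, 300, 900), c("+", "+", "-"),
        matrix(rpois(9, 20), nrow = 3,
               dimnames = list(NULL, c("s1", "s2", "s3"))),
        group = c("control", "control", "knockdown"))
    d <- withr::local_tempdir()
    paths <- writeJunctionCounts(x, d)
    y <- readJunctionCounts(paths, group = sampleGroups(x),
                            sample_names = colnames(junctionCounts(x)))
    expect_equal(junctionCounts(y), junctionCounts(x))
    expect_equal(as.character(junctionRanges(y)),
                 as.character(junctionRanges(x)))
})

test_that("sequence extraction orients flanks by transcript strand", {
    genome <- Biostrings::DNAStringSet(c(chrT = paste(
        c("AA", "CCCGGTTT", "GC"), collapse = "")))
    # exon [3,10] with flank 2: upstream AA, body CCCGGTTT, downstream GC
    iv <- GenomicRanges::GRanges("chrT", IRanges::IRanges(3, 10),
                                 strand = "+")
    s <- extractSequences(genome, iv, flank = 2)
    expect_equal(s$upstream_flank, "AA")
    expect_equal(s$exon_body, "CCCGGTTT")
    expect_equal(s$downstream_flank, "GC")

    GenomicRanges::strand(iv) <- "-"
    sm <- extractSequences(genome, iv, flank = 2)
    expect_equal(sm$upstream_flank, "GC")   # revcomp of GC is GC
    expect_equal(sm$exon_body, "AAACCGGG")
    expect_equal(sm$downstream_flank, "TT")

    # revcomp symmetry on a palindromic genome: identical extractions
    pal <- Biostrings::DNAStringSet(c(chrP = "ACGCGCGT"))
    ivp <- GenomicRanges::GRanges("chrP", IRanges::IRanges(3, 6),
                                  strand = "+")
    ivm <- ivp; GenomicRanges::strand(ivm) <- "-"
    expect_equal(extractSequences(pal, ivp, flank = 2),
                 extractSequences(pal, ivm, flank = 2))

    GenomicRanges::strand(iv) <- "*"
    expect_error(extractSequences(genome, iv, flank = 2), "strand")
    GenomicRanges::strand(iv) <- "+"
    expect_error(extractSequences(genome, iv, flank = 5), "contig")
})

test_that("bedGraph tracks answer point queries with half-open semantics", {
    path <- withr::local_tempfile(fileext = ".bedGraph")
    writeLines(c("chr1\t0\t10\t1.5", "chr1\t10\t20\t2.0"), path)
    tr <- readConservationTrack(path)
    expect_equal(trackScoreAt(tr, "chr1", 5), 1.5)
    expect_equal(trackScoreAt(tr, "chr1", 10), 1.5)  # boundary base: own row
    expect_equal(trackScoreAt(tr, "chr1", 11), 2.0)
    expect_true(is.na(trackScoreAt(tr, "chr1", 25)))
    expect_true(is.na(trackScoreAt(tr, "chr9", 5)))

    writeLines(c("chr1\t0\t10\t1.5", "chr1\t5\t20\t2.0"), path)
    expect_error(readConservationTrack(path), "overlapping")
})

test_that("chromosome name harmonisation maps both directions", {
    expect_equal(harmonizeChroms(c("1", "chrX", "MT")),
                 c("chr1", "chrX", "chrM"))
    expect_equal(harmonizeChroms(c("chr1", "chrM"), style = "plain"),
                 c("1", "MT"))
})
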