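test_that("cassette triples are found by their boundary signature", {
    # introns [101,200], [301,400], [101,400]: exon [201,300], length 100
    x <- make_junction_experiment(
        "chr1", c(101, 301, 101), c(200, 400, 400), "+",
        cbind(c(30L, 50L, 20L)), "control")
    ev <- findCassetteEvents(1:3, x, cluster_id = "c1")
    expect_equal(nrow(ev), 1)
    expect_equal(ev$exon_start, 201)
    expect_equal(ev$exon_end, 300)
    expect_equal(ev$exon_length, 100)
    expect_equal(ev$intron_start, 101)
    expect_equal(ev$intron_end, 400)

    # central exon of 300 bp exceeds the 250 bp cap: no event
    x2 <- make_junction_experiment(
        "chr1", c(101, 501, 101), c(200, 600, 600), "+",
        cbind(c(30L, 50L, 20L)), "control")
    expect_equal(nrow(findCassetteEvents(1:3, x2)), 0)

    # three junctions without shared outer boundaries: no event
    x3 <- make_junction_experiment(
        "chr1", c(101, 301, 120), c(200, 400, 410), "+",
        cbind(c(30L, 50L, 20L)), "control")
    expect_equal(nrow(findCassetteEvents(1:3, x3)), 0)
})

test_that("triple enumeration matches the brute-force oracle", {
    set.seed(23)
    for (rep in 1:40) {
        n <- sample(3:8, 1)
        # draw splice sites on a small grid to provoke boundary sharing
        start <- sample(seq(100, 1000, by = 50), n, replace = TRUE)
        end <- start + sample(seq(40, 400, by = 37), n, replace = TRUE)
        keep <- !duplicated(paste(start, end))
        start <- start[keep]; end <- end[keep]
        if (length(start) < 3) next
        x <- make_junction_experiment(
            "chr1", start, end, "+",
            cbind(sample(10:100, length(start))), "control")
        got <- findCassetteEvents(seq_along(start), x)
        want <- oracle_triples(start, end)
        if (is.null(want)) {
            expect_equal(nrow(got), 0)
        } else {
            expect_equal(nrow(got), nrow(want))
            expect_setequal(paste(got$exon_start, got$exon_end),
                            paste(want$exon_start, want$exon_end))
        }
    }
})

test_that("duplicate exons keep the best-supported triple", {
    # two triples implying the same exon; second inclusion pair better read
    x <- make_junction_experiment(
        "chr1", c(101, 301, 101, 51, 301, 51), c(200, 400, 400, 200, 450, 450),
        "+", cbind(c(10L, 10L, 5L, 90L, 90L, 5L)), "control")
    ev <- findCassetteEvents(1:6, x)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$inc1, 4)  # the 90-read pair wins
})

test_that("novelty is judged per junction against the reference", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    # inclusion transcript (3 exons) and skipping transcript (2 exons)
    write_gtf_lines(gtf, data.frame(
        chrom = "chr1",
        start = c(1, 201, 401, 1, 401),
        end = c(100, 300, 500, 100, 500),
        strand = "+", gene = "G1",
        tx = c("T.inc", "T.inc", "T.inc", "T.skip", "T.skip")))
    ann <- readGTF(gtf)
    x <- make_junction_experiment(
        "chr1", c(101, 301, 101), c(200, 400, 400), "+",
        cbind(c(30L, 50L, 20L)), "control")
    ev <- findCassetteEvents(1:3, x)
    expect_equal(annotateNovelty(ev, x, ann)$annot_status, "both_annotated")
    expect_false(annotateNovelty(ev, x, ann)$novel)
    expect_equal(annotateNovelty(ev, x, ann)$gene, "G1")

    # reference lacking the inclusion junctions: the classic novel cryptic
    write_gtf_lines(gtf, data.frame(
        chrom = "chr1", start = c(1, 401), end = c(100, 500),
        strand = "+", gene = "G1", tx = "T.skip"))
    st <- annotateNovelty(ev, x, readGTF(gtf))$annot_status
    expect_equal(st, "inclusion_novel")

    # strand-unknown event matches junctions annotated on either strand
    xu <- make_junction_experiment(
        "chr1", c(101, 301, 101), c(200, 400, 400), "*",
        cbind(c(30L, 50L, 20L)), "control")
    evu <- findCassetteEvents(1:3, xu)
    write_gtf_lines(gtf, data.frame(
        chrom = "chr1", start = c(1, 201, 401, 1, 401),
        end = c(100, 300, 500, 100, 500),
        strand = "-", gene = "G1",
        tx = c("T.inc", "T.inc", "T.inc", "T.skip", "T.skip")))
    expect_equal(annotateNovelty(evu, xu, readGTF(gtf))$annot_status,
                 "both_annotated")
})

test_that("PSI follows the bounded mean-inclusion form", {
    # inclusion 30 and 50, skipping 20: m = 40, PSI = 40/60
    x <- make_junction_experiment(
        "chr1", c(101, 301, 101), c(200, 400, 400), "+",
        cbind(c(30L, 50L, 20L),       # sample 1
              c(0L, 0L, 100L)),       # sample 2: zero inclusion
        group = c("control", "knockdown"))
    ev <- findCassetteEvents(1:3, x)
    ev <- computePsi(ev, x, min_event_reads = 1)
    expect_equal(ev$psi.sample1, 40 / 60, tolerance = 1e-12)
    expect_equal(ev$psi.sample2, 0)
    expect_equal(ev$dpsi, 0 - 40 / 60)

    # per-sample coverage floor marks PSI missing
    ev2 <- computePsi(findCassetteEvents(1:3, x), x, min_event_reads = 70)
    expect_true(is.na(ev2$psi.sample1))   # m + s = 60 < 70
    expect_false(is.na(ev2$psi.sample2))  # m + s = 100
    expect_false(ev2$quantifiable)

    # literal-ratio variant: m / s, capped at 1
    ev3 <- computePsi(findCassetteEvents(1:3, x), x, min_event_reads = 1,
                      literal_ratio = TRUE)
    expect_equal(ev3$psi.sample1, 1)      # 40/20 capped
})

test_that("group means and dpsi average per-sample PSI", {
    x <- make_junction_experiment(
        "chr1", c(101, 301, 101), c(200, 400, 400), "+",
        matrix(c(0L, 0L, 100L,   1L, 1L, 48L,   2L, 2L, 48L,
                 30L, 30L, 70L,  34L, 34L, 66L, 32L, 32L, 68L),
               nrow = 3),
        group = rep(c("control", "knockdown"), each = 3))
    ev <- computePsi(findCassetteEvents(1:3, x), x, min_event_reads = 1)
    expect_equal(ev$psi_control, mean(c(0, 1 / 49, 2 / 50)))
    expect_equal(ev$psi_case, mean(c(0.30, 34 / 100, 32 / 100)))
    expect_equal(ev$dpsi, ev$psi_case - ev$psi_control)
    expect_true(ev$quantifiable)
})

test_that("classification thresholds partition the PSI plane", {
    expect_equal(classifyEvent(0.05, 0.25), "cryptic")
    expect_equal(classifyEvent(0.95, -0.20), "skiptic")
    expect_equal(classifyEvent(0.50, 0.05), "weak")
    expect_equal(classifyEvent(0.50, 0.20), "included")
    expect_equal(classifyEvent(0.50, -0.20), "skipped")
    # boundary semantics: cryptic needs strict inequalities
    expect_equal(classifyEvent(0.10, 0.25), "included")
    expect_equal(classifyEvent(0.05, 0.10), "included")
    expect_equal(classifyEvent(0.90, -0.25), "skipped")
    expect_true(is.na(classifyEvent(NA, 0.3)))

    # every quantifiable event gets exactly one label
    set.seed(31)
    pc <- runif(500); dp <- runif(500, -1, 1)
    dp <- pmin(pmax(dp, -pc), 1 - pc)  # keep psi_case in [0,1]
    lab <- classifyEvent(pc, dp)
    expect_true(all(lab %in% c("cryptic", "skiptic", "included",
                               "skipped", "weak")))
    expect_false(any(lab == "cryptic" & lab == "skiptic"))
})

test_that("only significant clusters are scanned unless scan_all", {
    sim <- simulateJunctionDataset(simulationConfig(seed = 2,
                                                    n_clusters = 40,
                                                    n_cryptic = 8,
                                                    n_skiptic = 0))
    x <- sim$experiment
    cl <- clusterJunctions(x)
    dm <- differentialSplicing(x, cl)
    ev <- runClassification(x, cl, dm)
    expect_true(all(ev$cluster_id %in% dm$cluster_id[dm$significant]))
    ev_all <- runClassification(x, cl, dm, scan_all = TRUE)
    expect_gte(nrow(ev_all), nrow(ev))

    # no significant clusters -> empty table
    dm0 <- dm; dm0$significant <- FALSE
    ev0 <- runClassification(x, cl, dm0)
    expect_equal(nrow(ev0), 0)
    expect_equal(unname(attr(ev0, "summary")["n_cassette"]), 0L)

    # mismatched cluster ids are rejected
    dm_bad <- dm; dm_bad$cluster_id[1] <- "nonexistent"
    expect_error(runClassification(x, cl, dm_bad), "do not match")
})

test_that("PSI stays in [0,1] and dpsi in [-1,1] on simulated data", {
    sim <- simulateJunctionDataset(simulationConfig(seed = 6,
                                                    n_clusters = 50,
                                                    n_cryptic = 15,
                                                    n_skiptic = 15))
    x <- sim$experiment
    cl <- clusterJunctions(x)
    dm <- differentialSplicing(x, cl)
    ev <- runClassification(x, cl, dm, scan_all = TRUE)
    psis <- unlist(ev[grep("^psi\\.", names(ev))])
    expect_true(all(psis >= 0 & psis <= 1, na.rm = TRUE))
    expect_true(all(abs(ev$dpsi) <= 1, na.rm = TRUE))
})
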