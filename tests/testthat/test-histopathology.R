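test_that("tile sampling packs the ROI without overlap, deterministically", {
    g1 <- sampleTiles(1000, 1000, seed = 1)
    expect_equal(nrow(g1$origins), 1)
    expect_equal(c(g1$origins$x, g1$origins$y), c(0, 0))

    g3 <- sampleTiles(3000, 1000, seed = 2)
    expect_lte(nrow(g3$origins), 3)
    o <- g3$origins
    if (nrow(o) > 1)
        for (i in 2:nrow(o))
            for (j in seq_len(i - 1))
                expect_false(abs(o$x[i] - o$x[j]) < 1000 &
                                 abs(o$y[i] - o$y[j]) < 1000)

    expect_identical(sampleTiles(8000, 6000, seed = 7),
                     sampleTiles(8000, 6000, seed = 7))
    expect_error(sampleTiles(900, 5000), "at least one tile")
    big <- sampleTiles(40000, 40000, max_tiles = 300, seed = 3)
    expect_lte(nrow(big$origins), 300)
})

test_that("case scores follow the density and presence definitions", {
    grid <- list(origins = data.frame(tile_id = 1:129, x = 0, y = 0),
                 tile_side = 1000, tile_area_mm2 = 0.345)
    class(grid) <- "TileGrid"
    det <- data.frame(
        tile_id = c(1:10, 1:40),
        label = rep(c("abnormal", "normal"), c(10, 40)))
    s <- scoreCase(det, grid, "case1")
    expect_equal(s$analysed_area_mm2, 129 * 0.345)      # 44.505 ~ 44.5
    expect_equal(round(s$analysed_area_mm2, 1), 44.5)
    expect_equal(s$misloc_pct, 100 * 10 / 129)          # 7.752
    expect_equal(round(s$misloc_pct, 3), 7.752)
    expect_equal(s$normal_per_mm2, 40 / 44.505)
    expect_equal(s$abnormal_fraction, 10 / 50)

    # presence-based: duplicating a tile's detections changes nothing
    s2 <- scoreCase(rbind(det, det[det$tile_id == 1, ]), grid)
    expect_equal(s2$misloc_pct, s$misloc_pct)

    # no abnormal neurons -> 0
    s0 <- scoreCase(det[det$label == "normal", ], grid)
    expect_equal(s0$misloc_pct, 0)

    expect_error(scoreCase(data.frame(tile_id = 999, label = "normal"),
                           grid), "absent from grid")
    empty <- grid; empty$origins <- empty$origins[0, ]
    expect_error(scoreCase(det, empty), "zero tiles")
})

test_that("cumulative curves are normalised, monotone and cross at the
           median", {
    # equal scores at ages 60, 70, 80: cumulative 1/3, 2/3, 1 -> crossing 70
    sc <- data.frame(case_id = c("a", "b", "c"), misloc_pct = c(5, 5, 5),
                     age_death = c(80, 60, 70))
    cc <- cumulativeMislocCurve(sc)
    expect_equal(cc$curve$age_death, c(60, 70, 80))
    expect_equal(cc$curve$cumulative, c(1, 2, 3) / 3)
    expect_equal(cc$median_crossing_age, 70)

    # one case carrying all mislocalisation: a step at its age
    sc2 <- data.frame(case_id = c("a", "b", "c"),
                      misloc_pct = c(0, 12, 0), age_death = c(60, 71, 80))
    cc2 <- cumulativeMislocCurve(sc2)
    expect_equal(cc2$curve$cumulative, c(0, 1, 1))
    expect_equal(cc2$median_crossing_age, 71)

    # non-decreasing, ends at exactly 1
    set.seed(81)
    sc3 <- data.frame(case_id = paste0("c", 1:20),
                      misloc_pct = runif(20, 0, 50),
                      age_death = sample(40:95, 20))
    cc3 <- cumulativeMislocCurve(sc3)
    expect_true(!is.unsorted(cc3$curve$cumulative))
    expect_equal(cc3$curve$cumulative[20], 1)

    expect_error(cumulativeMislocCurve(sc3[1, ]), ">= 2 cases")
    sc3$misloc_pct <- 0
    expect_error(cumulativeMislocCurve(sc3), "zero")
})

test_that("age correlation uses Spearman ranks with guards", {
    sc <- data.frame(misloc_pct = c(1, 2, 3, 4, 5) * 3,
                     age_death = c(50, 60, 70, 80, 90))
    r <- correlateAge(sc)
    expect_equal(r$rho, 1)
    expect_equal(r$n, 5)

    # permutation null: mean correlation near zero
    set.seed(91)
    base <- data.frame(misloc_pct = runif(12, 0, 40),
                       age_death = 50:61)
    rs <- replicate(1000, {
        b <- base; b$misloc_pct <- sample(b$misloc_pct)
        correlateAge(b)$rho
    })
    expect_lt(abs(mean(rs)), 0.05)

    expect_error(correlateAge(sc[1:4, ]), ">= 5")
    sc$misloc_pct <- 7
    expect_error(correlateAge(sc), "constant")
})

test_that("cohort summaries reproduce the packaged table's printed rows", {
    path <- system.file("extdata", "cohort_table1.tsv", package = "cryptex")
    d <- readCohortTable(path)
    expect_equal(nrow(d), 96)

    a <- cohortSummary(d, "FTLD-TDP A")
    expect_equal(a$n, 28)
    expect_equal(a$mean_age_onset, 59.6)
    expect_equal(a$mean_age_death, 66.1)
    expect_equal(a$mean_duration, 6.5)
    expect_equal(a$mean_brain_weight_g, 1142)
    expect_equal(a$mean_pm_delay_h, 64.0)
    expect_equal(a$sex, "18(M):10(F)")

    cc <- cohortSummary(d, "FTLD-TDP C")
    expect_equal(cc$n, 12)
    expect_equal(cc$mean_age_death, 72.6)
    expect_equal(cc$sex, "6(M):6(F)")

    # independent spreadsheet-style recomputation for every group row
    for (g in unique(d$group)) {
        r <- d[d$group == g, ]
        s <- cohortSummary(d, g)
        expect_equal(s$mean_age_death,
                     floor(mean(r$age_death, na.rm = TRUE) * 10 + 0.5 +
                               1e-9) / 10,
                     info = g)
        expect_equal(s$n, nrow(r), info = g)
    }

    # a single-record group summarises to itself
    one <- d[d$case_id == 1, ]
    s1 <- cohortSummary(one, "FTLD-TDP A")
    expect_equal(s1$mean_age_death, 73)
    expect_equal(s1$n, 1)

    bad <- d; bad$age_death[1] <- 10
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(readCohortTable(tmp), "before age at onset")
    expect_error(cohortSummary(d, "no-such-group"), "not present")
})

test_that("the configured age effect yields a moderate Spearman r under
           case-level frailty", {
    # frailty SD 2.2 was chosen to put the control-group correlation near
    # the moderate (~0.55) regime at n = 35
    rs <- vapply(1:15, function(s) {
        sim <- simulateDetections(simulationConfig(
            seed = 400 + s, misloc_frailty_sd = 2.2, n_cases_disease = 4))
        sc <- do.call(rbind, lapply(names(sim$detections), function(cid)
            scoreCase(sim$detections[[cid]], sim$grids[[cid]], cid)))
        sc <- merge(sc, sim$cohort, by = "case_id")
        correlateAge(sc[sc$group == "control", ])$rho
    }, 1)
    expect_equal(mean(rs), 0.55, tolerance = 0.15)
})
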