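## Quantitative neuropathology of hnRNP K mislocalisation: random
## non-overlapping tile sampling over a region of interest, per-case density
## and mislocalisation metrics from labelled neuron detections, age-ordered
## cumulative mislocalisation curves and cohort summary tables.

TILE_AREA_MM2 <- 0.345   # area of one 1000x1000-pixel tile at 20x

#' Sample random non-overlapping tiles over a region of interest
#'
#' Seeded rejection sampling of axis-aligned `tile_side`-pixel square tiles
#' inside a `roi_width` x `roi_height` ROI. Candidate origins are drawn
#' uniformly; a candidate overlapping an accepted tile is rejected. Sampling
#' stops at `max_tiles` accepted tiles or after 10,000 consecutive
#' rejections. Deterministic for a fixed seed.
#'
#' @param roi_width,roi_height ROI size in pixels (each >= `tile_side`).
#' @param tile_side tile side in pixels (default 1000).
#' @param max_tiles hard cap on the number of tiles (default 300).
#' @param seed integer seed.
#' @param tile_area_mm2 physical tile area (default 0.345 mm^2).
#' @return a list of class `TileGrid`: `origins` (data.frame `x`, `y`,
#'   `tile_id`), `tile_side`, `tile_area_mm2`, `roi_width`, `roi_height`,
#'   `seed`.
#' @export
sampleTiles <- function(roi_width, roi_height, tile_side = 1000,
                        max_tiles = 300, seed = 1,
                        tile_area_mm2 = TILE_AREA_MM2) {
    if (roi_width < tile_side || roi_height < tile_side)
        stop("ROI must be at least one tile in both dimensions")
    rng <- local_rng(seed)
    xs <- ys <- numeric(0)
    consecutive <- 0L
    batch <- 512L                    # candidates drawn per RNG call
    while (length(xs) < max_tiles && consecutive < 10000L) {
        cand <- rng$unif(2L * batch)
        cxs <- floor(cand[seq_len(batch)] * (roi_width - tile_side + 1))
        cys <- floor(cand[batch + seq_len(batch)] *
                         (roi_height - tile_side + 1))
        for (i in seq_len(batch)) {
            clash <- any(abs(cxs[i] - xs) < tile_side &
                             abs(cys[i] - ys) < tile_side)
            if (clash) {
                consecutive <- consecutive + 1L
                if (consecutive >= 10000L) break
            } else {
                xs <- c(xs, cxs[i]); ys <- c(ys, cys[i])
                consecutive <- 0L
                if (length(xs) >= max_tiles) break
            }
        }
    }
    grid <- list(origins = data.frame(tile_id = seq_along(xs),
                                      x = xs, y = ys),
                 tile_side = tile_side, tile_area_mm2 = tile_area_mm2,
                 roi_width = roi_width, roi_height = roi_height,
                 seed = seed)
    class(grid) <- "TileGrid"
    grid
}

#' @export
print.TileGrid <- function(x, ...) {
    cat("TileGrid:", nrow(x$origins), "tiles of", x$tile_side, "px (",
        x$tile_area_mm2, "mm^2 ) in", x$roi_width, "x", x$roi_height,
        "ROI\n")
    invisible(x)
}

## deterministic substream RNG that does not disturb the global RNG state
local_rng <- function(seed) {
    env <- new.env()
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    with_state <- function(fun) {
        function(...) {
            old <- if (exists(".Random.seed", globalenv()))
                get(".Random.seed", globalenv()) else NULL
            assign(".Random.seed", env$state, globalenv())
            out <- fun(...)
            env$state <- get(".Random.seed", globalenv())
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, globalenv())
            out
        }
    }
    list(unif = with_state(stats::runif),
         pois = with_state(stats::rpois),
         binom = with_state(stats::rbinom),
         gamma = with_state(stats::rgamma),
         multinom = with_state(stats::rmultinom),
         sample = with_state(base::sample),
         norm = with_state(stats::rnorm))
}

#' Score one case from labelled neuron detections
#'
#' Computes the three per-case metrics: the density of normally stained
#' neurons per mm^2 of analysed tissue, the mislocalisation percentage (the
#' percentage of tiles containing at least one abnormal neuron — a
#' presence-based metric, insensitive to duplicated detections within a
#' tile), and the abnormal fraction of all counted neurons.
#'
#' @param detections a `data.frame` with columns `tile_id` and `label`
#'   (`"normal"` / `"abnormal"`); may be empty.
#' @param grid a `TileGrid` from [sampleTiles()]; every detection's
#'   `tile_id` must exist in it.
#' @param case_id optional identifier copied into the output.
#' @return a one-row `data.frame`: `case_id`, `n_tiles`,
#'   `analysed_area_mm2`, `normal_per_mm2`, `misloc_pct`,
#'   `abnormal_fraction`.
#' @export
scoreCase <- function(detections, grid, case_id = NA_character_) {
    n_tiles <- nrow(grid$origins)
    if (n_tiles == 0) stop("grid has zero tiles")
    if (nrow(detections) &&
        !all(detections$tile_id %in% grid$origins$tile_id))
        stop("detection tile_id absent from grid")
    area <- n_tiles * grid$tile_area_mm2
    n_normal <- sum(detections$label == "normal")
    n_abnormal <- sum(detections$label == "abnormal")
    tiles_abn <- length(unique(
        detections$tile_id[detections$label == "abnormal"]))
    data.frame(case_id = case_id, n_tiles = n_tiles,
               analysed_area_mm2 = area,
               normal_per_mm2 = n_normal / area,
               misloc_pct = 100 * tiles_abn / n_tiles,
               abnormal_fraction =
                   if (n_normal + n_abnormal == 0) NA_real_
                   else n_abnormal / (n_normal + n_abnormal),
               stringsAsFactors = FALSE)
}

#' Age-ordered cumulative mislocalisation curve
#'
#' Cases are sorted by age at death (ties broken by `case_id`, stably); the
#' running total of `misloc_pct` is divided by the group total, giving a
#' non-decreasing curve from 0 to 1 with ascending age. The median crossing
#' age is the smallest age at which the curve reaches 0.5; between two
#' groups, the onset gap is `crossing(reference) - crossing(other)`, so an
#' earlier-onset disease group yields a positive gap.
#'
#' @param scores a `data.frame` with columns `case_id`, `misloc_pct`,
#'   `age_death` (one group).
#' @return a list: `curve` (data.frame `case_id`, `age_death`,
#'   `cumulative`), `median_crossing_age`. Errors if the group total is 0.
#' @export
cumulativeMislocCurve <- function(scores) {
    if (nrow(scores) < 2) stop("need >= 2 cases with ages")
    total <- sum(scores$misloc_pct)
    if (total <= 0) stop("group total mislocalisation is zero; ",
                         "curve undefined")
    o <- order(scores$age_death, scores$case_id)
    s <- scores[o, ]
    cum <- cumsum(s$misloc_pct) / total
    curve <- data.frame(case_id = s$case_id, age_death = s$age_death,
                        cumulative = cum, stringsAsFactors = FALSE)
    list(curve = curve,
         median_crossing_age = s$age_death[which(cum >= 0.5)[1]])
}

#' Onset gap between two groups' cumulative curves
#'
#' @param scores_ref,scores_other per-group score tables (see
#'   [cumulativeMislocCurve()]); the gap is the reference group's median
#'   crossing age minus the other group's.
#' @return a list: `crossing_ref`, `crossing_other`, `gap_years`.
#' @export
mislocOnsetGap <- function(scores_ref, scores_other) {
    a <- cumulativeMislocCurve(scores_ref)$median_crossing_age
    b <- cumulativeMislocCurve(scores_other)$median_crossing_age
    list(crossing_ref = a, crossing_other = b, gap_years = a - b)
}

#' Rank correlation of mislocalisation with age at death
#'
#' Two-sided Spearman correlation; requires at least 5 cases and a
#' non-constant score vector.
#'
#' @param scores a `data.frame` with columns `misloc_pct` and `age_death`.
#' @return a list: `rho`, `p_value`, `n`.
#' @export
correlateAge <- function(scores) {
    ok <- stats::complete.cases(scores[, c("misloc_pct", "age_death")])
    s <- scores[ok, ]
    if (nrow(s) < 5) stop("need >= 5 cases")
    if (length(unique(s$misloc_pct)) == 1)
        stop("scores are constant; correlation undefined")
    ct <- suppressWarnings(stats::cor.test(s$misloc_pct, s$age_death,
                                           method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(s))
}

#' Read a cohort demographics table
#'
#' A TSV with columns `case_id`, `clinical_dx`, `group` (pathological
#' diagnosis), `age_onset`, `age_death`, `duration`, `sex`, `brain_weight_g`,
#' `mutation`, `pm_delay_h`; empty cells are missing values. A transcription
#' of the study cohort ships with the package:
#' `system.file("extdata", "cohort_table1.tsv", package = "cryptex")`.
#'
#' @param path TSV path.
#' @return a `data.frame` of cohort records.
#' @export
readCohortTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
    need <- c("case_id", "group", "age_death", "sex")
    if (!all(need %in% colnames(d)))
        stop("cohort table needs columns ", paste(need, collapse = ", "))
    bad <- !is.na(d$age_onset) & !is.na(d$age_death) &
        d$age_death < d$age_onset
    if (any(bad))
        stop("age at death before age at onset for case(s): ",
             paste(d$case_id[bad], collapse = ", "))
    d
}

#' Per-group cohort summary
#'
#' Arithmetic means over non-missing values of age at onset, age at death,
#' disease duration, brain weight and post-mortem delay, plus sex counts.
#' Ages, duration and delay are rounded to 1 decimal and brain weight to
#' whole grams, matching the usual cohort-table presentation.
#'
#' @param records cohort `data.frame` from [readCohortTable()].
#' @param group a pathological-diagnosis group label present in `records`.
#' @return a list: `group`, `n`, `mean_age_onset`, `mean_age_death`,
#'   `mean_duration`, `mean_brain_weight_g`, `mean_pm_delay_h`, `sex`
#'   (string `"M:F"`).
#' @export
cohortSummary <- function(records, group) {
    r <- records[records$group == group, ]
    if (!nrow(r)) stop("group '", group, "' not present")
    # half-up rounding, the convention of printed cohort tables
    # (base round() is half-even: 62.25 -> 62.2, tables print 62.3)
    rnd <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5 + 1e-9) / 10^d
    m1 <- function(v) if (all(is.na(v))) NA_real_
                      else rnd(mean(v, na.rm = TRUE), 1)
    m0 <- function(v) if (all(is.na(v))) NA_real_
                      else rnd(mean(v, na.rm = TRUE), 0)
    list(group = group, n = nrow(r),
         mean_age_onset = m1(r$age_onset),
         mean_age_death = m1(r$age_death),
         mean_duration = m1(r$duration),
         mean_brain_weight_g = m0(r$brain_weight_g),
         mean_pm_delay_h = m1(r$pm_delay_h),
         sex = paste0(sum(r$sex == "M", na.rm = TRUE), "(M):",
                      sum(r$sex == "F", na.rm = TRUE), "(F)"))
}
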