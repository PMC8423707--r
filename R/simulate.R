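## Seeded generators for every input the pipeline consumes: junction count
## matrices over cassette-topology clusters with planted cryptic/skiptic
## events, a toy genome + GTF in which planted cryptic exons are
## unannotated, motif-planted sequence sets, and per-neuron detection tables
## with an age-dependent mislocalisation process. One global seed fans out
## to per-generator substreams by fixed offsets, so generators are pure
## functions of (seed, config) and stages stay independent.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generators with the defaults used
#' throughout the test-bench: 200 cassette clusters (20 planted cryptic, 20
#' planted skiptic), 3 vs 3 samples at 500 reads per cluster per sample,
#' Dirichlet concentration 500 (a low-overdispersion cell-line knockdown,
#' where read depth rather than biological variability limits PSI accuracy;
#' pass smaller values to emulate noisier designs); planted cryptic events
#' have control PSI in
#' `[0, 0.08]` and a PSI gain in `[0.15, 0.35]` (mirrored for skiptic); the
#' motif generator plants `CCC[AT]` at 86% vs 48% prevalence in 100-sequence
#' sets of 200 bp; the pathology generator draws 35 control and 28 disease
#' cases whose per-tile abnormal-neuron rate grows exponentially with age,
#' with the disease process advanced by 18 years.
#'
#' @param seed integer master seed.
#' @param n_clusters,n_cryptic,n_skiptic cluster counts.
#' @param samples_per_group samples per condition.
#' @param depth reads per cluster per sample.
#' @param concentration Dirichlet-multinomial concentration of the count
#'   draws (larger = closer to multinomial).
#' @param psi_control_cryptic,dpsi_cryptic ranges (length-2) for planted
#'   cryptic events; skiptic events mirror them
#'   (`psi_control = 1 - psi`, `dpsi` negated).
#' @param psi_null_range control-and-case PSI range of unplanted clusters.
#' @param intron_range,exon_range junction geometry in bases.
#' @param motif,motif_prevalence_a,motif_prevalence_b,n_motif_seqs,motif_seq_length
#'   motif generator settings (bracket patterns allowed).
#' @param n_cases_control,n_cases_disease,age_range_control pathology cohort
#'   sizes and the control age-at-death range (disease ages are the control
#'   range minus `onset_shift_years`).
#' @param onset_shift_years years by which the disease mislocalisation
#'   process is advanced.
#' @param misloc_rate_scale,misloc_rate_tau,misloc_age_ref exponential
#'   age model of the per-tile abnormal-neuron rate:
#'   `rate = scale * exp((age - ref) / tau)`.
#' @param misloc_frailty_sd SD of a per-case log-normal frailty multiplying
#'   the rate (0 = none).
#' @param normal_density_mm2 density of normally stained neurons.
#' @param tiles_per_case tiles sampled per case.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             n_clusters = 200, n_cryptic = 20,
                             n_skiptic = 20, samples_per_group = 3,
                             depth = 500, concentration = 500,
                             psi_control_cryptic = c(0, 0.08),
                             dpsi_cryptic = c(0.15, 0.35),
                             psi_null_range = c(0.2, 0.8),
                             intron_range = c(300, 800),
                             exon_range = c(60, 240),
                             motif = "CCC[AT]",
                             motif_prevalence_a = 0.86,
                             motif_prevalence_b = 0.48,
                             n_motif_seqs = 100,
                             motif_seq_length = 200,
                             n_cases_control = 35, n_cases_disease = 28,
                             age_range_control = c(45, 96),
                             onset_shift_years = 18,
                             misloc_rate_scale = 1.0,
                             misloc_rate_tau = 10,
                             misloc_age_ref = 96,
                             misloc_frailty_sd = 0,
                             normal_density_mm2 = 25,
                             tiles_per_case = 129) {
    if (n_cryptic + n_skiptic > n_clusters)
        stop("planted event counts exceed n_clusters")
    cfg <- as.list(environment())
    class(cfg) <- "SimulationConfig"
    cfg
}

## substream offsets (see module comment)
SEED_LAYOUT <- 101L; SEED_COUNTS <- 202L; SEED_GENOME <- 303L
SEED_MOTIF <- 404L; SEED_DETECT <- 505L

## cluster geometry and planted classes; pure function of (seed, config)
simulate_layout <- function(config) {
    rng <- local_rng(config$seed + SEED_LAYOUT)
    n <- config$n_clusters
    classes <- c(rep("cryptic", config$n_cryptic),
                 rep("skiptic", config$n_skiptic),
                 rep("null", n - config$n_cryptic - config$n_skiptic))
    classes <- classes[rng$sample(n)]
    runif_in <- function(k, r) r[1] + rng$unif(k) * (r[2] - r[1])
    intron1 <- round(runif_in(n, config$intron_range))
    intron2 <- round(runif_in(n, config$intron_range))
    exon_len <- round(runif_in(n, config$exon_range))
    flank_exon <- 150L                      # flanking exon width in the GTF
    pitch <- max(2L * max(config$intron_range) +
                     max(config$exon_range) + 2L * flank_exon + 1000L, 4000L)
    gene_start <- 500L + (seq_len(n) - 1L) * pitch

    up_exon_end <- gene_start + flank_exon - 1L
    j1_start <- up_exon_end + 1L
    j1_end <- j1_start + intron1 - 1L
    exon_start <- j1_end + 1L
    exon_end <- exon_start + exon_len - 1L
    j2_start <- exon_end + 1L
    j2_end <- j2_start + intron2 - 1L
    down_exon_end <- j2_end + flank_exon

    psi_ctrl <- psi_case <- numeric(n)
    for (i in seq_len(n)) {
        if (classes[i] == "cryptic") {
            psi_ctrl[i] <- runif_in(1, config$psi_control_cryptic)
            psi_case[i] <- psi_ctrl[i] + runif_in(1, config$dpsi_cryptic)
        } else if (classes[i] == "skiptic") {
            psi_ctrl[i] <- 1 - runif_in(1, config$psi_control_cryptic)
            psi_case[i] <- psi_ctrl[i] - runif_in(1, config$dpsi_cryptic)
        } else {
            psi_ctrl[i] <- psi_case[i] <- runif_in(1, config$psi_null_range)
        }
    }
    if (any(psi_case < 0 | psi_case > 1))
        stop("infeasible PSI ranges in configuration")
    data.frame(cluster = seq_len(n), class = classes, chrom = "chrS",
               strand = "+", gene_start = gene_start,
               up_exon_end = up_exon_end,
               j1_start = j1_start, j1_end = j1_end,
               exon_start = exon_start, exon_end = exon_end,
               j2_start = j2_start, j2_end = j2_end,
               down_exon_end = down_exon_end,
               psi_control = psi_ctrl, psi_case = psi_case,
               stringsAsFactors = FALSE)
}

psi_to_props <- function(psi) c(psi, psi, 1 - psi) / (1 + psi)

#' Simulate a junction count dataset with planted events
#'
#' Lays out `n_clusters` cassette triples (two inclusion junctions and one
#' skipping junction per cluster) on a toy chromosome and draws per-sample
#' junction counts from a Dirichlet-multinomial whose group-specific usage
#' realises the planted PSI values: cryptic clusters have low control PSI
#' and a positive PSI shift in the case group, skiptic clusters the mirror
#' image, and null clusters identical usage in both groups. A PSI of `psi`
#' maps to junction usage `(psi, psi, 1-psi) / (1+psi)` over (inclusion 1,
#' inclusion 2, skipping).
#'
#' @param config a [simulationConfig()].
#' @return a list: `experiment` (a [JunctionExperiment-class], groups
#'   `control` / `knockdown`) and `truth` (a `data.frame` with the planted
#'   class, coordinates and PSI per cluster).
#' @export
simulateJunctionDataset <- function(config) {
    layout <- simulate_layout(config)
    rng <- local_rng(config$seed + SEED_COUNTS)
    n <- nrow(layout)
    spg <- config$samples_per_group
    groups <- rep(c("control", "knockdown"), each = spg)
    cts <- matrix(0L, nrow = 3L * n, ncol = 2L * spg)
    colnames(cts) <- paste0(groups, rep(seq_len(spg), 2))
    for (i in seq_len(n)) {
        for (s in seq_len(2L * spg)) {
            psi <- if (groups[s] == "control") layout$psi_control[i]
                   else layout$psi_case[i]
            alpha <- config$concentration * psi_to_props(psi)
            g <- rng$gamma(3, shape = alpha, rate = 1)
            if (sum(g) == 0) g <- alpha
            cts[(i - 1L) * 3L + 1:3, s] <-
                rng$multinom(1, config$depth, g / sum(g))[, 1]
        }
    }
    gr <- GenomicRanges::GRanges(
        rep(layout$chrom, each = 3),
        IRanges::IRanges(
            as.vector(rbind(layout$j1_start, layout$j2_start,
                            layout$j1_start)),
            as.vector(rbind(layout$j1_end, layout$j2_end, layout$j2_end))),
        strand = rep(layout$strand, each = 3))
    truth <- layout
    truth$row_inc1 <- (seq_len(n) - 1L) * 3L + 1L
    truth$row_inc2 <- (seq_len(n) - 1L) * 3L + 2L
    truth$row_skip <- (seq_len(n) - 1L) * 3L + 3L
    list(experiment = JunctionExperiment(cts, gr, group = groups),
         truth = truth)
}

#' Simulate the matching toy genome and transcript annotation
#'
#' Writes a random-sequence genome FASTA and a GENCODE-dialect GTF for the
#' same cluster layout as [simulateJunctionDataset()] (same seed and
#' config). Every cluster's gene gets a two-exon skipping transcript; null
#' and skiptic clusters additionally get the three-exon inclusion
#' transcript, so their inclusion junctions are annotated, whereas planted
#' cryptic exons are absent from the annotation and come out
#' `inclusion_novel`.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return a list: `fasta`, `gtf` (paths), `truth` (the layout table).
#' @export
simulateAnnotation <- function(config, dir = tempfile("synth_annot")) {
    layout <- simulate_layout(config)
    if (any(layout$down_exon_end[-nrow(layout)] >= layout$gene_start[-1]))
        stop("coordinate collision between clusters")
    rng <- local_rng(config$seed + SEED_GENOME)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    glen <- max(layout$down_exon_end) + 500L
    bases <- c("A", "C", "G", "T")[ceiling(rng$unif(glen) * 4)]
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- layout$chrom[1]
    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fasta)

    lines <- character(0)
    gtf_exon <- function(start, end, gene, tx) {
        sprintf(paste0("%s\tsynth\texon\t%d\t%d\t.\t+\t.\t",
                       "gene_id \"%s\"; transcript_id \"%s\";"),
                layout$chrom[1], start, end, gene, tx)
    }
    for (i in seq_len(nrow(layout))) {
        g <- sprintf("GENE%04d", i)
        up_s <- layout$gene_start[i]; up_e <- layout$up_exon_end[i]
        dn_s <- layout$j2_end[i] + 1L; dn_e <- layout$down_exon_end[i]
        lines <- c(lines,
                   gtf_exon(up_s, up_e, g, paste0(g, ".skip")),
                   gtf_exon(dn_s, dn_e, g, paste0(g, ".skip")))
        if (layout$class[i] != "cryptic") {
            tx <- paste0(g, ".inc")
            lines <- c(lines,
                       gtf_exon(up_s, up_e, g, tx),
                       gtf_exon(layout$exon_start[i], layout$exon_end[i],
                                g, tx),
                       gtf_exon(dn_s, dn_e, g, tx))
        }
    }
    gtf <- file.path(dir, "annotation.gtf")
    writeLines(lines, gtf)
    list(fasta = fasta, gtf = gtf, truth = layout)
}

#' Simulate two sequence sets with a planted motif
#'
#' Generates i.i.d.-background DNA sequences scrubbed of the motif, then
#' plants one motif occurrence (a random concrete alternative for bracket
#' patterns) at a random position in each sequence independently with its
#' set's prevalence, so the expected presence fraction equals the
#' prevalence.
#'
#' @param config a [simulationConfig()].
#' @return a list: `set_a`, `set_b` (character vectors), `motif`,
#'   `prevalence_a`, `prevalence_b`.
#' @export
simulateMotifSequences <- function(config) {
    rng <- local_rng(config$seed + SEED_MOTIF)
    alts <- expand_bracket_pattern(config$motif)
    if (nchar(alts[1]) >= config$motif_seq_length)
        stop("motif must be shorter than the sequence length")
    rand_seq <- function(len)
        paste(c("A", "C", "G", "T")[ceiling(rng$unif(len) * 4)],
              collapse = "")
    scrub <- function(s) {
        for (iter in 1:100) {
            hit <- FALSE
            for (a in alts) {
                p <- regexpr(a, s, fixed = TRUE)
                if (p > 0) {
                    hit <- TRUE
                    substr(s, p, p + nchar(a) - 1L) <- rand_seq(nchar(a))
                }
            }
            if (!hit) return(s)
        }
        gsub(paste(alts, collapse = "|"), "", s)
    }
    gen_set <- function(n, prevalence) {
        vapply(seq_len(n), function(i) {
            s <- scrub(rand_seq(config$motif_seq_length))
            if (rng$unif(1) < prevalence) {
                a <- alts[ceiling(rng$unif(1) * length(alts))]
                pos <- ceiling(rng$unif(1) * (nchar(s) - nchar(a) + 1L))
                substr(s, pos, pos + nchar(a) - 1L) <- a
            }
            s
        }, "")
    }
    list(set_a = gen_set(config$n_motif_seqs, config$motif_prevalence_a),
         set_b = gen_set(config$n_motif_seqs, config$motif_prevalence_b),
         motif = config$motif,
         prevalence_a = config$motif_prevalence_a,
         prevalence_b = config$motif_prevalence_b)
}

#' Simulate neuron detection tables with an age-dependent process
#'
#' Draws a cohort of control and disease cases with ages at death, samples a
#' tile grid per case, and generates per-tile neuron detections: normal
#' neurons at a constant density and abnormal (mislocalised) neurons from a
#' Poisson whose rate grows exponentially with age. The disease group's
#' process age is `age + onset_shift_years`, i.e. the whole process —
#' mislocalisation rate and age distribution — is the control process
#' advanced by the configured shift, which makes the shift the estimand of
#' the cumulative-curve onset gap.
#'
#' @param config a [simulationConfig()].
#' @return a list: `cohort` (data.frame `case_id`, `group`, `age_death`),
#'   `detections` (named list of per-case data.frames with `tile_id`, `x`,
#'   `y`, `label`), `grids` (named list of `TileGrid`s), `truth` (the
#'   configured rate model and shift).
#' @export
simulateDetections <- function(config) {
    if (config$n_cases_control + config$n_cases_disease < 4)
        stop("need at least 4 cases")
    rng <- local_rng(config$seed + SEED_DETECT)
    ar <- config$age_range_control
    shift <- config$onset_shift_years
    n_ctrl <- config$n_cases_control; n_dis <- config$n_cases_disease
    ages <- c(ar[1] + rng$unif(n_ctrl) * (ar[2] - ar[1]),
              ar[1] - shift + rng$unif(n_dis) * (ar[2] - ar[1]))
    cohort <- data.frame(
        case_id = sprintf("case%03d", seq_len(n_ctrl + n_dis)),
        group = rep(c("control", "disease"), c(n_ctrl, n_dis)),
        age_death = round(ages, 1), stringsAsFactors = FALSE)
    rate <- function(process_age)
        config$misloc_rate_scale *
            exp((process_age - config$misloc_age_ref) /
                    config$misloc_rate_tau)
    detections <- list(); grids <- list()
    for (i in seq_len(nrow(cohort))) {
        grid <- sampleTiles(25000, 15000, max_tiles = config$tiles_per_case,
                            seed = config$seed + SEED_DETECT + i)
        nt <- nrow(grid$origins)
        process_age <- cohort$age_death[i] +
            if (cohort$group[i] == "disease") shift else 0
        lambda <- rate(process_age)
        if (config$misloc_frailty_sd > 0)
            lambda <- lambda * exp(rng$norm(1, 0,
                                            config$misloc_frailty_sd))
        n_abn <- rng$pois(nt, lambda)
        n_norm <- rng$pois(nt, config$normal_density_mm2 *
                               grid$tile_area_mm2)
        tile_id <- rep(grid$origins$tile_id, n_norm + n_abn)
        label <- unlist(lapply(seq_len(nt), function(t)
            rep(c("normal", "abnormal"), c(n_norm[t], n_abn[t]))))
        k <- length(tile_id)
        det <- data.frame(tile_id = tile_id,
                          x = floor(rng$unif(k) * grid$tile_side),
                          y = floor(rng$unif(k) * grid$tile_side),
                          label = if (k) label else character(0),
                          stringsAsFactors = FALSE)
        detections[[cohort$case_id[i]]] <- det
        grids[[cohort$case_id[i]]] <- grid
    }
    list(cohort = cohort, detections = detections, grids = grids,
         truth = list(onset_shift_years = shift,
                      misloc_rate_scale = config$misloc_rate_scale,
                      misloc_rate_tau = config$misloc_rate_tau,
                      misloc_age_ref = config$misloc_age_ref))
}
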