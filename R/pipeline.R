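#' Experiment configuration
#'
#' Bundles everything needed for an end-to-end simulated experiment:
#' marker map, simulator model mixture, mismatch-repair genotype and
#' short-patch parameters, purine selection toggle, number of meioses, seed,
#' distance bin edges for the co-repair table, and the tract-extension
#' probability for length estimation.
#'
#' @param map A \linkS4class{MarkerMap}, or a path to a marker TSV.
#' @param weights model mixture weights (see \code{\link{modelConfig}}).
#' @param genotype mismatch-repair genotype (see \code{\link{applyGenotype}}).
#' @param selection apply purine selection (keep survivors only)?
#' @param n number of meioses to simulate.
#' @param seed integer seed; mandatory for simulation runs.
#' @param binEdges distance bin edges (bp) for the co-repair table.
#' @param pExtend per-base tract-extension probability for length estimates.
#' @param shortPatch A \code{\link{shortPatchParams}}.
#' @param outDir optional output directory for TSV reports.
#' @param ... further arguments passed to \code{\link{modelConfig}}
#'   (\code{pResect}, \code{pSynth}, \code{resolutionBias},
#'   \code{engagementCOProb}, \code{recipient}, \code{dsbRegion}).
#' @return list of class \code{"ExperimentConfig"}.
#' @examples
#' experimentConfig(n = 10, seed = 1)
#' @export
experimentConfig <- function(map = rosyMarkerMap(),
                             weights = c(two_end_engagement = 1),
                             genotype = "Xpc_Msh6", selection = TRUE,
                             n = 100L, seed = NULL, binEdges = 21,
                             pExtend = 0.99717,
                             shortPatch = shortPatchParams(),
                             outDir = NULL, ...) {
    if (is.character(map))
        map <- readMarkerTable(map)
    if (is.null(seed))
        stop("a seed is mandatory for simulation runs")
    structure(list(map = map,
                   model = modelConfig(weights = weights, seed = seed, ...),
                   genotype = genotype, selection = selection,
                   n = as.integer(n), seed = as.integer(seed),
                   binEdges = binEdges, pExtend = pExtend,
                   shortPatch = shortPatch, outDir = outDir),
              class = "ExperimentConfig")
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys mirror the \code{\link{experimentConfig}} arguments
#' (\code{marker_map}, \code{weights}, \code{genotype}, \code{selection},
#' \code{n_meioses}, \code{seed}, \code{bin_edges}, \code{p_extend},
#' \code{short_patch} with \code{repair_prob}/\code{strand_bias},
#' \code{out_dir}, and the model fields \code{resolution_bias},
#' \code{engagement_co_prob}, \code{p_resect}, \code{p_synth},
#' \code{recipient}).
#'
#' @param path YAML file path.
#' @return list of class \code{"ExperimentConfig"}.
#' @export
readExperimentConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sp <- shortPatchParams(
        repairProb = y$short_patch$repair_prob %||% 0.82,
        strandBias = y$short_patch$strand_bias %||% 0.5)
    args <- list(
        map = y$marker_map %||% rosyMarkerMap(),
        weights = unlist(y$weights %||% list(two_end_engagement = 1)),
        genotype = y$genotype %||% "Xpc_Msh6",
        selection = y$selection %||% TRUE,
        n = y$n_meioses %||% 100L,
        seed = y$seed,
        binEdges = y$bin_edges %||% 21,
        pExtend = y$p_extend %||% 0.99717,
        shortPatch = sp,
        outDir = y$out_dir)
    for (key in c("resolution_bias", "engagement_co_prob", "p_resect",
                  "p_synth", "recipient")) {
        if (!is.null(y[[key]])) {
            arg <- c(resolution_bias = "resolutionBias",
                     engagement_co_prob = "engagementCOProb",
                     p_resect = "pResect", p_synth = "pSynth",
                     recipient = "recipient")[[key]]
            args[[arg]] <- y[[key]]
        }
    }
    do.call(experimentConfig, args)
}

.writeTsv <- function(tab, dir, name) {
    if (is.null(dir))
        return(invisible(NULL))
    utils::write.table(tab, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Run a simulated recombination experiment end to end
#'
#' Pipeline: simulate recombinant duplexes under the configured model
#' mixture; apply the mismatch-repair genotype; apply purine selection
#' (optionally); observe each survivor at the marker level; reconstruct and
#' classify tracts; tabulate co-repair pairs by distance; estimate tract
#' lengths.  When \code{config$outDir} is set, writes \code{products.tsv}
#' (per-strand segments), \code{observations.tsv}, \code{tracts.tsv},
#' \code{pairs.tsv}, \code{summary.tsv} and \code{run_log.txt} (config echo
#' and seed).  Byte-identical outputs under a fixed seed.
#'
#' @param config An \code{\link{experimentConfig}}.
#' @return (invisibly) list with \code{products}, \code{observations},
#'   \code{analyses}, \code{tracts} (data.frame), \code{pairs},
#'   \code{pairBins}, \code{estimates}, \code{summary}.
#' @examples
#' res <- runExperiment(experimentConfig(n = 20, seed = 11,
#'                                       weights = c(sdsa = 1)))
#' res$summary$transNCOFraction
#' @export
runExperiment <- function(config) {
    if (!inherits(config, "ExperimentConfig"))
        stop("config must come from experimentConfig()")
    map <- config$map
    products <- simulateMeiosis(map, config$model, config$n)
    repaired <- lapply(products, applyGenotype, genotype = config$genotype,
                       map = map, params = config$shortPatch)
    keep <- vapply(repaired, survivesPurine, logical(1), map = map)
    selected <- if (config$selection) repaired[keep] else repaired
    if (length(selected) == 0L)
        warning("no recombinants survive selection; report will be partial")
    observations <- lapply(selected, observeRecombinant, map = map)
    analyses <- lapply(observations, analyzeRecombinant, map = map,
                       p = config$pExtend)

    tractRows <- list()
    for (an in analyses) {
        for (ti in seq_along(an$tracts)) {
            tr <- an$tracts[[ti]]
            tractRows[[length(tractRows) + 1L]] <- data.frame(
                eventId = an$eventId, tract = ti, label = an$label,
                nMarkers = length(tr$positions),
                spanMin = tr$spanMin, spanMax = tr$spanMax,
                displayStart = tr$displayStart, displayEnd = tr$displayEnd,
                cisTrans = tr$cisTrans, patchy = tr$patchy,
                nUnrepaired = sum(tr$outcomes == "unrepaired"),
                nConverted = sum(tr$outcomes == "converted"),
                nRestored = sum(tr$outcomes == "restored"),
                stringsAsFactors = FALSE)
        }
    }
    tracts <- if (length(tractRows)) do.call(rbind, tractRows)
              else data.frame()
    emptyPairs <- data.frame(distance = numeric(0), class = character(0))
    pairs <- if (length(analyses))
        do.call(rbind, c(lapply(analyses, `[[`, "pairs"),
                         make.row.names = FALSE))
    else emptyPairs
    pairBins <- binPairsByDistance(
        if (nrow(pairs) > 0L) pairs else emptyPairs,
        edges = config$binEdges)
    estimates <- if (length(analyses))
        do.call(rbind, c(lapply(analyses, `[[`, "estimates"),
                         make.row.names = FALSE))
    else data.frame(a = numeric(0), b = numeric(0), estimate = numeric(0))

    labels <- vapply(analyses, function(a)
        if (is.na(a$label)) "unresolved" else a$label, character(1))
    multi <- if (nrow(tracts) > 0L)
        tracts[tracts$label == "NCO" & !is.na(tracts$label) &
               tracts$cisTrans != "undetermined", , drop = FALSE]
    else data.frame()
    transFrac <- if (nrow(multi) > 0L)
        mean(multi$cisTrans == "trans") else NA_real_
    nicksPer <- vapply(selected, function(d)
        length(nicks(d)$top) + length(nicks(d)$bottom), numeric(1))
    summary <- list(
        n = config$n, nSelected = length(selected),
        survivalRate = if (config$n > 0) mean(keep) else NA_real_,
        nCO = sum(labels == "CO"), nNCO = sum(labels == "NCO"),
        transNCOFraction = transFrac,
        meanNicksPerProduct = if (length(selected)) mean(nicksPer)
                              else NA_real_,
        meanTractEstimate = if (!is.null(estimates) && nrow(estimates) > 0L)
            mean(estimates$estimate) else NA_real_)

    dir <- config$outDir
    if (!is.null(dir)) {
        if (!dir.exists(dir))
            dir.create(dir, recursive = TRUE)
        segRows <- list()
        for (d in selected) {
            tr <- truthInfo(d)
            for (strand in c("top", "bottom")) {
                segs <- strandSegments(d, strand)
                segRows[[length(segRows) + 1L]] <- data.frame(
                    event_id = tr$eventId, model = tr$model,
                    label = tr$label, strand = strand,
                    start = segs$start, end = segs$end,
                    parent = segs$parent, stringsAsFactors = FALSE)
            }
        }
        .writeTsv(do.call(rbind, segRows), dir, "products.tsv")
        writeObservedTable(observations, file.path(dir, "observations.tsv"))
        .writeTsv(tracts, dir, "tracts.tsv")
        .writeTsv(pairs, dir, "pairs.tsv")
        .writeTsv(data.frame(metric = names(summary),
                             value = vapply(summary, function(x)
                                 format(x, digits = 10), character(1))),
                  dir, "summary.tsv")
        log <- c(sprintf("hdnaTracts run, seed %d", config$seed),
                 sprintf("genotype: %s; selection: %s; n: %d",
                         config$genotype, config$selection, config$n),
                 sprintf("weights: %s",
                         paste(names(config$model$weights),
                               config$model$weights, sep = "=",
                               collapse = " ")),
                 sprintf("pExtend: %g; binEdges: %s", config$pExtend,
                         paste(config$binEdges, collapse = ",")))
        writeLines(log, file.path(dir, "run_log.txt"))
    }
    invisible(list(products = products, observations = observations,
                   analyses = analyses, tracts = tracts, pairs = pairs,
                   pairBins = pairBins, estimates = estimates,
                   summary = summary))
}

#' Fisher tests on the printed contingency tables
#'
#' Recomputes the three published 2x2 comparisons: co-repair of close versus
#' distant adjacent marker pairs in canonical-MMR mutants (40/2 vs 40/71);
#' marker repair in double mutants versus canonical-MMR single mutants
#' (2/134 vs 274/60); and tract patchiness in the same comparison (1/31 vs
#' 35/4).  Each is tested with the two-sided exact test and checked against
#' the printed significance bound (P < 0.0001).
#'
#' @return \code{data.frame} with columns \code{comparison}, \code{a11},
#'   \code{a12}, \code{a21}, \code{a22}, \code{p}, \code{bound},
#'   \code{passes}.
#' @examples
#' runPaperTables()
#' @export
runPaperTables <- function() {
    tabs <- list(
        co_repair_by_distance = matrix(c(40, 40, 2, 71), nrow = 2),
        marker_repair_by_genotype = matrix(c(2, 274, 134, 60), nrow = 2),
        patchiness_by_genotype = matrix(c(1, 35, 31, 4), nrow = 2))
    rows <- lapply(names(tabs), function(nm) {
        tab <- tabs[[nm]]
        p <- fisherExactTwoSided(tab)
        data.frame(comparison = nm, a11 = tab[1, 1], a12 = tab[1, 2],
                   a21 = tab[2, 1], a22 = tab[2, 2], p = p, bound = 1e-4,
                   passes = p < 1e-4, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
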