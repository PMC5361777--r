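#' Read a pipeline configuration
#'
#' Structured-text (YAML, which includes JSON) configuration with blocks:
#' `input` (`fasta_dir`, `manifest`, optional `family_models` YAML), and
#' optional `thresholds` (`redundancy_identity` 95, `annotation_identity` 95
#' — strict: best identity must exceed it, `conservation_identity` 50),
#' `align` (`gap_open` -11, `gap_extend` -1, optional NCBI-format `matrix`
#' path), `out_dir`, `seed`, `focal_species` (default: first species in the
#' manifest).
#'
#' @param path config file path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validatePipelineConfig(cfg, base = dirname(path))
}

#' @rdname readPipelineConfig
#' @param cfg config list.
#' @param base directory against which relative paths resolve.
#' @export
validatePipelineConfig <- function(cfg, base = ".") {
    resolve <- function(p) {
        if (is.null(p) || file.exists(p)) p else file.path(base, p)
    }
    if (is.null(cfg$input$fasta_dir) || is.null(cfg$input$manifest)) {
        stop("config requires input: fasta_dir and manifest")
    }
    cfg$input$fasta_dir <- resolve(cfg$input$fasta_dir)
    cfg$input$manifest <- resolve(cfg$input$manifest)
    cfg$input$family_models <- resolve(cfg$input$family_models)
    th <- cfg$thresholds %||% list()
    th$redundancy_identity <- th$redundancy_identity %||% 95
    th$annotation_identity <- th$annotation_identity %||% 95
    th$conservation_identity <- th$conservation_identity %||% 50
    for (t in names(th)) {
        if (!(th[[t]] > 0 && th[[t]] <= 100)) stop("threshold ", t, " must be in (0, 100]")
    }
    cfg$thresholds <- th
    al <- cfg$align %||% list()
    al$gap_open <- al$gap_open %||% -11L
    al$gap_extend <- al$gap_extend %||% -1L
    cfg$align <- al
    cfg$out_dir <- cfg$out_dir %||% "tickpi_out"
    cfg
}

stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
}

#' Run the full repertoire pipeline
#'
#' Executes classify -> dedup -> repertoire (three axes) -> conservation ->
#' report. Writes, under `out_dir`: family assignments, redundancy clusters,
#' species-by-family non-redundant counts, the classic one-row-per-family repertoire
#' report, the catalytic-type rollup, conservation hits and per-query summary,
#' the per-cluster time-point presence table (each as TSV with a JSON mirror),
#' and a run log with package version, thresholds and input digests. Analysis
#' stages are seed-free; reruns on identical inputs are byte-identical.
#'
#' @param config config list (see [readPipelineConfig()]) or a config file
#'   path.
#' @param models optional named list of [FamilyModel-class] objects overriding
#'   the config/defaults.
#' @return invisibly, a list with the in-memory stage results (`pis`,
#'   `assignments`, `clusters`, `counts`, `matrices`, `report`, `rollup`,
#'   `conservation`, `outDir`).
#' @export
runAll <- function(config, models = NULL) {
    if (is.character(config)) config <- readPipelineConfig(config)
    config <- validatePipelineConfig(config)
    outDir <- config$out_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    manifest <- stage("core_io", parseLibraryManifest(config$input$manifest))
    pis <- stage("core_io", readLibraryFastaSet(config$input$fasta_dir, manifest))

    if (is.null(models)) {
        models <- if (!is.null(config$input$family_models)) {
            stage("family_classification", readFamilyModels(config$input$family_models))
        } else defaultFamilyModels()
    }
    params <- alignParams(
        substitutionMatrix = if (!is.null(config$align$matrix))
            readSubstitutionMatrix(config$align$matrix) else defaultSubstitutionMatrix(),
        gapOpen = config$align$gap_open, gapExtend = config$align$gap_extend)

    assignments <- stage("family_classification",
        assignFamilies(pis, models, params = params,
                       identityThreshold = config$thresholds$annotation_identity))
    keep <- assignments$family != "UNASSIGNED"
    assigned <- assignments[keep, , drop = FALSE]
    kept <- pis[assigned$record_id]

    clusters <- stage("redundancy_clustering", {
        out <- list()
        groups <- split(assigned$record_id,
                        list(speciesCode(kept), assigned$family), drop = TRUE)
        for (g in names(sort(vapply(groups, function(x) min(match(x, recordIds(pis))),
                                    numeric(1))))) {
            sub <- kept[groups[[g]]]
            fam <- assigned$family[match(groups[[g]][1L], assigned$record_id)]
            out <- c(out, dedup(sub, fam,
                                threshold = config$thresholds$redundancy_identity,
                                params = params))
        }
        out
    })
    counts <- nonredundantCounts(clusters)

    focal <- config$focal_species %||% manifest$species_code[1L]
    focalClusters <- Filter(function(cl) cl@speciesCode == focal, clusters)
    matrices <- stage("repertoire_analysis", {
        lapply(stats::setNames(nm = c("sex", "feeding", "tissue")), function(ax)
            buildRepertoireMatrix(focalClusters, kept,
                                  conditionAxis(ax, manifest, species = focal)))
    })
    tps <- stage("repertoire_analysis", timepointPresence(focalClusters, kept, manifest))
    report <- stage("repertoire_analysis", reportRepertoire(matrices))

    focalCounts <- counts[counts$species == focal, piFamilies(), drop = FALSE]
    rollup <- stage("family_classification",
        catalyticRollup(stats::setNames(as.integer(focalCounts[1L, ]), piFamilies())))

    conservation <- stage("conservation_screen", {
        reps <- vapply(focalClusters, function(cl) cl@representativeId, "")
        fams <- vapply(focalClusters, function(cl) cl@familyId, "")
        qseqs <- stats::setNames(as.character(sequences(kept[reps])), reps)
        others <- kept[speciesCode(kept) != focal]
        sfams <- assigned$family[match(recordIds(others), assigned$record_id)]
        hits <- screenConservation(qseqs, fams, others, sfams,
            minIdentity = config$thresholds$conservation_identity, params = params)
        list(hits = hits, summary = conservationSummary(hits, reps))
    })

    stage("report", {
        writeTableMirror(assignments, file.path(outDir, "assignments"))
        writeTableMirror(clusterTable(clusters), file.path(outDir, "clusters"))
        writeTableMirror(counts, file.path(outDir, "counts"))
        writeTableMirror(report, file.path(outDir, "repertoire_report"))
        writeTableMirror(rollup, file.path(outDir, "rollup"))
        writeTableMirror(conservation$hits, file.path(outDir, "conservation_hits"))
        writeTableMirror(conservation$summary, file.path(outDir, "conservation_summary"))
        writeTableMirror(tps, file.path(outDir, "timepoint_presence"))
        inputs <- c(config$input$manifest,
                    list.files(config$input$fasta_dir, pattern = "\\.fasta$",
                               full.names = TRUE))
        log <- c(sprintf("tickPI version: %s",
                         as.character(utils::packageVersion("tickPI"))),
                 sprintf("thresholds: redundancy>=%s annotation>%s conservation>=%s",
                         config$thresholds$redundancy_identity,
                         config$thresholds$annotation_identity,
                         config$thresholds$conservation_identity),
                 sprintf("gap scores: open %d extend %d",
                         config$align$gap_open, config$align$gap_extend),
                 sprintf("records: %d, assigned: %d, clusters: %d",
                         length(pis), nrow(assigned), length(clusters)),
                 sprintf("input %s md5 %s", basename(inputs),
                         unname(tools::md5sum(inputs))))
        writeLines(log, file.path(outDir, "run_log.txt"))
    })

    invisible(list(pis = pis, assignments = assignments, clusters = clusters,
                   counts = counts, matrices = matrices, report = report,
                   rollup = rollup, conservation = conservation,
                   outDir = outDir))
}

#' Render the classic repertoire report
#'
#' One row per family, ordered numerically, with the ten classic columns (`F`,
#' `M`, `F_M`, `FD`, `UF`, `FD_UF`, `SG`, `MG`, `SG_MG`, `total`) plus
#' `detected` (clusters present on at least one side of any axis) and
#' `neither_tissue` (clusters never seen in a dissected-tissue library), and a
#' totals row.
#'
#' @param matrices named list of [RepertoireMatrix-class] objects for the
#'   `sex`, `feeding` and `tissue` axes sharing one family universe.
#' @return data.frame report.
#' @export
reportRepertoire <- function(matrices) {
    need <- c("sex", "feeding", "tissue")
    if (!all(need %in% names(matrices))) {
        stop("need matrices for axes: ", paste(need, collapse = ", "))
    }
    fams <- rownames(matrices$sex@counts)
    for (ax in need) {
        if (!identical(rownames(matrices[[ax]]@counts), fams)) {
            stop("axis ", ax, " has a different family universe")
        }
    }
    det <- function(m) rowSums(m@counts[, 1:3, drop = FALSE])
    detected <- pmax(det(matrices$sex), det(matrices$feeding),
                     det(matrices$tissue))
    out <- data.frame(
        family = fams,
        F = matrices$sex@counts[, 1], M = matrices$sex@counts[, 2],
        F_M = matrices$sex@counts[, 3],
        FD = matrices$feeding@counts[, 1], UF = matrices$feeding@counts[, 2],
        FD_UF = matrices$feeding@counts[, 3],
        SG = matrices$tissue@counts[, 1], MG = matrices$tissue@counts[, 2],
        SG_MG = matrices$tissue@counts[, 3],
        total = matrices$sex@counts[, 4],
        detected = detected,
        neither_tissue = matrices$tissue@counts[, 4] - det(matrices$tissue),
        row.names = NULL, stringsAsFactors = FALSE)
    totals <- c(family = "Total", lapply(out[-1], sum))
    rbind(out, as.data.frame(totals, stringsAsFactors = FALSE))
}
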