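#' Construct a synthetic-scenario configuration
#'
#' The defaults describe the package's reference study-like scenario: a focal
#' species with whole-body male/female x fed/unfed libraries plus dissected
#' female salivary-gland and midgut libraries at 48, 96 and 120 h (the design
#' of the underlying transcriptome comparison), two additional species, 40
#' planted clusters across six families, member-to-representative identity 98
#' (well above the 95 redundancy threshold), an inter-cluster identity ceiling
#' of 80 (well below it), and cross-species homologs planted at 40, 55, 70 and
#' 85 percent identity (outside the 47-53 guard band around the conservation
#' threshold).
#'
#' @param speciesCodes species codes; the first is the focal species.
#' @param clusterPlan data.frame `species`, `family`, `nClusters`,
#'   `clusterSize`.
#' @param intraIdentity planted member identity (percent, default 98).
#' @param interCeiling inter-cluster identity ceiling (percent, default 80).
#' @param homologPlan data.frame `family`, `species`, `targetIdentity`.
#' @param libraryPlan manifest data.frame for all libraries (default: the
#'   reference design above).
#' @param membershipProb per-library cluster presence probability (default
#'   0.5).
#' @param seqLength planted ancestor length (default 240).
#' @param fragmentProb probability a non-seed member is a truncated fragment
#'   (default 0.2).
#' @param seed mandatory integer seed.
#' @return a [ScenarioConfig-class].
#' @export
#' @examples
#' cfg <- scenarioConfig(seed = 1)
#' sum(cfg@clusterPlan$nClusters)
scenarioConfig <- function(speciesCodes = c("aam", "isc", "iri"),
                           clusterPlan = NULL, intraIdentity = 98,
                           interCeiling = 80, homologPlan = NULL,
                           libraryPlan = NULL, membershipProb = 0.5,
                           seqLength = 240L, fragmentProb = 0.2, seed) {
    focal <- speciesCodes[1L]
    others <- speciesCodes[-1L]
    if (is.null(clusterPlan)) {
        clusterPlan <- data.frame(
            species = focal,
            family = c("I1", "I2", "I8", "I25", "I39", "I43"),
            nClusters = c(3L, 6L, 4L, 5L, 4L, 6L),
            clusterSize = c(3L, 3L, 2L, 3L, 2L, 2L))
        if (length(others)) {
            clusterPlan <- rbind(clusterPlan, data.frame(
                species = rep(others, each = 3L),
                family = rep(c("I1", "I2", "I25"), length(others)),
                nClusters = 2L, clusterSize = 2L))
        }
    }
    if (is.null(homologPlan) && length(others) >= 2L) {
        homologPlan <- data.frame(
            family = c("I1", "I1", "I2", "I2", "I25", "I25", "I25", "I1"),
            species = c(others[1L], others[2L], others[1L], others[2L],
                        others[1L], others[2L], others[1L], others[1L]),
            targetIdentity = c(85, 70, 55, 85, 70, 55, 40, 40))
    } else if (is.null(homologPlan)) {
        homologPlan <- data.frame(family = character(0), species = character(0),
                                  targetIdentity = numeric(0))
    }
    if (is.null(libraryPlan)) {
        whole <- data.frame(
            library_id = paste0(focal, c("_WF_FD", "_WF_UF", "_WM_FD", "_WM_UF")),
            species_code = focal, sex = c("F", "F", "M", "M"),
            feeding_state = c("fed", "unfed", "fed", "unfed"),
            tissue = "whole", timepoint_h = NA_integer_)
        diss <- expand.grid(tissue = c("SG", "MG"), timepoint_h = c(48L, 96L, 120L),
                            stringsAsFactors = FALSE)
        diss <- data.frame(
            library_id = paste0(focal, "_", diss$tissue, "_", diss$timepoint_h, "h"),
            species_code = focal, sex = "F", feeding_state = "fed",
            tissue = diss$tissue, timepoint_h = diss$timepoint_h)
        other <- if (length(others)) data.frame(
            library_id = paste0(others, "_W"), species_code = others,
            sex = NA_character_, feeding_state = NA_character_,
            tissue = "whole", timepoint_h = NA_integer_) else NULL
        libraryPlan <- rbind(whole, diss, other)
    }
    methods::new("ScenarioConfig", speciesCodes = speciesCodes,
                 clusterPlan = clusterPlan, intraIdentity = intraIdentity,
                 interCeiling = interCeiling, homologPlan = homologPlan,
                 libraryPlan = validateManifest(libraryPlan),
                 membershipProb = membershipProb,
                 seqLength = as.integer(seqLength),
                 fragmentProb = fragmentProb, seed = as.integer(seed))
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf(paste0("ScenarioConfig: %d species, %d planted clusters, ",
                       "%d homolog targets, %d libraries, seed %d\n"),
                length(object@speciesCodes), sum(object@clusterPlan$nClusters),
                nrow(object@homologPlan), nrow(object@libraryPlan), object@seed))
})

#' Substitution-only mutation to a target identity
#'
#' Substitutes exactly `round(len * (100 - targetIdentity) / 100)` positions,
#' chosen without replacement from the unprotected positions, each replaced by
#' one of the 19 alternative residues uniformly. Gapless identity to the input
#' is therefore exact by construction. Protected positions (planted motifs)
#' are never touched.
#'
#' @param seq amino-acid string (length >= 20).
#' @param targetIdentity target percent identity in (0, 100].
#' @param protect integer positions that must not be substituted.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return mutated sequence string.
#' @export
#' @examples
#' mutateToIdentity(strrep("MKTAYIAKQR", 10), 90, seed = 1)
mutateToIdentity <- function(seq, targetIdentity, protect = integer(0),
                             seed = NULL) {
    if (!(targetIdentity > 0 && targetIdentity <= 100)) {
        stop("targetIdentity must be in (0, 100]")
    }
    len <- nchar(seq)
    if (len < 20) stop("sequence must have length >= 20")
    nmut <- round(len * (100 - targetIdentity) / 100)
    if (nmut == 0) return(seq)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
                   get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
    }
    candidates <- setdiff(seq_len(len), protect)
    if (length(candidates) < nmut) {
        stop("target identity ", targetIdentity,
             " would require substituting protected (motif) positions")
    }
    pos <- sample(candidates, nmut)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (p in pos) {
        chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1L)
    }
    paste(chars, collapse = "")
}

# random amino-acid sequence (uniform over the 20 residues)
randomProtein <- function(len) {
    paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
}

# build a family ancestor: random backbone with the family's diagnostic
# motifs embedded in the first 60% of the sequence; returns the sequence and
# the protected (motif) positions
plantFamilyAncestor <- function(len, motifs) {
    seq <- randomProtein(len)
    protect <- integer(0)
    if (length(motifs)) {
        # spread motif anchors over the first 60%, leaving room between them
        span <- floor(0.6 * len)
        starts <- floor(seq(5, span - max(nchar(motifs)) - 5,
                            length.out = length(motifs)))
        for (k in seq_along(motifs)) {
            # default motifs are (near-)literal patterns; any '.' wildcard is
            # realised with a random residue
            pat <- strsplit(motifs[k], "", fixed = TRUE)[[1L]]
            pat[pat == "."] <- sample(AA_LETTERS, sum(pat == "."), replace = TRUE)
            lit <- paste(pat, collapse = "")
            substr(seq, starts[k], starts[k] + nchar(lit) - 1L) <- lit
            protect <- c(protect, seq(starts[k], starts[k] + nchar(lit) - 1L))
        }
    }
    list(seq = seq, protect = sort(unique(protect)))
}

#' Generate a synthetic scenario with ground truth
#'
#' Plants, per species and family: a family ancestor carrying that family's
#' diagnostic motifs; cluster ancestors mutated from it on disjoint position
#' blocks so that any two clusters of one family stay at or below the
#' inter-cluster ceiling; and cluster members mutated from their ancestor at
#' the intra-cluster identity (some as truncated fragments). Cross-species
#' homologs are mutants of focal-species cluster ancestors at the planned
#' target identities. Cluster-to-library memberships are drawn per library and
#' distributed over members so that the member union equals the cluster's
#' planted set. Record ids are opaque serials. Everything is deterministic
#' given the config seed; per species-and-family sub-streams are derived from
#' it by fixed offsets.
#'
#' @param config a [ScenarioConfig-class].
#' @return list with `pis` (a [PISet-class] of all records with library
#'   memberships), `manifest` (the library data.frame) and `truth` (planted
#'   partition, family labels, cluster library sets, homolog pairs with
#'   realized identities, expected per-axis matrices and expected
#'   species-by-family counts).
#' @seealso [writeScenario()], [scenarioConfig()]
#' @export
generateScenario <- function(config) {
    methods::validObject(config)
    plan <- config@clusterPlan
    len <- config@seqLength
    # feasibility of the separation plan before any generation
    interRate <- ceiling(len * (100 - config@interCeiling) / 200 + 0.025 * len)
    motifLens <- vapply(piFamilies(), function(f)
        sum(nchar(.DEFAULT_MOTIFS[[f]])), integer(1))
    for (i in seq_len(nrow(plan))) {
        avail <- len - motifLens[[plan$family[i]]]
        if (plan$nClusters[i] * interRate > avail) {
            stop("infeasible separation constraints: ", plan$nClusters[i],
                 " clusters of family ", plan$family[i],
                 " need more unprotected positions than length ", len, " offers")
        }
    }
    manifest <- config@libraryPlan
    serial <- 0L
    nextId <- function() {
        serial <<- serial + 1L
        sprintf("R%05d", serial)
    }
    ids <- character(0); seqs <- character(0); species <- character(0)
    libs <- list()
    truthCluster <- character(0)   # planted cluster key per record
    truthFamily <- character(0)
    clusterKey <- character(0); clusterRep <- character(0)
    clusterSpecies <- character(0); clusterFamily <- character(0)
    clusterLibs <- list()
    ancestorSeq <- list(); ancestorProtect <- list()

    spFams <- unique(plan[, c("species", "family")])
    for (u in seq_len(nrow(spFams))) {
        sp <- spFams$species[u]; fam <- spFams$family[u]
        spIdx <- match(sp, config@speciesCodes)
        famIdx <- match(fam, piFamilies())
        set.seed(config@seed + 7919L * spIdx + 101L * famIdx)
        anc <- plantFamilyAncestor(len, .DEFAULT_MOTIFS[[fam]])
        rows <- plan[plan$species == sp & plan$family == fam, , drop = FALSE]
        nClu <- sum(rows$nClusters)
        sizes <- rep(rows$clusterSize, rows$nClusters)
        # disjoint substitution blocks keep inter-cluster identity <= ceiling
        freePos <- setdiff(seq_len(len), anc$protect)
        blocks <- split(freePos[seq_len(nClu * interRate)],
                        rep(seq_len(nClu), each = interRate))
        spLibs <- manifest$library_id[manifest$species_code == sp]
        for (ci in seq_len(nClu)) {
            key <- paste(sp, fam, ci, sep = "_")
            cseq <- mutateBlock(anc$seq, blocks[[ci]])
            # cluster library set: independent draws, at least one library
            present <- spLibs[stats::runif(length(spLibs)) < config@membershipProb]
            if (!length(present)) present <- sample(spLibs, 1L)
            clusterKey <- c(clusterKey, key)
            clusterSpecies <- c(clusterSpecies, sp)
            clusterFamily <- c(clusterFamily, fam)
            clusterLibs[[key]] <- sort(present)
            ancestorSeq[[key]] <- cseq
            ancestorProtect[[key]] <- anc$protect
            memberSeqs <- cseq
            for (mi in seq_len(sizes[ci] - 1L)) {
                ms <- mutateToIdentity(cseq, config@intraIdentity,
                                       protect = anc$protect)
                if (stats::runif(1) < config@fragmentProb) {
                    keep <- floor(stats::runif(1, 0.75, 0.9) * len)
                    ms <- substr(ms, 1L, keep)
                }
                memberSeqs <- c(memberSeqs, ms)
            }
            # distribute the cluster's libraries over members; union must equal
            # the planted set
            memberLibs <- lapply(memberSeqs, function(x) {
                got <- present[stats::runif(length(present)) < 0.7]
                if (!length(got)) got <- sample(present, 1L)
                got
            })
            covered <- unique(unlist(memberLibs))
            for (lb in setdiff(present, covered)) {
                j <- sample(length(memberLibs), 1L)
                memberLibs[[j]] <- c(memberLibs[[j]], lb)
            }
            mIds <- vapply(memberSeqs, function(x) nextId(), "")
            clusterRep <- c(clusterRep, mIds[1L])
            ids <- c(ids, mIds)
            seqs <- c(seqs, memberSeqs)
            species <- c(species, rep(sp, length(mIds)))
            libs <- c(libs, lapply(memberLibs, function(x) sort(unique(x))))
            truthCluster <- c(truthCluster, rep(key, length(mIds)))
            truthFamily <- c(truthFamily, rep(fam, length(mIds)))
        }
    }

    # planted cross-species homologs: mutants of focal cluster ancestors
    focal <- config@speciesCodes[1L]
    homologs <- NULL
    hp <- config@homologPlan
    if (nrow(hp) > 0) {
        for (i in seq_len(nrow(hp))) {
            fam <- hp$family[i]; sp <- hp$species[i]; tgt <- hp$targetIdentity[i]
            keys <- clusterKey[clusterSpecies == focal & clusterFamily == fam]
            if (!length(keys)) {
                stop("homolog plan names family ", fam,
                     " with no focal-species clusters")
            }
            key <- keys[((i - 1L) %% length(keys)) + 1L]
            set.seed(config@seed + 60013L + 17L * i)
            hseq <- mutateToIdentity(ancestorSeq[[key]], tgt,
                                     protect = ancestorProtect[[key]])
            hid <- nextId()
            spLib <- manifest$library_id[manifest$species_code == sp][1L]
            ids <- c(ids, hid); seqs <- c(seqs, hseq)
            species <- c(species, sp)
            libs <- c(libs, list(spLib))
            hkey <- paste(sp, fam, "hom", i, sep = "_")
            truthCluster <- c(truthCluster, hkey)
            truthFamily <- c(truthFamily, fam)
            clusterKey <- c(clusterKey, hkey)
            clusterSpecies <- c(clusterSpecies, sp)
            clusterFamily <- c(clusterFamily, fam)
            clusterRep <- c(clusterRep, hid)
            clusterLibs[[hkey]] <- spLib
            realized <- 100 * (1 - round(len * (100 - tgt) / 100) / len)
            homologs <- rbind(homologs, data.frame(
                query_id = clusterRep[match(key, clusterKey)],
                subject_id = hid, subject_species = sp, family = fam,
                target_identity = tgt, realized_identity = realized,
                stringsAsFactors = FALSE))
        }
    } else {
        homologs <- data.frame(query_id = character(0), subject_id = character(0),
                               subject_species = character(0), family = character(0),
                               target_identity = numeric(0),
                               realized_identity = numeric(0))
    }

    pis <- PISet(stats::setNames(seqs, ids), species = species, libraries = libs)
    truth <- list(
        clusters = data.frame(record_id = ids, cluster = truthCluster,
                              family = truthFamily, species = species,
                              stringsAsFactors = FALSE),
        representatives = stats::setNames(clusterRep, clusterKey),
        clusterLibraries = clusterLibs,
        clusterSpecies = stats::setNames(clusterSpecies, clusterKey),
        clusterFamily = stats::setNames(clusterFamily, clusterKey),
        homologs = homologs,
        expectedCounts = truthCounts(clusterSpecies, clusterFamily),
        expectedMatrix = truthMatrices(clusterKey, clusterSpecies,
                                       clusterFamily, clusterLibs,
                                       manifest, focal))
    list(pis = pis, manifest = manifest, truth = truth)
}

# substitute every position in block with a different residue (deterministic
# identity drop of exactly length(block)/len)
mutateBlock <- function(seq, block) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (p in block) chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1L)
    paste(chars, collapse = "")
}

# generator-side (independent) expected species x family cluster counts
truthCounts <- function(clusterSpecies, clusterFamily) {
    tab <- table(clusterSpecies, clusterFamily)
    as.data.frame.matrix(tab)
}

# generator-side (independent) expected two-way matrices for the focal
# species; intentionally simple set arithmetic, not the package's
# buildRepertoireMatrix
truthMatrices <- function(clusterKey, clusterSpecies, clusterFamily,
                          clusterLibs, manifest, focal) {
    m <- manifest[manifest$species_code == focal, ]
    sides <- list(
        sex = list(m$library_id[m$sex %in% "F"], m$library_id[m$sex %in% "M"]),
        feeding = list(m$library_id[m$feeding_state %in% "fed" & m$tissue == "whole"],
                       m$library_id[m$feeding_state %in% "unfed" & m$tissue == "whole"]),
        tissue = list(m$library_id[m$tissue == "SG"], m$library_id[m$tissue == "MG"]))
    focalKeys <- clusterKey[clusterSpecies == focal]
    fam <- stats::setNames(clusterFamily, clusterKey)
    out <- list()
    for (ax in names(sides)) {
        l <- sides[[ax]][[1]]; r <- sides[[ax]][[2]]
        rows <- t(vapply(piFamilies(), function(f) {
            ks <- focalKeys[fam[focalKeys] == f]
            inL <- vapply(ks, function(k) any(clusterLibs[[k]] %in% l), logical(1))
            inR <- vapply(ks, function(k) any(clusterLibs[[k]] %in% r), logical(1))
            c(left_exclusive = sum(inL & !inR), right_exclusive = sum(!inL & inR),
              shared = sum(inL & inR), row_total = length(ks))
        }, numeric(4)))
        rownames(rows) <- piFamilies()
        out[[ax]] <- rows
    }
    out
}

#' Write a scenario to disk
#'
#' Emits the pipeline's input contract: one FASTA per library (named
#' `<library_id>.fasta`, containing every record observed in that library), a
#' `manifest.tsv`, and a `truth.json` with the planted ground truth.
#'
#' @param scenario result of [generateScenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pis <- scenario$pis
    libs <- libraryIds(pis)
    chars <- as.character(sequences(pis))
    for (lib in scenario$manifest$library_id) {
        sel <- vapply(libs, function(x) lib %in% x, logical(1))
        writeFasta(stats::setNames(chars[sel], recordIds(pis)[sel]),
                   file.path(dir, paste0(lib, ".fasta")))
    }
    writeLibraryManifest(scenario$manifest, file.path(dir, "manifest.tsv"))
    jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Read per-library FASTA files back into a PISet
#'
#' Reads `<library_id>.fasta` for every manifest library and unions the
#' records: a record appearing in several library files gets the union of
#' those libraries as its membership set. Sequences of a shared id must agree
#' across files.
#'
#' @param dir directory holding the FASTA files.
#' @param manifest library manifest data.frame.
#' @return a [PISet-class].
#' @export
readLibraryFastaSet <- function(dir, manifest) {
    acc <- list()
    for (i in seq_len(nrow(manifest))) {
        lib <- manifest$library_id[i]
        path <- file.path(dir, paste0(lib, ".fasta"))
        if (!file.exists(path)) next
        p <- readFasta(path, species = manifest$species_code[i])
        chars <- as.character(sequences(p))
        for (k in seq_along(chars)) {
            id <- recordIds(p)[k]
            if (is.null(acc[[id]])) {
                acc[[id]] <- list(seq = chars[k],
                                  species = manifest$species_code[i],
                                  libs = lib)
            } else {
                if (!identical(acc[[id]]$seq, chars[k])) {
                    stop("record ", id, " has inconsistent sequences across libraries")
                }
                acc[[id]]$libs <- c(acc[[id]]$libs, lib)
            }
        }
    }
    if (!length(acc)) {
        stop("no FASTA records found under ", dir)
    }
    PISet(stats::setNames(vapply(acc, `[[`, "", "seq"), names(acc)),
          species = vapply(acc, `[[`, "", "species"),
          libraries = lapply(acc, function(x) sort(unique(x$libs))))
}
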