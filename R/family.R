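#' The 18 accepted inhibitor families
#'
#' Tick protein sets in this framework are classified into 18 MEROPS-style
#' inhibitor families; any sequence that cannot be placed in one of them is
#' excluded downstream.
#'
#' @return character vector of family tokens in numeric order.
#' @export
#' @examples
#' piFamilies()
piFamilies <- function() {
    c("I1", "I2", "I4", "I8", "I21", "I25", "I29", "I31", "I32", "I35",
      "I39", "I43", "I51", "I53", "I63", "I68", "I72", "I74")
}

#' Family-to-catalytic-type map
#'
#' Which protease catalytic type each inhibitor family targets: serine
#' (Kazal, Kunitz, serpin, TIL, secretogranin, PEBP, madanin, chimadanin,
#' variegin), cysteine (cystatin, CTLA, thyropin, IAP), metallo (TIMP, oprin,
#' pro-MBP, TCI) or nonspecific (alpha-2-macroglobulin).
#'
#' @return named list: catalytic type -> family tokens.
#' @export
#' @examples
#' catalyticTypeMap()$serine
catalyticTypeMap <- function() {
    list(serine  = c("I1", "I2", "I4", "I8", "I21", "I51", "I53", "I72", "I74"),
         cysteine = c("I25", "I29", "I31", "I32"),
         metallo = c("I35", "I43", "I63", "I68"),
         nonspecific = "I39")
}

#' @rdname catalyticTypeMap
#' @param familyId family token(s).
#' @return for `familyCatalyticType`: catalytic type per family.
#' @export
familyCatalyticType <- function(familyId) {
    map <- catalyticTypeMap()
    rev <- stats::setNames(rep(names(map), lengths(map)), unlist(map))
    unname(rev[familyId])
}

#' Construct a family model
#'
#' @param familyId family token (see [piFamilies()]).
#' @param familyName common name.
#' @param motifs character vector of motif regular expressions (may be empty
#'   for identity-only families).
#' @param minMotifHits minimum number of distinct motifs that must match.
#' @param referenceMembers named character vector or `AAStringSet` of
#'   annotated members (may be empty).
#' @return a [FamilyModel-class] object.
#' @export
familyModel <- function(familyId, familyName, motifs = character(0),
                        minMotifHits = max(1L, length(motifs)),
                        referenceMembers = Biostrings::AAStringSet()) {
    if (!methods::is(referenceMembers, "AAStringSet")) {
        referenceMembers <- Biostrings::AAStringSet(referenceMembers)
    }
    methods::new("FamilyModel", familyId = familyId, familyName = familyName,
                 catalyticType = familyCatalyticType(familyId),
                 motifs = as.character(motifs),
                 minMotifHits = as.integer(minMotifHits),
                 referenceMembers = referenceMembers)
}

#' @rdname tickPI-accessors
#' @export
setMethod("familyId", "FamilyModel", function(x) x@familyId)

setMethod("show", "FamilyModel", function(object) {
    cat(sprintf("FamilyModel %s (%s, %s): %d motif(s), min hits %d, %d reference(s)\n",
                object@familyId, object@familyName, object@catalyticType,
                length(object@motifs), object@minMotifHits,
                length(object@referenceMembers)))
})

# Heuristic diagnostic motifs. These are NOT curated domain models: they are
# simple consensus stand-ins (mostly literal 6-7-mers, cysteine-flavoured for
# the disulfide-stabilised families) that the synthetic generator plants and
# that real-data users are expected to override via readFamilyModels().
.DEFAULT_MOTIFS <- list(
    I1  = c("CGSDGK", "TYDNKC"),   # Kazal-like spacing
    I2  = c("GPCKAR", "FYGGCG"),   # Kunitz-like
    I4  = c("FKGKWK", "DRPFLM"),   # serpin RCL-flank-like
    I8  = c("DDCPKG", "CCQTCA"),   # TIL cysteine-rich
    I21 = c("SVNPYL", "YEKRGD"),   # secretogranin-like
    I25 = c("QVVAGW", "NYFIKV"),   # cystatin-like
    I29 = c("ERFNIN", "YGWMDE"),   # propeptide-like
    I31 = c("TCNRAL", "GQVWCD"),   # thyropin-like
    I32 = c("GFYYLG", "RCFFCM"),   # BIR-like
    I35 = c("CTCVPP", "GYQSKH"),   # TIMP-like
    I39 = c("GCGEQN", "FSDQVN"),   # thioester-region-like
    I43 = c("WGYLGS", "QNVCRT"),   # oprin-like
    I51 = c("GIHRYV", "WDAPSR"),   # PEBP-like
    I53 = c("DDSEED", "QPMAHE"),   # madanin-like (cysteine-free)
    I63 = c("YRGCQL", "HSTDWF"),   # pro-MBP-like
    I68 = c("CQLSNG", "HKGCPK"),   # TCI-like
    I72 = character(0),            # chimadanin: no conserved domain; identity-only
    I74 = c("DPGMHKT"))            # variegin-like (single motif, tiny protein)

.FAMILY_NAMES <- c(
    I1 = "Kazal", I2 = "Kunitz", I4 = "serpin", I8 = "TIL",
    I21 = "secretogranin", I25 = "cystatin", I29 = "CTLA", I31 = "thyropin",
    I32 = "IAP", I35 = "TIMP", I39 = "alpha-2-macroglobulin", I43 = "oprin",
    I51 = "PEBP", I53 = "madanin", I63 = "pro-MBP", I68 = "TCI",
    I72 = "chimadanin", I74 = "variegin")

#' Default family models
#'
#' Models for all 18 families with the package's heuristic diagnostic motifs
#' (see the package vignette for why these are stand-ins, not curated domain
#' definitions) and no reference members. Families with two motifs require
#' both to hit; I74 has a single motif; I72 has none and is identity-only.
#'
#' @param referenceMembers optional named list: family token -> `AAStringSet`
#'   (or named character vector) of annotated reference members.
#' @return named list of [FamilyModel-class] objects in family order.
#' @export
#' @examples
#' models <- defaultFamilyModels()
#' models$I2
defaultFamilyModels <- function(referenceMembers = list()) {
    out <- lapply(piFamilies(), function(f) {
        refs <- referenceMembers[[f]]
        if (is.null(refs)) refs <- Biostrings::AAStringSet()
        m <- .DEFAULT_MOTIFS[[f]]
        familyModel(f, .FAMILY_NAMES[[f]], motifs = m,
                    minMotifHits = max(1L, length(m)),
                    referenceMembers = refs)
    })
    stats::setNames(out, piFamilies())
}

#' Read family models from a YAML config
#'
#' The config maps family tokens to `name`, `motifs`, `min_motif_hits` and an
#' optional `reference_fasta` path (resolved relative to the config file).
#'
#' @param path YAML file path.
#' @return named list of [FamilyModel-class] objects.
#' @export
readFamilyModels <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(path)
    out <- lapply(names(cfg), function(f) {
        e <- cfg[[f]]
        refs <- Biostrings::AAStringSet()
        if (!is.null(e$reference_fasta)) {
            rp <- e$reference_fasta
            if (!file.exists(rp)) rp <- file.path(base, e$reference_fasta)
            refs <- sequences(readFasta(rp))
        }
        motifs <- as.character(unlist(e$motifs))
        familyModel(f, e$name %||% .FAMILY_NAMES[[f]] %||% f, motifs = motifs,
                    minMotifHits = as.integer(e$min_motif_hits %||%
                                              max(1L, length(motifs))),
                    referenceMembers = refs)
    })
    stats::setNames(out, names(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count diagnostic motif hits
#'
#' Number of distinct motifs of a family model with at least one match in the
#' sequence; overlapping matches of one motif count once.
#'
#' @param seq amino-acid string.
#' @param model a [FamilyModel-class] with at least one motif.
#' @return integer hit count (0 is a valid result).
#' @export
#' @examples
#' m <- defaultFamilyModels()$I2
#' scanMotifs(paste0("AAA", m@motifs[1], "AAA", m@motifs[2]), m)
scanMotifs <- function(seq, model) {
    if (length(model@motifs) == 0) {
        stop("family ", model@familyId, " has no motifs (identity-only family)")
    }
    sum(vapply(model@motifs, function(p) grepl(p, seq), logical(1)))
}

#' Assign a record to a family
#'
#' Two-rule procedure. (1) Motif rule: the model whose distinct-motif hit
#' count reaches its `minMotifHits`; when several qualify the one with the
#' most hits wins, and a tie leaves the record `UNASSIGNED` with an ambiguity
#' flag (mirroring the elimination of sequences whose family cannot be
#' verified). (2) Identity rule: best global identity (shorter-sequence
#' denominator) to any reference member, accepted only when strictly above 95.
#' Otherwise `UNASSIGNED`. An optional hint fallback accepts the record's
#' free-text annotation hint when it names a known family.
#'
#' @param seq amino-acid string.
#' @param models named list of [FamilyModel-class] objects.
#' @param params [AlignParams-class] for the identity rule (mode is forced
#'   global).
#' @param identityThreshold strict lower bound for the identity rule
#'   (default 95: a best identity of exactly 95.0 is rejected).
#' @param hint optional free-text family hint.
#' @param useHint accept `hint` as a last-resort method (default `FALSE`).
#' @return list with `family` (token or `"UNASSIGNED"`), `method` (`"motif"`,
#'   `"identity"`, `"hint"` or `NA`), `evidence` (hit count or best identity)
#'   and `ambiguous` flag.
#' @export
assignFamily <- function(seq, models, params = alignParams(),
                         identityThreshold = 95, hint = NA_character_,
                         useHint = FALSE) {
    motifModels <- Filter(function(m) length(m@motifs) > 0, models)
    hits <- vapply(motifModels, function(m) scanMotifs(seq, m), integer(1))
    qualifies <- hits >= vapply(motifModels, function(m) m@minMotifHits, integer(1))
    if (any(qualifies)) {
        qh <- hits[qualifies]
        top <- which(qh == max(qh))
        if (length(top) > 1) {
            return(list(family = "UNASSIGNED", method = NA_character_,
                        evidence = max(qh), ambiguous = TRUE))
        }
        f <- names(qh)[top]
        return(list(family = f, method = "motif", evidence = unname(qh[top]),
                    ambiguous = FALSE))
    }
    # identity rule against annotated references
    gparams <- methods::initialize(params, mode = "global")
    bestId <- -Inf; bestFam <- NA_character_
    for (m in models) {
        refs <- m@referenceMembers
        for (k in seq_along(refs)) {
            id <- sequenceIdentity(seq, as.character(refs[[k]]), gparams,
                                   convention = "shorter")
            if (id > bestId) { bestId <- id; bestFam <- m@familyId }
        }
    }
    if (is.finite(bestId) && bestId > identityThreshold) {
        return(list(family = bestFam, method = "identity",
                    evidence = bestId, ambiguous = FALSE))
    }
    if (useHint && !is.na(hint) && hint %in% names(models)) {
        return(list(family = hint, method = "hint", evidence = NA_real_,
                    ambiguous = FALSE))
    }
    list(family = "UNASSIGNED", method = NA_character_,
         evidence = if (is.finite(bestId)) bestId else NA_real_,
         ambiguous = FALSE)
}

#' Assign every record of a PISet
#'
#' @param pis a [PISet-class].
#' @param models named list of [FamilyModel-class] objects.
#' @param ... passed to [assignFamily()].
#' @return data.frame with columns `record_id`, `family`, `method`,
#'   `evidence`, `ambiguous`.
#' @export
assignFamilies <- function(pis, models = defaultFamilyModels(), ...) {
    ids <- recordIds(pis)
    chars <- as.character(sequences(pis))
    hints <- annotationHint(pis)
    rows <- lapply(seq_along(ids), function(i)
        assignFamily(chars[i], models, hint = hints[i], ...))
    data.frame(record_id = ids,
               family = vapply(rows, `[[`, "", "family"),
               method = vapply(rows, `[[`, "", "method"),
               evidence = vapply(rows, function(r) as.numeric(r$evidence), 0),
               ambiguous = vapply(rows, `[[`, logical(1), "ambiguous"),
               stringsAsFactors = FALSE)
}

#' Catalytic-type rollup
#'
#' Sums non-redundant per-family counts into the four protease catalytic
#' types and reports each type's share of the grand total (one decimal).
#'
#' @param counts named non-negative integer vector over family tokens.
#' @return data.frame with columns `catalytic_type`, `count`, `percent`,
#'   ordered serine, cysteine, metallo, nonspecific.
#' @export
#' @examples
#' catalyticRollup(c(I2 = 10, I25 = 5, I39 = 5))
catalyticRollup <- function(counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    bad <- setdiff(names(counts), piFamilies())
    if (length(bad)) stop("unknown family token(s): ", paste(bad, collapse = ", "))
    total <- sum(counts)
    if (total == 0) stop("all counts are zero")
    map <- catalyticTypeMap()
    rows <- lapply(names(map), function(ct) {
        n <- sum(counts[intersect(names(counts), map[[ct]])])
        data.frame(catalytic_type = ct, count = n,
                   percent = roundHalfUp(100 * n / total, 1))
    })
    do.call(rbind, rows)
}
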