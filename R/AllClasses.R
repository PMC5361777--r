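#' @importClassesFrom Biostrings AAStringSet
NULL

#' PISet: a set of putative protease-inhibitor protein records
#'
#' The central sequence container. Wraps an [Biostrings::AAStringSet] whose
#' names are the (unique) record ids, alongside per-record species codes, the
#' libraries each record was observed in, and an optional free-text family
#' hint.
#'
#' Validity: record ids unique and non-empty; every sequence of length >= 1
#' over the alphabet `ACDEFGHIKLMNPQRSTVWY` plus `X` (unknown) and `*` (stop);
#' `species` and `hint` parallel to the sequences; `libraries` a list of
#' character vectors parallel to the sequences.
#'
#' @slot seqs an `AAStringSet`, names are record ids.
#' @slot species character vector of species codes, one per record.
#' @slot libraries list of character vectors: library ids per record.
#' @slot hint character vector of free-text annotation hints (`NA` if none).
#'
#' @seealso [PISet()], [recordIds()], [readFasta()]
#' @exportClass PISet
setClass("PISet",
    representation(seqs = "AAStringSet", species = "character",
                   libraries = "list", hint = "character"))

setValidity("PISet", function(object) {
    n <- length(object@seqs)
    ids <- names(object@seqs)
    msg <- character(0)
    if (is.null(ids) && n > 0) msg <- c(msg, "sequences must be named by record id")
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        msg <- c(msg, paste0("duplicate record id(s): ", paste(dup, collapse = ", ")))
    }
    if (length(object@species) != n) msg <- c(msg, "species must parallel sequences")
    if (length(object@libraries) != n) msg <- c(msg, "libraries must parallel sequences")
    if (length(object@hint) != n) msg <- c(msg, "hint must parallel sequences")
    if (n > 0) {
        chars <- as.character(object@seqs)
        if (any(nchar(chars) < 1)) msg <- c(msg, "all sequences must have length >= 1")
        bad <- regexpr(sprintf("[^%s*]", paste(c(AA_LETTERS, "X"), collapse = "")), chars)
        if (any(bad > 0)) {
            i <- which(bad > 0)[1L]
            msg <- c(msg, sprintf("record '%s' has a non-alphabet character at position %d",
                                  ids[i], bad[i]))
        }
    }
    if (length(msg)) msg else TRUE
})

#' FamilyModel: one MEROPS-style inhibitor family
#'
#' Describes one protease-inhibitor family: its MEROPS-style id (I1, I2, ...),
#' common name, the catalytic type of the proteases its members inhibit, an
#' ordered list of diagnostic motif patterns (regular expressions over the
#' amino-acid alphabet), the minimum number of distinct motifs that must hit
#' for a motif-based family call, and annotated reference members used for the
#' identity-based call. Families without motifs (e.g. I72, which shows no
#' conserved domain) are identity-only.
#'
#' @slot familyId family token, one of the 18 accepted ids (see
#'   [piFamilies()]).
#' @slot familyName common name (e.g. "Kunitz", "serpin", "cystatin").
#' @slot catalyticType one of `"serine"`, `"cysteine"`, `"metallo"`,
#'   `"nonspecific"`.
#' @slot motifs character vector of motif patterns (may be empty).
#' @slot minMotifHits integer, minimum distinct motif hits for assignment.
#' @slot referenceMembers an `AAStringSet` of annotated members (may be empty).
#'
#' @seealso [familyModel()], [defaultFamilyModels()], [assignFamily()]
#' @exportClass FamilyModel
setClass("FamilyModel",
    representation(familyId = "character", familyName = "character",
                   catalyticType = "character", motifs = "character",
                   minMotifHits = "integer", referenceMembers = "AAStringSet"))

setValidity("FamilyModel", function(object) {
    msg <- character(0)
    if (length(object@familyId) != 1L || !(object@familyId %in% piFamilies()))
        msg <- c(msg, paste0("familyId must be one of: ", paste(piFamilies(), collapse = ", ")))
    if (!(object@catalyticType %in% names(catalyticTypeMap())))
        msg <- c(msg, "catalyticType must be serine, cysteine, metallo or nonspecific")
    if (length(object@familyId) == 1L && object@familyId %in% piFamilies() &&
        object@catalyticType != familyCatalyticType(object@familyId))
        msg <- c(msg, sprintf("family %s has catalytic type '%s', not '%s'",
                              object@familyId, familyCatalyticType(object@familyId),
                              object@catalyticType))
    if (length(object@minMotifHits) != 1L || is.na(object@minMotifHits) ||
        object@minMotifHits < 1L)
        msg <- c(msg, "minMotifHits must be a positive integer")
    if (length(object@motifs) > 0 && object@minMotifHits > length(object@motifs))
        msg <- c(msg, "minMotifHits cannot exceed the number of motifs")
    if (length(msg)) msg else TRUE
})

#' AlignParams: pairwise alignment parameters
#'
#' Substitution matrix plus affine gap scores and alignment mode. A gap of
#' length L costs `gapOpen + (L - 1) * gapExtend` (both negative; the first
#' gap residue pays the opening). Defaults are BLOSUM62 with open -11 /
#' extend -1, the classic protein-search parameterisation; `X` and `*` score 0
#' against everything and never count as matches, so unknown residues cannot
#' inflate identity.
#'
#' @slot substitutionMatrix named square integer matrix over the amino-acid
#'   alphabet (plus `X` and `*`).
#' @slot gapOpen negative integer.
#' @slot gapExtend negative integer, `gapOpen <= gapExtend < 0`.
#' @slot mode `"global"` or `"local"`.
#'
#' @seealso [alignParams()], [align()]
#' @exportClass AlignParams
setClass("AlignParams",
    representation(substitutionMatrix = "matrix", gapOpen = "integer",
                   gapExtend = "integer", mode = "character"))

setValidity("AlignParams", function(object) {
    msg <- character(0)
    m <- object@substitutionMatrix
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
        msg <- c(msg, "substitution matrix must be square with identical row/col names")
    else if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (!(object@mode %in% c("global", "local")))
        msg <- c(msg, "mode must be 'global' or 'local'")
    if (!(object@gapOpen <= object@gapExtend && object@gapExtend < 0L))
        msg <- c(msg, "need gapOpen <= gapExtend < 0")
    if (length(msg)) msg else TRUE
})

#' AlignmentResult: one pairwise alignment
#'
#' Output of [align()]: the optimal score under the chosen mode, the aligned
#' strings, column/match/gap counts, the half-open (0-based) spans of the
#' aligned regions, and the full input lengths (needed for the
#' shorter-sequence identity denominator).
#'
#' @slot mode `"global"` or `"local"`.
#' @slot score numeric alignment score.
#' @slot alignedColumns number of alignment columns.
#' @slot matches columns with identical non-`X` residues.
#' @slot gapColumns columns containing a gap.
#' @slot querySpan,subjectSpan integer length-2 half-open `[start, end)`
#'   0-based spans.
#' @slot queryLength,subjectLength full input sequence lengths.
#' @slot alignedQuery,alignedSubject gapped aligned strings.
#'
#' @seealso [align()], [percentIdentity()]
#' @exportClass AlignmentResult
setClass("AlignmentResult",
    representation(mode = "character", score = "numeric",
                   alignedColumns = "integer", matches = "integer",
                   gapColumns = "integer", querySpan = "integer",
                   subjectSpan = "integer", queryLength = "integer",
                   subjectLength = "integer", alignedQuery = "character",
                   alignedSubject = "character"))

setValidity("AlignmentResult", function(object) {
    msg <- character(0)
    if (object@matches > object@alignedColumns)
        msg <- c(msg, "matches cannot exceed alignedColumns")
    if (object@gapColumns > object@alignedColumns)
        msg <- c(msg, "gapColumns cannot exceed alignedColumns")
    if (object@querySpan[2] > object@queryLength ||
        object@subjectSpan[2] > object@subjectLength)
        msg <- c(msg, "spans must lie within sequence bounds")
    if (length(msg)) msg else TRUE
})

#' RedundancyCluster: one non-redundant sequence cluster
#'
#' A set of same-species, same-family records whose members each match the
#' cluster representative at or above the redundancy threshold (default 95\%
#' identity, global alignment, shorter-sequence denominator). The
#' representative is the cluster seed: the longest member, ties broken by
#' ascending record id.
#'
#' @slot familyId family token.
#' @slot speciesCode species code shared by all members.
#' @slot representativeId id of the retained representative.
#' @slot memberIds ids of all members (includes the representative).
#' @slot memberIdentities identity of each member to the representative
#'   (the representative's own is 100).
#'
#' @seealso [dedup()], [clusterTable()]
#' @exportClass RedundancyCluster
setClass("RedundancyCluster",
    representation(familyId = "character", speciesCode = "character",
                   representativeId = "character", memberIds = "character",
                   memberIdentities = "numeric"))

setValidity("RedundancyCluster", function(object) {
    msg <- character(0)
    if (length(object@memberIds) < 1L) msg <- c(msg, "cluster must be non-empty")
    if (!(object@representativeId %in% object@memberIds))
        msg <- c(msg, "representative must be a member")
    if (length(object@memberIdentities) != length(object@memberIds))
        msg <- c(msg, "memberIdentities must parallel memberIds")
    if (length(msg)) msg else TRUE
})

#' ConditionAxis: a two-sided condition contrast
#'
#' Defines one presence/absence contrast (sex, feeding state or tissue) as two
#' disjoint sets of library ids with display labels.
#'
#' @slot axisName one of `"sex"`, `"feeding"`, `"tissue"`.
#' @slot leftLabel,rightLabel side labels (`F`/`M`, `FD`/`UF`, `SG`/`MG`).
#' @slot leftLibraries,rightLibraries disjoint character vectors of library
#'   ids.
#'
#' @seealso [conditionAxis()], [buildRepertoireMatrix()]
#' @exportClass ConditionAxis
setClass("ConditionAxis",
    representation(axisName = "character", leftLabel = "character",
                   rightLabel = "character", leftLibraries = "character",
                   rightLibraries = "character"))

setValidity("ConditionAxis", function(object) {
    msg <- character(0)
    if (length(intersect(object@leftLibraries, object@rightLibraries)) > 0)
        msg <- c(msg, "axis sides must be disjoint library sets")
    if (!(object@axisName %in% c("sex", "feeding", "tissue")))
        msg <- c(msg, "axisName must be sex, feeding or tissue")
    if (length(msg)) msg else TRUE
})

#' RepertoireMatrix: per-family exclusive/shared presence counts
#'
#' One row per family with counts of clusters found exclusively on the left
#' side of a condition axis, exclusively on the right, or on both sides
#' (shared), plus the family's non-redundant total, and a totals row. Matrices
#' built by [buildRepertoireMatrix()] have a totals row equal to the column
#' sums; matrices transcribed from a printed table (see
#' [readRepertoireTable()]) keep the printed totals row as-is.
#'
#' @slot axisName,leftLabel,rightLabel the axis description.
#' @slot counts numeric matrix, rows = families, columns
#'   `left_exclusive`, `right_exclusive`, `shared`, `row_total`.
#' @slot totals named numeric totals row (same columns).
#' @slot neitherCount for the tissue axis: clusters detected in no library of
#'   either side (`NA` for axes covering all libraries).
#' @slot source `"computed"` or `"transcribed"`.
#'
#' @seealso [buildRepertoireMatrix()], [marginalTotal()], [reportRepertoire()]
#' @exportClass RepertoireMatrix
setClass("RepertoireMatrix",
    representation(axisName = "character", leftLabel = "character",
                   rightLabel = "character", counts = "matrix",
                   totals = "numeric", neitherCount = "numeric",
                   source = "character"))

setValidity("RepertoireMatrix", function(object) {
    msg <- character(0)
    cn <- c("left_exclusive", "right_exclusive", "shared", "row_total")
    if (!identical(colnames(object@counts), cn))
        msg <- c(msg, paste0("counts columns must be: ", paste(cn, collapse = ", ")))
    cc <- object@counts
    if (any(cc < 0, na.rm = TRUE)) msg <- c(msg, "all counts must be >= 0")
    det <- rowSums(cc[, 1:3, drop = FALSE], na.rm = TRUE)
    if (any(det > cc[, "row_total"], na.rm = TRUE))
        msg <- c(msg, "detected total cannot exceed row total")
    if (object@source == "computed" &&
        !isTRUE(all.equal(unname(object@totals),
                          unname(colSums(cc, na.rm = TRUE)))))
        msg <- c(msg, "computed matrices must have totals equal to column sums")
    if (length(msg)) msg else TRUE
})

#' ScenarioConfig: synthetic-scenario description
#'
#' Declares what the synthetic-data generator plants: species, per
#' species-and-family cluster plans, identity levels, cross-species homolog
#' pairs, the library design and cluster-to-library membership probabilities.
#' Validity enforces the separation guarantee (intra-cluster identity above
#' the dedup threshold, inter-cluster ceiling below it) and keeps homolog
#' targets out of the 47-53 guard band around the conservation threshold.
#'
#' @slot speciesCodes species codes; the first is the focal species.
#' @slot clusterPlan data.frame with columns `species`, `family`, `nClusters`,
#'   `clusterSize`.
#' @slot intraIdentity planted member-to-representative identity (percent).
#' @slot interCeiling upper bound for identity between different clusters of
#'   one family (percent).
#' @slot homologPlan data.frame with columns `family`, `species`,
#'   `targetIdentity`: one subject per row, mutated from a focal-species
#'   cluster ancestor.
#' @slot libraryPlan data.frame manifest for the focal species (see
#'   [parseLibraryManifest()] for columns).
#' @slot membershipProb probability a cluster is observed in any given
#'   focal-species library (each cluster is forced into at least one).
#' @slot seqLength length of planted ancestor sequences.
#' @slot fragmentProb probability a cluster member is a truncated fragment.
#' @slot seed mandatory integer seed.
#'
#' @seealso [scenarioConfig()], [generateScenario()]
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
    representation(speciesCodes = "character", clusterPlan = "data.frame",
                   intraIdentity = "numeric", interCeiling = "numeric",
                   homologPlan = "data.frame", libraryPlan = "data.frame",
                   membershipProb = "numeric", seqLength = "integer",
                   fragmentProb = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- character(0)
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a seed is mandatory")
    if (!(object@intraIdentity > 95 && 95 > object@interCeiling))
        msg <- c(msg, "need intraIdentity > 95 > interCeiling (separation guarantee)")
    if (nrow(object@homologPlan) > 0) {
        t <- object@homologPlan$targetIdentity
        if (any(t > 47 & t < 53))
            msg <- c(msg, "homolog targets must avoid the 47-53 guard band")
    }
    if (object@membershipProb <= 0 || object@membershipProb > 1)
        msg <- c(msg, "membershipProb must be in (0, 1]")
    if (object@seqLength < 60L) msg <- c(msg, "seqLength must be >= 60")
    if (length(msg)) msg else TRUE
})
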