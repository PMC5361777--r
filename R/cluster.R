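#' @rdname tickPI-accessors
#' @export
setMethod("familyId", "RedundancyCluster", function(x) x@familyId)

#' @rdname tickPI-accessors
#' @export
setMethod("speciesCode", "RedundancyCluster", function(x) x@speciesCode)

setMethod("show", "RedundancyCluster", function(object) {
    cat(sprintf("RedundancyCluster %s/%s: representative %s, %d member(s)\n",
                object@speciesCode, object@familyId, object@representativeId,
                length(object@memberIds)))
})

#' Collapse redundant sequences within one species and family
#'
#' Greedy incremental clustering in the longest-first style: records are
#' sorted by descending length (ties by ascending record id); the first record
#' seeds cluster 1; each subsequent record joins the first existing cluster
#' whose representative it matches at or above the threshold (global
#' alignment, shorter-sequence identity denominator), otherwise it seeds a new
#' cluster. The seed (longest member) is the retained representative, so the
#' most complete sequence survives deduplication. When planted intra-cluster
#' identity exceeds the threshold and inter-cluster identity stays below it,
#' this greedy result provably equals single-linkage clustering at the same
#' threshold regardless of input order.
#'
#' @param pis a [PISet-class] whose records all share one species (and one
#'   family).
#' @param familyId family token recorded on the clusters.
#' @param threshold redundancy threshold in (0, 100]; identity `>= threshold`
#'   is deemed redundant (default 95).
#' @param params [AlignParams-class]; mode is forced global.
#' @return list of [RedundancyCluster-class] objects in seeding order.
#' @export
#' @examples
#' p <- PISet(c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'              b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'              c = "WWLPNNEHHHGGGDDDCCCAAAVVVTTTSSSRR"), species = "aam")
#' length(dedup(p, "I2"))
dedup <- function(pis, familyId, threshold = 95, params = alignParams()) {
    if (!(threshold > 0 && threshold <= 100)) stop("threshold must be in (0, 100]")
    n <- length(pis)
    if (n == 0) return(list())
    if (length(unique(speciesCode(pis))) > 1) {
        stop("dedup requires records of a single species")
    }
    gparams <- methods::initialize(params, mode = "global")
    ids <- recordIds(pis)
    chars <- as.character(sequences(pis))
    ord <- order(-nchar(chars), ids)
    repIdx <- integer(0)                 # index (into ord'd vectors) of each seed
    members <- list()
    identities <- list()
    for (k in ord) {
        placed <- FALSE
        for (ci in seq_along(repIdx)) {
            idv <- sequenceIdentity(chars[k], chars[repIdx[ci]], gparams,
                                    convention = "shorter")
            if (idv >= threshold) {
                members[[ci]] <- c(members[[ci]], k)
                identities[[ci]] <- c(identities[[ci]], idv)
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            repIdx <- c(repIdx, k)
            members[[length(repIdx)]] <- k
            identities[[length(repIdx)]] <- 100
        }
    }
    sp <- speciesCode(pis)[1L]
    lapply(seq_along(repIdx), function(ci) {
        methods::new("RedundancyCluster", familyId = familyId, speciesCode = sp,
                     representativeId = ids[repIdx[ci]],
                     memberIds = ids[members[[ci]]],
                     memberIdentities = identities[[ci]])
    })
}

#' Tabulate clusters
#'
#' @param clusters list of [RedundancyCluster-class] objects.
#' @return data.frame with one row per cluster: `cluster_id`, `family`,
#'   `species`, `representative`, `members` (comma-joined), `identities`.
#' @export
clusterTable <- function(clusters) {
    if (length(clusters) == 0) {
        return(data.frame(cluster_id = character(0), family = character(0),
                          species = character(0), representative = character(0),
                          members = character(0), identities = character(0)))
    }
    data.frame(
        cluster_id = sprintf("C%04d", seq_along(clusters)),
        family = vapply(clusters, function(x) x@familyId, ""),
        species = vapply(clusters, function(x) x@speciesCode, ""),
        representative = vapply(clusters, function(x) x@representativeId, ""),
        members = vapply(clusters, function(x) paste(x@memberIds, collapse = ","), ""),
        identities = vapply(clusters, function(x)
            paste(format(x@memberIdentities, trim = TRUE), collapse = ","), ""),
        stringsAsFactors = FALSE)
}

#' Non-redundant counts per species and family
#'
#' @param clusters list of [RedundancyCluster-class] objects (possibly from
#'   several species/families).
#' @param species optional species codes to include as all-zero rows even when
#'   absent.
#' @return data.frame: one row per species, one column per family (all 18),
#'   plus a `total` column; attribute `grand_total` carries the overall sum.
#' @export
nonredundantCounts <- function(clusters, species = NULL) {
    fams <- piFamilies()
    sp <- unique(c(species, vapply(clusters, function(x) x@speciesCode, "")))
    m <- matrix(0L, nrow = length(sp), ncol = length(fams),
                dimnames = list(sp, fams))
    for (cl in clusters) m[cl@speciesCode, cl@familyId] <- m[cl@speciesCode, cl@familyId] + 1L
    out <- data.frame(species = sp, m, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
    out$total <- as.integer(rowSums(m))
    attr(out, "grand_total") <- sum(m)
    out
}
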