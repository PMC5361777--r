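#' Construct a condition axis
#'
#' Builds the standard two-sided contrasts from a library manifest:
#' `"sex"` = female vs male libraries, `"feeding"` = fed vs unfed whole-body
#' libraries, `"tissue"` = salivary gland vs midgut libraries (any time
#' point). The two sides are always disjoint.
#'
#' @param axisName `"sex"`, `"feeding"` or `"tissue"`.
#' @param manifest library manifest data.frame (see
#'   [parseLibraryManifest()]).
#' @param species restrict to one species code (default: all).
#' @return a [ConditionAxis-class] object.
#' @export
conditionAxis <- function(axisName = c("sex", "feeding", "tissue"), manifest,
                          species = NULL) {
    axisName <- match.arg(axisName)
    if (!is.null(species)) manifest <- manifest[manifest$species_code %in% species, ]
    pick <- function(keep) manifest$library_id[keep & !is.na(keep)]
    ax <- switch(axisName,
        sex = list("F", "M", pick(manifest$sex == "F"), pick(manifest$sex == "M")),
        feeding = list("FD", "UF",
                       pick(manifest$feeding_state == "fed" & manifest$tissue == "whole"),
                       pick(manifest$feeding_state == "unfed" & manifest$tissue == "whole")),
        tissue = list("SG", "MG", pick(manifest$tissue == "SG"),
                      pick(manifest$tissue == "MG")))
    methods::new("ConditionAxis", axisName = axisName, leftLabel = ax[[1]],
                 rightLabel = ax[[2]], leftLibraries = ax[[3]],
                 rightLibraries = ax[[4]])
}

setMethod("show", "ConditionAxis", function(object) {
    cat(sprintf("ConditionAxis %s: %s (%d libraries) vs %s (%d libraries)\n",
                object@axisName, object@leftLabel, length(object@leftLibraries),
                object@rightLabel, length(object@rightLibraries)))
})

#' Libraries a cluster is present in
#'
#' A cluster is "present" in every library in which any of its (redundant)
#' members was observed: the union of member library sets.
#'
#' @param cluster a [RedundancyCluster-class].
#' @param pis the [PISet-class] carrying the members' library memberships.
#' @return character vector of library ids.
#' @export
clusterPresence <- function(cluster, pis) {
    libs <- libraryIds(pis)
    sort(unique(unlist(libs[cluster@memberIds], use.names = FALSE)))
}

#' Two-way presence partition
#'
#' @param leftPresent,rightPresent sets (character vectors) of cluster ids
#'   present on each side.
#' @return named integer vector `c(left_exclusive, right_exclusive, shared)`.
#' @export
#' @examples
#' partitionTwoWay(letters[1:13], letters[3:21])
partitionTwoWay <- function(leftPresent, rightPresent) {
    l <- unique(leftPresent); r <- unique(rightPresent)
    c(left_exclusive = length(setdiff(l, r)),
      right_exclusive = length(setdiff(r, l)),
      shared = length(intersect(l, r)))
}

#' Build a repertoire presence matrix for one axis
#'
#' For each family, the deduplicated clusters present on each side of the axis
#' are partitioned into left-exclusive / right-exclusive / shared counts;
#' families with no detections are kept as zero rows; a totals row (column
#' sums) is appended. For the tissue axis the number of clusters present in no
#' library of either side is surfaced as `neitherCount`.
#'
#' @param clusters list of [RedundancyCluster-class] objects of one species.
#' @param pis the [PISet-class] carrying library memberships.
#' @param axis a [ConditionAxis-class].
#' @param families family universe for the rows (default all 18).
#' @return a [RepertoireMatrix-class].
#' @export
buildRepertoireMatrix <- function(clusters, pis, axis,
                                  families = piFamilies()) {
    fams <- vapply(clusters, function(x) x@familyId, "")
    if (length(clusters) && any(!(fams %in% families))) {
        stop("cluster family outside the family universe: ",
             paste(setdiff(fams, families), collapse = ", "))
    }
    presence <- lapply(clusters, clusterPresence, pis = pis)
    cid <- if (length(clusters)) sprintf("C%04d", seq_along(clusters)) else character(0)
    counts <- matrix(0, nrow = length(families), ncol = 4,
                     dimnames = list(families, c("left_exclusive",
                         "right_exclusive", "shared", "row_total")))
    neither <- 0
    for (f in families) {
        sel <- which(fams == f)
        counts[f, "row_total"] <- length(sel)
        if (!length(sel)) next
        left <- cid[sel][vapply(presence[sel], function(p)
            any(p %in% axis@leftLibraries), logical(1))]
        right <- cid[sel][vapply(presence[sel], function(p)
            any(p %in% axis@rightLibraries), logical(1))]
        part <- partitionTwoWay(left, right)
        counts[f, 1:3] <- part
        neither <- neither + (length(sel) - sum(part))
    }
    methods::new("RepertoireMatrix", axisName = axis@axisName,
                 leftLabel = axis@leftLabel, rightLabel = axis@rightLabel,
                 counts = counts, totals = colSums(counts),
                 neitherCount = if (axis@axisName == "tissue") neither else NA_real_,
                 source = "computed")
}

setMethod("show", "RepertoireMatrix", function(object) {
    cat(sprintf("RepertoireMatrix [%s] %s vs %s (%s)\n", object@axisName,
                object@leftLabel, object@rightLabel, object@source))
    print(object@counts)
    cat("totals:", paste(names(object@totals), object@totals, sep = "=",
                         collapse = "  "), "\n")
    if (!is.na(object@neitherCount)) {
        cat("clusters in neither tissue:", object@neitherCount, "\n")
    }
})

#' Repertoire matrix counts
#'
#' @param x a [RepertoireMatrix-class].
#' @return the per-family counts matrix.
#' @export
repertoireCounts <- function(x) x@counts

#' Side marginal of a repertoire matrix
#'
#' The number of clusters detected on one side of the axis:
#' `side_exclusive + shared`, taken from the matrix's totals row. For matrices
#' the package computes, the totals row equals the per-family column sums, so
#' this is identical to summing the families; for matrices transcribed from a
#' printed table the printed totals are used as-is.
#'
#' @param matrix a [RepertoireMatrix-class].
#' @param side `"left"` or `"right"`.
#' @return integer marginal count.
#' @export
#' @rdname marginalTotal
setMethod("marginalTotal", "RepertoireMatrix", function(matrix, side = c("left", "right")) {
    side <- match.arg(side)
    excl <- switch(side, left = "left_exclusive", right = "right_exclusive")
    unname(matrix@totals[excl] + matrix@totals["shared"])
})

#' Per-family side total
#'
#' Number of clusters of one family detected on one side of the axis
#' (`side_exclusive + shared` for that family's row).
#'
#' @param matrix a [RepertoireMatrix-class].
#' @param family family token.
#' @param side `"left"` or `"right"`.
#' @return integer count.
#' @export
familySideTotal <- function(matrix, family, side = c("left", "right")) {
    side <- match.arg(side)
    excl <- switch(side, left = "left_exclusive", right = "right_exclusive")
    unname(matrix@counts[family, excl] + matrix@counts[family, "shared"])
}

#' Share percentage
#'
#' `100 * count / total`, rounded half-up to the nearest integer — the style
#' used for statements like "164 (~32%) were found exclusively in females".
#'
#' @param count numerator.
#' @param total denominator (>= 1).
#' @return integer percentage.
#' @export
#' @examples
#' sharePercent(164, 515)
sharePercent <- function(count, total) {
    if (total < 1) stop("total must be >= 1")
    roundHalfUp(100 * count / total, 0)
}

#' Read a transcribed repertoire table
#'
#' Reads a repertoire-table TSV (columns `family`, `F`, `M`, `F_M`, `FD`, `UF`,
#' `FD_UF`, `SG`, `MG`, `SG_MG`, `total`, with a final `Total` row) into one
#' [RepertoireMatrix-class] per axis. The printed totals row is preserved
#' verbatim (`source = "transcribed"`), because published tables are not
#' always internally consistent with their own family rows; `NA` cells (e.g. a
#' family contributed from an external single-tissue study) stay `NA`.
#'
#' @param path TSV path.
#' @return named list of [RepertoireMatrix-class]: `sex`, `feeding`,
#'   `tissue`.
#' @export
readRepertoireTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "-"))
    need <- c("family", "F", "M", "F_M", "FD", "UF", "FD_UF",
              "SG", "MG", "SG_MG", "total")
    if (!all(need %in% names(df))) {
        stop("repertoire table must have columns: ", paste(need, collapse = ", "))
    }
    totRow <- df$family == "Total"
    if (sum(totRow) != 1) stop("table must have exactly one 'Total' row")
    fam <- df[!totRow, ]
    tot <- df[totRow, ]
    mk <- function(axisName, ll, rl, cols) {
        counts <- as.matrix(fam[, c(cols, "total")])
        dimnames(counts) <- list(fam$family, c("left_exclusive",
            "right_exclusive", "shared", "row_total"))
        totals <- stats::setNames(as.numeric(tot[, c(cols, "total")]),
                                  colnames(counts))
        methods::new("RepertoireMatrix", axisName = axisName, leftLabel = ll,
                     rightLabel = rl, counts = counts, totals = totals,
                     neitherCount = NA_real_, source = "transcribed")
    }
    list(sex = mk("sex", "F", "M", c("F", "M", "F_M")),
         feeding = mk("feeding", "FD", "UF", c("FD", "UF", "FD_UF")),
         tissue = mk("tissue", "SG", "MG", c("SG", "MG", "SG_MG")))
}

#' Per-cluster time-point presence table
#'
#' Supplementary table resolving presence of each cluster in the dissected
#' tissue libraries by time point (48/96/120 h); the two-way tissue matrix
#' aggregates over time points.
#'
#' @param clusters list of [RedundancyCluster-class] objects.
#' @param pis the [PISet-class] carrying memberships.
#' @param manifest library manifest data.frame.
#' @return data.frame: `cluster_id`, `family`, `representative`, one logical
#'   column per tissue-time combination present in the manifest.
#' @export
timepointPresence <- function(clusters, pis, manifest) {
    dis <- manifest[manifest$tissue %in% c("SG", "MG"), ]
    combos <- unique(paste0(dis$tissue, "_", dis$timepoint_h, "h"))
    base <- data.frame(
        cluster_id = if (length(clusters)) sprintf("C%04d", seq_along(clusters)) else character(0),
        family = vapply(clusters, function(x) x@familyId, ""),
        representative = vapply(clusters, function(x) x@representativeId, ""),
        stringsAsFactors = FALSE)
    for (cmb in combos) {
        libs <- dis$library_id[paste0(dis$tissue, "_", dis$timepoint_h, "h") == cmb]
        base[[cmb]] <- vapply(clusters, function(cl)
            any(clusterPresence(cl, pis) %in% libs), logical(1))
    }
    base
}
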