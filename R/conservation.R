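#' Cross-species conservation screen
#'
#' Screens a focal species' non-redundant representatives against same-family
#' sequences of other species. For each query and subject species, the single
#' best local-alignment hit (by score) is kept, and retained only when its
#' identity — local alignment, columns denominator, the convention
#' translated-search tools report — reaches the threshold. A query supplied as
#' a nucleotide contig is translated with [longestOrfProtein()] first.
#'
#' @param queries named character vector (or `AAStringSet`) of focal-species
#'   query proteins, or nucleotide contigs when `translate = TRUE`.
#' @param queryFamily family token per query (recycled if length 1).
#' @param subjects a [PISet-class] of other-species proteins.
#' @param subjectFamily family token per subject record (recycled if length
#'   1).
#' @param minIdentity retention threshold, identity `>= minIdentity` is kept
#'   (default 50).
#' @param params [AlignParams-class]; mode is forced local.
#' @param translate treat queries as nucleotide contigs.
#' @return data.frame sorted by descending identity with columns `query_id`,
#'   `subject_id`, `subject_species`, `family_id`, `identity_percent`,
#'   `aligned_columns`, `score`.
#' @export
screenConservation <- function(queries, queryFamily, subjects, subjectFamily,
                               minIdentity = 50, params = alignParams(),
                               translate = FALSE) {
    if (methods::is(queries, "AAStringSet")) {
        queries <- stats::setNames(as.character(queries), names(queries))
    }
    if (translate) queries <- vapply(queries, longestOrfProtein, "")
    qf <- rep_len(queryFamily, length(queries))
    sf <- rep_len(subjectFamily, length(subjects))
    lparams <- methods::initialize(params, mode = "local")
    empty <- data.frame(query_id = character(0), subject_id = character(0),
                        subject_species = character(0), family_id = character(0),
                        identity_percent = numeric(0), aligned_columns = integer(0),
                        score = numeric(0))
    if (length(subjects) == 0 || length(queries) == 0) return(empty)
    sIds <- recordIds(subjects)
    sSp <- speciesCode(subjects)
    sChars <- as.character(sequences(subjects))
    rows <- list()
    for (qi in seq_along(queries)) {
        q <- queries[[qi]]
        if (!nzchar(q)) next
        sel <- which(sf == qf[qi])
        for (sp in unique(sSp[sel])) {
            cand <- sel[sSp[sel] == sp]
            best <- NULL
            for (si in cand) {
                r <- align(q, sChars[si], lparams)
                if (is.null(best) || r@score > best$r@score) {
                    best <- list(r = r, si = si)
                }
            }
            if (is.null(best) || best$r@alignedColumns < 1) next
            idv <- percentIdentity(best$r, "columns")
            if (idv >= minIdentity) {
                rows[[length(rows) + 1L]] <- data.frame(
                    query_id = names(queries)[qi], subject_id = sIds[best$si],
                    subject_species = sp, family_id = qf[qi],
                    identity_percent = idv,
                    aligned_columns = best$r@alignedColumns,
                    score = best$r@score, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out[order(-out$identity_percent, out$query_id, out$subject_species), ,
        drop = FALSE]
}

#' Identity band of a conservation hit
#'
#' @param identity identity percentage(s).
#' @return `">=80"`, `"65-80"`, `"50-65"` or `NA` below 50.
#' @export
identityBand <- function(identity) {
    ifelse(identity >= 80, ">=80",
        ifelse(identity >= 65, "65-80",
            ifelse(identity >= 50, "50-65", NA_character_)))
}

#' Summarise conservation hits per query
#'
#' Per query: the best identity for each subject species, the number of
#' species with a retained hit, and the identity band of the best hit overall
#' — the per-family banding style used when reporting how conserved a family's
#' members are across species.
#'
#' @param hits data.frame from [screenConservation()].
#' @param queryIds all query ids (so queries without hits appear with species
#'   count 0).
#' @return data.frame: `query_id`, `n_species`, `best_identity`, `band`,
#'   `species_hits` (comma-joined `species:identity` pairs).
#' @export
conservationSummary <- function(hits, queryIds) {
    rows <- lapply(queryIds, function(q) {
        h <- hits[hits$query_id == q, , drop = FALSE]
        if (nrow(h) == 0) {
            return(data.frame(query_id = q, n_species = 0L,
                              best_identity = NA_real_, band = NA_character_,
                              species_hits = "", stringsAsFactors = FALSE))
        }
        best <- tapply(h$identity_percent, h$subject_species, max)
        data.frame(query_id = q, n_species = length(best),
                   best_identity = max(best),
                   band = identityBand(max(best)),
                   species_hits = paste(names(best), unname(best), sep = ":",
                                        collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
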