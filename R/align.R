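#' Default substitution matrix
#'
#' BLOSUM62 restricted to the 20 standard residues, extended with `X`
#' (unknown) and `*` (stop) rows/columns that score 0 against everything.
#' Scoring unknowns as neutral keeps them from inflating either similarity or
#' dissimilarity; identity counting additionally never treats `X` as a match.
#'
#' @return named integer matrix over the 22-letter alphabet.
#' @export
defaultSubstitutionMatrix <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b62 <- e$BLOSUM62[AA_LETTERS, AA_LETTERS]
    full <- matrix(0L, nrow = 22, ncol = 22,
                   dimnames = list(AA_ALLOWED, AA_ALLOWED))
    full[AA_LETTERS, AA_LETTERS] <- as.integer(b62)
    storage.mode(full) <- "integer"
    full
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout: `#` comment lines, a header row of
#' single-letter column names, then one row per residue beginning with its
#' letter. Letters absent from the file but present in the package alphabet
#' (`X`, `*`) are added with score 0 against everything.
#'
#' @param path matrix file path.
#' @return named integer matrix covering the package alphabet.
#' @export
readSubstitutionMatrix <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 2) stop("not a matrix file: ", path)
    header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    letters <- vapply(rows, `[`, "", 1L)
    vals <- lapply(rows, function(r) as.integer(r[-1L]))
    if (any(lengths(vals) != length(header))) {
        stop("matrix row length disagrees with header in ", path)
    }
    m <- do.call(rbind, vals)
    dimnames(m) <- list(letters, header)
    keep <- intersect(AA_ALLOWED, letters)
    full <- matrix(0L, 22, 22, dimnames = list(AA_ALLOWED, AA_ALLOWED))
    full[keep, keep] <- m[keep, keep]
    full["X", ] <- 0L; full[, "X"] <- 0L
    full["*", ] <- 0L; full[, "*"] <- 0L
    storage.mode(full) <- "integer"
    full
}

#' Construct alignment parameters
#'
#' @param substitutionMatrix named symmetric integer matrix (default
#'   [defaultSubstitutionMatrix()]).
#' @param gapOpen,gapExtend negative integers; a gap of length L costs
#'   `gapOpen + (L - 1) * gapExtend`. Defaults -11 / -1.
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return an [AlignParams-class] object.
#' @export
#' @examples
#' alignParams(mode = "local")
alignParams <- function(substitutionMatrix = defaultSubstitutionMatrix(),
                        gapOpen = -11L, gapExtend = -1L,
                        mode = c("global", "local")) {
    mode <- match.arg(mode)
    methods::new("AlignParams", substitutionMatrix = substitutionMatrix,
                 gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
                 mode = mode)
}

setMethod("show", "AlignParams", function(object) {
    cat(sprintf("AlignParams: %s, gap open %d / extend %d, %dx%d matrix\n",
                object@mode, object@gapOpen, object@gapExtend,
                nrow(object@substitutionMatrix), ncol(object@substitutionMatrix)))
})

#' Pairwise protein alignment
#'
#' Optimal global (Needleman-Wunsch) or local (Smith-Waterman) alignment with
#' affine gaps, computed by an exact three-state dynamic program in compiled
#' code. Traceback ties resolve diagonal, then up, then left, so results are
#' bit-stable. Match counting never credits `X` columns.
#'
#' @param a,b amino-acid strings (non-empty, package alphabet).
#' @param params an [AlignParams-class] object.
#' @return an [AlignmentResult-class] object.
#' @export
#' @examples
#' r <- align("MKT", "MRT", alignParams())
#' r@score
#' percentIdentity(r, "columns")
align <- function(a, b, params = alignParams()) {
    if (methods::is(a, "AAString") || methods::is(a, "AAStringSet"))
        a <- as.character(a)[1L]
    if (methods::is(b, "AAString") || methods::is(b, "AAStringSet"))
        b <- as.character(b)[1L]
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    m <- params@substitutionMatrix
    res <- .alignCpp(a, b, m, paste(rownames(m), collapse = ""),
                     params@gapOpen, params@gapExtend,
                     params@mode == "local")
    methods::new("AlignmentResult",
        mode = params@mode, score = res$score,
        alignedColumns = res$alignedColumns, matches = res$matches,
        gapColumns = res$gapColumns,
        querySpan = c(res$queryStart, res$queryEnd),
        subjectSpan = c(res$subjectStart, res$subjectEnd),
        queryLength = nchar(a), subjectLength = nchar(b),
        alignedQuery = res$alignedQuery, alignedSubject = res$alignedSubject)
}

setMethod("show", "AlignmentResult", function(object) {
    cat(sprintf("%s alignment: score %g, %d columns, %d matches, %d gap columns\n",
                object@mode, object@score, object@alignedColumns,
                object@matches, object@gapColumns))
    if (object@alignedColumns > 0 && object@alignedColumns <= 80) {
        cat(" ", object@alignedQuery, "\n ", object@alignedSubject, "\n")
    }
})

#' Percent identity of an alignment
#'
#' Two denominators are supported because the underlying publications rarely
#' state one: `"columns"` divides matches by the number of alignment columns
#' (the convention translated-search tools report), `"shorter"` divides by the
#' length of the shorter input sequence (so a fragment collapses onto the
#' full-length sequence it came from). Values are reported to one decimal,
#' ties rounding up.
#'
#' @param r an [AlignmentResult-class] with at least one aligned column.
#' @param convention `"columns"` or `"shorter"`.
#' @return identity percentage, one decimal.
#' @export
#' @rdname percentIdentity
setMethod("percentIdentity", "AlignmentResult", function(r, convention = c("columns", "shorter")) {
    convention <- match.arg(convention)
    if (r@alignedColumns < 1) stop("alignment has zero aligned columns")
    den <- switch(convention,
                  columns = r@alignedColumns,
                  shorter = min(r@queryLength, r@subjectLength))
    roundHalfUp(100 * r@matches / den, 1)
})

#' Identity between two sequences
#'
#' Convenience wrapper: aligns `a` and `b` and returns the percent identity.
#' The package's two decision rules use different settings: redundancy
#' collapse uses global mode with the shorter-sequence denominator; the
#' cross-species conservation screen uses local mode with the columns
#' denominator.
#'
#' @param a,b amino-acid strings.
#' @param params an [AlignParams-class].
#' @param convention see [percentIdentity()].
#' @return identity percentage (one decimal); 0 for an empty local alignment.
#' @export
sequenceIdentity <- function(a, b, params = alignParams(),
                             convention = c("columns", "shorter")) {
    convention <- match.arg(convention)
    r <- align(a, b, params)
    if (r@alignedColumns < 1) return(0)
    percentIdentity(r, convention)
}
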