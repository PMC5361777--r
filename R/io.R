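#' Construct a PISet
#'
#' @param seqs named character vector or `AAStringSet` of amino-acid
#'   sequences; names are record ids.
#' @param species species code(s), recycled to the number of records.
#' @param libraries list of character vectors of library ids per record
#'   (default: none).
#' @param hint optional character vector of free-text family hints.
#' @return a [PISet-class] object.
#' @export
#' @examples
#' PISet(c(r1 = "MKT", r2 = "MRT"), species = "aam",
#'       libraries = list("L1", c("L1", "L2")))
PISet <- function(seqs, species, libraries = NULL, hint = NULL) {
    if (!methods::is(seqs, "AAStringSet")) {
        chars <- toupper(as.character(seqs))
        bad <- regexpr(sprintf("[^%sX*]", paste(AA_LETTERS, collapse = "")), chars)
        if (any(bad > 0)) {
            i <- which(bad > 0)[1L]
            stop(sprintf("record %d has a non-alphabet character at position %d",
                         i, bad[i]))
        }
        seqs <- Biostrings::AAStringSet(stats::setNames(chars, names(seqs)))
    }
    n <- length(seqs)
    species <- rep_len(as.character(species), n)
    if (is.null(libraries)) libraries <- rep(list(character(0)), n)
    if (is.null(hint)) hint <- rep(NA_character_, n)
    hint <- rep_len(as.character(hint), n)
    methods::new("PISet", seqs = seqs, species = species,
                 libraries = as.list(libraries), hint = hint)
}

#' @rdname tickPI-accessors
#' @export
setMethod("recordIds", "PISet", function(x) names(x@seqs))

#' @rdname tickPI-accessors
#' @export
setMethod("sequences", "PISet", function(x) x@seqs)

#' @rdname tickPI-accessors
#' @export
setMethod("speciesCode", "PISet", function(x) x@species)

#' @rdname tickPI-accessors
#' @export
setMethod("libraryIds", "PISet", function(x) {
    stats::setNames(x@libraries, names(x@seqs))
})

#' @rdname tickPI-accessors
#' @export
setMethod("annotationHint", "PISet", function(x) x@hint)

#' @describeIn PISet number of records.
#' @param x a `PISet`.
#' @export
setMethod("length", "PISet", function(x) length(x@seqs))

#' @describeIn PISet subset records by index, logical or record id.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PISet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@seqs))
    methods::initialize(x, seqs = x@seqs[i], species = x@species[i],
                        libraries = x@libraries[i], hint = x@hint[i])
})

setMethod("show", "PISet", function(object) {
    cat(sprintf("PISet with %d record(s) from %d species\n",
                length(object@seqs), length(unique(object@species))))
    if (length(object@seqs) > 0) {
        k <- seq_len(min(5L, length(object@seqs)))
        w <- Biostrings::width(object@seqs)[k]
        cat(sprintf("  %s (%s, %d aa)\n", names(object@seqs)[k],
                    object@species[k], w), sep = "")
        if (length(object@seqs) > 5) cat("  ...\n")
    }
})

#' Read a protein FASTA file
#'
#' Reads records in file order; the header token before the first whitespace
#' becomes the record id; sequences are uppercased and validated against the
#' amino-acid alphabet (20 residues plus `X` and `*`).
#'
#' @param path FASTA file path.
#' @param species species code to attach to every record.
#' @return a [PISet-class]; an empty file returns an empty set with a warning.
#' @export
#' @seealso [writeFasta()]
readFasta <- function(path, species = NA_character_) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0) {
        warning("empty FASTA file: ", path)
        return(PISet(Biostrings::AAStringSet(), species = character(0)))
    }
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids)) {
        stop("duplicate record id in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    chars <- toupper(as.character(raw))
    bad <- regexpr(sprintf("[^%sX*]", paste(AA_LETTERS, collapse = "")), chars)
    if (any(bad > 0)) {
        i <- which(bad > 0)[1L]
        stop(sprintf("record '%s': non-alphabet character '%s' at position %d",
                     ids[i], substr(chars[i], bad[i], bad[i]), bad[i]))
    }
    if (any(nchar(chars) < 1)) {
        stop("record '", ids[which(nchar(chars) < 1)[1L]], "' has an empty sequence")
    }
    PISet(stats::setNames(chars, ids), species = species)
}

#' Write sequences to FASTA
#'
#' @param x a [PISet-class] or named character vector / `AAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
    seqs <- if (methods::is(x, "PISet")) sequences(x)
            else if (methods::is(x, "AAStringSet")) x
            else Biostrings::AAStringSet(x)
    Biostrings::writeXStringSet(seqs, filepath = path)
    invisible(path)
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in frames +1, +2, +3 (forward) and -1, -2,
#' -3 (reverse complement) under the standard genetic code. Codons containing
#' `N` translate to `X`; stop codons are rendered `*`; trailing partial codons
#' are dropped.
#'
#' @param nt a single nucleotide string over `A`, `C`, `G`, `T`, `N` (length
#'   >= 3).
#' @return named character vector of the six translations
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
#' @examples
#' sixFrameTranslate("ATGAAA")
sixFrameTranslate <- function(nt) {
    nt <- toupper(nt)
    if (nchar(nt) < 3) stop("nucleotide sequence must have length >= 3")
    if (grepl("[^ACGTN]", nt)) {
        stop("invalid base at position ", regexpr("[^ACGTN]", nt))
    }
    fwd <- Biostrings::DNAString(nt)
    rev <- Biostrings::reverseComplement(fwd)
    one <- function(s, off) {
        len <- length(s) - off
        n <- 3L * (len %/% 3L)
        if (n < 3L) return("")
        as.character(Biostrings::translate(
            Biostrings::subseq(s, start = off + 1L, width = n),
            if.fuzzy.codon = "X"))
    }
    out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
             one(rev, 0L), one(rev, 1L), one(rev, 2L))
    stats::setNames(out, c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Longest stop-free translated stretch
#'
#' Selects one protein per nucleotide contig: the longest stop-free stretch
#' across all six frame translations. Ties break by frame order +1, +2, +3,
#' -1, -2, -3, then by leftmost start within a frame. This mirrors what a
#' translated similarity search effectively scores and is deterministic.
#'
#' @param nt a single nucleotide string (see [sixFrameTranslate()]).
#' @return amino-acid string; `""` when no stop-free stretch of length >= 1
#'   exists.
#' @export
#' @examples
#' longestOrfProtein("ATGAAATAA")
longestOrfProtein <- function(nt) {
    frames <- sixFrameTranslate(nt)
    best <- ""
    for (f in frames) {
        if (!nzchar(f)) next
        pieces <- strsplit(f, "*", fixed = TRUE)[[1L]]
        for (p in pieces) {
            if (nchar(p) > nchar(best)) best <- p
        }
    }
    best
}

.SEX_LEVELS <- c("F", "M")
.FEED_LEVELS <- c("fed", "unfed")
.TISSUE_LEVELS <- c("SG", "MG", "whole")
.TIME_LEVELS <- c(48, 96, 120)

#' Parse a library manifest
#'
#' Reads the tab-separated library manifest with columns `library_id`,
#' `species_code`, `sex`, `feeding_state`, `tissue`, `timepoint_h`. `NA`
#' tokens are accepted case-insensitively. Dissected-tissue libraries (SG/MG)
#' must carry a time point in \{48, 96, 120\}; whole-body libraries must not.
#'
#' @param path TSV file path.
#' @return a data.frame of validated libraries.
#' @export
parseLibraryManifest <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("library_id", "species_code", "sex", "feeding_state",
              "tissue", "timepoint_h")
    if (!all(need %in% names(df))) {
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    }
    df <- df[, need]
    na_in <- function(x) toupper(trimws(x)) %in% c("NA", "")
    df$sex[na_in(df$sex)] <- NA
    df$feeding_state[na_in(df$feeding_state)] <- NA
    df$timepoint_h[na_in(df$timepoint_h)] <- NA
    validateManifest(df)
}

#' Validate a library manifest data.frame
#'
#' @param df data.frame with the manifest columns (see
#'   [parseLibraryManifest()]).
#' @return the validated data.frame with `timepoint_h` as integer.
#' @export
validateManifest <- function(df) {
    if (anyDuplicated(df$library_id)) {
        stop("duplicate library_id: ",
             paste(unique(df$library_id[duplicated(df$library_id)]), collapse = ", "))
    }
    checkEnum <- function(col, levels) {
        v <- df[[col]]
        bad <- which(!is.na(v) & !(v %in% as.character(levels)))
        if (length(bad)) {
            stop(sprintf("row %d: unknown token '%s' in column %s",
                         bad[1L], v[bad[1L]], col))
        }
    }
    checkEnum("sex", .SEX_LEVELS)
    checkEnum("feeding_state", .FEED_LEVELS)
    checkEnum("tissue", .TISSUE_LEVELS)
    checkEnum("timepoint_h", .TIME_LEVELS)
    df$timepoint_h <- as.integer(df$timepoint_h)
    dissected <- df$tissue %in% c("SG", "MG")
    if (any(dissected & is.na(df$timepoint_h))) {
        stop("row ", which(dissected & is.na(df$timepoint_h))[1L],
             ": SG/MG library requires a timepoint in {48, 96, 120}")
    }
    if (any(!dissected & !is.na(df$timepoint_h))) {
        stop("row ", which(!dissected & !is.na(df$timepoint_h))[1L],
             ": whole-body library must have timepoint NA")
    }
    df
}

#' Write a library manifest
#'
#' @param df manifest data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeLibraryManifest <- function(df, path) {
    out <- df
    out$timepoint_h <- ifelse(is.na(out$timepoint_h), "NA", out$timepoint_h)
    out$sex <- ifelse(is.na(out$sex), "NA", out$sex)
    out$feeding_state <- ifelse(is.na(out$feeding_state), "NA", out$feeding_state)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# shared TSV + JSON mirror writer for all pipeline tables
writeTableMirror <- function(df, pathBase) {
    utils::write.table(df, paste0(pathBase, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(df, paste0(pathBase, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    invisible(pathBase)
}
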