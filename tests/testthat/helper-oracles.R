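# Test-side oracles and fixture builders, independent of the package's
# dynamic-programming implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rndProt <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Exhaustive enumeration over all gapped alignments (affine costs carried via
# the last-move state). Exponential: only for tiny sequences.
bruteGlobalScore <- function(a, b, sub, open, ext) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    rec <- function(i, j, last) {
        if (i == n && j == m) return(0)
        best <- -Inf
        if (i < n && j < m) {
            best <- max(best, sub[av[i + 1], bv[j + 1]] + rec(i + 1, j + 1, "M"))
        }
        if (i < n) {
            best <- max(best, (if (last == "X") ext else open) + rec(i + 1, j, "X"))
        }
        if (j < m) {
            best <- max(best, (if (last == "Y") ext else open) + rec(i, j + 1, "Y"))
        }
        best
    }
    rec(0, 0, "start")
}

# Local score: best global score over all substring pairs, floored at 0.
bruteLocalScore <- function(a, b, sub, open, ext) {
    n <- nchar(a); m <- nchar(b)
    best <- 0
    for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
        s <- bruteGlobalScore(substr(a, i1, i2), substr(b, j1, j2), sub, open, ext)
        if (s > best) best <- s
    }
    best
}

# Biostrings as an independent oracle for both modes. The package convention
# (gap of length L costs open + (L-1)*extend) maps to Biostrings penalties
# gapOpening = -(open) - (-extend), gapExtension = -extend.
biostringsScore <- function(a, b, mode, open = -11, ext = -1) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    s <- Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = e$BLOSUM62,
        gapOpening = -open + ext, gapExtension = -ext,
        type = if (mode == "local") "local" else "global"))
    if (mode == "local") max(0, s) else s
}

# Single-linkage clustering oracle: connected components of the graph whose
# edges join pairs at identity >= threshold (global, shorter denominator).
singleLinkagePartition <- function(pis, threshold = 95, params = alignParams()) {
    ids <- recordIds(pis)
    chars <- as.character(sequences(pis))
    n <- length(ids)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (n > 1) {
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
            idv <- sequenceIdentity(chars[i], chars[j], params, "shorter")
            if (idv >= threshold) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    canonicalPartition(split(ids, comp))
}

# order-independent representation of a partition
canonicalPartition <- function(groups) {
    sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","), "")))
}

clusterPartition <- function(clusters) {
    canonicalPartition(lapply(clusters, function(cl) cl@memberIds))
}

# a small planted scenario used by several suites
miniScenario <- function(seed, nSpecies = 1L) {
    sp <- c("aam", "isc", "iri")[seq_len(nSpecies)]
    plan <- data.frame(species = sp[1], family = c("I1", "I2", "I25"),
                       nClusters = 3L, clusterSize = 3L)
    scenarioConfig(speciesCodes = sp, clusterPlan = plan,
                   homologPlan = data.frame(family = character(0),
                                            species = character(0),
                                            targetIdentity = numeric(0)),
                   seed = seed)
}
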