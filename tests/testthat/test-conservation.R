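test_that("an identical subject is a 100% hit", {
    set.seed(401)
    q <- rndProt(80)
    subjects <- PISet(c(s1 = q, s2 = rndProt(80)), species = "isc")
    hits <- screenConservation(c(q1 = q), "I1", subjects, c("I1", "I1"))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$subject_id, "s1")
    expect_equal(hits$identity_percent, 100)
})

test_that("empty subject sets yield empty results", {
    hits <- screenConservation(c(q1 = rndProt(50)), "I1",
                               PISet(character(0), character(0)), character(0))
    expect_equal(nrow(hits), 0L)
})

test_that("planted homologs are recovered above threshold and only there", {
    scn <- generateScenario(scenarioConfig(seed = 41))
    truth <- scn$truth
    focal <- truth$clusters$species == "aam"
    reps <- truth$representatives[truth$clusterSpecies == "aam"]
    fams <- truth$clusterFamily[truth$clusterSpecies == "aam"]
    qseqs <- stats::setNames(
        as.character(sequences(scn$pis[unname(reps)])), unname(reps))
    others <- scn$pis[!focal]
    otherFams <- truth$clusters$family[match(recordIds(others),
                                             truth$clusters$record_id)]
    hits <- screenConservation(qseqs, unname(fams), others, otherFams,
                               minIdentity = 50)

    for (i in seq_len(nrow(truth$homologs))) {
        h <- truth$homologs[i, ]
        found <- hits[hits$query_id == h$query_id &
                      hits$subject_id == h$subject_id, ]
        if (h$target_identity >= 53) {
            expect_equal(nrow(found), 1L, info = paste("target", h$target_identity))
            expect_lte(abs(found$identity_percent - h$target_identity), 3)
        } else {
            expect_equal(nrow(found), 0L, info = paste("target", h$target_identity))
        }
    }
    # hits only ever pair a query with another species, same family
    expect_true(all(hits$identity_percent >= 50))
    expect_false(any(hits$subject_species == "aam"))
})

test_that("the retention threshold is inclusive and filters monotonically", {
    scn <- generateScenario(scenarioConfig(seed = 43))
    truth <- scn$truth
    reps <- truth$representatives[truth$clusterSpecies == "aam"]
    fams <- truth$clusterFamily[truth$clusterSpecies == "aam"]
    qseqs <- stats::setNames(
        as.character(sequences(scn$pis[unname(reps)])), unname(reps))
    others <- scn$pis[truth$clusters$species != "aam"]
    otherFams <- truth$clusters$family[match(recordIds(others),
                                             truth$clusters$record_id)]
    h50 <- screenConservation(qseqs, unname(fams), others, otherFams, 50)
    expect_gt(nrow(h50), 0L)

    # a hit at exactly the threshold is retained (>= semantics)
    idv <- min(h50$identity_percent)
    hAt <- screenConservation(qseqs, unname(fams), others, otherFams, idv)
    expect_true(any(hAt$identity_percent == idv))
    hAbove <- screenConservation(qseqs, unname(fams), others, otherFams, idv + 0.1)
    expect_false(any(hAbove$identity_percent == idv))

    # monotone shrinkage with rising threshold
    key <- function(h) paste(h$query_id, h$subject_id)
    for (th in c(60, 70, 80)) {
        expect_true(all(key(screenConservation(qseqs, unname(fams), others,
                                               otherFams, th)) %in% key(h50)))
    }
})

test_that("hit identities are reproducible from their alignments", {
    scn <- generateScenario(scenarioConfig(seed = 47))
    truth <- scn$truth
    reps <- truth$representatives[truth$clusterSpecies == "aam"]
    fams <- truth$clusterFamily[truth$clusterSpecies == "aam"]
    qseqs <- stats::setNames(
        as.character(sequences(scn$pis[unname(reps)])), unname(reps))
    others <- scn$pis[truth$clusters$species != "aam"]
    otherFams <- truth$clusters$family[match(recordIds(others),
                                             truth$clusters$record_id)]
    hits <- screenConservation(qseqs, unname(fams), others, otherFams, 50)
    lp <- alignParams(mode = "local")
    for (i in seq_len(nrow(hits))) {
        r <- align(qseqs[[hits$query_id[i]]],
                   as.character(sequences(others[hits$subject_id[i]])), lp)
        # recount matched columns from the aligned strings themselves
        qa <- strsplit(r@alignedQuery, "")[[1]]
        sa <- strsplit(r@alignedSubject, "")[[1]]
        matches <- sum(qa == sa & qa != "-" & qa != "X")
        expect_equal(roundHalfUp(100 * matches / length(qa), 1),
                     hits$identity_percent[i])
        expect_equal(r@alignedColumns, hits$aligned_columns[i])
    }
})

test_that("conservation summaries band queries by best identity", {
    hits <- data.frame(query_id = c("q1", "q1", "q2"),
                       subject_id = c("s1", "s2", "s3"),
                       subject_species = c("spA", "spB", "spA"),
                       family_id = "I1",
                       identity_percent = c(84, 91, 55),
                       aligned_columns = c(100L, 100L, 100L),
                       score = c(400, 450, 120))
    s <- conservationSummary(hits, c("q1", "q2", "q3"))
    expect_equal(s$n_species, c(2L, 1L, 0L))
    expect_equal(s$band, c(">=80", "50-65", NA))
    expect_equal(identityBand(c(80, 79.9, 65, 64.9, 50, 49)),
                 c(">=80", "65-80", "65-80", "50-65", "50-65", NA))
})
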