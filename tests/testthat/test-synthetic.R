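test_that("mutateToIdentity plants exact substitution counts", {
    set.seed(501)
    s <- rndProt(100)
    expect_equal(mutateToIdentity(s, 100), s)

    m90 <- mutateToIdentity(s, 90, seed = 3)
    diffs <- sum(strsplit(s, "")[[1]] != strsplit(m90, "")[[1]])
    expect_equal(diffs, 10L)
    expect_equal(nchar(m90), 100L)

    # protected positions never change
    prot <- 1:40
    mp <- mutateToIdentity(s, 70, protect = prot, seed = 4)
    expect_equal(substr(mp, 1, 40), substr(s, 1, 40))

    # infeasible when the unprotected positions cannot absorb the mutations
    expect_error(mutateToIdentity(s, 30, protect = 1:95), "protected")
    expect_error(mutateToIdentity(rndProt(10), 90), "length >= 20")
    expect_error(mutateToIdentity(s, 0), "targetIdentity")
})

test_that("realized identity agrees with the alignment module", {
    set.seed(502)
    for (target in c(60, 75, 97)) {
        for (k in 1:15) {
            s <- rndProt(200)
            m <- mutateToIdentity(s, target)
            # the optimal affine-gap alignment can gain a few extra matches
            # through gaps, so the recovered identity sits at or slightly
            # above the planted value
            idv <- sequenceIdentity(s, m, convention = "shorter")
            expect_lte(abs(idv - target), 2, label = paste("target", target))
        }
    }
})

test_that("a one-cluster config produces the promised records and truth", {
    cfg <- scenarioConfig(
        speciesCodes = "aam",
        clusterPlan = data.frame(species = "aam", family = "I2",
                                 nClusters = 1L, clusterSize = 3L),
        homologPlan = data.frame(family = character(0), species = character(0),
                                 targetIdentity = numeric(0)),
        libraryPlan = data.frame(library_id = "L1", species_code = "aam",
                                 sex = "F", feeding_state = "fed",
                                 tissue = "whole", timepoint_h = NA_integer_),
        seed = 1)
    scn <- generateScenario(cfg)
    expect_equal(length(scn$pis), 3L)
    expect_equal(length(unique(scn$truth$clusters$cluster)), 1L)
    expect_equal(unique(scn$truth$clusters$family), "I2")
    # every record observed somewhere, memberships within the manifest
    expect_true(all(lengths(libraryIds(scn$pis)) >= 1L))
    expect_true(all(unlist(libraryIds(scn$pis)) %in% "L1"))
})

test_that("generation is deterministic and leaks nothing through ids", {
    cfg <- scenarioConfig(seed = 53)
    s1 <- generateScenario(cfg)
    s2 <- generateScenario(scenarioConfig(seed = 53))
    expect_identical(as.character(sequences(s1$pis)),
                     as.character(sequences(s2$pis)))
    expect_identical(libraryIds(s1$pis), libraryIds(s2$pis))
    expect_identical(s1$truth$homologs, s2$truth$homologs)
    # ids are opaque serials
    expect_true(all(grepl("^R\\d{5}$", recordIds(s1$pis))))

    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeScenario(s1, d1); writeScenario(s2, d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                         info = f)
    }

    # record order does not influence dedup decisions
    truth <- s1$truth$clusters
    sub <- s1$pis[truth$record_id[truth$family == "I2" & truth$species == "aam"]]
    set.seed(503)
    shuffled <- sub[sample(length(sub))]
    expect_equal(clusterPartition(dedup(shuffled, "I2")),
                 clusterPartition(dedup(sub, "I2")))
})

test_that("config invariants are enforced before generation", {
    expect_error(scenarioConfig(seed = 1, intraIdentity = 94), "separation")
    expect_error(scenarioConfig(seed = 1, interCeiling = 96), "separation")
    expect_error(scenarioConfig(seed = 1,
        homologPlan = data.frame(family = "I1", species = "isc",
                                 targetIdentity = 50)), "guard band")
    expect_error(
        generateScenario(scenarioConfig(
            speciesCodes = "aam",
            clusterPlan = data.frame(species = "aam", family = "I2",
                                     nClusters = 12L, clusterSize = 2L),
            homologPlan = data.frame(family = character(0),
                                     species = character(0),
                                     targetIdentity = numeric(0)),
            seed = 1)),
        "infeasible separation")
})

test_that("separation soundness: dedup recovers the planted partition", {
    for (seed in c(3, 8, 15)) {
        scn <- generateScenario(miniScenario(seed = seed))
        truth <- scn$truth$clusters
        for (f in unique(truth$family)) {
            sel <- truth$family == f
            planted <- canonicalPartition(split(truth$record_id[sel],
                                                truth$cluster[sel]))
            got <- clusterPartition(dedup(scn$pis[truth$record_id[sel]], f))
            expect_equal(got, planted, info = paste("seed", seed, "family", f))
        }
    }
})

test_that("scenario FASTA files round-trip through the library reader", {
    scn <- generateScenario(miniScenario(seed = 59))
    d <- withr::local_tempdir()
    writeScenario(scn, d)
    back <- readLibraryFastaSet(d, scn$manifest)
    expect_setequal(recordIds(back), recordIds(scn$pis))
    ord <- match(recordIds(scn$pis), recordIds(back))
    expect_equal(unname(as.character(sequences(back))[ord]),
                 unname(as.character(sequences(scn$pis))))
    expect_equal(libraryIds(back)[recordIds(scn$pis)], libraryIds(scn$pis))
})
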