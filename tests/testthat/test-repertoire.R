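test_that("two-way partitions follow set arithmetic", {
    # 13 present on the left, 19 on the right, 11 shared
    left <- sprintf("c%02d", 1:13)
    right <- sprintf("c%02d", 3:21)
    expect_equal(unname(partitionTwoWay(left, right)), c(2L, 8L, 11L))
    expect_equal(unname(partitionTwoWay(letters[1:3], letters[4:7])), c(3L, 4L, 0L))
    expect_equal(unname(partitionTwoWay(letters[1:5], letters[1:5])), c(0L, 0L, 5L))
})

test_that("cluster presence is the union of member library sets", {
    p <- PISet(c(a = rndProt(30), b = rndProt(30)), species = "aam",
               libraries = list("L1", "L2"))
    cl <- new("RedundancyCluster", familyId = "I2", speciesCode = "aam",
              representativeId = "a", memberIds = c("a", "b"),
              memberIdentities = c(100, 99))
    expect_equal(clusterPresence(cl, p), c("L1", "L2"))
    solo <- new("RedundancyCluster", familyId = "I2", speciesCode = "aam",
                representativeId = "a", memberIds = "a", memberIdentities = 100)
    expect_equal(clusterPresence(solo, p), "L1")
})

test_that("repertoire matrices equal the generator's truth on all axes", {
    scn <- generateScenario(scenarioConfig(seed = 23))
    truth <- scn$truth
    focal <- "aam"
    sel <- truth$clusters$species == focal
    pis <- scn$pis
    clusters <- lapply(unique(truth$clusters$cluster[sel]), function(key) {
        ids <- truth$clusters$record_id[truth$clusters$cluster == key]
        new("RedundancyCluster", familyId = truth$clusterFamily[[key]],
            speciesCode = focal,
            representativeId = truth$representatives[[key]],
            memberIds = ids, memberIdentities = rep(100, length(ids)))
    })
    manifest <- scn$manifest
    for (ax in c("sex", "feeding", "tissue")) {
        m <- buildRepertoireMatrix(clusters, pis,
                                   conditionAxis(ax, manifest, species = focal))
        expect_equal(unname(m@counts), unname(truth$expectedMatrix[[ax]]),
                     info = ax)
        # row conservation: exclusive + exclusive + shared = detected
        det <- rowSums(m@counts[, 1:3])
        expect_true(all(det <= m@counts[, "row_total"]))
        expect_equal(unname(m@totals), unname(colSums(m@counts)))
    }

    # the sex axis covers every focal library, so every cluster is detected
    msex <- buildRepertoireMatrix(clusters, pis,
                                  conditionAxis("sex", manifest, species = focal))
    expect_equal(unname(rowSums(msex@counts[, 1:3])),
                 unname(msex@counts[, "row_total"]))
})

test_that("swapping axis sides swaps the exclusives and fixes shared", {
    scn <- generateScenario(miniScenario(seed = 29))
    truth <- scn$truth$clusters
    clusters <- lapply(unique(truth$cluster), function(key) {
        ids <- truth$record_id[truth$cluster == key]
        new("RedundancyCluster", familyId = scn$truth$clusterFamily[[key]],
            speciesCode = "aam", representativeId = scn$truth$representatives[[key]],
            memberIds = ids, memberIdentities = rep(100, length(ids)))
    })
    ax <- conditionAxis("sex", scn$manifest, species = "aam")
    swapped <- new("ConditionAxis", axisName = "sex", leftLabel = ax@rightLabel,
                   rightLabel = ax@leftLabel, leftLibraries = ax@rightLibraries,
                   rightLibraries = ax@leftLibraries)
    m1 <- buildRepertoireMatrix(clusters, scn$pis, ax)
    m2 <- buildRepertoireMatrix(clusters, scn$pis, swapped)
    expect_equal(m1@counts[, "left_exclusive"], m2@counts[, "right_exclusive"])
    expect_equal(m1@counts[, "shared"], m2@counts[, "shared"])
})

test_that("marginals and share percentages follow their definitions", {
    tbl <- readRepertoireTable(system.file("extdata", "repertoire_table_a_americanum.tsv",
                                           package = "tickPI"))
    expect_equal(marginalTotal(tbl$feeding, "left"), 442)
    expect_equal(marginalTotal(tbl$feeding, "right"), 231)
    expect_equal(marginalTotal(tbl$tissue, "left"), 206)
    expect_equal(marginalTotal(tbl$tissue, "right"), 164)

    expect_equal(sharePercent(164, 515), 32)
    expect_equal(sharePercent(202, 515), 39)
    expect_equal(sharePercent(0, 10), 0)
    expect_error(sharePercent(1, 0), "total")

    # on computed matrices the totals-row marginal equals the family sum
    scn <- generateScenario(miniScenario(seed = 31))
    truth <- scn$truth$clusters
    clusters <- lapply(unique(truth$cluster), function(key) {
        ids <- truth$record_id[truth$cluster == key]
        new("RedundancyCluster", familyId = scn$truth$clusterFamily[[key]],
            speciesCode = "aam", representativeId = scn$truth$representatives[[key]],
            memberIds = ids, memberIdentities = rep(100, length(ids)))
    })
    m <- buildRepertoireMatrix(clusters, scn$pis,
                               conditionAxis("sex", scn$manifest, species = "aam"))
    expect_equal(marginalTotal(m, "left"),
                 sum(m@counts[, "left_exclusive"] + m@counts[, "shared"]))
})

test_that("the tissue axis surfaces clusters found in neither tissue", {
    scn <- generateScenario(scenarioConfig(seed = 37))
    truth <- scn$truth$clusters
    sel <- truth$species == "aam"
    clusters <- lapply(unique(truth$cluster[sel]), function(key) {
        ids <- truth$record_id[truth$cluster == key]
        new("RedundancyCluster", familyId = scn$truth$clusterFamily[[key]],
            speciesCode = "aam", representativeId = scn$truth$representatives[[key]],
            memberIds = ids, memberIdentities = rep(100, length(ids)))
    })
    m <- buildRepertoireMatrix(clusters, scn$pis,
                               conditionAxis("tissue", scn$manifest, species = "aam"))
    expect_equal(m@neitherCount,
                 sum(m@counts[, "row_total"]) - sum(m@counts[, 1:3]))
})
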