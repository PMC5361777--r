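# build a sequence carrying a family's diagnostic motifs on a random
# backbone; returns the sequence and the motif positions
plantFamilySeq <- function(familyId, len = 200, models = defaultFamilyModels()) {
    motifs <- models[[familyId]]@motifs
    seq <- rndProt(len)
    protect <- integer(0)
    at <- 10
    for (m in motifs) {
        substr(seq, at, at + nchar(m) - 1) <- m
        protect <- c(protect, at:(at + nchar(m) - 1))
        at <- at + nchar(m) + 15
    }
    list(seq = seq, protect = protect)
}

test_that("family inventory and catalytic map are consistent", {
    expect_length(piFamilies(), 18L)
    map <- catalyticTypeMap()
    expect_setequal(unlist(map), piFamilies())
    expect_equal(familyCatalyticType(c("I2", "I25", "I43", "I39")),
                 c("serine", "cysteine", "metallo", "nonspecific"))
})

test_that("motif scanning counts distinct motifs once each", {
    models <- defaultFamilyModels()
    m <- models$I2
    both <- paste0("AAAA", m@motifs[1], "GGGG", m@motifs[2], "AAAA")
    expect_equal(scanMotifs(both, m), 2L)
    one <- paste0("AAAA", m@motifs[1], "GGGG", m@motifs[1], "AAAA")
    expect_equal(scanMotifs(one, m), 1L)   # repeats of one motif count once
    expect_equal(scanMotifs(rndProt(50), m) <= 2L, TRUE)
    expect_error(scanMotifs("MKT", models$I72), "no motifs")
})

test_that("motif rule assigns planted sequences to their family", {
    models <- defaultFamilyModels()
    set.seed(201)
    for (f in c("I1", "I2", "I25", "I39", "I74")) {
        ps <- plantFamilySeq(f)
        a <- assignFamily(ps$seq, models)
        expect_equal(a$family, f)
        expect_equal(a$method, "motif")
    }
})

test_that("identity rule is strictly greater than 95", {
    set.seed(202)
    ref <- rndProt(120)
    models <- defaultFamilyModels(referenceMembers = list(I53 = c(ref1 = ref)))
    q97 <- mutateToIdentity(ref, 97, seed = 1)
    a <- assignFamily(q97, models)
    expect_equal(a$family, "I53")
    expect_equal(a$method, "identity")
    expect_gt(a$evidence, 95)

    # exactly 95.0 fails the strict bound and the record is eliminated
    q95 <- mutateToIdentity(ref, 95, seed = 2)
    a95 <- assignFamily(q95, models)
    expect_equal(a95$evidence, 95.0)
    expect_equal(a95$family, "UNASSIGNED")
})

test_that("ambiguous multi-family motif evidence is left unassigned", {
    models <- defaultFamilyModels()
    seq <- paste0("GGGG", models$I2@motifs[1], "AA", models$I2@motifs[2],
                  "GGGG", models$I25@motifs[1], "AA", models$I25@motifs[2])
    a <- assignFamily(seq, models)
    expect_equal(a$family, "UNASSIGNED")
    expect_true(a$ambiguous)
})

test_that("default motifs rarely fire on random sequences", {
    models <- defaultFamilyModels()
    motifModels <- Filter(function(m) length(m@motifs) > 0, models)
    set.seed(203)
    falsePos <- 0L
    n <- 1000L
    for (k in seq_len(n)) {
        s <- rndProt(300)
        hits <- vapply(motifModels, function(m)
            scanMotifs(s, m) >= m@minMotifHits, logical(1))
        if (any(hits)) falsePos <- falsePos + 1L
    }
    expect_lte(falsePos / n, 0.05)
})

test_that("assignment is exact on planted data and robust to 5% noise", {
    scn <- generateScenario(scenarioConfig(seed = 5))
    asg <- assignFamilies(scn$pis)
    truth <- scn$truth$clusters
    expect_equal(asg$family[match(truth$record_id, asg$record_id)], truth$family)

    # motif-sparing 5% substitution noise on fresh planted sequences
    models <- defaultFamilyModels()
    set.seed(204)
    fams <- setdiff(piFamilies(), "I72")
    total <- 0L; correct <- 0L
    for (f in fams) {
        ps <- plantFamilySeq(f)
        for (rep in 1:6) {
            noisy <- mutateToIdentity(ps$seq, 95, protect = ps$protect)
            a <- assignFamily(noisy, models)
            total <- total + 1L
            if (identical(a$family, f)) correct <- correct + 1L
        }
    }
    expect_gte(correct / total, 0.99)
})

test_that("catalytic rollup reproduces shares and conserves the total", {
    expect_equal(catalyticRollup(c(I39 = 10))$percent[4], 100)
    expect_error(catalyticRollup(c(I39 = 0)), "all counts are zero")
    expect_error(catalyticRollup(c(I2 = -1)), "non-negative")
    expect_error(catalyticRollup(c(Z9 = 3)), "unknown family")

    set.seed(205)
    for (k in 1:10) {
        counts <- stats::setNames(sample(0:50, 18, TRUE), piFamilies())
        if (sum(counts) == 0) counts["I2"] <- 1
        r <- catalyticRollup(counts)
        expect_equal(sum(r$count), sum(counts))
    }
})

test_that("family models load from a YAML config", {
    cfgPath <- system.file("extdata", "family_models_example.yaml",
                           package = "tickPI")
    models <- readFamilyModels(cfgPath)
    expect_named(models, c("I2", "I25", "I72"))
    expect_equal(models$I2@motifs, c("GPCKAR", "FYGGCG"))
    expect_equal(models$I2@catalyticType, "serine")
    expect_length(models$I72@motifs, 0L)
})
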