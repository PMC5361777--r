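test_that("FASTA reading preserves order, ids and sequences", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">s1 some description", "MKT"), f)
    p <- readFasta(f, species = "aam")
    expect_equal(recordIds(p), "s1")
    expect_equal(as.character(sequences(p)), c(s1 = "MKT"))

    writeLines(c(">a", "mk", ">b", "MR"), f)
    p <- readFasta(f)
    expect_equal(recordIds(p), c("a", "b"))
    expect_equal(unname(as.character(sequences(p))), c("MK", "MR"))
})

test_that("FASTA round trip is the identity on valid records", {
    set.seed(11)
    ids <- sprintf("rec%02d", 1:8)
    seqs <- stats::setNames(vapply(1:8, function(i) rndProt(sample(5:40, 1)), ""), ids)
    seqs[3] <- paste0(substr(seqs[3], 1, 4), "X", substr(seqs[3], 6, nchar(seqs[3])))
    f <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(seqs, f)
    back <- readFasta(f)
    expect_equal(recordIds(back), ids)
    expect_equal(as.character(sequences(back)), seqs)
})

test_that("FASTA reader rejects malformed input", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "MK", ">a", "MR"), f)
    expect_error(readFasta(f), "duplicate record id.*a")

    writeLines(c(">a", "MK3T"), f)
    expect_error(readFasta(f), "position 3")

    writeLines(character(0), f)
    expect_warning(p <- readFasta(f), "empty")
    expect_equal(length(p), 0L)
})

test_that("six-frame translation follows the standard code and conventions", {
    expect_equal(unname(sixFrameTranslate("ATGAAA")["+1"]), "MK")
    expect_equal(unname(sixFrameTranslate("TTTCAT")["-1"]), "MK")
    expect_equal(unname(sixFrameTranslate("ATGANAAAA")["+1"]), "MXK")
    expect_error(sixFrameTranslate("AT"), "length >= 3")
    expect_error(sixFrameTranslate("ATGQ"), "invalid base")

    set.seed(21)
    for (k in 1:25) {
        nt <- paste(sample(c("A", "C", "G", "T"), sample(9:60, 1), TRUE),
                    collapse = "")
        tr <- sixFrameTranslate(nt)
        # frame lengths
        for (off in 0:2) {
            expect_equal(nchar(tr[[off + 1]]), (nchar(nt) - off) %/% 3)
            expect_equal(nchar(tr[[off + 4]]), (nchar(nt) - off) %/% 3)
        }
        # frame +2 equals frame +1 of the sequence minus its first base
        expect_equal(unname(tr["+2"]),
                     unname(sixFrameTranslate(substr(nt, 2, nchar(nt)))["+1"]))
    }
})

test_that("longest ORF selection matches the frame translations", {
    # frame +1 reads MKTLGLH then a stop; every other frame is interrupted
    # earlier, so the forward open reading frame wins
    expect_equal(longestOrfProtein("ATGAAAACTTTAGGATTACATTAA"), "MKTLGLH")
    # a stretch can also come from the reverse strand: the reverse complement
    # of ATGAAATAA reads LFH in its first frame, longer than the forward MK
    expect_equal(longestOrfProtein("ATGAAATAA"), "LFH")
    set.seed(31)
    for (k in 1:60) {
        nt <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
        orf <- longestOrfProtein(nt)
        frames <- sixFrameTranslate(nt)
        pieces <- unlist(strsplit(frames, "*", fixed = TRUE))
        expect_equal(nchar(orf), max(0, nchar(pieces)))
        expect_false(grepl("*", orf, fixed = TRUE))
        expect_true(nchar(orf) == 0 ||
                    any(vapply(frames, grepl, logical(1), pattern = orf,
                               fixed = TRUE)))
    }
})

test_that("library manifest validation enforces the design constraints", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("library_id\tspecies_code\tsex\tfeeding_state\ttissue\ttimepoint_h",
                 "L1\taam\tF\tfed\tSG\t48",
                 "L2\taam\tM\tunfed\twhole\tna"), f)
    m <- parseLibraryManifest(f)
    expect_equal(m$library_id, c("L1", "L2"))
    expect_equal(m$timepoint_h, c(48L, NA))
    expect_true(is.na(m$sex[2]) == FALSE)

    writeLines(c("library_id\tspecies_code\tsex\tfeeding_state\ttissue\ttimepoint_h",
                 "L3\taam\tF\tfed\tSG\tNA"), f)
    expect_error(parseLibraryManifest(f), "SG/MG library requires a timepoint")

    writeLines(c("library_id\tspecies_code\tsex\tfeeding_state\ttissue\ttimepoint_h",
                 "L4\taam\tQ\tfed\twhole\tNA"), f)
    expect_error(parseLibraryManifest(f), "row 1.*'Q'.*sex")

    writeLines(c("library_id\tspecies_code\tsex\tfeeding_state\ttissue\ttimepoint_h",
                 "L5\taam\tF\tfed\twhole\t48"), f)
    expect_error(parseLibraryManifest(f), "whole-body library must have timepoint NA")
})

test_that("PISet validity catches duplicate ids and bad alphabets", {
    expect_error(PISet(c(a = "MKT", a = "MRT"), "aam"), "duplicate")
    expect_error(PISet(c(a = "MK T"), "aam"), "non-alphabet")
    p <- PISet(c(a = "MKT", b = "MRTX"), "aam", libraries = list("L1", c("L1", "L2")))
    expect_equal(length(p), 2L)
    expect_equal(recordIds(p["b"]), "b")
    expect_equal(libraryIds(p)$b, c("L1", "L2"))
})
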