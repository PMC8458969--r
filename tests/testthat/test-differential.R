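tab1 <- loadTable1Fixture()

test_that("stage deltas are wild-type minus mutant in percentage points", {
    expect_equal(deltaPoints(tab1, "rps16", 56313, stage = 1), 79.02)
    expect_equal(deltaPoints(tab1, "ndhB", 141424, stage = 2), 33.56)
    eq <- EditingTable(matrix(0.4, 2, 4,
                              dimnames = list(NULL, unname(editingSamples()))),
                       gene = c("a", "b"), position = 1:2)
    expect_identical(deltaPoints(eq, "a", 1, stage = 1), 0)
})

test_that("classification matches the published per-site narrative", {
    rec <- classifyEditing(tab1)
    r <- rec[rec$key == "rps16-56313", ]
    expect_identical(as.character(r$categoryS1), "decreased")
    expect_identical(as.character(r$categoryS2), "still_decreased")

    r <- rec[rec$key == "ndhF-124681", ]
    expect_equal(r$deltaS1, 8.5)
    expect_identical(as.character(r$categoryS1), "unaffected")
    expect_identical(as.character(r$categoryS2), "newly_affected")
})

test_that("identical efficiencies are always unaffected; exact ties too", {
    eq <- EditingTable(matrix(0.55, 3, 4,
                              dimnames = list(NULL, unname(editingSamples()))),
                       gene = "g", position = 1:3)
    rec <- classifyEditing(eq)
    expect_true(all(rec$categoryS1 == "unaffected"))
    expect_true(all(rec$categoryS2 == "unaffected"))

    # a delta of exactly the threshold is not "more than" it
    m <- matrix(c(0.60, 0.60, 0.50, 0.50), 1,
                dimnames = list(NULL, unname(editingSamples())))
    tie <- EditingTable(m, gene = "g", position = 9L)
    rec <- classifyEditing(tie, thresholdPoints = 10)
    expect_identical(as.character(rec$categoryS1), "unaffected")
    expect_identical(as.character(rec$categoryS2), "unaffected")
})

test_that("raising the threshold never recruits new decreased sites", {
    prev <- NULL
    for (thr in c(5, 10, 15, 25, 40)) {
        rec <- classifyEditing(tab1, thresholdPoints = thr)
        dec <- rec$key[rec$categoryS1 == "decreased"]
        if (!is.null(prev)) expect_true(all(dec %in% prev))
        prev <- dec
    }
})

test_that("summary counts are invariant under row permutation", {
    s0 <- summarizeEditing(classifyEditing(tab1), tab1)
    set.seed(5)
    perm <- tab1[sample(nrow(tab1)), ]
    s1 <- summarizeEditing(classifyEditing(perm), perm)
    for (f in c("nSites", "nCoding", "nCodingGenes", "nNonsynonymous",
                "nDecreasedS1", "nRestored", "nNewlyAffected",
                "nDecreasedS2", "nDecreasedS2Genes"))
        expect_identical(s1[[f]], s0[[f]])
    expect_setequal(s1$restored, s0$restored)
    # and each stage's categories partition the sites
    rec <- classifyEditing(tab1)
    expect_identical(sum(table(rec$categoryS1)), nrow(tab1))
    expect_identical(sum(table(rec$categoryS2)), nrow(tab1))
})

test_that("an empty record set summarises to zero counts", {
    empty <- EditingTable(matrix(numeric(0), 0, 4,
                                 dimnames = list(NULL,
                                                 unname(editingSamples()))),
                          position = integer(0))
    s <- summarizeEditing(classifyEditing(empty), empty)
    expect_identical(s$nSites, 0L)
    expect_identical(s$nDecreasedS1, 0L)
    expect_identical(s$nRestored, 0L)
})

test_that("missing samples and duplicate keys are refused", {
    sub <- tab1[, 1:3]
    expect_error(classifyEditing(sub), "Gmpgl2_S2")
    # duplicated (gene, site) keys are refused at construction already
    expect_error(rbind(tab1[1, ], tab1[1, ]), "duplicated")
})
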