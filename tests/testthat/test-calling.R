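test_that("editing efficiency is the edited-read fraction and scale-invariant", {
    expect_identical(computeEfficiency(50, 0), 0)
    expect_identical(computeEfficiency(0, 50), 1)
    expect_equal(computeEfficiency(2098, 7902), 0.7902)
    set.seed(3)
    nr <- sample(1:500, 50)
    nv <- sample(0:500, 50)
    for (k in c(2L, 7L, 100L))
        expect_equal(computeEfficiency(k * nr, k * nv),
                     computeEfficiency(nr, nv))
    expect_error(computeEfficiency(0, 0), "zero coverage")
})

test_that("discovery filter applies count and frequency criteria in order", {
    expect_true(applyDiscoveryFilter(4, 3)$pass)
    expect_identical(applyDiscoveryFilter(4, 2)$reason, "min_var")
    # violates min_ref and frequency; min_ref is reported (stated order)
    expect_identical(applyDiscoveryFilter(1, 19)$reason, "min_ref")
    # frequency bounds are inclusive at 0.1 and 0.9 exactly
    expect_true(applyDiscoveryFilter(27, 3)$pass)
    expect_true(applyDiscoveryFilter(2, 18)$pass)
    # count minima are checked before the frequency window
    expect_identical(applyDiscoveryFilter(9, 1)$reason, "min_var")
    expect_identical(applyDiscoveryFilter(0, 0)$reason, "no_coverage")
    expect_identical(applyDiscoveryFilter(100, 3)$reason, "frequency")
})

test_that("discovery filter agrees with brute force over a count grid", {
    th <- filterThresholds()
    grid <- expand.grid(nRef = 0:100, nVar = 0:100)
    got <- applyDiscoveryFilter(grid$nRef, grid$nVar, th)$pass
    want <- mapply(function(r, v) {
        tot <- r + v
        if (tot == 0) return(FALSE)
        f <- v / tot
        r >= 2 && v >= 3 && f >= 0.1 && f <= 0.9
    }, grid$nRef, grid$nVar)
    expect_identical(got, unname(want))
})

test_that("site calling reports every covered sample once a site passes anywhere", {
    counts <- rbind(
        toyCounts(10, "+", "C", "T", 10, 10, "A"),   # passes in A
        toyCounts(10, "+", "C", "T", 100, 1, "B"),   # fails in B, covered
        toyCounts(30, "+", "C", "T", 100, 1, "A"))   # never passes
    et <- callSites(counts)
    expect_identical(nrow(et), 1L)
    expect_identical(sitePositions(et), 10L)
    expect_equal(unname(efficiencies(et)[1, ]), c(0.5, 1 / 101))

    none <- callSites(toyCounts(5, "+", "C", "T", 100, 1, "A"))
    expect_identical(nrow(none), 0L)
    expect_identical(sampleLabels(none), "A")

    # targeted mode quantifies panel positions regardless of the filter
    tg <- callSites(counts, mode = "targeted",
                    panel = data.frame(position = c(10L, 30L),
                                       strand = "+"))
    expect_identical(nrow(tg), 2L)
    expect_true(is.na(efficiencies(tg)["site-30", "B"]))
})

test_that("discovery recovers simulated truth sites without false positives", {
    cfg <- simulationConfig(seed = 11, nGenes = 12, nSites = 50,
                            siteEfficiency = 0.5, coverage = 200,
                            errorRate = 0)
    sim <- generateReference(cfg)
    counts <- simulateCounts(sim, positions = "genes", seed = 12)
    et <- callSites(counts)
    truthKeys <- paste(panelSites(truthPanel(sim))$position,
                       panelSites(truthPanel(sim))$strand)
    gotKeys <- paste(sitePositions(et), siteStrands(et))
    expect_setequal(gotKeys, truthKeys)   # all 50, nothing else
})

test_that("region annotation follows CDS > intron > downstream > intergenic", {
    toy <- toyAnnotation()
    ann <- annotateRegion(c(150, 250, 450, 700, 951), toy$genes,
                          downstreamWindow = 200,
                          referenceLength = 2000)
    expect_identical(ann$region, c("CDS", "intron", "downstream",
                                   "intergenic", "downstream"))
    expect_identical(ann$gene_id, c("geneA", "geneA", "geneA",
                                    "geneA", "geneB"))
    # 951 is 50 nt past the 3' end of minus-strand geneB (its start)
    expect_error(annotateRegion(2005, toy$genes, referenceLength = 2000),
                 "outside")
})

test_that("amino-acid consequences use the plastid genetic code", {
    expect_identical(predictAminoAcidChange("TCA", 2), "Ser-Leu")
    expect_identical(predictAminoAcidChange("ACA", 2), "Thr-Ile")
    expect_identical(predictAminoAcidChange("CAT", 1), "His-Tyr")
    expect_identical(predictAminoAcidChange("CTC", 3), "Unchanged")
    expect_error(predictAminoAcidChange("AAA", 1), "no C")
})

test_that("reference-sense and transcript-sense records agree on minus strands", {
    # same minus-strand site, reported plus-strand (G>A) and
    # transcript-sense (C>T): identical efficiencies after ingest
    p1 <- withr::local_tempfile(fileext = ".tsv")
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeRawCounts(toyCounts(1100, "-", "G", "A", 30, 70, "s")[-7], p1)
    writeRawCounts(toyCounts(1100, "-", "C", "T", 30, 70, "s")[-7], p2)
    a <- readSiteCounts(p1, "s", sense = "reference")
    b <- readSiteCounts(p2, "s", sense = "transcript")
    expect_identical(a, b)
    ea <- callSites(a, mode = "targeted",
                    panel = data.frame(position = 1100L, strand = "-"))
    expect_equal(unname(efficiencies(ea)[1, 1]), 0.7)
})

test_that("annotation of called sites reproduces simulated codon contexts", {
    cfg <- simulationConfig(seed = 21, nGenes = 10, nSites = 30,
                            siteEfficiency = 0.5, coverage = 300,
                            errorRate = 0, intronProb = 0.5)
    sim <- generateReference(cfg)
    counts <- simulateCounts(sim, positions = "sites", seed = 22)
    et <- callSites(counts, mode = "targeted",
                    panel = data.frame(
                        position = panelSites(truthPanel(sim))$position,
                        strand = panelSites(truthPanel(sim))$strand))
    ann <- annotateSites(et, geneModels(sim), refSequence(sim))
    ps <- panelSites(truthPanel(sim))
    i <- match(sitePositions(ann), ps$position)
    expect_identical(regionLabels(ann), as.character(ps$region[i]))
    expect_identical(aaChanges(ann), as.character(ps$change[i]))
    expect_identical(geneIds(ann), as.character(ps$gene[i]))
})
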