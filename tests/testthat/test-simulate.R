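test_that("generation is a pure function of the configuration", {
    cfg <- simulationConfig(seed = 33, nGenes = 6, nSites = 10)
    a <- generateReference(cfg)
    b <- generateReference(cfg)
    expect_identical(as.character(refSequence(a)), as.character(refSequence(b)))
    expect_identical(as.data.frame(geneRanges(geneModels(a))),
                     as.data.frame(geneRanges(geneModels(b))))
    expect_identical(truthMatrix(truthPanel(a)), truthMatrix(truthPanel(b)))
    expect_identical(simulateCounts(a, seed = 5), simulateCounts(b, seed = 5))
})

test_that("degenerate configurations behave as specified", {
    empty <- generateReference(simulationConfig(seed = 2, nSites = 0))
    expect_identical(nrow(panelSites(truthPanel(empty))), 0L)
    expect_gt(refLength(refSequence(empty)), 0)

    wired <- generateReference(simulationConfig(seed = 3, nGenes = 5,
                                                intronProb = 1, nSites = 0))
    for (g in S4Vectors::mcols(geneRanges(geneModels(wired)))$gene_id) {
        expect_identical(length(exonRanges(geneModels(wired), g)), 2L)
        expect_identical(length(intronRanges(geneModels(wired), g)), 1L)
    }

    expect_error(generateReference(simulationConfig(seed = 4, nGenes = 2,
                                                    codonRange = c(10L, 12L),
                                                    nSites = 5000)),
                 "infeasible")
})

test_that("simulated counts follow the binomial editing model", {
    cfg <- simulationConfig(seed = 6, nGenes = 4, nSites = 5,
                            siteEfficiency = 0, coverage = 50,
                            errorRate = 0)
    sim <- generateReference(cfg)
    cnt <- simulateCounts(sim, positions = "genes", seed = 7)
    expect_true(all(cnt$n_var == 0))            # e = 0, error 0
    expect_true(all(cnt$ref_base == "C" & cnt$var_base == "T"))
    expect_true(all(cnt$n_ref + cnt$n_var == 50))

    half <- generateReference(simulationConfig(seed = 8, nGenes = 4,
                                               nSites = 5,
                                               siteEfficiency = 0.5,
                                               coverage = 1e6,
                                               errorRate = 0))
    cnt <- simulateCounts(half, positions = "sites", seed = 9)
    freq <- cnt$n_var / (cnt$n_ref + cnt$n_var)
    expect_true(all(abs(freq - 0.5) <= 0.002))  # within 4 binomial SD
})

test_that("the curated-table panel reproduces published structure on a toy plastome", {
    sim <- panelFromTable1()
    ps <- panelSites(truthPanel(sim))
    expect_identical(nrow(ps), 43L)
    regs <- table(ps$region)
    expect_identical(as.integer(regs[c("CDS", "downstream", "intergenic",
                                       "intron")]), c(38L, 1L, 2L, 2L))
    truth <- truthMatrix(truthPanel(sim))
    i <- which(ps$gene == "rps16" & ps$siteLabel == "56313")
    expect_identical(unname(truth[i, c("Gmpgl2_S1", "Gmpgl2_S2")]), c(0, 0))
    types <- sort(unique(ps$change[ps$region == "CDS" &
                                   ps$change != "Unchanged"]))
    expect_identical(types, c("His-Tyr", "Pro-Leu", "Ser-Leu", "Ser-Phe",
                              "Thr-Ile", "Thr-Met"))
    # determinism
    expect_identical(as.character(refSequence(panelFromTable1())),
                     as.character(refSequence(sim)))
})

test_that("discovery at low error keeps sensitivity high and false positives bounded", {
    cfg <- simulationConfig(seed = 14, nGenes = 10, nSites = 40,
                            siteEfficiency = c(0.2, 0.8), coverage = 200,
                            errorRate = 0.001)
    sim <- generateReference(cfg)
    cnt <- simulateCounts(sim, positions = "genes", seed = 15)
    et <- callSites(cnt)
    truthKeys <- paste(panelSites(truthPanel(sim))$position,
                       panelSites(truthPanel(sim))$strand)
    gotKeys <- paste(sitePositions(et), siteStrands(et))
    expect_true(all(truthKeys %in% gotKeys))    # sensitivity 1
    nNonSites <- length(unique(paste(cnt$position, cnt$strand))) -
        length(truthKeys)
    fp <- length(setdiff(gotKeys, truthKeys))
    # bounded by the min_var >= 3 binomial tail at this coverage
    bound <- pbinom(2, 200, 0.001, lower.tail = FALSE)
    expect_lte(fp / nNonSites, bound)
})
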