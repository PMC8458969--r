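toyProtein <- function(pairs, classes = NULL) {
    n <- nrow(pairs)
    if (is.null(classes)) classes <- rep(c("P", "L", "S"), length.out = n)
    PPRProtein("toy", data.frame(
        class = classes,
        start = seq(1, by = 35, length.out = n),
        end = seq(35, by = 35, length.out = n),
        aa5 = pairs$aa5, aaLast = pairs$aaLast))
}

test_that("code extraction returns one residue pair per P/L/S motif in order", {
    pairs17 <- data.frame(aa5 = rep(c("T", "N", "S"), length.out = 17),
                          aaLast = rep(c("D", "N"), length.out = 17))
    prot <- PPRProtein("p17", data.frame(
        class = c(rep(c("P", "L", "S"), length.out = 17), "E1", "E2", "E+"),
        start = seq(1, by = 35, length.out = 20),
        end = seq(35, by = 35, length.out = 20),
        aa5 = c(pairs17$aa5, "A", "A", "A"),
        aaLast = c(pairs17$aaLast, "A", "A", "A")))
    code <- extractCode(prot)
    expect_identical(nrow(code), 17L)
    expect_identical(code$aa5, pairs17$aa5)

    onlyE <- PPRProtein("e", data.frame(class = c("E1", "E2"),
                                        start = c(1, 40), end = c(35, 75),
                                        aa5 = "A", aaLast = "A"))
    expect_identical(nrow(extractCode(onlyE)), 0L)

    toy <- toyProtein(data.frame(aa5 = c("T", "T", "N"),
                                 aaLast = c("D", "N", "D")))
    expect_identical(extractCode(toy),
                     data.frame(aa5 = c("T", "T", "N"),
                                aaLast = c("D", "N", "D"),
                                stringsAsFactors = FALSE))

    # motifs shorter than 5 residues cannot carry the code
    expect_error(PPRProtein("bad", data.frame(class = "P", start = 1,
                                              end = 3, aa5 = "T",
                                              aaLast = "D")),
                 "shorter")
})

test_that("window extraction follows the upstream register on both strands", {
    toy <- toyAnnotation()
    ref <- toy$reference
    seqchar <- as.character(ref[[1]])
    # pick a plus-strand C far enough from the start
    pos <- regexpr("C", substring(seqchar, 100))[[1]] + 99
    w <- buildWindow(pos, "+", ref, n = 17, offset = -4)
    expect_identical(nchar(w@window), 17L)
    expect_identical(w@window, substring(seqchar, pos - 20, pos - 4))

    w1 <- buildWindow(pos, "+", ref, n = 1, offset = -1)
    expect_identical(w1@window, substring(seqchar, pos - 1, pos - 1))

    # minus strand: reverse complement of the corresponding plus slice
    gpos <- regexpr("G", substring(seqchar, 100))[[1]] + 99
    wm <- buildWindow(gpos, "-", ref, n = 6, offset = -4)
    slice <- substring(seqchar, gpos + 4, gpos + 9)
    expect_identical(wm@window, as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(slice))))

    cpos <- regexpr("C", seqchar)[[1]]
    if (cpos < 21)
        expect_error(buildWindow(cpos, "+", ref, n = 17, offset = -4),
                     "past the reference")
    expect_error(buildWindow(pos, "+", ref, 17, offset = 4), "negative")
})

test_that("match index counts code-permitted nucleotides motif by motif", {
    pairs <- data.frame(aa5 = c("T", "T", "N"), aaLast = c("D", "N", "D"))
    tab <- pprCodeTable(data.frame(aa5 = c("T", "T", "N"),
                                   aaLast = c("D", "N", "D"),
                                   nucleotides = c("G", "A", "U")))
    mi <- matchIndex(pairs, "GAA", tab)
    expect_identical(mi$matches, 2L)
    expect_identical(mi$total, 3L)

    expect_identical(matchIndex(pairs, "GAA", universalCode(pairs))$matches, 3L)
    none <- pprCodeTable(data.frame(aa5 = "X", aaLast = "X",
                                    nucleotides = "A"))
    expect_identical(matchIndex(pairs, "GAA", none)$matches, 0L)

    expect_error(matchIndex(pairs, "GAAA", tab), "length")

    # growing any permissible set never lowers the match count
    set.seed(9)
    for (rep in 1:20) {
        win <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
        base <- pprCodeTable(data.frame(
            aa5 = pairs$aa5, aaLast = pairs$aaLast,
            nucleotides = vapply(1:3, function(i) paste(
                sample(c("A", "C", "G", "U"), sample(0:2, 1)),
                collapse = ""), character(1))))
        grown <- pprCodeTable(data.frame(
            aa5 = pairs$aa5, aaLast = pairs$aaLast,
            nucleotides = vapply(strsplit(base@entries$nucleotides, ""),
                                 function(x) paste(unique(c(x, "A", "G")),
                                                   collapse = ""),
                                 character(1))))
        expect_gte(matchIndex(pairs, win, grown)$matches,
                   matchIndex(pairs, win, base)$matches)
    }
})

test_that("target scanning matches brute-force rescoring and ranks planted sites first", {
    # planted perfect 5-motif target: code TD,TN,ND,TD,TN permits GAUGA;
    # background transcript has no other C
    pairs <- data.frame(aa5 = c("T", "T", "N", "T", "T"),
                        aaLast = c("D", "N", "D", "D", "N"))
    prot <- toyProtein(pairs)
    code <- defaultPPRCode()
    tx <- paste(rep("GAT", 40), collapse = "")
    # place GATGA then 3 spacer bases then the edited C at position 129
    tx <- paste0(substring(tx, 1, 100), "GATGA", "AAA", "C",
                 substring(tx, 109, 120))
    ref <- Biostrings::DNAStringSet(paste0(strrep("A", 30), tx,
                                           strrep("A", 30)))
    names(ref) <- "toy"
    g <- GenomicRanges::GRanges("toy", IRanges::IRanges(31, 30 + nchar(tx)),
                                strand = "+")
    S4Vectors::mcols(g)$gene_id <- "g1"
    gms <- GeneModelSet(g, g)
    hits <- scanTargets(prot, ref, gms, code, offset = -4)
    expect_identical(hits$position[1], 30L + 109L)
    expect_identical(hits$matches[1], 5L)
    expect_identical(hits$total[1], 5L)

    # brute force over a random 2 kb two-strand annotation
    toy <- toyAnnotation()
    got <- scanTargets(prot, toy$reference, toy$genes, code, offset = -4)
    seqchar <- as.character(toy$reference[[1]])
    revcomp <- function(s) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    brute <- list()
    for (spec in list(list(101, 400, "+", "geneA"),
                      list(1001, 1300, "-", "geneB"))) {
        for (pos in spec[[1]]:spec[[2]]) {
            b <- substring(seqchar, pos, pos)
            b <- if (spec[[3]] == "+") b else chartr("ACGT", "TGCA", b)
            if (b != "C") next
            win <- if (spec[[3]] == "+")
                substring(seqchar, pos - 8, pos - 4)
            else revcomp(substring(seqchar, pos + 4, pos + 8))
            if (nchar(win) < 5) next
            nts <- chartr("T", "U", strsplit(win, "")[[1]])
            k <- sum(vapply(seq_len(5), function(i)
                nts[i] %in% permittedNucleotides(code, pairs$aa5[i],
                                                 pairs$aaLast[i]),
                logical(1)))
            brute[[length(brute) + 1]] <- data.frame(
                position = pos, matches = k)
        }
    }
    brute <- do.call(rbind, brute)
    brute <- brute[order(-brute$matches, brute$position), ]
    expect_identical(got$position, brute$position)
    expect_identical(got$matches, as.integer(brute$matches))
    # ties are broken by ascending position
    for (f in unique(got$fraction)) {
        sub <- got$position[got$fraction == f]
        expect_false(is.unsorted(sub))
    }

    # a reference without any transcript-sense C yields nothing
    refA <- Biostrings::DNAStringSet(strrep("AGT", 200))
    names(refA) <- "toy"
    gA <- GenomicRanges::GRanges("toy", IRanges::IRanges(101, 400),
                                 strand = "+")
    S4Vectors::mcols(gA)$gene_id <- "gA"
    expect_identical(nrow(scanTargets(prot, refA, GeneModelSet(gA, gA),
                                      code)), 0L)
})
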