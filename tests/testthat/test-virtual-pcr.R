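## shared toy template pieces
SSP5315_REAL <- "CTGAAGCGGATCGAGAACAAGATCAACC"  # S realized as G

makeTemplate <- function(ssp_at, site, site_at, len, filler = "AC") {
    ch <- strsplit(strrep(filler, ceiling(len / nchar(filler))), "")[[1]][1:len]
    tpl <- paste(ch, collapse = "")
    ins <- function(tpl, s, at)
        paste0(substr(tpl, 1, at), s, substr(tpl, at + nchar(s) + 1, len))
    tpl <- ins(tpl, SSP5315_REAL, ssp_at)
    ins(tpl, site, site_at)
}

test_that("SSP sites are found with exact 3' seeds on both strands", {
    cat <- loadCatalog()
    s <- cat$ssp[["5315"]]
    tpl <- paste0(strrep("T", 30), SSP5315_REAL, strrep("T", 30))
    hits <- findSspSites(tpl, s)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$start, 30L)
    expect_identical(hits$strand, "+")
    expect_identical(hits$three_prime_pos, 30L + 27L)
    ## minus strand
    hits_rc <- findSspSites(revComp(tpl), s)
    expect_identical(nrow(hits_rc), 1L)
    expect_identical(hits_rc$strand, "-")
    expect_identical(hits_rc$three_prime_pos, hits_rc$start)
    ## a mismatch at the final 3' base is fatal even with tolerance
    tpl_mm <- paste0(strrep("T", 30), substr(SSP5315_REAL, 1, 27), "G",
                     strrep("T", 30))
    cfg1 <- pcrConfig(ssp_max_mismatches = 1)
    got <- findSspSites(tpl_mm, s, cfg1)
    expect_identical(nrow(got[got$strand == "+", ]), 0L)
    ## but an internal mismatch is tolerated at max_mismatches = 1
    tpl_mm2 <- paste0(strrep("T", 30), "CTGAAGCGGATCGAGAACAAGATCTACC",
                      strrep("T", 30))
    got2 <- findSspSites(tpl_mm2, s, cfg1)
    expect_identical(nrow(got2[got2$strand == "+", ]), 1L)
    expect_identical(got2$mismatches[got2$strand == "+"], 1L)
    ## N in the footprint kills annealing
    tpl_n <- paste0(strrep("T", 30), sub("GCGG", "GNGG", SSP5315_REAL),
                    strrep("T", 30))
    expect_identical(nrow(findSspSites(tpl_n, s, cfg1)), 0L)
})

test_that("PST annealing geometry and flank rules", {
    cat <- loadCatalog()
    pst <- cat$pst[["5605"]]  # GGATCC, dN10
    tpl <- paste0(strrep("A", 40), "GGATCC", strrep("A", 40))  # site at 40
    an <- findPstAnneal(tpl, pst)
    expect_identical(nrow(an), 2L)
    minus <- an[an$strand == "-", ]
    expect_identical(c(minus$start, minus$end), c(40L, 40L + 16L))
    expect_identical(minus$extends, "left")
    plus <- an[an$strand == "+", ]
    expect_identical(c(plus$start, plus$end), c(30L, 46L))
    expect_identical(plus$extends, "right")
    ## truncated flank: site 5 bp from the right edge loses "-" orientation
    tpl2 <- paste0(strrep("A", 40), "GGATCC", strrep("A", 5))
    an2 <- findPstAnneal(tpl2, pst)
    expect_identical(an2$strand, "+")
    ## N in a flank removes that orientation only
    tpl3 <- paste0(strrep("A", 40), "GGATCC", "AANAA",
                   strrep("A", 20))
    an3 <- findPstAnneal(tpl3, pst)
    expect_identical(an3$strand, "+")
})

test_that("amplicon geometry matches the worked example", {
    ## SSP 5' at 100 extending rightward, GGATCC at 600:
    ## round-2 length = (600 - 100) + 6 + 10 + 19 = 535
    cat <- loadCatalog()
    tpl <- makeTemplate(100, "GGATCC", 600, 1000)
    amp <- predictAmplicons(tpl, cat$ssp[["5315"]], cat$pst[["5605"]])
    expect_identical(nrow(amp), 1L)
    expect_identical(amp$round2_len_bp, 535L)
    expect_identical(amp$round1_len_bp, 535L)  # tail length = adapter length
    expect_identical(c(amp$start, amp$end), c(100L, 616L))
    expect_identical(amp$orientation, "SSP-forward")
    ## product sequence has exactly the predicted length
    prod <- productSequence(tpl, amp[1, ], cat$pst[["5605"]])
    expect_identical(nchar(prod), 535L)
    expect_identical(substr(prod, 1, 19), cat$tail)
})

test_that("orientation and range filters suppress impossible products", {
    cat <- loadCatalog()
    s <- cat$ssp[["5315"]]
    pst <- cat$pst[["5605"]]
    ## PST site beyond the polymerase limit
    far <- makeTemplate(100, "GGATCC", 3500, 4000)
    expect_identical(nrow(predictAmplicons(far, s, pst)), 0L)
    ## PST site upstream of a forward SSP
    up <- makeTemplate(600, "GGATCC", 100, 1000)
    expect_identical(nrow(predictAmplicons(up, s, pst)), 0L)
    ## tail must equal the adapter
    ok <- makeTemplate(100, "GGATCC", 600, 1000)
    expect_error(predictAmplicons(ok, s, pst, tail = "ACGTACGTACGTACGTACG"),
                 "adapter")
})

test_that("amplicon lengths equal the string-extension oracle on fixtures", {
    cat <- loadCatalog()
    s <- cat$ssp[["5315"]]
    cfg <- pcrConfig(min_product_bp = 1)
    set.seed(41)
    for (i in 1:25) {
        pst <- cat$pst[[sample(length(cat$pst), 1)]]
        tpl <- randSeq(2500)
        ## implant an SSP realization to guarantee occasional products
        at <- sample(2000, 1)
        substr(tpl, at, at + 27) <- SSP5315_REAL
        got <- predictAmplicons(tpl, s, pst, cfg = cfg)
        pal <- palindromeSequence(pst)
        want <- sort(c(
            oracleExtensionLengths(tpl, sspRealizations(primerSequence(s)),
                                   pal, 10, 19, 1, 3000),
            oracleExtensionLengths(revComp(tpl),
                                   sspRealizations(primerSequence(s)),
                                   pal, 10, 19, 1, 3000)))
        expect_identical(sort(got$round2_len_bp), as.integer(want),
                         info = paste(i, primerId(pst)))
    }
})

test_that("product lengths are strand-symmetric", {
    cat <- loadCatalog()
    s <- cat$ssp[["5315"]]
    set.seed(42)
    for (i in 1:10) {
        tpl <- randSeq(3000)
        at <- sample(2500, 1)
        substr(tpl, at, at + 27) <- SSP5315_REAL
        pst <- cat$pst[[sample(length(cat$pst), 1)]]
        cfg <- pcrConfig(min_product_bp = 1)
        a <- predictAmplicons(tpl, s, pst, cfg = cfg)
        b <- predictAmplicons(revComp(tpl), s, pst, cfg = cfg)
        expect_identical(sort(a$round2_len_bp), sort(b$round2_len_bp))
    }
})

test_that("filtering is monotone in the product window", {
    cat <- loadCatalog()
    s <- cat$ssp[["5315"]]
    pst <- cat$pst[["5605"]]
    set.seed(43)
    tpl <- randSeq(4000)
    substr(tpl, 50, 77) <- SSP5315_REAL
    full <- predictAmplicons(tpl, s, pst,
                             cfg = pcrConfig(max_product_bp = 4100,
                                             min_product_bp = 1))
    narrow <- predictAmplicons(tpl, s, pst,
                               cfg = pcrConfig(max_product_bp = 2000,
                                               min_product_bp = 300))
    expect_true(all(narrow$round2_len_bp %in% full$round2_len_bp))
    expect_lte(nrow(narrow), nrow(full))
    expect_true(all(narrow$round2_len_bp >= 300 &
                    narrow$round2_len_bp <= 2000))
    ## an unconstrained window reproduces the unfiltered set
    again <- predictAmplicons(tpl, s, pst,
                              cfg = pcrConfig(max_product_bp = 4100,
                                              min_product_bp = 1))
    expect_identical(full, again)
})

test_that("every amplicon contains both primer footprints at its ends", {
    cat <- loadCatalog()
    s <- cat$ssp[["5315"]]
    set.seed(44)
    for (i in 1:5) {
        tpl <- randSeq(3000)
        substr(tpl, 100, 127) <- SSP5315_REAL
        for (pid in c("5605", "5608", "5615")) {
            pst <- cat$pst[[pid]]
            amp <- predictAmplicons(tpl, s, pst,
                                    cfg = pcrConfig(min_product_bp = 1))
            pal <- palindromeSequence(pst)
            for (r in seq_len(nrow(amp))) {
                row <- amp[r, ]
                span <- substr(tpl, row$start + 1, row$end)
                if (row$strand == "+") {
                    expect_true(startsWith(span, SSP5315_REAL) ||
                                iupacMatches(primerSequence(s),
                                             substr(span, 1, 28)))
                    ## core at the far end: palindrome then flank
                    expect_identical(
                        substr(tpl, row$site_pos + 1, row$site_pos + 6), pal)
                    expect_identical(row$end - row$site_pos, 16L)
                } else {
                    expect_identical(row$site_pos - row$start, 10L)
                    expect_identical(
                        substr(tpl, row$site_pos + 1, row$site_pos + 6), pal)
                }
            }
        }
    }
})

test_that("nested round-2 SSP shortens products by the nested offset", {
    cat <- loadCatalog()
    outer <- ssp("out1", "GATTACAGATTACAGATTACAGATT", "F")
    nested <- ssp("nest1", "CCGGTTAACCGGTTAACCGGTTAAC", "F")
    tpl <- paste0(strrep("A", 50), primerSequence(outer), strrep("G", 40),
                  primerSequence(nested), strrep("AC", 150), "GGATCC",
                  strrep("T", 60))
    pst <- cat$pst[["5605"]]
    same <- predictAmplicons(tpl, outer, pst)
    cfg_n <- pcrConfig(second_round_ssp = "nest1")
    nest <- predictAmplicons(tpl, outer, pst, cfg = cfg_n, nested = nested)
    expect_identical(nrow(same), 1L)
    expect_identical(nrow(nest), 1L)
    offset <- 40L + 25L  # gap + outer length
    expect_identical(same$round2_len_bp - nest$round2_len_bp, offset)
    expect_identical(same$round1_len_bp, nest$round1_len_bp)
    ## nested SSP without a site inside the product yields nothing
    lost <- ssp("nest2", "GTCAGTCAGTCAGTCAGTCAGTCAG", "F")
    cfg_l <- pcrConfig(second_round_ssp = "nest2")
    expect_identical(
        nrow(predictAmplicons(tpl, outer, pst, cfg = cfg_l, nested = lost)),
        0L)
    ## config/nested id mismatch is an error
    expect_error(predictAmplicons(tpl, outer, pst, cfg = cfg_n,
                                  nested = lost), "nest1")
})

test_that("side products require facing orientations within range", {
    cat <- loadCatalog()
    pst <- cat$pst[["5605"]]
    cfg <- pcrConfig(report_side_products = TRUE)
    ## two GGATCC sites 500 bp apart: span 526 + two 19-nt tails = 564
    tpl <- paste0(strrep("A", 40), "GGATCC", strrep("C", 494), "GGATCC",
                  strrep("A", 40))
    sp <- enumerateSideProducts(tpl, pst, cfg)
    expect_identical(nrow(sp), 1L)
    expect_identical(sp$round2_len_bp, 564L)
    expect_true(sp$side_product)
    expect_identical(nchar(productSequence(tpl, sp[1, ], pst)), 564L)
    ## single site: nothing
    one <- paste0(strrep("A", 40), "GGATCC", strrep("A", 40))
    expect_identical(nrow(enumerateSideProducts(one, pst, cfg)), 0L)
    ## sites too far apart
    far <- paste0(strrep("A", 40), "GGATCC", strrep("AC", 2500), "GGATCC",
                  strrep("A", 40))
    expect_identical(nrow(enumerateSideProducts(far, pst, cfg)), 0L)
    ## disabled reporting is a hard error
    expect_error(enumerateSideProducts(tpl, pst, pcrConfig()), "disabled")
})

test_that("the Cartesian walk screen recovers fixture ground truth", {
    cat <- loadCatalog()
    spec <- fixtureSpec(6000, 0.5, 4242, data.frame(
        feature = c("ssp_site", "bam", "eco", "pma"),
        sequence = c(SSP5315_REAL, "GGATCC", "GAATTC", "CACGTG"),
        position = c(100, 700, 1400, 2300),
        strand = "+", stringsAsFactors = FALSE),
        forbidden = CATALOG_PALINDROMES)
    g <- generateGenome(spec)
    tset <- Biostrings::DNAStringSet(g$sequence)
    names(tset) <- "fixture"
    ## full-catalog screen: only the three implanted palindromes amplify
    tab <- runWalk(tset, "5315", cat, pcrConfig())
    expect_identical(nrow(tab), 3L)
    expect_setequal(tab$pst_id, c("5605", "5608", "5615"))
    expect_identical(tab$round2_len_bp,
                     as.integer(sort((c(700, 1400, 2300) - 100) + 16 + 19)))
    ## unknown ids are rejected with the available list
    expect_error(runWalk(tset, "9999", cat), "available")
    expect_error(runWalk(tset, "5315", cat, pst_ids = "nope"), "available")
    ## no SSP site anywhere warns (troubleshooting guidance)
    blank <- Biostrings::DNAStringSet(strrep("AC", 500))
    names(blank) <- "blank"
    expect_warning(out <- runWalk(blank, "5315", cat), "no SSP annealing")
    expect_identical(nrow(out), 0L)
})

test_that("tandem sites of one motif give multiple products, shortest first", {
    cat <- loadCatalog()
    tpl <- makeTemplate(50, "GGATCC", 700, 3000)
    substr(tpl, 1501, 1506) <- "GGATCC"
    tset <- Biostrings::DNAStringSet(tpl)
    names(tset) <- "t"
    tab <- runWalk(tset, "5315", cat, pst_ids = "5605")
    expect_identical(nrow(tab), 2L)
    expect_false(is.unsorted(tab$round2_len_bp))
})
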