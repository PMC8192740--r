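cet_tree5 <- function() {
    ape::read.tree(text = "((dolphin,vaquita),(right_whale,(minke,blue)));")
}

test_that("a fixed seed reproduces the simulation byte for byte", {
    tr <- cet_tree5()
    s1 <- simulateStudy(tr, nFamilies = 4L, seed = 7L)
    s2 <- simulateStudy(tr, nFamilies = 4L, seed = 7L)
    expect_identical(s1$familyProteins, s2$familyProteins)
    for (sp in names(s1$species)) {
        expect_identical(as.character(s1$species[[sp]]$genome),
                         as.character(s2$species[[sp]]$genome))
        expect_identical(s1$species[[sp]]$truth, s2$species[[sp]]$truth)
    }
    s3 <- simulateStudy(tr, nFamilies = 4L, seed = 8L)
    expect_false(identical(as.character(s1$species[[1L]]$genome),
                           as.character(s3$species[[1L]]$genome)))
})

test_that("zero loss probability keeps every originated family everywhere", {
    tr <- cet_tree5()
    set.seed(21)
    h <- simulateFamilyHistory(tr, 20L,
                               simulationConfig(lossProb = 0, dupProb = 0))
    for (sp in tr$tip.label) {
        expect_equal(nrow(h$tips[[sp]]), 20L)
        expect_true(all(h$tips[[sp]]$copies == 1L))
    }
    expect_true(all(h$events$type == "gain"))
})

test_that("without duplication each tip carries zero or one copy", {
    tr <- cet_tree5()
    set.seed(22)
    h <- simulateFamilyHistory(tr, 50L,
                               simulationConfig(lossProb = 0.3, dupProb = 0))
    copies <- unlist(lapply(h$tips, function(t) t$copies))
    expect_true(all(copies == 1L))
    expect_gt(sum(h$events$type == "loss"), 0L)
})

test_that("emitted sequence is consistent with the recorded ground truth", {
    set.seed(23)
    cfg <- simulationConfig(pseudoProb = 0)
    prots <- c(FAM001 = rand_protein(100), FAM002 = rand_protein(140))
    sim <- buildLocus(data.frame(family = c("FAM001", "FAM002"),
                                 copies = c(2L, 1L)),
                      prots, cfg, species = "t")
    chrom <- as.character(sim$genome[[1L]])
    for (i in seq_len(nrow(sim$truth))) {
        g <- sim$truth[i, ]
        cds <- substr(chrom, g$cds_start + 1L, g$cds_end)
        expect_equal(substr(cds, 1L, 3L), "ATG")
        expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in%
                    c("TAA", "TAG", "TGA"))
        expect_equal(tr_frame1(substr(cds, 1L, nchar(cds) - 3L)), g$protein)
        # splice signals at the implanted intron boundaries
        expect_equal(substr(chrom, g$intron_start + 1L, g$intron_start + 2L),
                     "GT")
        expect_equal(substr(chrom, g$intron_end - 1L, g$intron_end), "AG")
        # anatomy is contiguous: exon1 | intron | exon2
        expect_equal(g$exon1_end, g$intron_start)
        expect_equal(g$intron_end, g$exon2_start)
        expect_equal(substr(chrom, g$tata + 1L, g$tata + 4L), "TATA")
        # re-parsing the emitted annotation reproduces anchor coordinates
    }
    tf <- tempfile(fileext = ".gff3")
    writeAnnotationGff3(sim$annotation, tf)
    back <- readAnnotation(tf)
    expect_equal(back$start, sim$annotation$start)
    expect_equal(back$end, sim$annotation$end)
})

test_that("an implanted frameshift is classified at the implanted codon", {
    set.seed(24)
    cfg <- simulationConfig()
    prots <- c(FAM001 = rand_protein(120))
    sim <- buildLocus(data.frame(family = "FAM001", copies = 1L), prots, cfg,
                      species = "t",
                      statuses = c(t_FAM001.1 = "disrupted_frameshift"))
    g <- sim$truth[!sim$truth$anchor, ]
    chrom <- as.character(sim$genome[[1L]])
    cand <- substr(chrom, g$cds_start + 1L, g$cds_end)
    s <- classifyIntegrity(cand, prots[[1L]])
    expect_equal(s@state, "disrupted_frameshift")
    fs <- s@lesions[s@lesions$kind == "frameshift", ]
    expect_true(any(g$lesion_codon >= fs$ref_codon - 1L &
                    g$lesion_codon <= fs$ref_codon_hi + 1L))
})

test_that("an N-gap over a gene makes its interval unknown", {
    set.seed(25)
    cfg <- simulationConfig()
    prots <- c(FAM001 = rand_protein(100), FAM002 = rand_protein(100))
    sim <- buildLocus(data.frame(family = c("FAM001", "FAM002"),
                                 copies = c(1L, 1L)),
                      prots, cfg, species = "t",
                      gapGenes = "t_FAM001.1")
    loc <- extractLocus(sim$genome, sim$annotation, "S100A9", "S100A11")
    off <- loc@start
    g1 <- sim$truth[sim$truth$gene_id == "t_FAM001.1", ]
    g2 <- sim$truth[sim$truth$gene_id == "t_FAM002.1", ]
    expect_gte(nrow(locusGaps(loc)), 1L)
    expect_equal(markUnknown(c(g1$cds_start, g1$cds_end) - off,
                             locusGaps(loc)), "unknown")
    expect_equal(markUnknown(c(g2$cds_start, g2$cds_end) - off,
                             locusGaps(loc)), "ok")
})

test_that("read generation honours the junction fraction and the seed", {
    set.seed(26)
    cfg <- simulationConfig(junctionFraction = 1, coverage = 3)
    prots <- c(FAM001 = rand_protein(120))
    sim <- buildLocus(data.frame(family = "FAM001", copies = 1L), prots, cfg,
                      species = "t")
    chrom <- as.character(sim$genome[[1L]])
    rr <- generateReads(sim$truth, chrom, cfg, seed = 9L)
    expect_gt(nrow(rr$provenance), 0L)
    expect_true(all(rr$provenance$junction))
    # both anchors of every junction read respect the minimal overlap
    j <- rr$provenance
    expect_true(all(j$b1e - j$b1s >= cfg$minAnchor))
    expect_true(all(j$b2e - j$b2s >= cfg$minAnchor))
    # reads really are the spliced transcript at the recorded blocks
    for (i in seq_len(min(5L, nrow(j)))) {
        expect_equal(as.character(rr$reads[[j$read_id[i]]]),
                     paste0(substr(chrom, j$b1s[i] + 1L, j$b1e[i]),
                            substr(chrom, j$b2s[i] + 1L, j$b2e[i])))
    }

    rr2 <- generateReads(sim$truth, chrom, cfg, seed = 9L)
    expect_identical(as.character(rr$reads), as.character(rr2$reads))

    rr0 <- generateReads(sim$truth, chrom,
                         simulationConfig(coverage = 0,
                                          junctionFraction = 0), seed = 9L)
    expect_equal(length(rr0$reads), 0L)

    gapAll <- sim$truth
    gapAll$gapped <- TRUE
    expect_error(generateReads(gapAll, chrom, cfg, seed = 9L),
                 "no two-exon gene")
})
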