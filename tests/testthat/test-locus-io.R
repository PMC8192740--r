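test_that("readGenome normalizes case, maps non-ACGTN to N, rejects bad input", {
    tf <- tempfile(fileext = ".fa")
    writeLines(c(">chr1", "acgt"), tf)
    g <- readGenome(tf)
    expect_equal(as.character(g[["chr1"]]), "ACGT")

    writeLines(c(">chr1", "ACRT"), tf)
    expect_warning(g <- readGenome(tf), "replaced by N")
    expect_equal(as.character(g[["chr1"]]), "ACNT")

    writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), tf)
    expect_error(readGenome(tf), "duplicate")

    writeLines(character(0L), tf)
    expect_error(readGenome(tf), "empty")
})

test_that("genome FASTA round trip is exact", {
    set.seed(101)
    g <- Biostrings::DNAStringSet(c(chrA = rand_dna(500), chrB = rand_dna(73)))
    tf <- tempfile(fileext = ".fa")
    writeGenome(g, tf)
    g2 <- readGenome(tf)
    expect_identical(as.character(g2), as.character(g))
})

test_that("extractLocus spans anchors inclusively and computes length", {
    set.seed(102)
    chrom <- rand_dna(10000)
    genes <- data.frame(
        gene_id = c("g1", "g2"), seq_id = "chr1",
        start = c(1000L, 9000L), end = c(1500L, 9600L), strand = "+",
        symbol = c("S100A9", "S100A11"), stringsAsFactors = FALSE)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    loc <- extractLocus(genome, genes, "S100A9", "S100A11")
    expect_equal(length(loc), 8600L)
    expect_equal(loc@orientation, "+")
    expect_equal(as.character(locusSequence(loc)), substr(chrom, 1001, 9600))
    expect_equal(loc@anchorLeftRange, c(0L, 500L))
    expect_equal(loc@anchorRightRange, c(8000L, 8600L))
})

test_that("swapped anchors reverse-complement the locus", {
    set.seed(103)
    chrom <- rand_dna(10000)
    genes <- data.frame(
        gene_id = c("g1", "g2"), seq_id = "chr1",
        start = c(9000L, 1000L), end = c(9600L, 1500L), strand = "+",
        symbol = c("S100A9", "S100A11"), stringsAsFactors = FALSE)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    loc <- extractLocus(genome, genes, "S100A9", "S100A11")
    expect_equal(length(loc), 8600L)
    expect_equal(loc@orientation, "-")
    expect_equal(as.character(locusSequence(loc)),
                 revcomp(substr(chrom, 1001, 9600)))
    # left anchor precedes right anchor in locus frame
    expect_lt(loc@anchorLeftRange[1L], loc@anchorRightRange[1L])
})

test_that("extractLocus is orientation invariant", {
    set.seed(104)
    chrom <- rand_dna(6000)
    L <- nchar(chrom)
    genes <- data.frame(
        gene_id = c("g1", "g2"), seq_id = "chr1",
        start = c(500L, 5000L), end = c(800L, 5400L), strand = "+",
        symbol = c("S100A9", "S100A11"), stringsAsFactors = FALSE)
    loc1 <- extractLocus(Biostrings::DNAStringSet(c(chr1 = chrom)), genes,
                         "S100A9", "S100A11")
    # reverse-complement the whole chromosome and remap coordinates
    genes2 <- genes
    genes2$start <- L - genes$end
    genes2$end <- L - genes$start
    loc2 <- extractLocus(Biostrings::DNAStringSet(c(chr1 = revcomp(chrom))),
                         genes2, "S100A9", "S100A11")
    expect_equal(as.character(locusSequence(loc2)),
                 as.character(locusSequence(loc1)))
})

test_that("anchor errors are specific", {
    genes <- data.frame(
        gene_id = c("g1", "g2"), seq_id = c("chr1", "chr2"),
        start = c(0L, 0L), end = c(100L, 100L), strand = "+",
        symbol = c("S100A9", "S100A11"), stringsAsFactors = FALSE)
    genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(200),
                                         chr2 = rand_dna(200)))
    expect_error(extractLocus(genome, genes, "S100A9", "S100A11"),
                 "discontiguous")
    expect_error(extractLocus(genome, genes, "S100A9", "S100A8"),
                 "anchor not found")
})

test_that("gap track exactly covers maximal N-runs above threshold", {
    set.seed(105)
    for (rep in 1:20) {
        n <- 400L
        v <- sample(ACGT, n, replace = TRUE)
        nruns <- sample(0:3, 1L)
        for (k in seq_len(nruns)) {
            st <- sample(n - 30L, 1L)
            len <- sample(c(3L, 9L, 10L, 15L, 25L), 1L)
            v[st:(st + len - 1L)] <- "N"
        }
        s <- paste(v, collapse = "")
        gaps <- edcscan:::.gapTrack(s, 10L)
        # scanning oracle over the character vector
        r <- rle(strsplit(s, "")[[1L]] == "N")
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths
        keep <- r$values & r$lengths >= 10L
        exp <- cbind(start = starts[keep], end = ends[keep])
        expect_equal(unname(gaps), unname(exp))
    }
})

test_that("gene maps use GFF3 1-based and BED 0-based conventions", {
    set.seed(106)
    tg <- toy_genome(rand_dna(1000))
    loc <- extractLocus(tg$genome, tg$genes, "S100A9", "S100A11")
    calls <- data.frame(gene_id = c("gA", "gB"),
                        start = c(0L, 350L), end = c(300L, 700L),
                        strand = "+", status = c(NA, "disrupted_stop"),
                        stringsAsFactors = FALSE)
    gff <- tempfile(fileext = ".gff3"); bed <- tempfile(fileext = ".bed")
    writeGeneMap(loc, calls, gff, bed)
    glines <- readLines(gff)
    expect_equal(glines[1L], "##gff-version 3")
    f <- strsplit(grep("\tgene\t", glines, value = TRUE), "\t")
    expect_equal(as.integer(f[[1L]][4:5]), c(1L, 300L))
    expect_match(f[[2L]][9L], "status=disrupted_stop")
    blines <- readLines(bed)
    bf <- strsplit(blines, "\t")
    expect_equal(as.integer(bf[[1L]][2:3]), c(0L, 300L))
    expect_match(bf[[2L]][4L], "disrupted")

    # empty call set: valid files, GFF3 header retained
    empty <- calls[0L, ]
    writeGeneMap(loc, empty, gff, bed)
    expect_equal(readLines(gff)[1L], "##gff-version 3")
    expect_length(readLines(bed), 0L)

    bad <- data.frame(gene_id = "gX", start = -5L, end = 10L, strand = "+",
                      stringsAsFactors = FALSE)
    expect_error(writeGeneMap(loc, bad, gff, bed), "bounds")
})

test_that("markUnknown flags gap overlaps with exact boundaries", {
    gaps <- cbind(start = c(100L, 300L), end = c(150L, 320L))
    expect_equal(markUnknown(c(120L, 130L), gaps), "unknown")
    expect_equal(markUnknown(c(90L, 101L), gaps), "unknown")
    expect_equal(markUnknown(c(150L, 200L), gaps), "ok")   # 1 bp beyond
    expect_equal(markUnknown(c(0L, 100L), gaps), "ok")     # half-open abuts
    empty <- gaps[0L, , drop = FALSE]
    expect_equal(markUnknown(c(0L, 1000L), empty), "ok")
})

test_that("annotation GFF3 written by the simulator reads back identically", {
    set.seed(107)
    ann <- data.frame(gene_id = c("x1", "x2"), seq_id = "chr1",
                      start = c(10L, 400L), end = c(200L, 900L),
                      strand = "+", symbol = c("S100A9", "S100A11"),
                      stringsAsFactors = FALSE)
    tf <- tempfile(fileext = ".gff3")
    writeAnnotationGff3(ann, tf)
    back <- readAnnotation(tf)
    expect_equal(back$start, ann$start)
    expect_equal(back$end, ann$end)
    expect_equal(back$symbol, ann$symbol)
})
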