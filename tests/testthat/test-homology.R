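test_that("six-frame translation follows the standard code and the N rule", {
    f <- sixFrameTranslate("ATGGCC")
    expect_equal(f[["+1"]]$protein, "MA")
    expect_equal(f[["-1"]]$protein, "GH")  # translation of revcomp GGCCAT
    expect_equal(sixFrameTranslate("ATNGCC")[["+1"]]$protein, "XA")
    expect_equal(sixFrameTranslate("ATGGC")[["+1"]]$protein, "M")
    expect_error(sixFrameTranslate(""), "empty")
})

test_that("frame coordinate mapping is monotone and re-translates", {
    set.seed(201)
    s <- rand_dna(333)
    L <- nchar(s)
    frames <- sixFrameTranslate(s)
    for (fr in frames) {
        np <- nchar(fr$protein)
        if (np < 2L) next
        pos <- sort(sample(np, min(10L, np)))
        prev_nt <- -1L
        for (p in pos) {
            nt <- edcscan:::.frameToLocus(fr$frame, p, p, L)
            expect_equal(nt[2L] - nt[1L], 3L)
            codon <- substr(s, nt[1L] + 1L, nt[2L])
            if (fr$frame < 0L) codon <- revcomp(codon)
            expect_equal(tr_frame1(codon),
                         substr(fr$protein, p, p))
            if (fr$frame > 0L) expect_gt(nt[1L], prev_nt)
            prev_nt <- nt[1L]
        }
    }
})

test_that("translated search recovers an exactly encoded query at its self-score", {
    set.seed(202)
    q <- rand_protein(60)
    payload <- paste0(rand_dna(300), back_translate(q), rand_dna(300))
    frames <- sixFrameTranslate(payload)
    hits <- translatedSearch(q, "q", frames)
    expect_gte(nrow(hits), 1L)
    top <- hits[1L, ]
    expect_equal(top$q_start, 1L)
    expect_equal(top$q_end, nchar(q))
    expect_equal(top$score, oracle_sw(q, q))
    # score equals full Smith-Waterman against the hit frame
    fr <- frames[[paste0(ifelse(top$frame > 0, "+", "-"), abs(top$frame))]]
    expect_equal(top$score, oracle_sw(q, fr$protein))
})

test_that("search scores are invariant under reverse-complementing the locus", {
    set.seed(203)
    q <- rand_protein(50)
    payload <- paste0(rand_dna(200), back_translate(q), rand_dna(200))
    h1 <- translatedSearch(q, "q", sixFrameTranslate(payload))
    h2 <- translatedSearch(q, "q", sixFrameTranslate(revcomp(payload)))
    expect_equal(h1$score[1L], h2$score[1L])
    expect_equal(sign(h2$frame[1L]), -sign(h1$frame[1L]))  # opposite strands
    # same locus interval after mirroring
    L <- nchar(payload)
    expect_equal(c(L - h2$s_end[1L], L - h2$s_start[1L]),
                 c(h1$s_start[1L], h1$s_end[1L]))
})

test_that("no signal and degenerate queries are handled", {
    frames <- sixFrameTranslate(strrep("A", 600))
    hits <- translatedSearch("MKLV", "q", frames,
                             searchParams(word = 3))
    expect_equal(nrow(hits), 0L)
    expect_warning(h <- translatedSearch("MK", "q", frames), "shorter")
    expect_equal(nrow(h), 0L)
})

test_that("hit scores equal exhaustive Smith-Waterman on implanted homologs", {
    set.seed(204)
    for (rep in 1:20) {
        q <- rand_protein(sample(40:120, 1L))
        hom <- mutate_protein(q, 0.15)
        payload <- paste0(rand_dna(sample(200:800, 1L)),
                          back_translate(hom),
                          rand_dna(sample(200:800, 1L)))
        frames <- sixFrameTranslate(payload)
        hits <- translatedSearch(q, "q", frames)
        expect_gte(nrow(hits), 1L)
        oracle <- max(vapply(frames, function(fr)
            oracle_sw(q, fr$protein), numeric(1L)))
        expect_equal(hits$score[1L], oracle)
    }
})

test_that("iterative closure chains through newly derived proteins", {
    set.seed(205)
    X <- rand_protein(80)
    Y <- paste(sample(AA20, 80, replace = TRUE), collapse = "")
    protA <- paste0(X, Y)                    # gene A: X + Y
    protB <- paste0("M", mutate_protein(paste0("M", Y), 0.08))  # gene B ~ Y
    protB <- substr(protB, 1, 81)
    geneA <- paste0("ATG", substr(back_translate(protA), 4,
                                  nchar(protA) * 3), "TAA")
    geneB <- paste0(back_translate(protB), "TAA")
    payload <- paste0(rand_dna(300), geneA, rand_dna(400), geneB,
                      rand_dna(300))
    tg <- toy_genome(payload)
    loc <- extractLocus(tg$genome, tg$genes, "S100A9", "S100A11")
    p <- geneModelParams(minCdsLength = 150L)
    # seed query only matches the X half of gene A
    res <- iterativeClosure(c(seed = X), loc, searchParams(),
                            maxRounds = 4L, orfParams = p)
    expect_gte(res$rounds, 2L)
    covered <- function(ntStart) any(res$hits$s_start < ntStart + 30 &
                                     res$hits$s_end > ntStart)
    offA <- 300L + regexpr(substr(geneA, 1, 60), payload, fixed = TRUE)
    expect_true(any(res$hits$s_end - res$hits$s_start > 0))
    # gene B is only reachable through A's protein
    posB <- as.integer(regexpr(substr(geneB, 1, 60), payload, fixed = TRUE))
    start_locus_B <- tg$payloadStart - loc@start + posB - 1L
    expect_true(any(res$hits$s_start < start_locus_B + 200 &
                    res$hits$s_end > start_locus_B))

    # closure terminates immediately when there is nothing new to find
    res1 <- iterativeClosure(c(seed = rand_protein(60)), loc,
                             searchParams(), maxRounds = 4L, orfParams = p)
    expect_lte(res1$rounds, 1L)

    # order invariance of the final hit set
    q2 <- c(q1 = X, q2 = protB)
    ra <- iterativeClosure(q2, loc, searchParams(), 4L, p)
    rb <- iterativeClosure(q2[c(2L, 1L)], loc, searchParams(), 4L, p)
    key <- function(h) paste(h$frame, h$s_start, h$s_end, sep = ":")
    expect_setequal(key(ra$hits), key(rb$hits))
})
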