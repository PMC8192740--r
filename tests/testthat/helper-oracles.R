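# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different machinery than the implementation:
# Biostrings::pairwiseAlignment for alignment scores, regex for motifs,
# exhaustive enumeration for parsimony and spliced placements.

AA20 <- Biostrings::AA_STANDARD
ACGT <- c("A", "C", "G", "T")

rand_protein <- function(n, letters = AA20) {
    paste0("M", paste(sample(letters, n - 1L, replace = TRUE), collapse = ""))
}

rand_dna <- function(n) {
    paste(sample(ACGT, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(p, rate) {
    v <- strsplit(p, "")[[1L]]
    k <- rbinom(1L, length(v) - 1L, rate)
    if (k > 0L) {
        pos <- sample(seq(2L, length(v)), k)
        for (i in pos) v[i] <- sample(setdiff(AA20, v[i]), 1L)
    }
    paste(v, collapse = "")
}

mutate_dna <- function(d, rate) {
    v <- strsplit(d, "")[[1L]]
    k <- rbinom(1L, length(v), rate)
    if (k > 0L) {
        pos <- sample(length(v), k)
        for (i in pos) v[i] <- sample(setdiff(ACGT, v[i]), 1L)
    }
    paste(v, collapse = "")
}

back_translate <- function(p) edcscan:::.backTranslate(p)

revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# affine-gap local alignment oracle (independent implementation)
oracle_sw <- function(a, b, gapOpen = 11, gapExt = 1) {
    Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = edcSubstitutionMatrix(),
        gapOpening = gapOpen, gapExtension = gapExt,
        type = "local", scoreOnly = TRUE)
}

# translate frame-1 of a nucleotide string, partial codon dropped
tr_frame1 <- function(s) {
    n <- nchar(s) - (nchar(s) %% 3L)
    if (n < 3L) return("")
    edcscan:::.translateStr(substr(s, 1L, n))
}

# Brute-force single-frameshift oracle: every single-nucleotide deletion and
# every single-nucleotide insertion (penalized) plus the unedited sequence,
# translated in all three frames and scored by a linear-gap local alignment.
oracle_fs <- function(ref, dna, fsPen = 15, gapRes = 13) {
    n <- nchar(dna)
    variants <- dna; pen <- 0
    for (p in seq_len(n)) {
        variants <- c(variants,
                      paste0(substr(dna, 1L, p - 1L), substr(dna, p + 1L, n)))
        pen <- c(pen, fsPen)
    }
    for (p in 0:n) for (b in ACGT) {
        variants <- c(variants,
                      paste0(substr(dna, 1L, p), b, substr(dna, p + 1L, n)))
        pen <- c(pen, fsPen)
    }
    subj <- character(0L); penAll <- numeric(0L)
    for (i in seq_along(variants)) for (f in 1:3) {
        t <- tr_frame1(substr(variants[i], f, nchar(variants[i])))
        if (nchar(t) > 0L) { subj <- c(subj, t); penAll <- c(penAll, pen[i]) }
    }
    sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(subj), Biostrings::AAString(ref),
        substitutionMatrix = edcSubstitutionMatrix(),
        gapOpening = 0, gapExtension = gapRes,
        type = "local", scoreOnly = TRUE)
    max(sc - penAll)
}

# Brute-force spliced placement oracle: minimal mismatch count over all
# contiguous and two-block placements (blocks >= minAnchor, gap within
# intron bounds). Returns Inf when nothing fits under maxMismatch.
oracle_splice <- function(read, locus, minAnchor, maxMismatch, intronMin,
                          intronMax) {
    rc <- strsplit(read, "")[[1L]]
    lc <- strsplit(locus, "")[[1L]]
    r <- length(rc); L <- length(lc)
    best <- Inf
    for (i in seq_len(L - r + 1L)) {
        mm <- sum(lc[i:(i + r - 1L)] != rc)
        if (mm < best) best <- mm
    }
    if (r >= 2L * minAnchor) {
        for (s in seq.int(minAnchor, r - minAnchor)) {
            nL <- L - s + 1L
            lm <- rep(0L, nL)
            for (k in seq_len(s))
                lm <- lm + (lc[k:(nL + k - 1L)] != rc[k])
            rlen <- r - s
            nR <- L - rlen + 1L
            rm <- rep(0L, nR)
            for (k in seq_len(rlen))
                rm <- rm + (lc[k:(nR + k - 1L)] != rc[s + k])
            for (i in seq_len(nL)) {
                g <- i + s                      # 1-based intron start
                jLo <- g + intronMin; jHi <- min(g + intronMax, nR)
                if (jLo > jHi) next
                cand <- lm[i] + min(rm[jLo:jHi])
                if (cand < best) best <- cand
            }
        }
    }
    if (best > maxMismatch) Inf else best
}

# ---- parsimony oracles ------------------------------------------------------

# exhaustive Dollo: minimize losses over ancestral assignments (and unknown
# tips) constrained to exactly one gain (root state 1 counts as the origin)
oracle_dollo <- function(tree, states) {
    nt <- ape::Ntip(tree); nn <- ape::Nnode(tree)
    edges <- tree$edge
    tipState <- states[tree$tip.label]
    unknown <- which(tipState == "?")
    fixed <- ifelse(tipState == "P", 1L, 0L)
    if (!any(tipState == "P")) return(0L)
    bestLoss <- Inf
    nInt <- nn
    for (ia in 0:(2^nInt - 1L)) {
        intStates <- as.integer(intToBits(ia))[seq_len(nInt)]
        nu <- length(unknown)
        for (ua in 0:(max(1L, 2^nu) - 1L)) {
            st <- fixed
            if (nu > 0L)
                st[unknown] <- as.integer(intToBits(ua))[seq_len(nu)]
            full <- c(st, intStates)
            gains <- full[nt + 1L]   # origin at root
            losses <- 0L
            for (k in seq_len(nrow(edges))) {
                p <- full[edges[k, 1L]]; c <- full[edges[k, 2L]]
                if (p == 0L && c == 1L) gains <- gains + 1L
                if (p == 1L && c == 0L) losses <- losses + 1L
            }
            if (gains == 1L && losses < bestLoss) bestLoss <- losses
            if (nu == 0L) break
        }
    }
    bestLoss
}

# exhaustive Fitch: minimal state changes over ancestral assignments
oracle_fitch <- function(tree, states) {
    nt <- ape::Ntip(tree); nn <- ape::Nnode(tree)
    edges <- tree$edge
    tipState <- states[tree$tip.label]
    unknown <- which(tipState == "?")
    fixed <- ifelse(tipState == "P", 1L, 0L)
    best <- Inf
    for (ia in 0:(2^nn - 1L)) {
        intStates <- as.integer(intToBits(ia))[seq_len(nn)]
        nu <- length(unknown)
        for (ua in 0:(max(1L, 2^nu) - 1L)) {
            st <- fixed
            if (nu > 0L)
                st[unknown] <- as.integer(intToBits(ua))[seq_len(nu)]
            full <- c(st, intStates)
            ch <- sum(full[edges[, 1L]] != full[edges[, 2L]])
            if (ch < best) best <- ch
            if (nu == 0L) break
        }
    }
    best
}

# the three rooted binary shapes on five tips (labeled representatives)
five_tip_shapes <- function() {
    lapply(c("((((A,B),C),D),E);",
             "(((A,B),C),(D,E));",
             "(((A,B),(C,D)),E);"),
           function(s) ape::read.tree(text = s))
}

all_patterns <- function(taxa, states = c("P", "A", "?")) {
    g <- expand.grid(rep(list(states), length(taxa)),
                     stringsAsFactors = FALSE)
    colnames(g) <- taxa
    g
}

# ---- fixture builders -------------------------------------------------------

# a tiny genome with two anchor genes and arbitrary payload between them
toy_genome <- function(payload, pad = 200L) {
    left <- rand_dna(pad)
    right <- rand_dna(pad)
    anchorL <- rand_dna(300L)
    anchorR <- rand_dna(300L)
    chrom <- paste0(left, anchorL, payload, anchorR, right)
    genes <- data.frame(
        gene_id = c("a9", "a11"), seq_id = "chr1",
        start = c(pad, pad + 300L + nchar(payload)),
        end = c(pad + 300L, pad + 300L + nchar(payload) + 300L),
        strand = "+", symbol = c("S100A9", "S100A11"),
        stringsAsFactors = FALSE)
    list(genome = Biostrings::DNAStringSet(c(chr1 = chrom)), genes = genes,
         payloadStart = pad + 300L)
}

fake_hit <- function(sStart, sEnd, frame = 1L, queryId = "q") {
    L <- NA
    data.frame(query_id = queryId, frame = frame,
               q_start = 1L, q_end = (sEnd - sStart) %/% 3L,
               aa_start = 1L, aa_end = (sEnd - sStart) %/% 3L,
               s_start = sStart, s_end = sEnd, score = 100,
               stringsAsFactors = FALSE)
}
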