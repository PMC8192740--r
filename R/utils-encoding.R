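# Residue/nucleotide encodings shared by the Rcpp kernels.
# Protein codes index the substitution matrix rows; nucleotides are
# A=0, C=1, G=2, T=3, N=4.

.pkgenv <- new.env(parent = emptyenv())

#' Protein substitution matrix used for all local alignments
#'
#' BLOSUM62 with the stop-codon row and column overridden to -4 against every
#' residue, so that translated-search hits can cross pseudogene stop codons
#' during discovery while still being penalized.
#'
#' @return A numeric matrix with amino-acid dimnames (including `*` and `X`).
#' @export
edcSubstitutionMatrix <- function() {
    if (is.null(.pkgenv$submat)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        m <- e$BLOSUM62
        storage.mode(m) <- "double"
        m["*", ] <- -4
        m[, "*"] <- -4
        .pkgenv$submat <- m
    }
    .pkgenv$submat
}

.aaAlphabet <- function() rownames(edcSubstitutionMatrix())

# Integer codes (0-based) for a protein string; unknown letters map to X.
.encodeAA <- function(x) {
    alpha <- .aaAlphabet()
    v <- match(strsplit(as.character(x), "", fixed = TRUE)[[1L]], alpha)
    v[is.na(v)] <- match("X", alpha)
    as.integer(v - 1L)
}

.dnaLut <- function() {
    if (is.null(.pkgenv$dnalut)) {
        lut <- rep(4L, 256L)
        lut[utf8ToInt("A") + 1L] <- 0L
        lut[utf8ToInt("C") + 1L] <- 1L
        lut[utf8ToInt("G") + 1L] <- 2L
        lut[utf8ToInt("T") + 1L] <- 3L
        lut[utf8ToInt("a") + 1L] <- 0L
        lut[utf8ToInt("c") + 1L] <- 1L
        lut[utf8ToInt("g") + 1L] <- 2L
        lut[utf8ToInt("t") + 1L] <- 3L
        .pkgenv$dnalut <- lut
    }
    .pkgenv$dnalut
}

.encodeDNA <- function(x) {
    .dnaLut()[utf8ToInt(as.character(x)) + 1L]
}

# Codon lookup for the Rcpp kernels: index 16*b1 + 4*b2 + b3 (+1 in R) maps
# to the 0-based residue code of the encoded amino acid, standard code.
.codonTable <- function() {
    if (is.null(.pkgenv$codontab)) {
        alpha <- .aaAlphabet()
        bases <- c("A", "C", "G", "T")
        tab <- integer(64L)
        for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
            codon <- paste0(bases[a + 1L], bases[b + 1L], bases[cc + 1L])
            aa <- Biostrings::GENETIC_CODE[[codon]]
            tab[16L * a + 4L * b + cc + 1L] <- match(aa, alpha) - 1L
        }
        .pkgenv$codontab <- tab
    }
    .pkgenv$codontab
}

.xCode <- function() match("X", .aaAlphabet()) - 1L
.stopCode <- function() match("*", .aaAlphabet()) - 1L

# Reverse codon table for uniform-synonymous back-translation.
.reverseCodonTable <- function() {
    if (is.null(.pkgenv$revcodon)) {
        gc <- Biostrings::GENETIC_CODE
        .pkgenv$revcodon <- split(names(gc), unname(gc))
    }
    .pkgenv$revcodon
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a nucleotide string in frame 1; codons containing anything other
# than A/C/G/T become X; trailing partial codon dropped.
.translateStr <- function(x) {
    n <- nchar(x)
    n <- n - n %% 3L
    if (n < 3L) return("")
    v <- .encodeDNA(substr(x, 1L, n))
    b1 <- v[seq(1L, n, 3L)]; b2 <- v[seq(2L, n, 3L)]; b3 <- v[seq(3L, n, 3L)]
    tab <- .codonTable()
    alpha <- .aaAlphabet()
    aa <- ifelse(b1 > 3L | b2 > 3L | b3 > 3L, .xCode(),
                 tab[16L * b1 + 4L * b2 + b3 + 1L])
    paste(alpha[aa + 1L], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
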