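# Amino-acid composition, degenerate motif scanning, cysteine duplets, and
# the SPRR subtype evidence bundle.

#' Amino-acid composition of a protein
#'
#' Per-residue fractions over the 20 standard amino acids, as a ProtParam-style
#' composition profile.
#'
#' @param protein protein sequence (character or [Biostrings::AAString]);
#'   must be non-empty and contain only standard residues.
#' @return Named numeric vector of length 20 summing to 1, with attribute
#'   `length` (the protein length).
#' @examples
#' aaComposition("QNQN")[c("Q", "N")]
#' @export
aaComposition <- function(protein) {
    protein <- as.character(protein)
    if (nchar(protein) == 0L) stop("empty protein")
    chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
    std <- Biostrings::AA_STANDARD
    if (!all(chars %in% std))
        stop("non-standard residue(s): ",
             paste(unique(chars[!chars %in% std]), collapse = ", "))
    counts <- table(factor(chars, levels = std))
    out <- as.numeric(counts) / length(chars)
    names(out) <- std
    attr(out, "length") <- length(chars)
    out
}

#' Scan a protein for a degenerate motif
#'
#' Reports every (possibly overlapping) start position where each non-X
#' pattern letter equals the protein letter. `X` in the pattern matches any
#' residue; `X` in the protein (from N-containing codons) matches only `X`
#' in the pattern, never a concrete letter, so ambiguous sequence cannot
#' inflate motif counts.
#'
#' @param protein protein sequence.
#' @param pattern motif over amino-acid letters plus `X` (e.g. the
#'   SPRR-cetacean motif `"QQCKQXCXP"`).
#' @return Sorted integer vector of 0-based start positions.
#' @examples
#' scanMotif("GQQCKQQCQPSQQCKQPCPP", "QQCKQXCXP")  # 1, 11
#' @export
scanMotif <- function(protein, pattern = "QQCKQXCXP") {
    protein <- as.character(protein)
    pattern <- as.character(pattern)
    stopifnot(nchar(pattern) >= 1L)
    n <- nchar(protein); k <- nchar(pattern)
    if (n < k) return(integer(0L))
    pv <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    sv <- strsplit(protein, "", fixed = TRUE)[[1L]]
    nStart <- n - k + 1L
    ok <- rep(TRUE, nStart)
    for (i in seq_len(k)) {
        if (pv[i] == "X") next
        ok <- ok & sv[seq.int(i, i + nStart - 1L)] == pv[i]
    }
    which(ok) - 1L
}

#' Count cysteine duplets
#'
#' Number of maximal runs of C of length at least 2, each counted once
#' (the distinctive SPRR5 feature).
#'
#' @param protein protein sequence (non-empty).
#' @return Integer count.
#' @examples
#' cysDuplets("ACCG")   # 1
#' cysDuplets("CCC")    # 1
#' cysDuplets("CACAC")  # 0
#' @export
cysDuplets <- function(protein) {
    protein <- as.character(protein)
    stopifnot(nchar(protein) > 0L)
    r <- rle(strsplit(protein, "", fixed = TRUE)[[1L]])
    sum(r$values == "C" & r$lengths >= 2L)
}

#' SPRR subtype evidence bundle
#'
#' Deterministic bundle of the composition, motif and duplet features used to
#' characterize SPRR subtypes: proline fraction (and a proline-rich flag),
#' cysteine duplet count (SPRR5 evidence when >= 2), count of the
#' SPRR-cetacean `QQCKQXCXP` motif (SPRRc evidence when >= 2 copies), and the
#' glutamine fraction (involucrin-style Q enrichment).
#'
#' @param protein protein sequence.
#' @param motif the SPRRc motif pattern.
#' @param pRichMin proline fraction above which a protein counts as P-rich.
#' @return list with `p_fraction`, `p_rich`, `cys_duplets`, `motif_count`,
#'   `q_fraction`, `sprrc` (logical) and `sprr5` (logical).
#' @export
sprrSubtypeEvidence <- function(protein, motif = "QQCKQXCXP",
                                pRichMin = 0.15) {
    protein <- as.character(protein)
    stopifnot(nchar(protein) > 0L)
    chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
    pFrac <- mean(chars == "P")
    qFrac <- mean(chars == "Q")
    dup <- cysDuplets(protein)
    mot <- length(scanMotif(protein, motif))
    list(p_fraction = pFrac, p_rich = pFrac >= pRichMin,
         cys_duplets = dup, motif_count = mot, q_fraction = qFrac,
         sprrc = mot >= 2L, sprr5 = dup >= 2L)
}

#' Feature table for a set of proteins
#'
#' @param proteins named protein vector.
#' @param motif the SPRRc motif pattern.
#' @return data.frame with one row per protein: length, P/Q/G/S/C fractions,
#'   cysteine duplets, motif count and the SPRR subtype evidence flags.
#' @export
proteinFeatureTable <- function(proteins, motif = "QQCKQXCXP") {
    p <- setNames(as.character(proteins), names(proteins))
    rows <- lapply(names(p), function(id) {
        x <- p[[id]]
        chars <- strsplit(x, "", fixed = TRUE)[[1L]]
        ev <- sprrSubtypeEvidence(x, motif)
        data.frame(gene_id = id, length = nchar(x),
                   p_fraction = ev$p_fraction, q_fraction = ev$q_fraction,
                   g_fraction = mean(chars == "G"),
                   s_fraction = mean(chars == "S"),
                   c_fraction = mean(chars == "C"),
                   cys_duplets = ev$cys_duplets,
                   motif_count = ev$motif_count,
                   p_rich = ev$p_rich, sprrc = ev$sprrc, sprr5 = ev$sprr5,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
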