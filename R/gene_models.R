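# From homology hits to SEDC gene models (two-exon anatomy) and coding
# integrity classification (intact / pseudogenized / truncated).

#' Gene-model parameters
#'
#' Defaults: minimal CDS length 150 nt; ORF extension window 300 nt upstream
#' of the hit; acceptor search (5'-UTR) within 300 nt of the start codon;
#' canonical GT/AG introns of 50-20,000 nt; TATA motif `TATAWA` with the
#' transcription start placed 25 nt after the TATA box; exon 1 of 20-300 nt;
#' integrity thresholds: coverage >= 0.9 intact, lesion-free coverage < 0.9
#' truncated, frameshift penalty 15, absent below score 40.
#'
#' @param minCdsLength minimal called CDS length in nt.
#' @param extWindow how far upstream of a hit the start codon is searched.
#' @param maxUtr maximal acceptor-to-ATG distance (5'-UTR length).
#' @param intronMin,intronMax intron length bounds.
#' @param tataOffset nt between the end of the TATA box and the
#'   transcription start (exon 1 start).
#' @param exon1Min,exon1Max,exon1Default exon 1 length bounds and the
#'   fallback length used when no TATA box is found.
#' @param coverageIntact,coverageTruncated reference-coverage thresholds.
#' @param fsPenalty frameshift penalty in the integrity aligner.
#' @param absentThreshold minimal alignment score below which a candidate is
#'   classified absent.
#' @param gapResidue linear per-residue penalty for codon-level indels in the
#'   integrity aligner.
#' @return A named parameter list.
#' @export
geneModelParams <- function(minCdsLength = 150L, extWindow = 300L,
                            maxUtr = 300L, intronMin = 50L,
                            intronMax = 20000L, tataOffset = 25L,
                            exon1Min = 20L, exon1Max = 300L,
                            exon1Default = 100L, coverageIntact = 0.9,
                            coverageTruncated = 0.6, fsPenalty = 15,
                            absentThreshold = 40, gapResidue = 13) {
    list(minCdsLength = as.integer(minCdsLength),
         extWindow = as.integer(extWindow), maxUtr = as.integer(maxUtr),
         intronMin = as.integer(intronMin), intronMax = as.integer(intronMax),
         tataOffset = as.integer(tataOffset), exon1Min = as.integer(exon1Min),
         exon1Max = as.integer(exon1Max),
         exon1Default = as.integer(exon1Default),
         coverageIntact = coverageIntact,
         coverageTruncated = coverageTruncated, fsPenalty = fsPenalty,
         absentThreshold = absentThreshold, gapResidue = gapResidue)
}

.stopCodons <- c("TAA", "TAG", "TGA")

# Coding-orientation sequence and hit start for a hit (locus frame).
.codingFrame <- function(locus, hit) {
    seqchar <- as.character(locusSequence(locus))
    L <- nchar(seqchar)
    if (hit$frame > 0L)
        list(seq = seqchar, a0 = hit$s_start, strand = "+", L = L)
    else
        list(seq = .revcomp(seqchar), a0 = L - hit$s_end, strand = "-", L = L)
}

.toLocusIv <- function(iv, strand, L) {
    if (is.null(iv)) return(NULL)
    if (strand == "+") as.integer(iv) else as.integer(c(L - iv[2L], L - iv[1L]))
}

#' Call an open reading frame from a homology hit
#'
#' Extends the hit's reading frame to a start codon at or upstream of the hit
#' start (never across an in-frame stop, within `extWindow` nt) and to the
#' nearest in-frame stop downstream. Among candidate ATGs the one maximizing
#' the local-alignment score against the query is chosen; ties go to the
#' longest CDS.
#'
#' @param locus a [Locus-class].
#' @param hit one row of a hit table from [translatedSearch()].
#' @param query the query protein the hit was found with.
#' @param params [geneModelParams()].
#' @return list with `cds` (`integer(2)` 0-based half-open locus interval
#'   including the stop codon), `strand`, `protein` (without the stop) and
#'   `codingStart`; or `cds = NULL` with a `reason` when no acceptable ORF
#'   exists.
#' @export
callOrf <- function(locus, hit, query, params = geneModelParams()) {
    cf <- .codingFrame(locus, hit)
    phase <- cf$a0 %% 3L
    n <- nchar(cf$seq)
    starts <- seq.int(phase + 1L, n - 2L, by = 3L)
    codons <- substring(cf$seq, starts, starts + 2L)
    hitIdx <- (cf$a0 - phase) %/% 3L + 1L   # codon index of hit start

    lo <- max(1L, hitIdx - params$extWindow %/% 3L)
    upIdx <- seq.int(hitIdx, lo)
    isStop <- codons[upIdx] %in% .stopCodons
    if (any(isStop)) upIdx <- upIdx[seq_len(which(isStop)[1L] - 1L)]
    cand <- upIdx[codons[upIdx] == "ATG"]
    if (!length(cand))
        return(list(cds = NULL, reason = "no ATG found within extension window"))

    stopIdxAll <- which(codons %in% .stopCodons)
    qcode <- .encodeAA(as.character(query))
    mat <- edcSubstitutionMatrix()
    best <- NULL
    for (atgIdx in cand) {
        stopIdx <- stopIdxAll[stopIdxAll >= atgIdx]
        if (!length(stopIdx)) next
        stopIdx <- stopIdx[1L]
        prot <- paste(codons[atgIdx:(stopIdx - 1L)], collapse = "")
        prot <- .translateStr(prot)
        sc <- sw_align_cpp(qcode, .encodeAA(prot), mat, 11, 1, FALSE)$score
        len <- stopIdx - atgIdx
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && len > best$len)) {
            best <- list(atgIdx = atgIdx, stopIdx = stopIdx, prot = prot,
                         sc = sc, len = len)
        }
    }
    if (is.null(best))
        return(list(cds = NULL, reason = "open-ended ORF"))
    cdsStart <- starts[best$atgIdx] - 1L            # 0-based coding coords
    cdsEnd <- starts[best$stopIdx] + 2L             # includes stop codon
    if (cdsEnd - cdsStart < params$minCdsLength)
        return(list(cds = NULL, reason = "CDS shorter than minimum length"))
    list(cds = .toLocusIv(c(cdsStart, cdsEnd), cf$strand, cf$L),
         strand = cf$strand, protein = best$prot,
         codingStart = cdsStart, reason = NULL)
}

#' Find the upstream noncoding exon of a SEDC gene call
#'
#' Searches upstream of the CDS for the canonical SEDC promoter anatomy: an
#' acceptor AG within `maxUtr` nt of the start codon (the one closest to the
#' CDS on ties), then a donor GT upstream within the intron length bounds
#' (closest to the acceptor), then a `TATAWA` box upstream of the putative
#' exon 1. If no consistent two-exon structure is found, a single-exon model
#' is reported with the TATA box searched directly upstream of the CDS.
#' Absence of structure is a reported outcome, not an error.
#'
#' @param locus a [Locus-class].
#' @param cds CDS interval (`integer(2)`, 0-based half-open, locus frame,
#'   stop codon included) from [callOrf()].
#' @param strand coding strand of the call.
#' @param geneId identifier for the resulting model.
#' @param protein translated CDS recorded in the model.
#' @param params [geneModelParams()].
#' @return A [SedcGeneModel-class].
#' @export
findUpstreamExon <- function(locus, cds, strand = "+", geneId = "gene",
                             protein = "", params = geneModelParams()) {
    seqchar <- as.character(locusSequence(locus))
    L <- nchar(seqchar)
    cod <- if (strand == "+") seqchar else .revcomp(seqchar)
    iv <- if (strand == "+") cds else c(L - cds[2L], L - cds[1L])
    c0 <- iv[1L]; cEnd <- iv[2L]

    din <- function(p) substr(cod, p + 1L, p + 2L)   # 0-based position p
    findTata <- function(hi, lo) {
        # closest TATAWA start t in [lo, hi], scanning downwards
        if (hi < lo || lo < 0L) return(NULL)
        for (t in seq.int(hi, lo))
            if (grepl("^TATA[AT]A", substr(cod, t + 1L, t + 6L)))
                return(t)
        NULL
    }

    acceptor <- NULL
    for (a in seq.int(c0, max(2L, c0 - params$maxUtr))) {
        if (din(a - 2L) == "AG") { acceptor <- a; break }
    }
    donor <- NULL
    if (!is.null(acceptor)) {
        dHi <- acceptor - params$intronMin
        dLo <- max(0L, acceptor - params$intronMax)
        if (dHi >= dLo) {
            for (d in seq.int(dHi, dLo)) {
                if (din(d) == "GT") { donor <- d; break }
            }
        }
    }

    if (!is.null(acceptor) && !is.null(donor)) {
        tHi <- donor - params$exon1Min - 6L - params$tataOffset
        tLo <- donor - params$exon1Max - 6L - params$tataOffset
        tata <- findTata(tHi, max(0L, tLo))
        e1 <- if (!is.null(tata)) tata + 6L + params$tataOffset
              else max(0L, donor - params$exon1Default)
        new("SedcGeneModel", geneId = geneId,
            exon1 = .toLocusIv(c(e1, donor), strand, L),
            intron = .toLocusIv(c(donor, acceptor), strand, L),
            exon2 = .toLocusIv(c(acceptor, cEnd), strand, L),
            cds = .toLocusIv(c(c0, cEnd), strand, L),
            tata = if (is.null(tata)) NULL
                   else .toLocusIv(c(tata, tata + 6L), strand, L)[1L],
            donor = "GT", acceptor = "AG", strand = strand,
            protein = protein, singleExon = FALSE)
    } else {
        tata <- findTata(c0 - params$tataOffset - 6L,
                         max(0L, c0 - 66L))
        new("SedcGeneModel", geneId = geneId,
            exon1 = NULL, intron = NULL,
            exon2 = .toLocusIv(c(c0, cEnd), strand, L),
            cds = .toLocusIv(c(c0, cEnd), strand, L),
            tata = if (is.null(tata)) NULL
                   else .toLocusIv(c(tata, tata + 6L), strand, L)[1L],
            donor = NA_character_, acceptor = NA_character_,
            strand = strand, protein = protein, singleExon = TRUE)
    }
}

#' Classify the coding integrity of a candidate gene region
#'
#' Aligns the reference ortholog protein against the candidate nucleotide
#' region with a frameshift-aware dynamic program (codon-match states plus
#' single-nucleotide insertion/deletion transitions carrying a frameshift
#' penalty; premature stop codons score -4 and are recorded as lesions).
#' States: `intact` when at least `coverageIntact` of the reference aligns
#' with no lesion; `disrupted_frameshift` / `disrupted_stop` with lesion
#' coordinates otherwise (a frameshift takes precedence, since stops
#' downstream of a frameshift are secondary); `truncated` when the alignment
#' is lesion-free but covers less of the reference; `absent` when the best
#' score falls below `absentThreshold`.
#'
#' Frameshift placement inside repetitive or degenerate context can be
#' ambiguous (several placements score identically, the same ambiguity that
#' indel normalization addresses in variant calling). The aligner therefore
#' reports, per frameshift lesion, the interval of co-optimal placements:
#' `ref_codon` is the leftmost-placement codon and `ref_codon_hi` the
#' rightmost one (identical when the placement is unique).
#'
#' @param candidate nucleotide sequence of the candidate region (character or
#'   [Biostrings::DNAString]), in coding orientation.
#' @param refProtein the reference ortholog protein (non-empty).
#' @param params [geneModelParams()].
#' @return A [GeneStatus-class].
#' @export
classifyIntegrity <- function(candidate, refProtein,
                              params = geneModelParams()) {
    refProtein <- as.character(refProtein)
    stopifnot(nchar(refProtein) > 0L)
    candidate <- toupper(as.character(candidate))
    emptyLes <- data.frame(kind = character(0L), ref_codon = integer(0L),
                           ref_codon_hi = integer(0L), nt_pos = integer(0L),
                           stringsAsFactors = FALSE)
    if (nchar(candidate) < 3L)
        return(new("GeneStatus", state = "absent", lesions = emptyLes,
                   score = 0, coverage = 0))
    pcode <- .encodeAA(refProtein)
    dcode <- .encodeDNA(candidate)
    al <- fs_align_cpp(pcode, dcode, edcSubstitutionMatrix(), .codonTable(),
                       .xCode(), .stopCode(), params$fsPenalty,
                       params$gapResidue, FALSE)
    cov <- al$covered / nchar(refProtein)
    if (al$score < params$absentThreshold)
        return(new("GeneStatus", state = "absent", lesions = emptyLes,
                   score = al$score, coverage = cov))
    lesions <- data.frame(
        kind = c("stop", "frameshift")[al$lesion_type],
        ref_codon = al$lesion_ref,
        ref_codon_hi = al$lesion_ref,
        nt_pos = al$lesion_dna, stringsAsFactors = FALSE)
    if (any(lesions$kind == "frameshift")) {
        # bound the placement-ambiguity interval with a rightmost-tie pass
        alR <- fs_align_cpp(pcode, dcode, edcSubstitutionMatrix(),
                            .codonTable(), .xCode(), .stopCode(),
                            params$fsPenalty, params$gapResidue, TRUE)
        fsL <- which(lesions$kind == "frameshift")
        fsR <- which(alR$lesion_type == 2L)
        if (length(fsR) == length(fsL))
            lesions$ref_codon_hi[fsL] <- pmax(lesions$ref_codon[fsL],
                                              alR$lesion_ref[fsR])
    }
    state <- if (any(lesions$kind == "frameshift")) "disrupted_frameshift"
             else if (any(lesions$kind == "stop")) "disrupted_stop"
             else if (cov >= params$coverageIntact) "intact"
             else "truncated"
    new("GeneStatus", state = state, lesions = lesions, score = al$score,
        coverage = cov)
}
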