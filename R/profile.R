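#' Uniform background residue distribution
#'
#' Default background for profile construction: each of the 20 standard
#' residues at frequency 1/20. Supply empirical frequencies to
#' \code{\link{buildProfile}} to override.
#'
#' @return named numeric vector over the 20 standard residues, summing to 1.
#' @export
uniformBackground <- function() {
    b <- rep(1 / 20, 20)
    names(b) <- AA_STANDARD
    b
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' Constructs a log-odds profile over the 20 standard residues from an
#' alignment of domain sequences. Duplicate seed sequences are collapsed
#' before counting (simple redundancy weighting), alignment columns with
#' more than 50\% gaps are dropped, and the score of residue \eqn{a} in a
#' column is
#' \deqn{\ln\frac{c_a + \lambda b_a}{(n_{\mathrm{eff}} + \lambda) b_a}}
#' where \eqn{c_a} is the residue count in the column, \eqn{b_a} the
#' background frequency, \eqn{\lambda} the pseudocount mass and
#' \eqn{n_{\mathrm{eff}}} the number of (unique) sequences with a residue
#' in the column. X scores 0 in every column; X in the seed contributes no
#' count.
#'
#' @param seedAlignment character vector of equal-length aligned strings
#'   (or the result of \code{\link{readSeedAlignment}}).
#' @param background named residue frequency vector (default uniform).
#' @param pseudocount positive pseudocount mass \eqn{\lambda} (default 1).
#' @param gapOpen,gapExtend affine gap penalties used when scanning
#'   (defaults 11 and 1, conventional protein-profile values).
#' @param cutoff minimum normalized hit score, in mean log-odds per
#'   profile column (default 1.0; calibrated so a random sequence yields
#'   no hits while true domains at moderate divergence are retained).
#' @return a \code{\linkS4class{ScoringProfile}}.
#' @examples
#' prof <- buildProfile(c("ACDEFGHIKLMN", "ACDEFGHIKLMN"))
#' length(prof)
#' @export
buildProfile <- function(seedAlignment, background = uniformBackground(),
                         pseudocount = 1, gapOpen = 11, gapExtend = 1,
                         cutoff = 1.0) {
    aln <- as.character(seedAlignment)
    if (length(aln) < 1L) stop("seed alignment is empty")
    if (length(unique(nchar(aln))) != 1L)
        stop("seed alignment is ragged: all rows must have equal length")
    if (pseudocount <= 0) stop("pseudocount must be positive")
    if (!all(AA_STANDARD %in% names(background)))
        stop("background must name all 20 standard residues")
    background <- background[AA_STANDARD] / sum(background[AA_STANDARD])
    aln <- unique(aln)

    mat <- do.call(rbind, strsplit(aln, ""))
    gap_frac <- colMeans(mat == "-")
    keep <- gap_frac <= 0.5
    if (!any(keep)) stop("all alignment columns exceed 50% gaps")
    mat <- mat[, keep, drop = FALSE]

    L <- ncol(mat)
    scores <- matrix(0, nrow = 21L, ncol = L,
                     dimnames = list(AA_ALPHABET21, NULL))
    for (j in seq_len(L)) {
        col <- mat[, j]
        col <- col[col != "-" & col != "X"]
        n_eff <- length(col)
        counts <- table(factor(col, levels = AA_STANDARD))
        scores[AA_STANDARD, j] <-
            log((as.numeric(counts) + pseudocount * background) /
                ((n_eff + pseudocount) * background))
    }
    new("ScoringProfile", scores = scores, gapOpen = gapOpen,
        gapExtend = gapExtend, cutoff = cutoff)
}

seqToIndex <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    idx <- match(chars, AA_ALPHABET21)
    if (anyNA(idx))
        stop("invalid residue ", sQuote(chars[which(is.na(idx))[1L]]),
             " at position ", which(is.na(idx))[1L])
    idx - 1L
}

#' Detect all non-overlapping S1 domain repeats in a protein
#'
#' Iterated best-local-hit search: the profile is aligned glocally
#' (profile in full, sequence locally) with affine gaps; the best hit is
#' accepted if its normalized score (raw score / profile length) reaches
#' the profile cutoff, its residues are masked, and the search repeats
#' until no acceptable hit remains. Hits are returned sorted by start with
#' \code{domain_index} assigned 1..k from N- to C-terminus.
#'
#' @param profile a \code{\linkS4class{ScoringProfile}}.
#' @param record a single named \code{AAStringSet} element, an
#'   \code{AAStringSet} of length 1, or a named character string.
#' @param cutoff optional cutoff override (defaults to the profile's).
#' @return data.frame with columns protein_id, domain_index, start, end,
#'   score (normalized); zero rows when nothing is found.
#' @export
scanSequence <- function(profile, record, cutoff = profileCutoff(profile)) {
    stopifnot(is(profile, "ScoringProfile"))
    if (is(record, "XStringSet")) {
        if (length(record) != 1L) stop("scanSequence expects a single record")
        id <- names(record)
        seq <- as.character(record)[[1L]]
    } else {
        id <- names(record)
        seq <- as.character(record)
    }
    if (is.null(id) || !nzchar(id)) id <- "seq1"
    if (!nzchar(seq)) stop("record is empty")

    idx <- seqToIndex(seq)
    mask <- rep(FALSE, length(idx))
    L <- length(profile)
    hits <- list()
    repeat {
        res <- .profile_align_core(profile@scores, idx, mask,
                                   profile@gapOpen, profile@gapExtend)
        if (!is.finite(res$score) || res$score / L < cutoff) break
        hits[[length(hits) + 1L]] <-
            data.frame(protein_id = id, start = res$start, end = res$end,
                       raw_score = res$score, stringsAsFactors = FALSE)
        mask[res$start:res$end] <- TRUE
        if (all(mask)) break
    }
    if (!length(hits)) {
        return(data.frame(protein_id = character(), domain_index = integer(),
                          start = integer(), end = integer(),
                          score = numeric(), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, hits)
    out <- out[order(out$start), , drop = FALSE]
    data.frame(protein_id = out$protein_id,
               domain_index = seq_len(nrow(out)),
               start = as.integer(out$start), end = as.integer(out$end),
               score = out$raw_score / L,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a whole set of proteins
#'
#' @param profile a \code{\linkS4class{ScoringProfile}}.
#' @param records an \code{AAStringSet} (named) or named character vector.
#' @param cutoff optional cutoff override.
#' @return one domain-annotation data.frame (the \code{\link{readDomainTable}}
#'   dialect) covering all records.
#' @export
scanProteins <- function(profile, records, cutoff = profileCutoff(profile)) {
    seqs <- asNamedChar(records)
    ids <- names(seqs)
    if (is.null(ids)) stop("records must be named")
    res <- lapply(ids, function(i) {
        s <- seqs[[i]]
        names(s) <- i
        scanSequence(profile, s, cutoff = cutoff)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Count S1 domain repeats in one protein
#'
#' @inheritParams scanSequence
#' @return integer: the number of accepted non-overlapping hits.
#' @export
countDomains <- function(profile, record, cutoff = profileCutoff(profile)) {
    nrow(scanSequence(profile, record, cutoff = cutoff))
}
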