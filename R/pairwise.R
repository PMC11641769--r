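#' BLOSUM62 substitution matrix extended with a neutral X
#'
#' The Biostrings BLOSUM62 table restricted to the 20 standard residues,
#' with an X row/column scoring 0 against everything (consistent with the
#' profile module's treatment of unknown residues).
#'
#' @return 21 x 21 integer-valued matrix.
#' @export
blosum62Matrix <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_STANDARD, AA_STANDARD]
    out <- matrix(0, 21, 21, dimnames = list(AA_ALPHABET21, AA_ALPHABET21))
    out[AA_STANDARD, AA_STANDARD] <- m
    out
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix format (comment lines
#' start with '#'; first non-comment line lists the column residues).
#'
#' @param path path to the matrix file.
#' @return square numeric matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
    rn <- vapply(rows, `[`, character(1), 1L)
    vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                     numeric(length(cols))))
    dimnames(vals) <- list(rn, cols)
    vals
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch global alignment of two protein sequences. A
#' gap of length \eqn{g} costs \code{gapOpen + g * gapExtend}. The default
#' scoring (BLOSUM62, open 10, extend 0.5) mirrors conventional
#' Clustal-like protein defaults.
#'
#' @param a,b non-empty protein sequences (character strings).
#' @param matrix substitution matrix (residue-named square matrix).
#' @param gapOpen,gapExtend affine gap penalties.
#' @return a \code{\linkS4class{PairwiseAln}}.
#' @examples
#' aln <- globalAlign("MKV", "MRV")
#' percentIdentity(aln)
#' @export
globalAlign <- function(a, b, matrix = blosum62Matrix(),
                        gapOpen = 10, gapExtend = 0.5) {
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    p <- pairwiseAlignment(a, b, type = "global",
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
    aa <- as.character(alignedPattern(p))[[1L]]
    bb <- as.character(alignedSubject(p))[[1L]]
    ca <- strsplit(aa, "")[[1L]]
    cb <- strsplit(bb, "")[[1L]]
    both <- ca != "-" & cb != "-"
    new("PairwiseAln", aAligned = aa, bAligned = bb,
        score = BiocGenerics::score(p),
        nIdentical = sum(both & ca == cb),
        nAlignedCols = sum(both))
}

#' Percent identity of a pairwise alignment
#'
#' Fraction in [0, 1]. With \code{denominator = "both-residues"} (default)
#' the denominator is the number of columns where both sequences carry a
#' residue (gap columns excluded); with \code{"columns"} it is the full
#' alignment length. Returns 0 for an alignment without any both-residue
#' column.
#'
#' @param aln a \code{\linkS4class{PairwiseAln}}.
#' @param denominator identity convention, see above.
#' @return numeric fraction in [0, 1].
#' @export
percentIdentity <- function(aln, denominator = c("both-residues", "columns")) {
    denominator <- match.arg(denominator)
    den <- if (denominator == "both-residues") aln@nAlignedCols
           else nchar(aln@aAligned)
    if (den == 0L) return(0)
    aln@nIdentical / den
}

pairIdentity <- function(a, b, matrix, gapOpen, gapExtend, denominator) {
    percentIdentity(globalAlign(a, b, matrix, gapOpen, gapExtend),
                    denominator = denominator)
}

# Vectorized identity for many pairs: one pairwiseAlignment call, identity
# from the C-level match/mismatch counters (identical residues over
# both-residue columns; nmatch + nmismatch is exactly the both-residue
# column count).
manyPairIdentities <- function(as, bs, matrix = blosum62Matrix(),
                               gapOpen = 10, gapExtend = 0.5,
                               denominator = "both-residues") {
    p <- pairwiseAlignment(unname(as), unname(bs), type = "global",
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
    nm <- Biostrings::nmatch(p)
    both <- nm + Biostrings::nmismatch(p)
    # Full alignment length: every column consumes one residue of a or b
    # except both-residue columns, which consume one of each.
    den <- if (denominator == "both-residues") both
           else nchar(as) + nchar(bs) - both
    ifelse(den == 0L, 0, nm / den)
}

#' Mean within-group identity
#'
#' Mean percent identity over all unordered pairs of the given sequences,
#' each pair aligned globally. This is the all-pairs replacement for a
#' joint multiple alignment.
#'
#' @param seqs character vector of at least two sequences.
#' @inheritParams globalAlign
#' @inheritParams percentIdentity
#' @return mean identity fraction in [0, 1].
#' @export
groupIdentity <- function(seqs, matrix = blosum62Matrix(),
                          gapOpen = 10, gapExtend = 0.5,
                          denominator = c("both-residues", "columns")) {
    denominator <- match.arg(denominator)
    seqs <- as.character(seqs)
    if (length(seqs) < 2L) stop("groupIdentity needs at least 2 sequences")
    idx <- utils::combn(length(seqs), 2L)
    mean(manyPairIdentities(seqs[idx[1L, ]], seqs[idx[2L, ]], matrix,
                            gapOpen, gapExtend, denominator))
}

#' Mean cross-group identity
#'
#' Mean percent identity over all A x B sequence pairs (within-group pairs
#' excluded). When both groups are the same single sequence this is 1.
#'
#' @param seqsA,seqsB non-empty character vectors of sequences.
#' @inheritParams globalAlign
#' @inheritParams percentIdentity
#' @return mean identity fraction in [0, 1].
#' @export
crossGroupIdentity <- function(seqsA, seqsB, matrix = blosum62Matrix(),
                               gapOpen = 10, gapExtend = 0.5,
                               denominator = c("both-residues", "columns")) {
    denominator <- match.arg(denominator)
    seqsA <- as.character(seqsA)
    seqsB <- as.character(seqsB)
    if (!length(seqsA) || !length(seqsB))
        stop("both groups must be non-empty")
    grid <- expand.grid(a = seq_along(seqsA), b = seq_along(seqsB))
    mean(manyPairIdentities(seqsA[grid$a], seqsB[grid$b], matrix,
                            gapOpen, gapExtend, denominator))
}
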