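#' @import methods
#' @importFrom stats setNames
#' @importFrom Rcpp evalCpp
#' @useDynLib S1Domains, .registration = TRUE
NULL

# 20 standard residues; X is the only ambiguity code kept after input mapping.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET21 <- c(AA_STANDARD, "X")

#' ScoringProfile: position-specific scoring model for the S1 domain
#'
#' A log-odds profile built from a seed alignment of domain sequences.
#' Column scores are natural-log odds against a background residue
#' distribution; \code{X} scores 0 in every column so unknown residues are
#' neutral. Scores are stored as a 21 x L matrix (rows = 20 residues + X,
#' columns = profile positions).
#'
#' @slot scores numeric matrix, 21 x L, rownames the residue alphabet.
#' @slot gapOpen non-negative gap opening penalty (a gap of length g costs
#'   \code{gapOpen + g * gapExtend}).
#' @slot gapExtend non-negative per-residue gap extension penalty.
#' @slot cutoff minimum normalized hit score (mean log-odds per profile
#'   column) for a domain hit to be accepted.
#' @exportClass ScoringProfile
setClass("ScoringProfile",
         representation(scores = "matrix",
                        gapOpen = "numeric",
                        gapExtend = "numeric",
                        cutoff = "numeric"))

setValidity("ScoringProfile", function(object) {
    msg <- character()
    if (!identical(rownames(object@scores), AA_ALPHABET21))
        msg <- c(msg, "score matrix rows must be the 21-letter alphabet (20 residues + X)")
    if (ncol(object@scores) < 10)
        msg <- c(msg, "profile must have at least 10 columns")
    if (!all(is.finite(object@scores)))
        msg <- c(msg, "all column scores must be finite")
    if (!all(object@scores["X", ] == 0))
        msg <- c(msg, "X must score 0 in every column")
    if (length(object@gapOpen) != 1L || object@gapOpen < 0)
        msg <- c(msg, "gapOpen must be a single non-negative number")
    if (length(object@gapExtend) != 1L || object@gapExtend < 0)
        msg <- c(msg, "gapExtend must be a single non-negative number")
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
        msg <- c(msg, "cutoff must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' @describeIn ScoringProfile number of profile columns
#' @param x,object a \code{ScoringProfile}
#' @export
setMethod("length", "ScoringProfile", function(x) ncol(x@scores))

#' @describeIn ScoringProfile compact description
#' @export
setMethod("show", "ScoringProfile", function(object) {
    cat("ScoringProfile of", ncol(object@scores), "columns\n")
    cat("  gapOpen:", object@gapOpen, " gapExtend:", object@gapExtend,
        " cutoff:", object@cutoff, "\n")
    cat("  mean self-score/column:",
        round(mean(apply(object@scores[AA_STANDARD, , drop = FALSE], 2, max)), 3), "\n")
})

#' @rdname ScoringProfile-class
#' @export
profileScores <- function(x) x@scores

#' @rdname ScoringProfile-class
#' @export
profileCutoff <- function(x) x@cutoff

#' PairwiseAlignment result container
#'
#' Global (Needleman-Wunsch, affine gap) alignment of two protein
#' sequences, with the identity bookkeeping used throughout the
#' identity-matrix analysis: \code{nAlignedCols} counts columns where both
#' symbols are residues (gap columns excluded), \code{nIdentical} counts
#' those columns with identical residues.
#'
#' @slot aAligned,bAligned equal-length aligned strings over residues + '-'.
#' @slot score optimal alignment score.
#' @slot nIdentical number of identical both-residue columns.
#' @slot nAlignedCols number of both-residue columns.
#' @exportClass PairwiseAln
setClass("PairwiseAln",
         representation(aAligned = "character",
                        bAligned = "character",
                        score = "numeric",
                        nIdentical = "integer",
                        nAlignedCols = "integer"))

setValidity("PairwiseAln", function(object) {
    msg <- character()
    if (nchar(object@aAligned) != nchar(object@bAligned))
        msg <- c(msg, "aligned strings must have equal length")
    a <- strsplit(object@aAligned, "")[[1]]
    b <- strsplit(object@bAligned, "")[[1]]
    if (any(a == "-" & b == "-"))
        msg <- c(msg, "no column may be gap/gap")
    if (object@nIdentical > object@nAlignedCols)
        msg <- c(msg, "nIdentical cannot exceed nAlignedCols")
    if (length(msg)) msg else TRUE
})

#' @describeIn PairwiseAln compact description
#' @param object a \code{PairwiseAln}
#' @export
setMethod("show", "PairwiseAln", function(object) {
    cat("PairwiseAln: score", object@score, "\n")
    cat(" ", object@aAligned, "\n ", object@bAligned, "\n")
    cat("  identity:", object@nIdentical, "/", object@nAlignedCols, "\n")
})

#' DomainGroup: per-position domain sets for one taxon group
#'
#' Multidomain proteins of one group (e.g. "Cyanobacteria RpS1"), sliced
#' into their k N-to-C domain positions. \code{members[[p]]} holds the
#' domain sequences occupying position p, one per protein, ordered by
#' protein id.
#'
#' @slot name group label.
#' @slot members list of length k; each element a named character vector of
#'   domain sequences (names = protein ids).
#' @exportClass DomainGroup
setClass("DomainGroup",
         representation(name = "character", members = "list"))

setValidity("DomainGroup", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@members) < 1L)
        msg <- c(msg, "group must have at least one domain position")
    seqs <- unlist(object@members, use.names = FALSE)
    if (length(seqs) == 0L || any(!nzchar(seqs)))
        msg <- c(msg, "every member sequence must be non-empty")
    if (length(msg)) msg else TRUE
})

#' @describeIn DomainGroup number of domain positions k
#' @param x,object a \code{DomainGroup}
#' @export
setMethod("length", "DomainGroup", function(x) length(x@members))

#' @describeIn DomainGroup compact description
#' @export
setMethod("show", "DomainGroup", function(object) {
    cat("DomainGroup", sQuote(object@name), "with",
        length(object@members), "domain positions\n")
    for (p in seq_along(object@members))
        cat("  position", p, ":", length(object@members[[p]]), "sequences\n")
})

#' @rdname DomainGroup-class
#' @export
groupName <- function(x) x@name

#' @rdname DomainGroup-class
#' @param position 1-based domain position
#' @export
groupMembers <- function(x, position) {
    if (missing(position)) x@members else x@members[[position]]
}

#' IdentityMatrix: position-by-position mean identities between two groups
#'
#' Cell (i, j) is the mean pairwise percent identity (fraction in [0,1])
#' between the domains at position i of group A and position j of group B.
#' \code{counts} records how many sequence pairs contributed to each cell.
#'
#' @slot groupA,groupB group names.
#' @slot values m x n numeric matrix of identity fractions.
#' @slot counts m x n integer matrix of contributing pair counts.
#' @exportClass IdentityMatrix
setClass("IdentityMatrix",
         representation(groupA = "character", groupB = "character",
                        values = "matrix", counts = "matrix"))

setValidity("IdentityMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@counts)))
        msg <- c(msg, "values and counts must have identical dimensions")
    v <- object@values[!is.na(object@values)]
    if (any(v < 0 | v > 1))
        msg <- c(msg, "identity values must lie in [0, 1]")
    if (any(object@counts[!is.na(object@values)] < 1))
        msg <- c(msg, "every present value needs at least one contributing pair")
    if (length(msg)) msg else TRUE
})

#' @describeIn IdentityMatrix compact display (percent, 1 decimal)
#' @param object an \code{IdentityMatrix}
#' @export
setMethod("show", "IdentityMatrix", function(object) {
    cat("IdentityMatrix:", object@groupA, "(rows) vs", object@groupB, "(cols)\n")
    print(round(100 * object@values, 1))
})

#' @rdname IdentityMatrix-class
#' @param x an \code{IdentityMatrix}
#' @export
identityValues <- function(x) x@values

#' @rdname IdentityMatrix-class
#' @export
identityCounts <- function(x) x@counts

#' PhyloTree: unrooted tree with branch lengths
#'
#' Minimal unrooted tree container produced by \code{\link{neighborJoining}}.
#' Leaves are numbered 1..n (in the order of \code{leafLabels}); internal
#' nodes n+1..; \code{root} is the internal node used as the serialization
#' anchor (the final join, degree 3 for n >= 3). Edge lengths are in the
#' units of the input distances (substitutions per site for corrected
#' distances).
#'
#' @slot edges integer matrix, m x 2: (from-node, to-node), from = node
#'   closer to the serialization anchor.
#' @slot lengths numeric vector of m non-negative branch lengths.
#' @slot leafLabels character vector of leaf labels (leaf i = node i).
#' @slot root integer id of the anchor node.
#' @exportClass PhyloTree
setClass("PhyloTree",
         representation(edges = "matrix", lengths = "numeric",
                        leafLabels = "character", root = "integer"))

setValidity("PhyloTree", function(object) {
    msg <- character()
    n <- length(object@leafLabels)
    if (n < 2) msg <- c(msg, "a tree needs at least 2 leaves")
    if (anyDuplicated(object@leafLabels))
        msg <- c(msg, "leaf labels must be unique")
    if (nrow(object@edges) != length(object@lengths))
        msg <- c(msg, "one length per edge required")
    if (any(object@lengths < 0))
        msg <- c(msg, "branch lengths must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @describeIn PhyloTree number of leaves
#' @param x,object a \code{PhyloTree}
#' @export
setMethod("length", "PhyloTree", function(x) length(x@leafLabels))

#' @describeIn PhyloTree compact description
#' @export
setMethod("show", "PhyloTree", function(object) {
    cat("PhyloTree with", length(object@leafLabels), "leaves, total length",
        round(sum(object@lengths), 4), "\n")
    cat(" ", toNewick(object), "\n")
})

#' @rdname PhyloTree-class
#' @export
leafLabels <- function(x) x@leafLabels

#' SyntheticTruth: generated sequences plus complete ground truth
#'
#' Output of the bead-on-a-string simulator: the protein records, the true
#' domain coordinates, taxonomy labels, the transfer source-position map
#' (present iff a transfer was requested) and the generating lineage tree.
#'
#' @slot records \code{AAStringSet} of generated proteins.
#' @slot annotations data.frame of true domain coordinates
#'   (protein_id, domain_index, start, end, score).
#' @slot taxonomy data.frame (id, domain_of_life, phylum, class_).
#' @slot sourceMap named list: target group name -> integer source position
#'   per target position (empty when no transfer).
#' @slot trueTree Newick string of the generating position-lineage tree.
#' @slot spec the \code{syntheticSpec} list the truth was generated from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(records = "AAStringSet", annotations = "data.frame",
                        taxonomy = "data.frame", sourceMap = "list",
                        trueTree = "character", spec = "list"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    ids <- names(object@records)
    if (!all(object@annotations$protein_id %in% ids))
        msg <- c(msg, "annotations must refer to generated records")
    w <- Biostrings::width(object@records)
    names(w) <- ids
    bad <- object@annotations$end > w[object@annotations$protein_id]
    if (any(bad))
        msg <- c(msg, "annotation coordinates must fit inside their records")
    if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticTruth compact description
#' @param object a \code{SyntheticTruth}
#' @export
setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@records), "proteins,",
        nrow(object@annotations), "true domains,",
        length(unique(object@taxonomy$domain_of_life)), "domain(s) of life\n")
    if (length(object@sourceMap))
        cat("  transfer source map:",
            paste(names(object@sourceMap), collapse = ", "), "\n")
})

#' @rdname SyntheticTruth-class
#' @param x a \code{SyntheticTruth}
#' @export
truthRecords <- function(x) x@records

#' @rdname SyntheticTruth-class
#' @export
truthAnnotations <- function(x) x@annotations

#' @rdname SyntheticTruth-class
#' @export
truthTaxonomy <- function(x) x@taxonomy

#' @rdname SyntheticTruth-class
#' @export
truthSourceMap <- function(x) x@sourceMap

#' @rdname SyntheticTruth-class
#' @export
truthTree <- function(x) x@trueTree
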