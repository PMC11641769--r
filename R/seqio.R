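#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet readAAStringSet readBStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject width
NULL

DOMAINS_OF_LIFE <- c("Archaea", "Bacteria", "Eukaryota")

# Map UniProt ambiguity codes to X; '*' (stop/translation artifacts) is
# stripped; anything else outside the 20-letter alphabet + X is an error.
sanitizeSequences <- function(seqs, ids) {
    seqs <- toupper(seqs)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
    has_amb <- grepl("[BZUO]", seqs)
    if (any(has_amb)) {
        warning("ambiguous residues B/Z/U/O mapped to X in: ",
                paste(ids[has_amb], collapse = ", "), call. = FALSE)
        seqs <- chartr("BZUO", "XXXX", seqs)
    }
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(bad > 0)) {
        i <- which(bad > 0)[1L]
        stop("non-amino-acid character ",
             sQuote(substr(seqs[i], bad[i], bad[i])),
             " at position ", bad[i], " of record ", sQuote(ids[i]))
    }
    seqs
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into an \code{AAStringSet}. The header token before
#' the first whitespace becomes the record id (unique within the file);
#' the remainder is kept as the \code{description} metadata column.
#' Sequences are upper-cased, \code{'*'} is stripped, and the ambiguity
#' codes B, Z, U, O are mapped to X with a warning. Any other character
#' outside the 20 standard residues plus X is an error.
#'
#' @param path path to a FASTA file.
#' @return \code{AAStringSet}, names = ids, with a \code{description}
#'   metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo protein", "MKV"), fa)
#' readProteins(fa)
#' @export
readProteins <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA file: ", path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    if (any(!nzchar(ids))) stop("FASTA record with empty id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
    seqs <- sanitizeSequences(as.character(raw), ids)
    if (any(!nzchar(seqs))) stop("empty sequence for record ",
                                 sQuote(ids[which(!nzchar(seqs))[1L]]))
    out <- AAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

#' Write protein sequences to FASTA
#'
#' @param records \code{AAStringSet} (names used as ids; a
#'   \code{description} metadata column, if present, is appended to the
#'   header).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeProteins <- function(records, path) {
    out <- records
    mc <- S4Vectors::mcols(records)
    if (!is.null(mc) && "description" %in% colnames(mc)) {
        desc <- mc$description
        names(out) <- ifelse(nzchar(desc),
                             paste(names(records), desc), names(records))
    }
    writeXStringSet(out, path, width = 60L)
    invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated with header columns \code{id}, \code{domain_of_life},
#' \code{phylum}, \code{class}; one row per sequence.
#' \code{domain_of_life} must be one of Archaea, Bacteria, Eukaryota;
#' phylum and class may be empty.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns id, domain_of_life, phylum, class_.
#' @export
readTaxonomy <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = NULL)
    names(tab)[names(tab) == "class"] <- "class_"
    need <- c("id", "domain_of_life", "phylum", "class_")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("taxonomy table missing column(s): ",
             paste(sub("_$", "", miss), collapse = ", "))
    bad <- setdiff(unique(tab$domain_of_life), DOMAINS_OF_LIFE)
    if (length(bad))
        stop("unknown domain_of_life value(s): ", paste(bad, collapse = ", "),
             " (expected Archaea, Bacteria or Eukaryota)")
    dup <- unique(tab$id[duplicated(tab$id)])
    if (length(dup)) stop("duplicate taxonomy id(s): ", paste(dup, collapse = ", "))
    tab[need]
}

#' Write a taxonomy table
#' @param taxonomy data.frame as returned by \code{\link{readTaxonomy}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTaxonomy <- function(taxonomy, path) {
    out <- taxonomy
    names(out)[names(out) == "class_"] <- "class"
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# Shared validation for domain-annotation tables. Coordinates are 1-based
# inclusive; per protein the intervals must be non-overlapping, sorted by
# start, with domain_index consecutive from 1 N->C.
validateAnnotations <- function(ann, lengths = NULL) {
    if (nrow(ann) == 0L) return(ann)
    if (any(ann$start < 1L) || any(ann$end < ann$start))
        stop("invalid domain interval: need 1 <= start <= end (protein ",
             sQuote(ann$protein_id[which(ann$end < ann$start | ann$start < 1L)[1L]]), ")")
    for (pid in unique(ann$protein_id)) {
        a <- ann[ann$protein_id == pid, ]
        a <- a[order(a$start), ]
        if (nrow(a) > 1L && any(a$start[-1L] <= a$end[-nrow(a)]))
            stop("overlapping domain intervals for protein ", sQuote(pid))
        if (!identical(as.integer(a$domain_index), seq_len(nrow(a))))
            stop("domain_index for protein ", sQuote(pid),
                 " must be consecutive 1..k in N->C order")
        if (!is.null(lengths)) {
            if (!pid %in% names(lengths))
                stop("annotation refers to unknown protein ", sQuote(pid))
            if (any(a$end > lengths[[pid]]))
                stop("domain interval exceeds length of protein ", sQuote(pid))
        }
    }
    ann[order(ann$protein_id, ann$start), , drop = FALSE]
}

#' Read / write domain-annotation tables
#'
#' TSV dialect with header \code{protein_id}, \code{domain_index},
#' \code{start}, \code{end}, \code{score}; coordinates 1-based inclusive.
#' Write-then-read reproduces the table exactly.
#'
#' @param path path to the TSV file.
#' @return data.frame with the five columns above.
#' @export
readDomainTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(protein_id = "character"))
    need <- c("protein_id", "domain_index", "start", "end", "score")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("domain table missing column(s): ", paste(miss, collapse = ", "))
    tab <- tab[need]
    tab$domain_index <- as.integer(tab$domain_index)
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
    tab$score <- as.numeric(tab$score)
    validateAnnotations(tab)
}

#' @rdname readDomainTable
#' @param annotations data.frame in the domain-table dialect.
#' @export
writeDomainTable <- function(annotations, path) {
    need <- c("protein_id", "domain_index", "start", "end", "score")
    miss <- setdiff(need, names(annotations))
    if (length(miss))
        stop("annotations missing column(s): ", paste(miss, collapse = ", "))
    ann <- validateAnnotations(annotations[need])
    utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an aligned FASTA seed alignment
#'
#' Equal-length aligned domain sequences (gaps as '-' or '.'); used by
#' \code{\link{buildProfile}}. Dots are normalized to dashes; residues are
#' validated as for \code{\link{readProteins}}.
#'
#' @param path path to aligned FASTA.
#' @return character vector of equal-length aligned strings (named by id).
#' @export
readSeedAlignment <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- readBStringSet(path)
    if (length(raw) == 0L) stop("empty seed alignment: ", path)
    ids <- sub("\\s.*$", "", names(raw))
    aln <- chartr(".", "-", toupper(as.character(raw)))
    if (length(unique(nchar(aln))) != 1L)
        stop("seed alignment is ragged: all rows must have equal length")
    has_amb <- grepl("[BZUO]", aln)
    if (any(has_amb)) {
        warning("ambiguous residues B/Z/U/O mapped to X in: ",
                paste(ids[has_amb], collapse = ", "), call. = FALSE)
        aln <- chartr("BZUO", "XXXX", aln)
    }
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX-]", aln)
    if (any(bad > 0)) {
        i <- which(bad > 0)[1L]
        stop("invalid character ", sQuote(substr(aln[i], bad[i], bad[i])),
             " in seed alignment row ", sQuote(ids[i]))
    }
    names(aln) <- ids
    aln
}

# as.character drops names from plain character vectors; keep them.
asNamedChar <- function(x) {
    nm <- names(x)
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- nm
    out
}
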