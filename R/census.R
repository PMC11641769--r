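#' Census of S1 domain counts by domain of life
#'
#' Groups proteins by (domain of life, number of detected domains) and
#' reports, per cell, the protein count and the size extremes with the ids
#' of the shortest and longest protein (ties broken by lexicographic id).
#' Proteins with zero detected domains are excluded (their number is
#' reported in a message); a record without a taxonomy label is an error.
#'
#' @param records \code{AAStringSet} of proteins.
#' @param annotations domain-annotation data.frame
#'   (\code{\link{readDomainTable}} dialect).
#' @param taxonomy taxonomy data.frame (\code{\link{readTaxonomy}}).
#' @return data.frame with columns domain_of_life, n_domains, count,
#'   min_len, max_len, shortest_id, longest_id, sorted by
#'   (domain_of_life, n_domains).
#' @export
buildCensus <- function(records, annotations, taxonomy) {
    seqs <- asNamedChar(records)
    ids <- names(seqs)
    missing_tax <- setdiff(ids, taxonomy$id)
    if (length(missing_tax))
        stop("no taxonomy label for record(s): ",
             paste(missing_tax, collapse = ", "))
    counts <- table(factor(annotations$protein_id, levels = ids))
    zero <- sum(counts == 0L)
    if (zero > 0L)
        message(zero, " protein(s) with 0 detected domains excluded from census")
    keep <- names(counts)[counts > 0L]
    if (!length(keep))
        return(data.frame(domain_of_life = character(), n_domains = integer(),
                          count = integer(), min_len = integer(),
                          max_len = integer(), shortest_id = character(),
                          longest_id = character(), stringsAsFactors = FALSE))
    dol <- setNames(taxonomy$domain_of_life, taxonomy$id)[keep]
    len <- nchar(seqs[keep])
    ndom <- as.integer(counts[keep])
    cells <- split(seq_along(keep), list(dol, ndom), drop = TRUE, sep = "\r")
    rows <- lapply(cells, function(ii) {
        o_short <- ii[order(len[ii], keep[ii])][1L]
        o_long <- ii[order(-len[ii], keep[ii])][1L]
        data.frame(domain_of_life = dol[ii[1L]], n_domains = ndom[ii[1L]],
                   count = length(ii), min_len = min(len[ii]),
                   max_len = max(len[ii]), shortest_id = keep[o_short],
                   longest_id = keep[o_long], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$domain_of_life, out$n_domains), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write / read a census table (TSV)
#'
#' @param census data.frame from \code{\link{buildCensus}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
censusToTsv <- function(census, path) {
    need <- c("domain_of_life", "n_domains", "count", "min_len", "max_len",
              "shortest_id", "longest_id")
    miss <- setdiff(need, names(census))
    if (length(miss))
        stop("census missing column(s): ", paste(miss, collapse = ", "))
    out <- census[need]
    out <- out[order(out$domain_of_life, out$n_domains), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname censusToTsv
#' @export
readCensus <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(domain_of_life = "character",
                                            shortest_id = "character",
                                            longest_id = "character"))
    tab$n_domains <- as.integer(tab$n_domains)
    tab$count <- as.integer(tab$count)
    tab$min_len <- as.integer(tab$min_len)
    tab$max_len <- as.integer(tab$max_len)
    tab
}
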