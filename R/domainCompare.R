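#' Slice multidomain proteins into a per-position domain group
#'
#' Selects proteins by taxonomy and/or id/description pattern, requires a
#' fixed domain count k, and cuts each selected protein into its k domain
#' sequences by the annotation coordinates. Proteins whose detected domain
#' count differs from k are excluded with a warning (a hard per-group k
#' mirrors the per-phylum domain-count regularity of RpS1). Member lists
#' are ordered by protein id.
#'
#' @param records \code{AAStringSet} of proteins.
#' @param annotations domain-annotation data.frame
#'   (\code{\link{readDomainTable}} dialect).
#' @param taxonomy optional taxonomy data.frame; required when filtering
#'   by taxonomic fields.
#' @param k required domain count for the group.
#' @param name group label.
#' @param domainOfLife,phylum optional taxonomy filters (exact match).
#' @param idPattern optional regular expression applied to protein ids.
#' @return a \code{\linkS4class{DomainGroup}} with \code{n_positions = k}.
#' @export
extractDomains <- function(records, annotations, taxonomy = NULL, k,
                           name = "group", domainOfLife = NULL,
                           phylum = NULL, idPattern = NULL) {
    seqs <- asNamedChar(records)
    ids <- names(seqs)
    ann <- validateAnnotations(annotations, lengths = nchar(seqs))

    sel <- ids
    if (!is.null(domainOfLife) || !is.null(phylum)) {
        if (is.null(taxonomy))
            stop("taxonomy table required for taxonomic filtering")
        tax <- taxonomy
        if (!is.null(domainOfLife))
            tax <- tax[tax$domain_of_life %in% domainOfLife, , drop = FALSE]
        if (!is.null(phylum))
            tax <- tax[tax$phylum %in% phylum, , drop = FALSE]
        sel <- intersect(sel, tax$id)
    }
    if (!is.null(idPattern)) sel <- sel[grepl(idPattern, sel)]
    if (!length(sel))
        stop("empty selection for group ", sQuote(name),
             " (filters: domainOfLife=", paste(domainOfLife, collapse = "/"),
             ", phylum=", paste(phylum, collapse = "/"),
             ", idPattern=", idPattern %||% "<none>", ")")

    counts <- table(factor(ann$protein_id, levels = sel))
    keep <- names(counts)[counts == k]
    drop <- setdiff(sel, keep)
    if (length(drop))
        warning("excluded ", length(drop), " protein(s) with domain count != ",
                k, ": ", paste(drop, collapse = ", "), call. = FALSE)
    if (!length(keep))
        stop("no protein matching filter for group ", sQuote(name),
             " has exactly ", k, " domains")
    keep <- sort(keep)

    members <- lapply(seq_len(k), function(p) {
        a <- ann[ann$protein_id %in% keep & ann$domain_index == p, ]
        a <- a[order(a$protein_id), ]
        doms <- substr(seqs[a$protein_id], a$start, a$end)
        names(doms) <- a$protein_id
        doms
    })
    new("DomainGroup", name = name, members = members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Position-by-position identity matrix between two domain groups
#'
#' Cell (i, j) is the mean pairwise identity between the domains at
#' position i of group A and position j of group B
#' (\code{\link{crossGroupIdentity}}). When both arguments are the same
#' group, diagonal cells are the within-position mean
#' (\code{\link{groupIdentity}}; 1 when the position holds a single
#' sequence).
#'
#' @param a,b \code{\linkS4class{DomainGroup}} objects.
#' @inheritParams globalAlign
#' @inheritParams percentIdentity
#' @return an \code{\linkS4class{IdentityMatrix}}.
#' @export
identityMatrix <- function(a, b = a, matrix = blosum62Matrix(),
                           gapOpen = 10, gapExtend = 0.5,
                           denominator = c("both-residues", "columns")) {
    denominator <- match.arg(denominator)
    same <- identical(a@members, b@members) && identical(a@name, b@name)
    m <- length(a)
    n <- length(b)
    vals <- matrix(NA_real_, m, n)
    cnts <- matrix(0L, m, n)
    for (i in seq_len(m)) {
        for (j in seq_len(n)) {
            sa <- a@members[[i]]
            sb <- b@members[[j]]
            if (same && i == j) {
                if (length(sa) < 2L) {
                    vals[i, j] <- 1
                    cnts[i, j] <- 1L
                } else {
                    vals[i, j] <- groupIdentity(sa, matrix, gapOpen, gapExtend,
                                                denominator = denominator)
                    cnts[i, j] <- as.integer(choose(length(sa), 2L))
                }
            } else {
                vals[i, j] <- tryCatch(
                    crossGroupIdentity(sa, sb, matrix, gapOpen, gapExtend,
                                       denominator = denominator),
                    error = function(e) stop("identity matrix cell (", i, ",",
                                             j, "): ", conditionMessage(e)))
                cnts[i, j] <- as.integer(length(sa) * length(sb))
            }
        }
    }
    dimnames(vals) <- dimnames(cnts) <-
        list(paste0("pos", seq_len(m)), paste0("pos", seq_len(n)))
    new("IdentityMatrix", groupA = a@name, groupB = b@name,
        values = vals, counts = cnts)
}

#' Best domain correspondence per row
#'
#' For each row (domain position of group A) reports the column (position
#' of group B) with the highest mean identity. Ties are broken by the
#' smaller column index and flagged in the \code{tied} column.
#'
#' @param m an \code{\linkS4class{IdentityMatrix}}.
#' @return data.frame with columns position_a, position_b, identity, tied.
#' @export
bestCorrespondence <- function(m) {
    v <- identityValues(m)
    if (!length(v)) stop("identity matrix is empty")
    out <- lapply(seq_len(nrow(v)), function(i) {
        row <- v[i, ]
        best <- max(row)
        js <- which(row == best)
        data.frame(position_a = i, position_b = js[1L], identity = best,
                   tied = if (length(js) > 1L)
                       paste(js, collapse = ",") else "",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Rank correlation between protein length and domain count
#'
#' Spearman rank correlation (midrank ties) between protein length in
#' residues and the number of detected domains. Proteins without any
#' annotation count as zero domains only if present in \code{records};
#' proteins with zero domains are included with count 0. When either
#' variable is constant the correlation is undefined and 0 is returned
#' with a warning.
#'
#' @param records \code{AAStringSet} (at least 3 proteins).
#' @param annotations domain-annotation data.frame.
#' @return Spearman rho in [-1, 1].
#' @export
lengthRepeatCorrelation <- function(records, annotations) {
    seqs <- asNamedChar(records)
    if (length(seqs) < 3L) stop("need at least 3 proteins")
    lens <- nchar(seqs)
    counts <- table(factor(annotations$protein_id, levels = names(seqs)))
    counts <- as.integer(counts)
    if (length(unique(lens)) == 1L || length(unique(counts)) == 1L) {
        warning("length or domain count is constant; correlation undefined, returning 0",
                call. = FALSE)
        return(0)
    }
    stats::cor(lens, counts, method = "spearman")
}

#' Write an identity matrix as TSV (percent, one decimal)
#'
#' Row/column headers are the domain positions; cells are identity
#' percentages rounded to one decimal.
#'
#' @param m an \code{\linkS4class{IdentityMatrix}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeIdentityMatrix <- function(m, path) {
    v <- round(100 * identityValues(m), 1)
    df <- data.frame(position = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
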