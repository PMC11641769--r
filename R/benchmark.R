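#' Seed alignment from generated ground truth
#'
#' Extracts the true domain sequences of the first \code{perGroup}
#' proteins of every group as an (ungapped, equal-length) seed alignment
#' for \code{\link{buildProfile}} — the synthetic counterpart of a curated
#' cross-taxon domain seed alignment.
#'
#' @param truth a \code{\linkS4class{SyntheticTruth}} from
#'   \code{\link{generateFamily}}.
#' @param perGroup proteins per group to contribute (default 2).
#' @return named character vector of domain sequences.
#' @export
truthSeedAlignment <- function(truth, perGroup = 2L) {
    tax <- truthTaxonomy(truth)
    ann <- truthAnnotations(truth)
    seqs <- as.character(truthRecords(truth))
    pick <- unlist(lapply(split(tax$id, tax$phylum), function(ids)
        sort(ids)[seq_len(min(perGroup, length(ids)))]), use.names = FALSE)
    a <- ann[ann$protein_id %in% pick, ]
    doms <- substr(seqs[a$protein_id], a$start, a$end)
    names(doms) <- paste0(a$protein_id, ".", a$domain_index)
    doms
}

#' End-to-end transfer recovery on one simulated family
#'
#' Runs the full analysis pipeline on a \code{\linkS4class{SyntheticTruth}}
#' carrying a transfer: builds a scanning profile from a train split of
#' the generated proteins (\code{\link{truthSeedAlignment}}), detects
#' domains, slices source and target groups, computes the cross-group
#' identity matrix, calls best correspondences, and places all source and
#' target domains on a neighbor-joining tree. Returns what each stage
#' recovered alongside the generator's truth.
#'
#' @param truth a \code{\linkS4class{SyntheticTruth}} with a transfer.
#' @param useTrueAnnotations bypass the scanner and use the generator's
#'   domain coordinates (default FALSE).
#' @param correction distance model for the tree (default "kimura").
#' @return list with elements:
#'   \describe{
#'     \item{countAccuracy}{fraction of proteins whose detected domain
#'       count equals the true count.}
#'     \item{idMatrix}{\code{\linkS4class{IdentityMatrix}}, target (rows)
#'       vs source (cols).}
#'     \item{correspondence}{\code{\link{bestCorrespondence}} output.}
#'     \item{sourceRecovered}{TRUE iff every target position's best match
#'       is the true source position.}
#'     \item{tree}{\code{\linkS4class{PhyloTree}} over source + target
#'       domains.}
#'     \item{cladeRecovered}{TRUE iff the tree has a bipartition grouping
#'       all target domains with the source group's true source-position
#'       domains.}
#'   }
#' @export
recoverTransfer <- function(truth, useTrueAnnotations = FALSE,
                            correction = c("kimura", "p")) {
    correction <- match.arg(correction)
    sm <- truthSourceMap(truth)
    if (!length(sm)) stop("truth carries no transfer")
    spec <- truth@spec
    nm <- vapply(spec$groups, `[[`, character(1), "name")
    targetName <- names(sm)[1L]
    srcName <- spec$transfer$source_group
    srcPos <- spec$transfer$source_position
    srcPhy <- spec$groups[[match(srcName, nm)]]$phylum %||% srcName
    tgtPhy <- spec$groups[[match(targetName, nm)]]$phylum %||% targetName
    k_src <- spec$groups[[match(srcName, nm)]]$k
    k_tgt <- spec$groups[[match(targetName, nm)]]$k

    recs <- truthRecords(truth)
    tax <- truthTaxonomy(truth)
    trueCounts <- table(factor(truthAnnotations(truth)$protein_id,
                               levels = names(recs)))
    if (useTrueAnnotations) {
        ann <- truthAnnotations(truth)
        countAccuracy <- 1
    } else {
        prof <- buildProfile(truthSeedAlignment(truth))
        ann <- scanProteins(prof, recs)
        gotCounts <- table(factor(ann$protein_id, levels = names(recs)))
        countAccuracy <- mean(gotCounts == trueCounts)
    }

    src <- extractDomains(recs, ann, tax, k = k_src, name = srcName,
                          phylum = srcPhy)
    tgt <- extractDomains(recs, ann, tax, k = k_tgt, name = targetName,
                          phylum = tgtPhy)
    m <- identityMatrix(tgt, src)
    bc <- bestCorrespondence(m)
    sourceRecovered <- all(bc$position_b == srcPos) && all(bc$tied == "")

    doms <- character(0)
    for (g in list(src, tgt)) {
        for (p in seq_len(length(g))) {
            x <- groupMembers(g, p)
            names(x) <- paste0(groupName(g), ".", names(x), ".p", p)
            doms <- c(doms, x)
        }
    }
    tree <- domainTree(doms, correction = correction)
    lab <- leafLabels(tree)
    inClade <- lab[grepl(paste0("^", targetName, "\\."), lab) |
                   grepl(paste0("^", srcName, "\\..*\\.p", srcPos, "$"), lab)]
    cladeRecovered <- hasClade(tree, inClade)

    list(countAccuracy = countAccuracy, idMatrix = m, correspondence = bc,
         sourceRecovered = sourceRecovered, tree = tree,
         cladeRecovered = cladeRecovered)
}
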