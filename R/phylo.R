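#' Convert percent identity to an evolutionary distance
#'
#' \code{"p"}: the raw proportion of differing sites, \eqn{d = 1 - I}.
#' \code{"kimura"}: Kimura's empirical correction for protein distances
#' (as used by MEGA-like tools), \eqn{d = -\ln(1 - p - 0.2 p^2)} with
#' \eqn{p = 1 - I}; an error is raised when the corrected argument is not
#' positive (identity too low for the correction, I < ~0.146).
#'
#' @param pIdentity identity fraction(s) in [0, 1].
#' @param correction "kimura" (default) or "p".
#' @return non-negative distance(s) in substitutions per site.
#' @examples
#' identityToDistance(0.75, "p")       # 0.25
#' identityToDistance(0.75, "kimura")  # -log(0.7375)
#' @export
identityToDistance <- function(pIdentity, correction = c("kimura", "p")) {
    correction <- match.arg(correction)
    if (any(pIdentity < 0 | pIdentity > 1))
        stop("identity must lie in [0, 1]")
    p <- 1 - pIdentity
    if (correction == "p") return(p)
    arg <- 1 - p - 0.2 * p^2
    if (any(arg <= 0))
        stop("Kimura correction undefined at identity ",
             paste(round(pIdentity[arg <= 0], 3), collapse = ", "),
             " (corrected argument <= 0); use correction = \"p\"")
    -log(arg)
}

checkDistanceMatrix <- function(d) {
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("distance matrix must be square")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        stop("distance matrix needs unique row/column labels")
    if (!identical(rownames(d), colnames(d)))
        stop("row and column labels must agree")
    if (any(d < 0)) stop("distances must be non-negative")
    if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
    if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
    if (nrow(d) < 2) stop("need at least 2 taxa")
    invisible(d)
}

#' Neighbor-joining tree construction
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion:
#' \eqn{Q(i,j) = (N-2) d(i,j) - r_i - r_j}. At each step the pair
#' minimizing Q is joined (ties broken by the lexicographically smallest
#' pair of node labels, a node's label being its smallest contained leaf
#' label); branch lengths follow the standard formulas, with negative
#' lengths clamped to zero and the deficit moved to the sister branch so
#' the joined pair's path length is preserved.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   unique row/column labels (n >= 2).
#' @return an unrooted \code{\linkS4class{PhyloTree}}.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' toNewick(neighborJoining(d))  # "(A:1,B:1,C:3);"
#' @export
neighborJoining <- function(d) {
    checkDistanceMatrix(d)
    labels <- rownames(d)
    n <- length(labels)

    edges <- matrix(integer(0), 0, 2)
    lens <- numeric(0)
    addEdge <- function(parent, child, len) {
        edges <<- rbind(edges, c(parent, child))
        lens <<- c(lens, max(0, len))
    }

    if (n == 2L) {
        # Single edge; serialized as a midpoint split.
        root <- 3L
        addEdge(root, 1L, d[1, 2] / 2)
        addEdge(root, 2L, d[1, 2] / 2)
        return(new("PhyloTree", edges = edges, lengths = lens,
                   leafLabels = labels, root = root))
    }

    active <- seq_len(n)          # node ids
    minLeaf <- labels             # smallest contained leaf label per node
    D <- d
    nextNode <- n + 1L

    while (length(active) > 3L) {
        N <- length(active)
        r <- rowSums(D)
        Q <- (N - 2) * D - outer(r, r, "+")
        diag(Q) <- Inf
        best <- min(Q)
        cand <- which(Q - best <= 1e-12 * max(1, abs(best)), arr.ind = TRUE)
        cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
        # Tie-break: lexicographically smallest (sorted) label pair.
        key <- apply(cand, 1, function(ij) {
            ls <- sort(c(minLeaf[active[ij[1]]], minLeaf[active[ij[2]]]))
            paste(ls, collapse = "\r")
        })
        pick <- cand[order(key)[1L], ]
        i <- pick[1]; j <- pick[2]
        vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
        vj <- D[i, j] - vi
        if (vi < 0) { vj <- vj + vi; vi <- 0 }
        if (vj < 0) { vi <- vi + vj; vj <- 0 }
        u <- nextNode; nextNode <- nextNode + 1L
        addEdge(u, active[i], vi)
        addEdge(u, active[j], vj)
        minLeaf[u] <- min(minLeaf[active[i]], minLeaf[active[j]])
        newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
        newd <- pmax(newd, 0)
        keep <- setdiff(seq_len(N), c(i, j))
        D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                   c(newd[keep], 0))
        active <- c(active[keep], u)
    }

    # Final three nodes join at the unrooted center (closed form).
    a <- active[1]; b <- active[2]; c <- active[3]
    va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    root <- nextNode
    addEdge(root, a, va)
    addEdge(root, b, vb)
    addEdge(root, c, vc)
    new("PhyloTree", edges = edges, lengths = lens,
        leafLabels = labels, root = root)
}

treeChildren <- function(tree) {
    kids <- split(seq_len(nrow(tree@edges)), tree@edges[, 1])
    kids  # named by parent node id: indices into edge rows
}

leafSetBelow <- function(tree, node, kids, n) {
    if (node <= n) return(node)
    rows <- kids[[as.character(node)]]
    unlist(lapply(tree@edges[rows, 2], leafSetBelow, tree = tree,
                  kids = kids, n = n))
}

#' Serialize a tree to Newick
#'
#' Deterministic serialization: at every internal node children are
#' ordered by the smallest leaf label they contain (lexicographically);
#' branch lengths are printed to 6 significant digits.
#'
#' @param tree a \code{\linkS4class{PhyloTree}}.
#' @return a single Newick string (terminated by ';').
#' @export
toNewick <- function(tree) {
    stopifnot(is(tree, "PhyloTree"))
    n <- length(tree@leafLabels)
    kids <- treeChildren(tree)
    fmt <- function(x) format(signif(x, 6), scientific = FALSE, trim = TRUE)
    rec <- function(node) {
        if (node <= n)
            return(list(str = tree@leafLabels[node],
                        min = tree@leafLabels[node]))
        rows <- kids[[as.character(node)]]
        parts <- lapply(rows, function(r) {
            sub <- rec(tree@edges[r, 2])
            list(str = paste0(sub$str, ":", fmt(tree@lengths[r])),
                 min = sub$min)
        })
        ord <- order(vapply(parts, `[[`, character(1), "min"))
        parts <- parts[ord]
        list(str = paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                                     collapse = ","), ")"),
             min = parts[[1L]]$min)
    }
    paste0(rec(tree@root)$str, ";")
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' @param tree a \code{\linkS4class{PhyloTree}}.
#' @return symmetric matrix of patristic distances, labeled by leaf.
#' @export
treeDistances <- function(tree) {
    n <- length(tree@leafLabels)
    nodes <- sort(unique(as.integer(tree@edges)))
    adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
    for (r in seq_len(nrow(tree@edges))) {
        a <- as.character(tree@edges[r, 1])
        b <- as.character(tree@edges[r, 2])
        adj[[a]] <- rbind(adj[[a]], c(tree@edges[r, 2], tree@lengths[r]))
        adj[[b]] <- rbind(adj[[b]], c(tree@edges[r, 1], tree@lengths[r]))
    }
    out <- matrix(0, n, n, dimnames = list(tree@leafLabels, tree@leafLabels))
    for (s in seq_len(n)) {
        dist <- setNames(rep(NA_real_, length(nodes)), nodes)
        dist[as.character(s)] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            for (k in seq_len(NROW(adj[[as.character(v)]]))) {
                nb <- adj[[as.character(v)]][k, 1]
                if (is.na(dist[as.character(nb)])) {
                    dist[as.character(nb)] <-
                        dist[as.character(v)] + adj[[as.character(v)]][k, 2]
                    queue <- c(queue, nb)
                }
            }
        }
        out[s, ] <- dist[as.character(seq_len(n))]
    }
    out
}

#' Does the tree contain a clade (bipartition) with exactly these leaves?
#'
#' TRUE iff removing some edge separates exactly the given leaf set from
#' the remaining leaves (the unrooted notion of monophyly).
#'
#' @param tree a \code{\linkS4class{PhyloTree}}.
#' @param labels character vector of leaf labels.
#' @return logical.
#' @export
hasClade <- function(tree, labels) {
    n <- length(tree@leafLabels)
    want <- match(labels, tree@leafLabels)
    if (anyNA(want)) stop("unknown leaf label(s): ",
                          paste(setdiff(labels, tree@leafLabels), collapse = ", "))
    want <- sort(want)
    if (length(want) %in% c(0L, n)) return(TRUE)
    kids <- treeChildren(tree)
    for (r in seq_len(nrow(tree@edges))) {
        below <- sort(leafSetBelow(tree, tree@edges[r, 2], kids, n))
        if (identical(below, want) ||
            identical(sort(setdiff(seq_len(n), below)), want))
            return(TRUE)
    }
    FALSE
}

#' Convert to an ape "phylo" object
#'
#' Full-precision conversion (no Newick round trip) for interoperation
#' with the ape/phangorn ecosystem.
#'
#' @param tree a \code{\linkS4class{PhyloTree}}.
#' @return an object of class \code{phylo}.
#' @export
asPhylo <- function(tree) {
    n <- length(tree@leafLabels)
    internals <- sort(unique(tree@edges[, 1]))
    remap <- seq_len(max(c(tree@edges, n)))
    remap[tree@root] <- n + 1L
    others <- setdiff(internals, tree@root)
    remap[others] <- n + 1L + seq_along(others)
    edge <- cbind(remap[tree@edges[, 1]], remap[tree@edges[, 2]])
    storage.mode(edge) <- "integer"
    phy <- list(edge = edge, edge.length = tree@lengths,
                tip.label = tree@leafLabels, Nnode = length(internals))
    class(phy) <- "phylo"
    ape::reorder.phylo(phy, "cladewise")
}

#' Read / write a labeled square distance matrix (TSV)
#'
#' First column holds the labels; remaining columns the distances.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
readDistanceMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    labels <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    dimnames(m) <- list(labels, colnames(tab)[-1L])
    checkDistanceMatrix(m)
    m
}

#' @rdname readDistanceMatrix
#' @param d labeled square distance matrix.
#' @export
writeDistanceMatrix <- function(d, path) {
    checkDistanceMatrix(d)
    df <- data.frame(label = rownames(d), d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Neighbor-joining tree of a set of domain sequences
#'
#' Convenience wrapper for the Fig-3-style analysis: all-pairs global
#' alignment, identity, identity-to-distance conversion, then
#' \code{\link{neighborJoining}}.
#'
#' @param seqs named character vector of (domain) sequences.
#' @param correction distance model, see \code{\link{identityToDistance}}.
#' @inheritParams globalAlign
#' @inheritParams percentIdentity
#' @return a \code{\linkS4class{PhyloTree}}.
#' @export
domainTree <- function(seqs, correction = c("kimura", "p"),
                       matrix = blosum62Matrix(), gapOpen = 10,
                       gapExtend = 0.5,
                       denominator = c("both-residues", "columns")) {
    correction <- match.arg(correction)
    denominator <- match.arg(denominator)
    nms <- names(seqs)
    seqs <- as.character(seqs)   # drops names for plain character input
    names(seqs) <- nms
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("seqs must be uniquely named")
    n <- length(seqs)
    if (n < 2L) stop("need at least 2 sequences")
    idx <- utils::combn(n, 2L)
    ids <- manyPairIdentities(seqs[idx[1L, ]], seqs[idx[2L, ]], matrix,
                              gapOpen, gapExtend, denominator)
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    dvals <- identityToDistance(ids, correction = correction)
    for (k in seq_len(ncol(idx))) {
        d[idx[1L, k], idx[2L, k]] <- dvals[k]
        d[idx[2L, k], idx[1L, k]] <- dvals[k]
    }
    neighborJoining(d)
}
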