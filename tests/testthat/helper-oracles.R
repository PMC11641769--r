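# Independent brute-force oracles used across the suite. Each is written
# as a direct enumeration so it shares no code path with the package's
# dynamic-programming implementations.

AA20 <- S1Domains:::AA_STANDARD

rand_seq <- function(n, alphabet = AA20) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- Global pairwise alignment oracle ------------------------------------
# Enumerates every global alignment path of a vs b (moves: diagonal,
# gap-in-b, gap-in-a), scoring affine gaps as gapOpen + g * gapExtend per
# maximal gap run. Exponential; fine for nchar <= 7.
enumerate_global_score <- function(a, b, matrix, gapOpen, gapExtend) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    best <- -Inf
    rec <- function(i, j, score, state) {
        if (i > length(av) && j > length(bv)) {
            best <<- max(best, score)
            return(invisible())
        }
        if (i <= length(av) && j <= length(bv))
            rec(i + 1, j + 1, score + matrix[av[i], bv[j]], "M")
        if (i <= length(av)) {   # av[i] against a gap
            open <- if (state == "A") 0 else gapOpen
            rec(i + 1, j, score - open - gapExtend, "A")
        }
        if (j <= length(bv)) {   # bv[j] against a gap
            open <- if (state == "B") 0 else gapOpen
            rec(i, j + 1, score - open - gapExtend, "B")
        }
        invisible()
    }
    rec(1, 1, 0, "M")
    best
}

# ---- Profile glocal alignment oracle -------------------------------------
# Enumerates all glocal alignments (profile consumed in full, sequence
# window free) with at most `max_gap` gap residues in total: deleted
# profile columns and inserted sequence residues. Gap runs cost
# gapOpen + len * gapExtend; a deletion run and an insertion run at the
# same place count as two events.
enumerate_profile_score <- function(scores, seq, gapOpen, gapExtend,
                                    max_gap = 2) {
    sv <- strsplit(seq, "")[[1]]
    L <- ncol(scores)
    n <- length(sv)
    run_cost <- function(positions) {
        if (!length(positions)) return(0)
        runs <- split(positions, cumsum(c(1, diff(positions) != 1)))
        sum(vapply(runs, function(r) gapOpen + length(r) * gapExtend,
                   numeric(1)))
    }
    best <- -Inf
    for (nd in 0:max_gap) {
        delsets <- if (nd == 0) list(integer(0)) else
            asplit(combn(L, nd), 2)
        for (delset in delsets) {
            kept <- setdiff(seq_len(L), delset)
            for (ni in 0:(max_gap - nd)) {
                # insertion slots: after consuming t kept columns (0..#kept)
                slots <- if (ni == 0) list(integer(0)) else
                    asplit(combn(length(kept) + 1, ni) - 1L, 2)
                for (slot in slots) {
                    consumed <- length(kept) + ni
                    if (consumed > n || consumed == 0) next
                    for (s in seq_len(n - consumed + 1)) {
                        # walk: kept columns in order, insertions at slots
                        j <- s
                        sc <- 0
                        ins_pos <- integer(0)   # for run costing of inserts
                        t <- 0
                        for (slot_t in sort(slot)) {
                            # handled inline below
                        }
                        slot_sorted <- sort(slot)
                        walk_ok <- TRUE
                        step <- 0
                        for (ci in seq_along(kept)) {
                            nins <- sum(slot_sorted == ci - 1L)
                            if (nins > 0) {
                                ins_pos <- c(ins_pos, step + seq_len(nins))
                                j <- j + nins
                                step <- step + nins
                            }
                            sc <- sc + scores[sv[j], kept[ci]]
                            j <- j + 1
                            step <- step + 1
                        }
                        nins <- sum(slot_sorted == length(kept))
                        if (nins > 0)
                            ins_pos <- c(ins_pos, step + seq_len(nins))
                        sc <- sc - run_cost(delset) - run_cost(ins_pos)
                        best <- max(best, sc)
                    }
                }
            }
        }
    }
    best
}

# ---- Unrooted topology enumeration + least-squares fit -------------------
# All unrooted binary topologies on labels 1..n, built by inserting each
# new leaf into every edge of every smaller topology. A topology is an
# edge list over nodes (leaves 1..n, internals n+1, ...).
enumerate_topologies <- function(n) {
    stopifnot(n >= 3)
    base <- list(list(edges = cbind(c(n + 1, n + 1, n + 1), c(1, 2, 3)),
                      next_node = n + 2))
    if (n == 3) return(base)
    trees <- base
    for (leaf in 4:n) {
        out <- list()
        for (tr in trees) {
            for (e in seq_len(nrow(tr$edges))) {
                ed <- tr$edges
                u <- tr$next_node
                a <- ed[e, 1]; b <- ed[e, 2]
                ed2 <- rbind(ed[-e, , drop = FALSE],
                             c(a, u), c(u, b), c(u, leaf))
                out[[length(out) + 1]] <- list(edges = ed2,
                                               next_node = u + 1)
            }
        }
        trees <- out
    }
    trees
}

# Leaf-to-leaf path (as edge indicator rows) for least-squares fitting.
topology_fits_additive <- function(edges, d, tol = 1e-8) {
    n <- nrow(d)
    nodes <- sort(unique(as.vector(edges)))
    adj <- lapply(setNames(nodes, nodes), function(x) integer(0))
    for (e in seq_len(nrow(edges))) {
        adj[[as.character(edges[e, 1])]] <-
            c(adj[[as.character(edges[e, 1])]], e)
        adj[[as.character(edges[e, 2])]] <-
            c(adj[[as.character(edges[e, 2])]], e)
    }
    other <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
    path_edges <- function(from, to) {
        # DFS
        seen <- c(from)
        stack <- list(list(v = from, path = integer(0)))
        while (length(stack)) {
            cur <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            if (cur$v == to) return(cur$path)
            for (e in adj[[as.character(cur$v)]]) {
                w <- other(e, cur$v)
                if (!w %in% seen) {
                    seen <- c(seen, w)
                    stack[[length(stack) + 1]] <-
                        list(v = w, path = c(cur$path, e))
                }
            }
        }
        stop("disconnected topology")
    }
    pairs <- combn(n, 2)
    A <- matrix(0, ncol(pairs), nrow(edges))
    y <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
        A[k, path_edges(pairs[1, k], pairs[2, k])] <- 1
        y[k] <- d[pairs[1, k], pairs[2, k]]
    }
    fit <- stats::lsfit(A, y, intercept = FALSE)
    ok <- max(abs(fit$residuals)) < tol && all(fit$coefficients > -tol)
    list(ok = ok, lengths = fit$coefficients)
}

# Splits (bipartitions, as sorted leaf index sets containing leaf 1's
# complement side) of a topology / PhyloTree, for topology comparison.
edge_splits <- function(edges, n) {
    nodes <- sort(unique(as.vector(edges)))
    adj <- lapply(setNames(nodes, nodes), function(x) integer(0))
    for (e in seq_len(nrow(edges))) {
        adj[[as.character(edges[e, 1])]] <-
            c(adj[[as.character(edges[e, 1])]], e)
        adj[[as.character(edges[e, 2])]] <-
            c(adj[[as.character(edges[e, 2])]], e)
    }
    other <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
    reach <- function(start, banned_edge) {
        seen <- start
        stack <- start
        while (length(stack)) {
            v <- stack[[1]]; stack <- stack[-1]
            for (e in adj[[as.character(v)]]) {
                if (e == banned_edge) next
                w <- other(e, v)
                if (!w %in% seen) { seen <- c(seen, w); stack <- c(stack, w) }
            }
        }
        sort(seen[seen <= n])
    }
    splits <- list()
    for (e in seq_len(nrow(edges))) {
        side <- reach(edges[e, 2], e)
        if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
        if (length(side) >= 2 && length(side) <= n - 2)
            splits[[length(splits) + 1]] <- side
    }
    unique(splits)
}

tree_splits <- function(tree) {
    edge_splits(tree@edges, length(leafLabels(tree)))
}

# Random tree with non-negative branch lengths; returns its additive
# distance matrix plus the generating splits.
random_additive_matrix <- function(n, min_len = 0.1, max_len = 2) {
    topo <- enumerate_topologies(n)
    pick <- topo[[sample(length(topo), 1)]]
    lens <- runif(nrow(pick$edges), min_len, max_len)
    nodes <- sort(unique(as.vector(pick$edges)))
    labels <- paste0("t", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    adj <- lapply(setNames(nodes, nodes), function(x) integer(0))
    for (e in seq_len(nrow(pick$edges))) {
        adj[[as.character(pick$edges[e, 1])]] <-
            c(adj[[as.character(pick$edges[e, 1])]], e)
        adj[[as.character(pick$edges[e, 2])]] <-
            c(adj[[as.character(pick$edges[e, 2])]], e)
    }
    other <- function(e, v)
        if (pick$edges[e, 1] == v) pick$edges[e, 2] else pick$edges[e, 1]
    dist_from <- function(s) {
        dd <- setNames(rep(NA_real_, length(nodes)), nodes)
        dd[as.character(s)] <- 0
        stack <- s
        while (length(stack)) {
            v <- stack[[1]]; stack <- stack[-1]
            for (e in adj[[as.character(v)]]) {
                w <- other(e, v)
                if (is.na(dd[as.character(w)])) {
                    dd[as.character(w)] <- dd[as.character(v)] + lens[e]
                    stack <- c(stack, w)
                }
            }
        }
        dd
    }
    for (i in seq_len(n)) d[i, ] <- dist_from(i)[as.character(seq_len(n))]
    list(d = d, splits = edge_splits(pick$edges, n), edges = pick$edges,
         lengths = lens)
}

same_split_set <- function(a, b) {
    key <- function(s) paste(s, collapse = ",")
    setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}
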