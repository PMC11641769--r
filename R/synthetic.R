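#' Specification for the bead-on-a-string family simulator
#'
#' Describes a set of multidomain protein families: an ancestral domain
#' per group, duplicated into k N-to-C positions (paralogous lineages),
#' each lineage then sampled into orthologous copies across proteins, with
#' flexible random linkers and terminal tails between/around domains.
#' An optional \code{transfer} seeds an "organellar" group from one
#' specific domain position of a "bacterial" source group — the
#' generative analogue of endosymbiotic domain inheritance.
#'
#' @param groups list of group specs, each a list with elements
#'   \code{name}, \code{n_proteins}, \code{k} (domain count),
#'   \code{divergence} (expected substitutions/site separating position
#'   lineages from the group ancestor), and optionally
#'   \code{domain_of_life} (default "Bacteria") and \code{phylum}.
#' @param transfer \code{NULL}, or a list with \code{source_group},
#'   \code{source_position}, \code{target_group_name} (must name one of
#'   \code{groups}) and \code{extra_divergence} (default 0.1): every
#'   domain position of the target group descends from the source group's
#'   \code{source_position} lineage ancestor.
#' @param seed mandatory integer seed; generation is fully deterministic
#'   given the spec.
#' @param root_divergence expected substitutions/site separating each
#'   group's ancestral domain from the single family root domain (default
#'   0.6). All groups are homologous — as real S1 domains are across the
#'   domains of life — but only distantly so; the transfer target ignores
#'   this and descends from its source position instead.
#' @param domain_len domain length in residues (default 80, inside the
#'   70-150 OB-fold range).
#' @param linker_len_range integer (min, max) for linker and terminal tail
#'   lengths (default c(10, 25)).
#' @param conservation fraction of domain sites frozen (never substituted;
#'   default 0.3, mimicking a conserved fold/binding site with variable
#'   loops), or a per-position weight vector of length \code{domain_len}
#'   (weight 1 = frozen; intermediate weights scale the substitution
#'   probability).
#' @param ortholog_scale multiplier applied to a group's divergence for
#'   the protein-level (orthologous) divergence within one position
#'   lineage (default 1/3: speciation divergence shallower than the
#'   ancient duplications separating positions).
#' @param background residue frequency vector (default uniform).
#' @return validated spec (list, class "syntheticSpec").
#' @export
syntheticSpec <- function(groups, transfer = NULL, seed,
                          root_divergence = 0.6,
                          domain_len = 80L, linker_len_range = c(10L, 25L),
                          conservation = 0.3, ortholog_scale = 1 / 3,
                          background = uniformBackground()) {
    if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
    if (root_divergence < 0) stop("root_divergence must be >= 0")
    if (!length(groups)) stop("at least one group required")
    for (g in groups) {
        if (is.null(g$name) || is.null(g$n_proteins) || is.null(g$k) ||
            is.null(g$divergence))
            stop("each group needs name, n_proteins, k and divergence")
        if (g$divergence < 0) stop("divergence must be >= 0")
        if (g$k < 1 || g$n_proteins < 1)
            stop("k and n_proteins must be >= 1")
    }
    nm <- vapply(groups, `[[`, character(1), "name")
    if (anyDuplicated(nm)) stop("group names must be unique")
    if (!is.null(transfer)) {
        need <- c("source_group", "source_position", "target_group_name")
        if (!all(need %in% names(transfer)))
            stop("transfer needs source_group, source_position, target_group_name")
        if (is.null(transfer$extra_divergence)) transfer$extra_divergence <- 0.1
        if (!transfer$source_group %in% nm)
            stop("unknown transfer source group ", sQuote(transfer$source_group))
        if (!transfer$target_group_name %in% nm)
            stop("unknown transfer target group ",
                 sQuote(transfer$target_group_name))
        src_k <- groups[[match(transfer$source_group, nm)]]$k
        if (transfer$source_position < 1 || transfer$source_position > src_k)
            stop("source_position must lie in 1..k of the source group")
        if (transfer$extra_divergence < 0)
            stop("extra_divergence must be >= 0")
    }
    if (length(conservation) == 1L) {
        if (conservation < 0 || conservation > 1)
            stop("conservation fraction must lie in [0, 1]")
    } else if (length(conservation) != domain_len) {
        stop("per-position conservation must have length domain_len")
    }
    if (length(linker_len_range) != 2L ||
        linker_len_range[1L] > linker_len_range[2L] ||
        linker_len_range[1L] < 0)
        stop("linker_len_range must be a non-negative (min, max) pair")
    structure(list(groups = groups, transfer = transfer,
                   seed = as.integer(seed),
                   root_divergence = root_divergence,
                   domain_len = as.integer(domain_len),
                   linker_len_range = as.integer(linker_len_range),
                   conservation = conservation,
                   ortholog_scale = ortholog_scale,
                   background = background[AA_STANDARD] /
                       sum(background[AA_STANDARD])),
              class = "syntheticSpec")
}

randomResidues <- function(n, background) {
    if (n == 0L) return("")
    paste(sample(AA_STANDARD, n, replace = TRUE, prob = background),
          collapse = "")
}

#' Substitute residues along a branch of given expected divergence
#'
#' Each site is substituted with probability
#' \eqn{(1 - w_i)(1 - e^{-d})} for divergence \eqn{d} and conservation
#' weight \eqn{w_i} (so weight-1 sites never change); the replacement is
#' drawn from the background distribution excluding the current residue.
#' Length is preserved (no indels). Uses R's global RNG; seed with
#' \code{set.seed} for reproducibility.
#'
#' @param seq protein sequence (single string).
#' @param divergence expected substitutions per site, >= 0.
#' @param conservation per-site weight(s) in [0, 1], recycled (default 0:
#'   all sites free).
#' @param background residue frequencies (default uniform).
#' @return mutated sequence of the same length.
#' @export
mutateSequence <- function(seq, divergence, conservation = 0,
                           background = uniformBackground()) {
    if (divergence < 0) stop("divergence must be >= 0")
    chars <- strsplit(seq, "")[[1L]]
    L <- length(chars)
    w <- rep_len(conservation, L)
    psub <- (1 - w) * (1 - exp(-divergence))
    hit <- which(stats::runif(L) < psub)
    bg <- background[AA_STANDARD] / sum(background[AA_STANDARD])
    for (i in hit) {
        pr <- bg
        pr[chars[i]] <- 0
        chars[i] <- sample(AA_STANDARD, 1L, prob = pr)
    }
    paste(chars, collapse = "")
}

assembleProtein <- function(domains, spec) {
    rng <- spec$linker_len_range
    npieces <- length(domains) + 1L
    lens <- sample(seq(rng[1L], rng[2L]), npieces, replace = TRUE)
    pieces <- character(2L * length(domains) + 1L)
    pieces[1L] <- randomResidues(lens[1L], spec$background)
    starts <- integer(length(domains))
    ends <- integer(length(domains))
    pos <- nchar(pieces[1L])
    for (i in seq_along(domains)) {
        starts[i] <- pos + 1L
        ends[i] <- pos + nchar(domains[i])
        pieces[2L * i] <- domains[i]
        pos <- ends[i]
        pieces[2L * i + 1L] <- randomResidues(lens[i + 1L], spec$background)
        pos <- pos + nchar(pieces[2L * i + 1L])
    }
    list(seq = paste(pieces, collapse = ""), start = starts, end = ends)
}

conservationWeights <- function(spec) {
    L <- spec$domain_len
    if (length(spec$conservation) == L && L > 1L) return(spec$conservation)
    f <- spec$conservation
    w <- numeric(L)
    nfrozen <- round(f * L)
    if (nfrozen > 0L) w[sample(L, nfrozen)] <- 1
    w
}

#' Generate a multidomain protein family with full ground truth
#'
#' Implements the generative model of \code{\link{syntheticSpec}}: one
#' ancestral domain per group; per-position lineage ancestors diverged
#' independently from it (within-protein paralogy); orthologous copies per
#' protein diverged from the lineage ancestor; random linkers/tails; and,
#' if a transfer is requested, the target group's lineage ancestors all
#' descend from the source group's \code{source_position} lineage.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return a \code{\linkS4class{SyntheticTruth}}.
#' @examples
#' sp <- syntheticSpec(groups = list(
#'          list(name = "Cyano", n_proteins = 3, k = 3, divergence = 0.3)),
#'        seed = 1)
#' generateFamily(sp)
#' @export
generateFamily <- function(spec) {
    stopifnot(inherits(spec, "syntheticSpec"))
    set.seed(spec$seed)
    w <- conservationWeights(spec)
    nm <- vapply(spec$groups, `[[`, character(1), "name")
    tr <- spec$transfer
    target <- if (is.null(tr)) NA_character_ else tr$target_group_name

    # One root domain for the whole family; every (non-target) group
    # ancestor diverges from it, so all groups stay homologous. The
    # transfer target's lineages are seeded after its source group exists.
    root <- randomResidues(spec$domain_len, spec$background)
    lineage <- vector("list", length(spec$groups))
    names(lineage) <- nm
    group_anc <- vector("list", length(spec$groups))
    names(group_anc) <- nm
    for (g in spec$groups) {
        if (identical(g$name, target)) next
        anc <- mutateSequence(root, spec$root_divergence, w, spec$background)
        group_anc[[g$name]] <- anc
        lineage[[g$name]] <- vapply(seq_len(g$k), function(p)
            mutateSequence(anc, g$divergence, w, spec$background),
            character(1))
    }
    if (!is.null(tr)) {
        g <- spec$groups[[match(target, nm)]]
        src_anc <- lineage[[tr$source_group]][tr$source_position]
        group_anc[[target]] <- src_anc
        lineage[[target]] <- vapply(seq_len(g$k), function(p)
            mutateSequence(src_anc, tr$extra_divergence, w, spec$background),
            character(1))
    }

    records <- character(0)
    ann <- list()
    tax <- list()
    for (g in spec$groups) {
        d_orth <- g$divergence * spec$ortholog_scale
        for (i in seq_len(g$n_proteins)) {
            pid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", g$name), i)
            doms <- vapply(lineage[[g$name]], mutateSequence, character(1),
                           divergence = d_orth, conservation = w,
                           background = spec$background)
            asm <- assembleProtein(doms, spec)
            records[pid] <- asm$seq
            ann[[pid]] <- data.frame(protein_id = pid,
                                     domain_index = seq_len(g$k),
                                     start = asm$start, end = asm$end,
                                     score = NA_real_,
                                     stringsAsFactors = FALSE)
            tax[[pid]] <- data.frame(id = pid,
                                     domain_of_life = g$domain_of_life %||% "Bacteria",
                                     phylum = g$phylum %||% g$name,
                                     class_ = "", stringsAsFactors = FALSE)
        }
    }
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    taxonomy <- do.call(rbind, tax)
    rownames(taxonomy) <- NULL

    sourceMap <- list()
    if (!is.null(tr)) {
        k_t <- spec$groups[[match(target, nm)]]$k
        sourceMap[[target]] <- setNames(rep(as.integer(tr$source_position), k_t),
                                        paste0("pos", seq_len(k_t)))
    }

    recs <- AAStringSet(records)
    S4Vectors::mcols(recs) <- S4Vectors::DataFrame(
        description = rep("synthetic bead-on-a-string protein", length(recs)))
    new("SyntheticTruth", records = recs, annotations = annotations,
        taxonomy = taxonomy, sourceMap = sourceMap,
        trueTree = lineageNewick(spec, nm, target),
        spec = unclass(spec))
}

# Generating lineage topology (positions as leaves "group.p").
lineageNewick <- function(spec, nm, target) {
    tr <- spec$transfer
    fmt_group <- function(g) {
        leaves <- paste0(g$name, ".", seq_len(g$k), ":", g$divergence)
        if (!is.null(tr) && identical(g$name, tr$source_group) &&
            !is.na(target)) {
            tg <- spec$groups[[match(target, nm)]]
            tleaves <- paste0(target, ".", seq_len(tg$k), ":",
                              tr$extra_divergence)
            sub <- paste0("(", paste(tleaves, collapse = ","), "):0")
            s <- tr$source_position
            leaves[s] <- paste0("(", g$name, ".", s, ":0,", sub, "):",
                                g$divergence)
        }
        paste0("(", paste(leaves, collapse = ","), ")")
    }
    keep <- Filter(function(g) !identical(g$name, target), spec$groups)
    subs <- vapply(keep, function(g) paste0(fmt_group(g), ":1"), character(1))
    if (length(subs) == 1L) return(paste0(fmt_group(keep[[1L]]), ";"))
    paste0("(", paste(subs, collapse = ","), ");")
}

#' Generate a mixed census fixture across the domains of life
#'
#' Builds one family per row of \code{rows}, mixing domain-of-life labels,
#' domain counts and protein size ranges; the first and last protein of
#' each row are pinned to the row's min/max length so census extremes are
#' exactly the specified range. Domain length per row is fitted to the
#' row's minimum protein size when the default would not fit. Protein
#' lengths couple positively with domain counts whenever the specified
#' ranges do, which the census correlation analysis relies on.
#'
#' @param rows data.frame with columns domain_of_life, n_domains,
#'   n_proteins, min_len, max_len (one census cell per row).
#' @param seed integer seed.
#' @param divergence within-row divergence of domains from the row
#'   ancestor (default 0.2).
#' @return a \code{\linkS4class{SyntheticTruth}} (no transfer, no tree).
#' @export
generateCensusFixture <- function(rows, seed, divergence = 0.2) {
    need <- c("domain_of_life", "n_domains", "n_proteins", "min_len", "max_len")
    miss <- setdiff(need, names(rows))
    if (length(miss))
        stop("rows missing column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(rows$domain_of_life), DOMAINS_OF_LIFE)
    if (length(bad))
        stop("unknown domain_of_life value(s): ", paste(bad, collapse = ", "))
    if (any(rows$min_len > rows$max_len)) stop("min_len must be <= max_len")
    set.seed(as.integer(seed))
    bg <- uniformBackground()

    records <- character(0)
    ann <- list()
    tax <- list()
    for (r in seq_len(nrow(rows))) {
        k <- rows$n_domains[r]
        np <- rows$n_proteins[r]
        min_linker <- 5L
        overhead <- (k - 1L) * min_linker
        dlen <- min(80L, (rows$min_len[r] - overhead) %/% k)
        if (dlen < 10L)
            stop("row ", r, ": min_len too small for ", k, " domains")
        anc <- randomResidues(dlen, bg)
        # Middle proteins cluster near the minimal architecture (a long
        # tail up to max_len), so length couples with domain count via
        # the k-dependent minimum, as in real multidomain families.
        mid <- if (np > 2L)
            pmin(rows$max_len[r],
                 rows$min_len[r] +
                     floor((rows$max_len[r] - rows$min_len[r]) *
                           stats::rbeta(np - 2L, 1.2, 4)))
        lens <- if (np == 1L) rows$min_len[r]
                else c(rows$min_len[r], mid, rows$max_len[r])
        for (i in seq_len(np)) {
            pid <- sprintf("%s%d_%03d", toupper(substr(rows$domain_of_life[r], 1, 3)),
                           k, i)
            doms <- vapply(seq_len(k), function(p)
                mutateSequence(anc, divergence, 0, bg), character(1))
            extra <- lens[i] - k * dlen - overhead
            # Split the slack across k+1 tails/linkers (min_linker floor
            # applies to the k-1 internal linkers only).
            cuts <- if (extra > 0L) sort(sample(0:extra, k, replace = TRUE))
                    else rep(0L, k)
            pieceLens <- diff(c(0L, cuts, extra))
            linkLens <- c(pieceLens[1L],
                          if (k > 1L) pieceLens[2L:k] + min_linker,
                          pieceLens[k + 1L])
            pieces <- character(0)
            starts <- integer(k); endsv <- integer(k)
            pos <- 0L
            for (p in seq_len(k)) {
                tail_p <- randomResidues(linkLens[p], bg)
                pieces <- c(pieces, tail_p, doms[p])
                starts[p] <- pos + linkLens[p] + 1L
                endsv[p] <- starts[p] + dlen - 1L
                pos <- endsv[p]
            }
            pieces <- c(pieces, randomResidues(linkLens[k + 1L], bg))
            seqstr <- paste(pieces, collapse = "")
            stopifnot(nchar(seqstr) == lens[i])
            records[pid] <- seqstr
            ann[[pid]] <- data.frame(protein_id = pid,
                                     domain_index = seq_len(k),
                                     start = starts, end = endsv,
                                     score = NA_real_, stringsAsFactors = FALSE)
            tax[[pid]] <- data.frame(id = pid,
                                     domain_of_life = rows$domain_of_life[r],
                                     phylum = "", class_ = "",
                                     stringsAsFactors = FALSE)
        }
    }
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    taxonomy <- do.call(rbind, tax)
    rownames(taxonomy) <- NULL
    recs <- AAStringSet(records)
    S4Vectors::mcols(recs) <- S4Vectors::DataFrame(
        description = rep("synthetic census protein", length(recs)))
    new("SyntheticTruth", records = recs, annotations = annotations,
        taxonomy = taxonomy, sourceMap = list(), trueTree = "",
        spec = list(rows = rows, seed = as.integer(seed),
                    divergence = divergence))
}

#' Default endosymbiosis benchmark spec
#'
#' The standard study conditions used throughout the package's recovery
#' benchmarks: a k = 3 "bacterial" source group (divergence 0.3
#' substitutions/site between position lineages), an independent
#' "bacterial" outgroup, and an "organellar" target group whose domains
#' all descend from position 3 of the source group.
#'
#' @param seed integer seed.
#' @param n_proteins proteins per group (default 5).
#' @param divergence lineage divergence (default 0.3).
#' @param source_position transferred position (default 3).
#' @param extra_divergence transfer branch length (default 0.1).
#' @param with_outgroup include the independent outgroup (default TRUE).
#' @return a \code{\link{syntheticSpec}}.
#' @export
endosymbiosisSpec <- function(seed, n_proteins = 5, divergence = 0.3,
                              source_position = 3, extra_divergence = 0.1,
                              with_outgroup = TRUE) {
    groups <- list(
        list(name = "SourceBac", n_proteins = n_proteins, k = 3,
             divergence = divergence, domain_of_life = "Bacteria",
             phylum = "SourcePhylum"),
        list(name = "Organelle", n_proteins = n_proteins, k = 3,
             divergence = divergence, domain_of_life = "Eukaryota",
             phylum = "Streptophyta"))
    if (with_outgroup)
        groups[[3]] <- list(name = "OtherBac", n_proteins = n_proteins, k = 3,
                            divergence = divergence,
                            domain_of_life = "Bacteria",
                            phylum = "OtherPhylum")
    syntheticSpec(groups = groups,
                  transfer = list(source_group = "SourceBac",
                                  source_position = source_position,
                                  target_group_name = "Organelle",
                                  extra_divergence = extra_divergence),
                  seed = seed)
}
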