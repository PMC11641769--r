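#' Run a pipeline stage by name
#'
#' Single programmatic entry point behind the command-line wrapper
#' (\code{inst/scripts/s1pipeline.R}). Each subcommand reads and writes
#' the package's file dialects and logs the package version and the full
#' parameter set via \code{message}.
#'
#' Subcommands and their arguments (all files are paths):
#' \describe{
#'   \item{simulate}{\code{seed}; optional \code{n_proteins},
#'     \code{divergence}; writes \code{fasta}, \code{domains},
#'     \code{taxonomy} (and \code{tree}: the generating lineage tree).}
#'   \item{scan}{\code{fasta}, \code{seed_alignment}, \code{domains}
#'     (output); optional \code{cutoff}, \code{gap_open}, \code{gap_extend}.}
#'   \item{census}{\code{fasta}, \code{domains}, \code{taxonomy},
#'     \code{out}.}
#'   \item{idmatrix}{\code{fasta}, \code{domains}, \code{taxonomy},
#'     \code{group_a}/\code{group_b} (phylum names), \code{k_a}/\code{k_b},
#'     \code{out}; optional \code{denominator}.}
#'   \item{correspond}{\code{fasta}, \code{domains}, \code{taxonomy},
#'     \code{group_a}, \code{group_b}, \code{k_a}, \code{k_b}, \code{out}.}
#'   \item{tree}{\code{distances} (square TSV), \code{out} (Newick).}
#'   \item{fetch}{\code{accessions} (character vector), \code{out};
#'     requires network access, cached per accession.}
#' }
#'
#' @param subcommand one of simulate, scan, census, idmatrix, correspond,
#'   tree, fetch.
#' @param args named list of arguments, see Details.
#' @return invisibly, the main output path (or object) of the stage.
#' @export
s1Pipeline <- function(subcommand = c("simulate", "scan", "census",
                                      "idmatrix", "correspond", "tree",
                                      "fetch"),
                       args = list()) {
    subcommand <- match.arg(subcommand)
    ver <- as.character(utils::packageVersion("S1Domains"))
    message("S1Domains ", ver, " :: ", subcommand, " :: ",
            paste(names(args), unlist(lapply(args, function(a)
                paste(format(a), collapse = ","))), sep = "=", collapse = " "))
    need <- function(what) {
        if (is.null(args[[what]]))
            stop("subcommand ", sQuote(subcommand), " requires argument ",
                 sQuote(what))
        args[[what]]
    }
    switch(subcommand,
        simulate = {
            spec <- endosymbiosisSpec(
                seed = as.integer(need("seed")),
                n_proteins = as.integer(args$n_proteins %||% 5L),
                divergence = as.numeric(args$divergence %||% 0.3))
            truth <- generateFamily(spec)
            writeProteins(truthRecords(truth), need("fasta"))
            writeDomainTable(truthAnnotations(truth), need("domains"))
            writeTaxonomy(truthTaxonomy(truth), need("taxonomy"))
            if (!is.null(args$tree)) writeLines(truthTree(truth), args$tree)
            invisible(args$fasta)
        },
        scan = {
            seed_aln <- readSeedAlignment(need("seed_alignment"))
            prof <- buildProfile(seed_aln,
                                 gapOpen = as.numeric(args$gap_open %||% 11),
                                 gapExtend = as.numeric(args$gap_extend %||% 1),
                                 cutoff = as.numeric(args$cutoff %||% 1.0))
            recs <- readProteins(need("fasta"))
            ann <- scanProteins(prof, recs)
            writeDomainTable(ann, need("domains"))
            invisible(args$domains)
        },
        census = {
            recs <- readProteins(need("fasta"))
            ann <- readDomainTable(need("domains"))
            tax <- readTaxonomy(need("taxonomy"))
            censusToTsv(buildCensus(recs, ann, tax), need("out"))
            invisible(args$out)
        },
        idmatrix = {
            m <- pipelineIdentityMatrix(args, need)
            writeIdentityMatrix(m, need("out"))
            invisible(args$out)
        },
        correspond = {
            m <- pipelineIdentityMatrix(args, need)
            bc <- bestCorrespondence(m)
            utils::write.table(bc, need("out"), sep = "\t", quote = FALSE,
                               row.names = FALSE)
            invisible(args$out)
        },
        tree = {
            d <- readDistanceMatrix(need("distances"))
            writeLines(toNewick(neighborJoining(d)), need("out"))
            invisible(args$out)
        },
        fetch = {
            fetchUniProt(need("accessions"), need("out"),
                         cacheDir = args$cache_dir)
            invisible(args$out)
        })
}

pipelineIdentityMatrix <- function(args, need) {
    recs <- readProteins(need("fasta"))
    ann <- readDomainTable(need("domains"))
    tax <- readTaxonomy(need("taxonomy"))
    den <- args$denominator %||% "both-residues"
    ga <- extractDomains(recs, ann, tax, k = as.integer(need("k_a")),
                         name = need("group_a"), phylum = need("group_a"))
    gb <- extractDomains(recs, ann, tax, k = as.integer(need("k_b")),
                         name = need("group_b"), phylum = need("group_b"))
    identityMatrix(ga, gb, denominator = den)
}

#' Fetch protein records from UniProt (network)
#'
#' Downloads FASTA records from the UniProt REST service, one accession
#' at a time, caching each under \code{cacheDir}, then concatenates the
#' requested set to \code{out}. The only networked operation in the
#' package; every analysis runs offline.
#'
#' @param accessions character vector of UniProt accessions.
#' @param out output FASTA path.
#' @param cacheDir cache directory (default
#'   \code{tools::R_user_dir("S1Domains", "cache")}).
#' @return the records, as \code{\link{readProteins}} returns them.
#' @export
fetchUniProt <- function(accessions, out,
                         cacheDir = tools::R_user_dir("S1Domains", "cache")) {
    if (is.null(cacheDir)) cacheDir <- tools::R_user_dir("S1Domains", "cache")
    dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(length(accessions))
    for (i in seq_along(accessions)) {
        acc <- accessions[i]
        dest <- file.path(cacheDir, paste0(acc, ".fasta"))
        if (!file.exists(dest) || file.size(dest) == 0) {
            url <- paste0("https://rest.uniprot.org/uniprotkb/", acc, ".fasta")
            status <- tryCatch(
                utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                error = function(e) -1L, warning = function(w) -1L)
            if (!identical(status, 0L) || !file.exists(dest) ||
                file.size(dest) == 0) {
                unlink(dest)
                stop("could not fetch UniProt record ", sQuote(acc),
                     " (network unavailable?)")
            }
        }
        paths[i] <- dest
    }
    lines <- unlist(lapply(paths, readLines))
    # UniProt headers are "sp|ACC|NAME ..."; expose the accession as id.
    lines <- sub("^>(sp|tr)\\|([^|]+)\\|(\\S*)", ">\\2 \\3", lines)
    writeLines(lines, out)
    readProteins(out)
}

#' Fetch S1 domain features for an accession from UniProt (network)
#'
#' Queries the UniProt REST JSON for one accession and returns its "S1
#' motif"/S1 domain feature ranges as a domain-annotation data.frame.
#' Used to bootstrap a real seed domain when no curated S1 seed alignment
#' is supplied; requires the jsonlite package and network access.
#'
#' @param accession UniProt accession.
#' @param cacheDir cache directory (as \code{\link{fetchUniProt}}).
#' @return data.frame in the \code{\link{readDomainTable}} dialect.
#' @export
fetchUniProtS1Features <- function(accession,
                                   cacheDir = tools::R_user_dir("S1Domains",
                                                                "cache")) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("fetchUniProtS1Features requires the jsonlite package")
    dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
    dest <- file.path(cacheDir, paste0(accession, ".json"))
    if (!file.exists(dest) || file.size(dest) == 0) {
        url <- paste0("https://rest.uniprot.org/uniprotkb/", accession,
                      ".json?fields=ft_domain")
        status <- tryCatch(
            utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
            error = function(e) -1L, warning = function(w) -1L)
        if (!identical(status, 0L) || !file.exists(dest) ||
            file.size(dest) == 0) {
            unlink(dest)
            stop("could not fetch UniProt features for ", sQuote(accession),
                 " (network unavailable?)")
        }
    }
    js <- jsonlite::fromJSON(dest, simplifyVector = FALSE)
    feats <- js$features %||% list()
    rows <- list()
    for (f in feats) {
        if (!identical(f$type, "Domain")) next
        if (!grepl("S1", f$description %||% "")) next
        rows[[length(rows) + 1L]] <- data.frame(
            protein_id = accession, domain_index = NA_integer_,
            start = as.integer(f$location$start$value),
            end = as.integer(f$location$end$value),
            score = NA_real_, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        stop("no S1 domain feature found for ", sQuote(accession))
    out <- do.call(rbind, rows)
    out <- out[order(out$start), ]
    out$domain_index <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
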