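.RANKS <- c("k", "p", "c", "o", "f", "g", "s")

#' Parse Greengenes-style lineage strings
#'
#' Splits lineages of the form
#' `"k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; ..."` into a
#' rank-by-OTU character matrix. Missing or empty fields (e.g. `"g__"`)
#' become `NA`.
#'
#' @param lineages character vector of lineage strings.
#' @return character matrix with rows `k, p, c, o, f, g, s` and one column
#'   per input lineage.
#' @export
parseLineages <- function(lineages) {
    out <- matrix(NA_character_, nrow = length(.RANKS), ncol = length(lineages),
                  dimnames = list(.RANKS, names(lineages)))
    fields <- strsplit(lineages, ";\\s*")
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        m <- regmatches(f, regexec("^([kpcofgs])__(.*)$", f))
        for (mm in m) {
            if (length(mm) == 3L && nzchar(mm[3L]))
                out[mm[2L], i] <- mm[3L]
        }
    }
    out
}

#' Default clade scheme
#'
#' A priority-ordered scheme of 26 mixed-rank clades (families, orders,
#' classes, phyla plus "other"/"unclassified" buckets) reflecting the taxa
#' that dominate *Fucus*-associated epibacterial communities —
#' Rhodobacteraceae, Flavobacteriaceae, Saprospiraceae, Thiotrichales,
#' Firmicutes, and the unresolved Proteobacteria/phylum buckets among them.
#' Each OTU is assigned to the first matching entry; the final two entries
#' ("other phyla", "unclassified") are catch-alls that make the assignment
#' total.
#'
#' Entry types: `taxon` (lineage carries `taxon` at `rank`), `unclassified`
#' (lineage carries `taxon` at `rank` but nothing at the next rank down),
#' `any` (any assignment at `rank`), `none` (no assignment at `rank`).
#'
#' @return `data.frame` with columns `clade`, `type`, `rank`, `taxon`.
#' @seealso [assignClades()], [readCladeScheme()]
#' @export
defaultCladeScheme <- function() {
    e <- function(clade, type, rank, taxon = NA_character_)
        data.frame(clade = clade, type = type, rank = rank, taxon = taxon,
                   stringsAsFactors = FALSE)
    rbind(
        e("Rhodobacteraceae",                 "taxon", "f", "Rhodobacteraceae"),
        e("Sphingomonadaceae",                "taxon", "f", "Sphingomonadaceae"),
        e("Hyphomonadaceae",                  "taxon", "f", "Hyphomonadaceae"),
        e("unclassified Alphaproteobacteria", "unclassified", "c", "Alphaproteobacteria"),
        e("other Alphaproteobacteria",        "taxon", "c", "Alphaproteobacteria"),
        e("Alteromonadaceae",                 "taxon", "f", "Alteromonadaceae"),
        e("Pseudoalteromonadaceae",           "taxon", "f", "Pseudoalteromonadaceae"),
        e("Colwelliaceae",                    "taxon", "f", "Colwelliaceae"),
        e("Thiotrichales",                    "taxon", "o", "Thiotrichales"),
        e("Oceanospirillales",                "taxon", "o", "Oceanospirillales"),
        e("other Gammaproteobacteria",        "taxon", "c", "Gammaproteobacteria"),
        e("Betaproteobacteria",               "taxon", "c", "Betaproteobacteria"),
        e("Deltaproteobacteria",              "taxon", "c", "Deltaproteobacteria"),
        e("unclassified Proteobacteria",      "unclassified", "p", "Proteobacteria"),
        e("other Proteobacteria",             "taxon", "p", "Proteobacteria"),
        e("Flavobacteriaceae",                "taxon", "f", "Flavobacteriaceae"),
        e("other Flavobacteriia",             "taxon", "c", "Flavobacteriia"),
        e("Saprospiraceae",                   "taxon", "f", "Saprospiraceae"),
        e("other Bacteroidetes",              "taxon", "p", "Bacteroidetes"),
        e("Firmicutes",                       "taxon", "p", "Firmicutes"),
        e("Actinobacteria",                   "taxon", "p", "Actinobacteria"),
        e("Cyanobacteria",                    "taxon", "p", "Cyanobacteria"),
        e("Planctomycetes",                   "taxon", "p", "Planctomycetes"),
        e("Verrucomicrobia",                  "taxon", "p", "Verrucomicrobia"),
        e("other phyla",                      "any",  "p"),
        e("unclassified",                     "none", "p")
    )
}

#' Read a clade scheme from YAML
#'
#' The YAML file holds a list of entries with fields `clade`, `type`
#' (`taxon`/`unclassified`/`any`/`none`), `rank` and (where applicable)
#' `taxon`, in priority order; the last entries should be catch-alls.
#'
#' @param path YAML file path.
#' @return `data.frame` as [defaultCladeScheme()].
#' @export
readCladeScheme <- function(path) {
    lst <- yaml::read_yaml(path)
    do.call(rbind, lapply(lst, function(x)
        data.frame(clade = x$clade, type = x$type, rank = x$rank,
                   taxon = if (is.null(x$taxon)) NA_character_ else x$taxon,
                   stringsAsFactors = FALSE)))
}

#' Assign each OTU to exactly one clade
#'
#' Applies a priority-ordered clade scheme to lineage strings: each OTU gets
#' the first matching clade. Schemes ending in `any`/`none` catch-alls (as
#' the default does) assign every OTU.
#'
#' @param lineages named character vector of lineage strings (names = OTU
#'   ids), as stored by [OtuExperiment()] / returned by [otuLineages()].
#' @param scheme clade scheme `data.frame` (default [defaultCladeScheme()]).
#' @return named character vector: OTU id -> clade.
#' @export
assignClades <- function(lineages, scheme = defaultCladeScheme()) {
    tax <- parseLineages(lineages)
    clade <- rep(NA_character_, length(lineages))
    childOf <- stats::setNames(c(.RANKS[-1L], NA), .RANKS)
    for (i in seq_len(nrow(scheme))) {
        open <- is.na(clade)
        if (!any(open)) break
        rk <- scheme$rank[i]
        hit <- switch(scheme$type[i],
            taxon = !is.na(tax[rk, ]) & tax[rk, ] == scheme$taxon[i],
            unclassified = {
                ch <- childOf[[rk]]
                !is.na(tax[rk, ]) & tax[rk, ] == scheme$taxon[i] &
                    is.na(tax[ch, ])
            },
            any  = !is.na(tax[rk, ]),
            none = is.na(tax[rk, ]),
            stop("unknown scheme entry type: ", scheme$type[i]))
        clade[open & hit] <- scheme$clade[i]
    }
    if (anyNA(clade))
        stop("scheme does not cover ", sum(is.na(clade)),
             " OTU(s); add catch-all entries")
    stats::setNames(clade, names(lineages))
}
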