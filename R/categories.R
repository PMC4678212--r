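#' Read and validate a category-rule configuration
#'
#' Rules live in a YAML list, one block per rule with fields \code{name},
#' \code{include} (non-empty list of case-insensitive substrings matched
#' against gene descriptions), optional \code{exclude}, and optional
#' \code{reassign_to}. A rule with \code{reassign_to} moves its matches out of
#' the category named by \code{name} and into \code{reassign_to} — this is how
#' GH9A1/KORRIGAN-like genes leave the cellulases and join cellulose
#' biosynthesis. The shipped default configuration
#' (\code{system.file("extdata", "default_categories.yaml", package =
#' "azflux")}) reconstructs the named abscission categories from their
#' annotation exemplars.
#'
#' @param path YAML file path, or omitted for the shipped default.
#' @return a list of validated rule lists, in file order.
#' @examples
#' rules <- readCategoryRules()
#' vapply(rules, `[[`, "", "name")
#' @export
readCategoryRules <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "default_categories.yaml",
                            package = "azflux")
    rules <- yaml::read_yaml(path)
    validateCategoryRules(rules)
}

#' @rdname readCategoryRules
#' @param rules a list of rule lists, e.g. parsed from YAML.
#' @export
validateCategoryRules <- function(rules) {
    if (!length(rules)) stop("empty category rule set")
    names_ <- vapply(rules, function(r) r$name %||% "", "")
    if (any(names_ == "")) stop("every rule needs a name")
    for (r in rules) {
        if (!length(r$include))
            stop("rule '", r$name, "' has no include keywords")
        if (!is.null(r$reassign_to) && !r$reassign_to %in% names_)
            stop("rule '", r$name, "' reassigns to undefined category '",
                 r$reassign_to, "'")
    }
    rules
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ruleMatches <- function(rule, descLower) {
    hit <- Reduce(`|`, lapply(tolower(rule$include), grepl, x = descLower,
                              fixed = TRUE))
    if (length(rule$exclude)) {
        ex <- Reduce(`|`, lapply(tolower(rule$exclude), grepl, x = descLower,
                                 fixed = TRUE))
        hit <- hit & !ex
    }
    hit
}

#' Assign genes to functional categories by annotation keywords
#'
#' Matching is case-insensitive substring search on the free-text gene
#' description. A gene may belong to several categories; genes matching no
#' rule stay uncategorized. Reassignment rules are applied after all base
#' rules: their matches are removed from the source category and added to the
#' target, so the total count of category memberships involved is conserved.
#'
#' @param annotations data.frame with columns \code{gene_id} and
#'   \code{description} (as from [geneAnnotation()]).
#' @param rules validated rules from [readCategoryRules()].
#' @return named list, one character vector of gene ids per category, in rule
#'   order (reassignment rules contribute no category of their own).
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2"),
#'                   description = c("cellulase precursor",
#'                                   "glycoside hydrolase 9A1 (KORRIGAN)"))
#' assignCategories(ann, readCategoryRules())[c("cellulases",
#'                                              "cellulose_biosynthesis")]
#' @export
assignCategories <- function(annotations, rules) {
    rules <- validateCategoryRules(rules)
    ids <- annotations$gene_id
    descLower <- tolower(annotations$description %||%
                         character(nrow(annotations)))
    base <- Filter(function(r) is.null(r$reassign_to), rules)
    moves <- Filter(function(r) !is.null(r$reassign_to), rules)
    catNames <- unique(vapply(base, `[[`, "", "name"))
    sets <- stats::setNames(vector("list", length(catNames)), catNames)
    for (r in base) {
        hit <- ids[.ruleMatches(r, descLower)]
        sets[[r$name]] <- union(sets[[r$name]], hit)
    }
    for (r in moves) {
        hit <- ids[.ruleMatches(r, descLower)]
        if (!length(hit)) next
        if (r$name %in% names(sets))
            sets[[r$name]] <- setdiff(sets[[r$name]], hit)
        sets[[r$reassign_to]] <- union(sets[[r$reassign_to]], hit)
    }
    lapply(sets, function(s) sort(s %||% character()))
}

#' Aggregate category expression into percent-of-transcriptome profiles
#'
#' For every category and sample, the summed expression of the category's
#' member genes as a percent of the total over all genes in the matrix
#' ([transcriptomeShare()]); plus member counts and the dominant gene per
#' category and condition. Categories whose members are all absent from the
#' matrix are reported with count 0 and a flat 0\% row (logged), never an
#' error.
#'
#' @param x a floored [AZExperiment] restricted to expressed genes.
#' @param mapping named list of gene-id vectors, as from
#'   [assignCategories()].
#' @return a [CategoryProfile-class].
#' @export
categoryProfile <- function(x, mapping) {
    stopifnot(is(x, "AZExperiment"))
    m <- assay(x)
    members <- lapply(mapping, function(g) intersect(g, rownames(m)))
    empty <- names(members)[lengths(members) == 0L]
    if (length(empty))
        message("categories with no expressed members: ",
                paste(empty, collapse = ", "))
    pct <- t(vapply(members,
                    function(g) transcriptomeShare(m, g),
                    numeric(ncol(m))))
    dimnames(pct) <- list(names(members), colnames(m))
    cm <- conditionMeans(x)
    rows <- list()
    for (catName in names(members)) {
        g <- members[[catName]]
        if (!length(g)) next
        for (cond in colnames(cm)) {
            tot <- sum(cm[g, cond])
            if (tot == 0) next
            dom <- dominantGeneShare(x, g, cond)
            rows[[length(rows) + 1L]] <- DataFrame(
                category = catName, condition = cond, gene = dom$gene,
                share = dom$share)
        }
    }
    dominant <- if (length(rows)) do.call(rbind, rows) else
        DataFrame(category = character(), condition = character(),
                  gene = character(), share = numeric())
    new("CategoryProfile", percent = pct,
        counts = stats::setNames(lengths(members), names(members)),
        dominant = dominant)
}

#' Dominant gene of a category in a condition
#'
#' The member gene with the largest condition-mean expression and its share
#' of the category total — e.g. a single cellulase carrying ~75\% of the
#' category's RNA in the abscission zone. Ties are broken by lexicographic
#' gene id and logged.
#'
#' @param x an [AZExperiment] (condition means are computed internally) or a
#'   gene-by-condition means matrix.
#' @param members non-empty character vector of member gene ids.
#' @param condition condition id (see [conditionMeans()] column names).
#' @return list with elements \code{gene} and \code{share} (in (0, 1]).
#' @export
dominantGeneShare <- function(x, members, condition) {
    cm <- if (is(x, "AZExperiment")) conditionMeans(x) else as.matrix(x)
    if (!condition %in% colnames(cm)) stop("unknown condition: ", condition)
    if (!length(members)) stop("empty category member set")
    missing <- setdiff(members, rownames(cm))
    if (length(missing))
        stop("member(s) absent from the matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    v <- cm[members, condition]
    names(v) <- members
    tot <- sum(v)
    if (tot == 0) stop("zero category total in condition ", condition)
    best <- max(v)
    top <- sort(names(v)[v == best])
    if (length(top) > 1L)
        message("dominant-gene tie in ", condition, ": ",
                paste(top, collapse = ", "), "; keeping ", top[1])
    list(gene = top[1], share = unname(best / tot))
}
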