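# Model construction and I/O (BiGG-style JSON and a minimal SBML L3+FBC
# subset).

#' Construct a metabolic model from parts
#'
#' @param metabolites data.frame with columns \code{id}, \code{compartment}
#'   and optionally \code{name}.
#' @param reactions list of reactions, each a list with \code{id},
#'   \code{metabolites} (named numeric of signed stoichiometric
#'   coefficients), \code{lower_bound}, \code{upper_bound} and optional
#'   \code{gene_reaction_rule}.
#' @param genes optional character vector of gene ids; the union with all
#'   genes referenced by GPR rules is stored.
#' @return a validated [MetabolicModel-class].
#' @examples
#' mets <- data.frame(id = c("A_c", "B_c"), compartment = "c")
#' rxns <- list(list(id = "R1", metabolites = c(A_c = -1, B_c = 1),
#'                   lower_bound = 0, upper_bound = 10,
#'                   gene_reaction_rule = "G1"))
#' makeMetabolicModel(mets, rxns)
#' @export
makeMetabolicModel <- function(metabolites, reactions, genes = character()) {
    metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
    if (is.null(metabolites$name)) metabolites$name <- metabolites$id
    metabolites <- metabolites[c("id", "compartment", "name")]
    metabolites$id <- as.character(metabolites$id)

    rid <- vapply(reactions, function(r) as.character(r$id), character(1))
    if (anyDuplicated(rid))
        stop(sprintf("duplicate reaction id: %s", rid[duplicated(rid)][1]),
             call. = FALSE)
    lb <- vapply(reactions, function(r) as.numeric(r$lower_bound), numeric(1))
    ub <- vapply(reactions, function(r) as.numeric(r$upper_bound), numeric(1))
    gpr <- vapply(reactions, function(r) {
        g <- r$gene_reaction_rule
        if (is.null(g) || is.na(g)) "" else as.character(g)
    }, character(1))

    i <- integer(); j <- integer(); x <- numeric()
    for (k in seq_along(reactions)) {
        st <- unlist(reactions[[k]]$metabolites)
        if (length(st) == 0)
            stop(sprintf("reaction %s has empty stoichiometry", rid[k]),
                 call. = FALSE)
        pos <- match(names(st), metabolites$id)
        if (anyNA(pos))
            stop(sprintf("reaction %s references undeclared metabolite(s): %s",
                         rid[k], paste(names(st)[is.na(pos)], collapse = ", ")),
                 call. = FALSE)
        i <- c(i, pos); j <- c(j, rep(k, length(st))); x <- c(x, as.numeric(st))
    }
    S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(nrow(metabolites), length(reactions)),
                              dimnames = list(metabolites$id, rid))
    S <- methods::as(S, "CsparseMatrix")

    rules <- vector("list", length(reactions))
    names(rules) <- rid
    for (k in seq_along(reactions)) {
        rules[k] <- list(tryCatch(parseGPR(gpr[k]), error = function(e) {
            warning(sprintf("reaction %s: unparseable GPR treated as empty (%s)",
                            rid[k], conditionMessage(e)), call. = FALSE)
            NULL
        }))
        if (is.null(rules[[k]])) gpr[k] <- ""
    }
    allGenes <- sort(unique(c(as.character(genes),
                              unlist(lapply(rules, gprGenes)))))
    new("MetabolicModel",
        metabolites = metabolites,
        reactions = data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                               gpr = gpr, stringsAsFactors = FALSE),
        stoichiometry = methods::as(S, "dgCMatrix"),
        gprRules = rules, genes = allGenes)
}

#' Read a genome-scale metabolic model
#'
#' Supports a BiGG-compatible JSON dialect (keys \code{metabolites},
#' \code{reactions} with \code{id}/\code{metabolites}/\code{lower_bound}/
#' \code{upper_bound}/\code{gene_reaction_rule}, \code{genes}) and an SBML
#' Level 3 + FBC subset (species, reactions with FBC flux-bound parameters,
#' gene-product associations).
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"}; guessed from the extension
#'   by default.
#' @return a validated [MetabolicModel-class].  Unparseable GPR strings are
#'   reported as warnings and treated as empty rules.
#' @export
readMetabolicModel <- function(path, format = c("auto", "json", "sbml")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop(sprintf("model file not found: %s", path), call. = FALSE)
    if (format == "auto")
        format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
            "sbml" else "json"
    if (format == "json") readModelJSON(path) else readModelSBML(path)
}

readModelJSON <- function(path) {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                        stop(sprintf("malformed model JSON '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
    if (is.null(doc$metabolites) || is.null(doc$reactions))
        stop(sprintf("model JSON '%s' lacks metabolites/reactions", path),
             call. = FALSE)
    mets <- data.frame(
        id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
        compartment = vapply(doc$metabolites, function(m)
            if (is.null(m$compartment)) "" else as.character(m$compartment),
            character(1)),
        name = vapply(doc$metabolites, function(m)
            if (is.null(m$name)) as.character(m$id) else as.character(m$name),
            character(1)),
        stringsAsFactors = FALSE)
    genes <- vapply(doc$genes, function(g)
        if (is.list(g)) as.character(g$id) else as.character(g), character(1))
    makeMetabolicModel(mets, doc$reactions, genes)
}

#' Write a metabolic model
#'
#' Serialization uses canonical lexicographic ordering of metabolite,
#' reaction and gene ids, so re-serializing a read file is byte-identical.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @param format \code{"json"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
writeMetabolicModel <- function(model, path, format = c("json", "sbml")) {
    format <- match.arg(format)
    if (format == "json") writeModelJSON(model, path)
    else writeModelSBML(model, path)
    invisible(path)
}

writeModelJSON <- function(model, path) {
    mets <- model@metabolites[order(model@metabolites$id), , drop = FALSE]
    rord <- order(model@reactions$id)
    rxns <- lapply(rord, function(k) {
        st <- model@stoichiometry[, k]
        st <- st[st != 0]
        st <- st[order(names(st))]
        list(id = model@reactions$id[k],
             metabolites = as.list(st),
             lower_bound = model@reactions$lower_bound[k],
             upper_bound = model@reactions$upper_bound[k],
             gene_reaction_rule = model@reactions$gpr[k])
    })
    doc <- list(
        metabolites = lapply(seq_len(nrow(mets)), function(k)
            list(id = mets$id[k], compartment = mets$compartment[k],
                 name = mets$name[k])),
        reactions = rxns,
        genes = as.list(sort(model@genes)))
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = 2), path)
}

# ---- SBML L3 + FBC subset ---------------------------------------------------

sbmlFindAll <- function(node, name)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))

readModelSBML <- function(path) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        stop(sprintf("malformed SBML '%s': %s", path, conditionMessage(e)),
             call. = FALSE))
    params <- sbmlFindAll(doc, "parameter")
    pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                            xml2::xml_attr(params, "id"))
    boundVal <- function(ref, default) {
        if (is.na(ref)) return(default)
        if (!ref %in% names(pval))
            stop(sprintf("SBML flux bound references unknown parameter '%s'",
                         ref), call. = FALSE)
        unname(pval[ref])
    }
    species <- sbmlFindAll(doc, "species")
    mets <- data.frame(
        id = xml2::xml_attr(species, "id"),
        compartment = xml2::xml_attr(species, "compartment"),
        name = ifelse(is.na(xml2::xml_attr(species, "name")),
                      xml2::xml_attr(species, "id"),
                      xml2::xml_attr(species, "name")),
        stringsAsFactors = FALSE)
    gps <- sbmlFindAll(doc, "geneProduct")
    geneById <- stats::setNames(
        ifelse(is.na(xml2::xml_attr(gps, "label")),
               xml2::xml_attr(gps, "id"), xml2::xml_attr(gps, "label")),
        xml2::xml_attr(gps, "id"))
    assocToString <- function(node) {
        nm <- xml2::xml_name(node)
        if (nm == "geneProductRef") {
            ref <- xml2::xml_attr(node, "geneProduct")
            g <- if (ref %in% names(geneById)) geneById[[ref]] else ref
            return(g)
        }
        kids <- xml2::xml_children(node)
        parts <- vapply(kids, assocToString, character(1))
        op <- if (nm == "and") " and " else " or "
        paste0("(", paste(parts, collapse = op), ")")
    }
    rnodes <- sbmlFindAll(doc, "reaction")
    rxns <- lapply(rnodes, function(rn) {
        id <- xml2::xml_attr(rn, "id")
        reac <- xml2::xml_find_all(rn,
            ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
        prod <- xml2::xml_find_all(rn,
            ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
        st <- c(
            stats::setNames(-as.numeric(ifelse(
                is.na(xml2::xml_attr(reac, "stoichiometry")), "1",
                xml2::xml_attr(reac, "stoichiometry"))),
                xml2::xml_attr(reac, "species")),
            stats::setNames(as.numeric(ifelse(
                is.na(xml2::xml_attr(prod, "stoichiometry")), "1",
                xml2::xml_attr(prod, "stoichiometry"))),
                xml2::xml_attr(prod, "species")))
        rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
        lb <- boundVal(xml2::xml_attr(rn, "lowerFluxBound"),
                       if (rev) -1000 else 0)
        ub <- boundVal(xml2::xml_attr(rn, "upperFluxBound"), 1000)
        gpa <- xml2::xml_find_first(rn,
            ".//*[local-name()='geneProductAssociation']")
        gpr <- ""
        if (!inherits(gpa, "xml_missing")) {
            kids <- xml2::xml_children(gpa)
            if (length(kids)) gpr <- assocToString(kids[[1]])
        }
        list(id = id, metabolites = as.list(st), lower_bound = lb,
             upper_bound = ub, gene_reaction_rule = gpr)
    })
    makeMetabolicModel(mets, rxns, genes = unname(geneById))
}

writeModelSBML <- function(model, path) {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
    num <- function(v) vapply(v, function(x) sprintf("%.17g", x), character(1))
    bounds <- sort(unique(c(model@reactions$lower_bound,
                            model@reactions$upper_bound)))
    bid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), num(bounds))
    bref <- function(v) unname(bid[num(v)])
    assocXML <- function(node) {
        if (node$op == "leaf")
            return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                           esc(node$gene)))
        inner <- paste(vapply(node$children, assocXML, character(1)),
                       collapse = "")
        sprintf("<fbc:%s>%s</fbc:%s>", node$op, inner, node$op)
    }
    mets <- model@metabolites[order(model@metabolites$id), , drop = FALSE]
    comps <- sort(unique(mets$compartment))
    lines <- c(
        '<?xml version="1.0" encoding="UTF-8"?>',
        paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
               'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
               'level="3" version="1" fbc:required="false">'),
        '<model id="model" fbc:strict="true">',
        "<listOfCompartments>",
        sprintf('<compartment id="%s" constant="true"/>', esc(comps)),
        "</listOfCompartments>",
        "<listOfSpecies>",
        sprintf(paste0('<species id="%s" compartment="%s" name="%s" ',
                       'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                       'constant="false"/>'),
                esc(mets$id), esc(mets$compartment), esc(mets$name)),
        "</listOfSpecies>",
        "<listOfParameters>",
        sprintf('<parameter id="%s" value="%s" constant="true"/>',
                unname(bid), num(bounds)),
        "</listOfParameters>",
        "<fbc:listOfGeneProducts>",
        sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                esc(sort(model@genes)), esc(sort(model@genes))),
        "</fbc:listOfGeneProducts>",
        "<listOfReactions>")
    for (k in order(model@reactions$id)) {
        r <- model@reactions[k, ]
        st <- model@stoichiometry[, k]
        st <- st[st != 0]
        st <- st[order(names(st))]
        sref <- function(ids, coefs)
            sprintf(paste0('<speciesReference species="%s" stoichiometry="%s" ',
                           'constant="true"/>'),
                    esc(ids), num(coefs))
        lines <- c(lines, sprintf(
            paste0('<reaction id="%s" reversible="%s" fast="false" ',
                   'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
            esc(r$id), tolower(r$lower_bound < 0),
            bref(r$lower_bound), bref(r$upper_bound)))
        if (any(st < 0))
            lines <- c(lines, "<listOfReactants>",
                       sref(names(st)[st < 0], -st[st < 0]),
                       "</listOfReactants>")
        if (any(st > 0))
            lines <- c(lines, "<listOfProducts>",
                       sref(names(st)[st > 0], st[st > 0]),
                       "</listOfProducts>")
        if (nzchar(r$gpr))
            lines <- c(lines, "<fbc:geneProductAssociation>",
                       assocXML(model@gprRules[[r$id]]@tree),
                       "</fbc:geneProductAssociation>")
        lines <- c(lines, "</reaction>")
    }
    lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
    writeLines(lines, path)
    invisible(path)
}
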