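# GPR rule parsing and min/max evaluation with determinant tracking.

gprLeaf <- function(gene) list(op = "leaf", gene = gene)

gprNode <- function(op, children) {
    # flatten nested same-operator nodes so "A and B and C" is one node
    flat <- list()
    for (ch in children) {
        if (ch$op == op) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
    }
    if (length(flat) == 1L) return(flat[[1L]])
    list(op = op, children = flat)
}

gprTokenize <- function(text) {
    m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1L]]
    if (m[1L] == -1L)
        return(data.frame(token = character(), pos = integer()))
    data.frame(token = regmatches(text, list(m))[[1L]],
               pos = as.integer(m), stringsAsFactors = FALSE)
}

gprTokenType <- function(tok) {
    lt <- tolower(tok)
    if (lt %in% c("and", "&", "&&")) return("AND")
    if (lt %in% c("or", "|", "||")) return("OR")
    if (tok == "(") return("LPAR")
    if (tok == ")") return("RPAR")
    "GENE"
}

#' Parse a gene-reaction rule string
#'
#' Parses boolean gene association strings as found in SBML FBC association
#' blocks and BiGG JSON \code{gene_reaction_rule} fields.  Operators
#' \code{and}/\code{or} (case-insensitive; \code{&}, \code{|} accepted) with
#' parentheses; when parentheses are absent \code{and} binds tighter than
#' \code{or}.  Adjacent same-operator nodes are flattened.
#'
#' @param ruleText the rule string; empty or whitespace-only yields
#'   \code{NULL}.
#' @return a [GPRRule-class] object, or \code{NULL} for an empty rule.
#' @examples
#' r <- parseGPR("(G1 and G2) or G3")
#' formatGPR(r)
#' @export
parseGPR <- function(ruleText) {
    if (is.null(ruleText) || length(ruleText) == 0L || is.na(ruleText) ||
        !nzchar(trimws(ruleText)))
        return(NULL)
    toks <- gprTokenize(ruleText)
    types <- vapply(toks$token, gprTokenType, character(1), USE.NAMES = FALSE)
    i <- 1L
    n <- nrow(toks)
    peek <- function() if (i <= n) types[i] else "END"
    bail <- function(msg, at = if (i <= n) toks$pos[i] else nchar(ruleText) + 1L)
        stop(sprintf("GPR parse error at position %d in '%s': %s",
                     at, ruleText, msg), call. = FALSE)
    parseExpr <- function() {
        terms <- list(parseTerm())
        while (peek() == "OR") {
            i <<- i + 1L
            terms <- c(terms, list(parseTerm()))
        }
        gprNode("or", terms)
    }
    parseTerm <- function() {
        factors <- list(parseFactor())
        while (peek() == "AND") {
            i <<- i + 1L
            factors <- c(factors, list(parseFactor()))
        }
        gprNode("and", factors)
    }
    parseFactor <- function() {
        tp <- peek()
        if (tp == "LPAR") {
            i <<- i + 1L
            e <- parseExpr()
            if (peek() != "RPAR") bail("expected ')'")
            i <<- i + 1L
            return(e)
        }
        if (tp == "GENE") {
            g <- toks$token[i]
            i <<- i + 1L
            return(gprLeaf(g))
        }
        if (tp == "END") bail("dangling operator")
        bail(sprintf("unexpected '%s'", toks$token[i]))
    }
    tree <- parseExpr()
    if (i <= n) bail(sprintf("unexpected '%s'", toks$token[i]))
    new("GPRRule", tree = tree)
}

#' Format a GPR rule back to a string
#'
#' Inverse of [parseGPR()]: \code{parseGPR(formatGPR(r))} reproduces the same
#' tree.
#'
#' @param rule a [GPRRule-class] object or \code{NULL}.
#' @return a character string (\code{""} for \code{NULL}).
#' @export
formatGPR <- function(rule) {
    if (is.null(rule)) return("")
    fmt <- function(node) {
        if (node$op == "leaf") return(node$gene)
        parts <- vapply(node$children, function(ch) {
            s <- fmt(ch)
            # an or-node inside an and-node needs parentheses under
            # and-over-or precedence
            if (node$op == "and" && ch$op == "or") paste0("(", s, ")") else s
        }, character(1))
        paste(parts, collapse = paste0(" ", node$op, " "))
    }
    fmt(rule@tree)
}

#' Genes referenced by a GPR rule
#'
#' @param rule a [GPRRule-class] object or \code{NULL}.
#' @return character vector of unique gene ids (empty for \code{NULL}).
#' @export
gprGenes <- function(rule) {
    if (is.null(rule)) return(character())
    walk <- function(node) {
        if (node$op == "leaf") return(node$gene)
        unlist(lapply(node$children, walk))
    }
    unique(walk(rule@tree))
}

#' Evaluate a GPR rule over numeric gene scores
#'
#' Propagates gene activity scores through the rule with complex/isozyme
#' semantics: the minimum over the children of an \code{and} node (all
#' complex subunits needed) and the maximum over the children of an \code{or}
#' node (any isozyme suffices).  The \emph{determinant} is the gene whose
#' score is propagated to the root; ties are broken towards the
#' lexicographically smallest gene id so repeated evaluation is
#' deterministic.
#'
#' Genes absent from \code{scores} (or scored \code{NA}) are treated as
#' unmeasured rather than inactive: the leaf is dropped from its parent
#' operator, a node whose children are all missing is dropped recursively,
#' and a fully missing rule evaluates to \code{NA} (undefined), never zero.
#'
#' @param rule a [GPRRule-class] object.
#' @param scores named numeric vector of non-negative gene scores.
#' @return list with elements \code{value} (non-negative score or \code{NA}
#'   when undefined), \code{determinant} (gene id or \code{NA}) and
#'   \code{missingGenes} (character vector of unmeasured genes).
#' @examples
#' r <- parseGPR("(A and B) or C")
#' evaluateGPR(r, c(A = 1, B = 4, C = 0.5))
#' @export
evaluateGPR <- function(rule, scores) {
    stopifnot(is(rule, "GPRRule"))
    if (length(scores) && any(!is.na(scores) & scores < 0))
        stop("gene scores must be non-negative")
    nms <- names(scores)
    evalNode <- function(node) {
        if (node$op == "leaf") {
            g <- node$gene
            idx <- match(g, nms)
            if (is.na(idx) || is.na(scores[[idx]]))
                return(list(value = NA_real_, det = NA_character_, missing = g))
            return(list(value = unname(scores[[idx]]), det = g,
                        missing = character()))
        }
        res <- lapply(node$children, evalNode)
        missing <- unique(unlist(lapply(res, `[[`, "missing")))
        vals <- vapply(res, `[[`, numeric(1), "value")
        ok <- !is.na(vals)
        if (!any(ok))
            return(list(value = NA_real_, det = NA_character_,
                        missing = missing))
        vals <- vals[ok]
        dets <- vapply(res[ok], `[[`, character(1), "det")
        v <- if (node$op == "and") min(vals) else max(vals)
        cand <- dets[vals == v]
        list(value = v, det = sort(cand)[1L], missing = missing)
    }
    r <- evalNode(rule@tree)
    list(value = r$value, determinant = r$det, missingGenes = r$missing)
}
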