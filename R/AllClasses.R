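#' @import methods
#' @importFrom S4Vectors SimpleList metadata DataFrame
#' @importClassesFrom S4Vectors SimpleList
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats quantile setNames median dist phyper rnorm runif
#' @importFrom utils head read.csv write.csv read.table write.table
NULL

#' Gene-protein-reaction rule
#'
#' A boolean expression over gene identifiers describing which gene products
#' catalyse a reaction: \code{and} nodes are enzyme complexes (all subunits
#' required), \code{or} nodes are isozymes (any one suffices).  The tree is a
#' nested list of nodes; each node is a list with element \code{op} equal to
#' \code{"leaf"}, \code{"and"} or \code{"or"}, a \code{gene} for leaves and a
#' \code{children} list otherwise.
#'
#' @slot tree parsed expression tree (nested list).
#' @seealso [parseGPR()], [evaluateGPR()], [formatGPR()]
#' @exportClass GPRRule
setClass("GPRRule", representation(tree = "list"))

setValidity("GPRRule", function(object) {
    chk <- function(node) {
        if (!is.list(node) || is.null(node$op))
            return("malformed GPR node")
        if (node$op == "leaf") {
            if (!is.character(node$gene) || !nzchar(node$gene))
                return("leaf node without gene id")
            return(TRUE)
        }
        if (!node$op %in% c("and", "or"))
            return(sprintf("unknown operator '%s'", node$op))
        if (length(node$children) == 0)
            return("empty operator node")
        for (ch in node$children) {
            r <- chk(ch)
            if (!isTRUE(r)) return(r)
        }
        TRUE
    }
    chk(object@tree)
})

#' Genome-scale metabolic model
#'
#' A stoichiometric network: metabolites with compartments, reactions with
#' flux bounds and gene-protein-reaction (GPR) rules, and the set of genes
#' referenced by those rules.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{compartment},
#'   \code{name}; ids unique.
#' @slot reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound}, \code{gpr} (rule string, may be empty); ids unique.
#' @slot stoichiometry sparse metabolite-by-reaction matrix of signed
#'   coefficients (negative = consumed).
#' @slot gprRules list of parsed [GPRRule-class] objects (or \code{NULL}),
#'   named by reaction id.
#' @slot genes character vector of all gene ids referenced by GPRs (plus any
#'   declared in the source file).
#' @seealso [readMetabolicModel()], [makeToyModel()]
#' @exportClass MetabolicModel
setClass("MetabolicModel", representation(
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "dgCMatrix",
    gprRules      = "list",
    genes         = "character"
))

setValidity("MetabolicModel", function(object) {
    m <- object@metabolites
    r <- object@reactions
    S <- object@stoichiometry
    msgs <- character()
    if (anyDuplicated(m$id))
        msgs <- c(msgs, sprintf("duplicate metabolite id: %s",
                                m$id[duplicated(m$id)][1]))
    if (anyDuplicated(r$id))
        msgs <- c(msgs, sprintf("duplicate reaction id: %s",
                                r$id[duplicated(r$id)][1]))
    if (any(r$lower_bound > r$upper_bound))
        msgs <- c(msgs, sprintf("reaction %s has lower_bound > upper_bound",
                                r$id[which(r$lower_bound > r$upper_bound)[1]]))
    if (!identical(rownames(S), as.character(m$id)) ||
        !identical(colnames(S), as.character(r$id)))
        msgs <- c(msgs, "stoichiometry dimnames do not match metabolite/reaction ids")
    nz <- Matrix::colSums(S != 0)
    if (nrow(r) > 0 && any(nz == 0))
        msgs <- c(msgs, sprintf("reaction %s has empty stoichiometry",
                                r$id[which(nz == 0)[1]]))
    gprGenesAll <- unique(unlist(lapply(object@gprRules, function(x)
        if (is.null(x)) character() else gprGenes(x))))
    extra <- setdiff(gprGenesAll, object@genes)
    if (length(extra))
        msgs <- c(msgs, sprintf("GPR gene(s) missing from gene set: %s",
                                paste(utils::head(extra, 3), collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' Metabolic task definition
#'
#' A metabolic function stated as: produce a required amount of each output
#' metabolite when only the listed input substrates are available in bounded
#' quantities.  Uptake bounds are non-negative magnitudes; sign conventions
#' are handled internally when the task is imposed on a model.
#'
#' @slot id task identifier.
#' @slot description free text.
#' @slot system one of the seven major metabolic systems (energy, nucleotide,
#'   carbohydrates, amino acid, lipid, vitamin & cofactor, glycan) or a custom
#'   label.
#' @slot subsystem free text.
#' @slot inputs data.frame with columns \code{metabolite}, \code{compartment},
#'   \code{lb}, \code{ub} (uptake magnitudes, non-negative).
#' @slot outputs data.frame, same columns (required production range); at
#'   least one output must have \code{lb > 0}.
#' @seealso [readTaskList()], [checkTaskFeasibility()]
#' @exportClass TaskDefinition
setClass("TaskDefinition", representation(
    id = "character", description = "character",
    system = "character", subsystem = "character",
    inputs = "data.frame", outputs = "data.frame"
))

setValidity("TaskDefinition", function(object) {
    msgs <- character()
    need <- c("metabolite", "compartment", "lb", "ub")
    for (nm in c("inputs", "outputs")) {
        df <- slot(object, nm)
        if (!all(need %in% names(df)))
            msgs <- c(msgs, sprintf("%s must have columns %s", nm,
                                    paste(need, collapse = ", ")))
    }
    if (!length(msgs)) {
        if (nrow(object@outputs) == 0 || !any(object@outputs$lb > 0))
            msgs <- c(msgs, "task must require at least one output with production lb > 0")
        if (nrow(object@inputs) && any(object@inputs$lb < 0 | object@inputs$ub < 0))
            msgs <- c(msgs, "uptake bounds must be non-negative magnitudes")
        if (nrow(object@inputs) && any(object@inputs$lb > object@inputs$ub))
            msgs <- c(msgs, "input lb > ub")
        if (nrow(object@outputs) && any(object@outputs$lb > object@outputs$ub))
            msgs <- c(msgs, "output lb > ub")
        if (any(is.na(unlist(object@inputs[c("lb", "ub")]))) ||
            any(is.na(unlist(object@outputs[c("lb", "ub")]))))
            msgs <- c(msgs, "bounds must be finite or Inf, not NA")
    }
    if (length(msgs)) msgs else TRUE
})

#' List of task definitions
#'
#' A [S4Vectors::SimpleList] of [TaskDefinition-class] objects with unique ids.
#'
#' @exportClass TaskSet
setClass("TaskSet", contains = "SimpleList",
         prototype = prototype(elementType = "TaskDefinition"))

setValidity("TaskSet", function(object) {
    ok <- vapply(object, is, logical(1), "TaskDefinition")
    if (!all(ok)) return("all elements must be TaskDefinition")
    ids <- vapply(as.list(object), function(t) t@id, character(1))
    if (anyDuplicated(ids))
        return(sprintf("duplicate task id: %s", ids[duplicated(ids)][1]))
    TRUE
})

#' Task-essential reaction and gene set
#'
#' The minimal set of reactions (the support of the parsimonious-FBA optimum)
#' that accomplishes a metabolic task in a given model, together with all
#' genes appearing in those reactions' GPR rules.  This is the precomputed
#' object expression data are scored against; scoring requires no solver.
#'
#' @slot taskId task identifier.
#' @slot feasible whether the task can be accomplished in the model; when
#'   \code{FALSE} the reaction and gene sets are empty.
#' @slot reactions reaction ids carrying flux above tolerance in the
#'   parsimonious optimum.
#' @slot genes all gene ids referenced by those reactions' GPR rules.
#' @slot fluxes named numeric vector: net flux per model reaction plus the
#'   task boundary fluxes (\code{UPTAKE[met]}, \code{DEMAND[met]}).
#' @seealso [extractEssentialSet()], [writeTaskEssentialSets()]
#' @exportClass TaskEssentialSet
setClass("TaskEssentialSet", representation(
    taskId = "character", feasible = "logical",
    reactions = "character", genes = "character", fluxes = "numeric"
))

setValidity("TaskEssentialSet", function(object) {
    if (!object@feasible && (length(object@reactions) || length(object@genes)))
        return("infeasible task must have empty reaction and gene sets")
    TRUE
})

#' List of task-essential sets
#' @exportClass TaskEssentialSets
setClass("TaskEssentialSets", contains = "SimpleList",
         prototype = prototype(elementType = "TaskEssentialSet"))

#' Per-reaction activity levels
#'
#' Reaction activity level (RAL) per reaction per sample: the gene activity
#' score of the reaction's determinant gene after min/max propagation through
#' its GPR rule.
#'
#' @slot ral numeric reaction-by-sample matrix of activity levels
#'   (\code{NA} where undefined).
#' @slot determinant character matrix of the determinant gene id per
#'   reaction/sample.
#' @slot defined logical matrix; \code{FALSE} where the GPR evaluation was
#'   undefined (no rule, or all genes unmeasured).
#' @seealso [reactionActivity()]
#' @exportClass ReactionActivity
setClass("ReactionActivity", representation(
    ral = "matrix", determinant = "matrix", defined = "matrix"
))

setValidity("ReactionActivity", function(object) {
    d <- dim(object@ral)
    if (!identical(dim(object@determinant), d) ||
        !identical(dim(object@defined), d))
        return("ral, determinant and defined must share dimensions")
    TRUE
})

#' Task score result
#'
#' A [SummarizedExperiment::SummarizedExperiment] (tasks as rows, samples as
#' columns) with assays:
#' \describe{
#'   \item{score}{continuous metabolic task score, mean over task reactions of
#'     RAL times the determinant gene's significance.}
#'   \item{active}{binary call: mean RAL strictly above \code{5*log(2)}.}
#'   \item{combined}{\code{score} where active, 0 otherwise.}
#'   \item{coverage}{fraction of task reactions with a defined RAL.}
#' }
#' Scores are comparable across samples within a task, never across tasks.
#'
#' @seealso [metabolicTaskScores()], [scoreTasks()]
#' @exportClass TaskScoreResult
setClass("TaskScoreResult", contains = "SummarizedExperiment")

#' Binary-combination metabolic clusters
#'
#' A partition of samples by the exact combination of their binary activity
#' over a set of selected tasks (at most \code{2^k} clusters for \code{k}
#' tasks).
#'
#' @slot signatures logical cluster-by-task matrix of the observed signatures.
#' @slot assignment named character vector mapping each sample to its cluster
#'   label.
#' @slot universeSize the number of possible signatures, \code{2^k}.
#' @seealso [binaryCombinationClusters()]
#' @exportClass MetabolicClusters
setClass("MetabolicClusters", representation(
    signatures = "matrix", assignment = "character", universeSize = "numeric"
))

setValidity("MetabolicClusters", function(object) {
    if (!all(object@assignment %in% rownames(object@signatures)))
        return("assignment refers to unknown cluster label")
    if (anyDuplicated(apply(object@signatures, 1, paste, collapse = "")))
        return("distinct clusters must have distinct signatures")
    TRUE
})
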