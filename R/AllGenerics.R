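# Constructors, accessors and show methods.

#' @rdname TaskSet-class
#' @param tasks list of [TaskDefinition-class] objects.
#' @export
TaskSet <- function(tasks = list()) {
    if (is(tasks, "TaskDefinition")) tasks <- list(tasks)
    new("TaskSet", S4Vectors::SimpleList(tasks))
}

#' @rdname TaskEssentialSets-class
#' @param sets list of [TaskEssentialSet-class] objects.
#' @export
TaskEssentialSets <- function(sets = list()) {
    if (is(sets, "TaskEssentialSet")) sets <- list(sets)
    new("TaskEssentialSets", S4Vectors::SimpleList(sets))
}

#' Model accessors
#'
#' @param x a [MetabolicModel-class].
#' @return \code{metabolites}/\code{reactions}: the corresponding
#'   data.frame; \code{stoichiometry}: the sparse metabolite-by-reaction
#'   matrix; \code{geneIds}: character vector of gene ids; \code{gprRule}:
#'   the parsed [GPRRule-class] for one reaction (or \code{NULL}).
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @rdname model-accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @rdname model-accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname model-accessors
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname model-accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname model-accessors
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@stoichiometry)

#' @rdname model-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname model-accessors
#' @export
setMethod("geneIds", "MetabolicModel", function(x) x@genes)

#' @rdname model-accessors
#' @param reaction reaction id.
#' @export
gprRule <- function(x, reaction) {
    stopifnot(is(x, "MetabolicModel"))
    if (!reaction %in% names(x@gprRules))
        stop(sprintf("unknown reaction: %s", reaction), call. = FALSE)
    x@gprRules[[reaction]]
}

#' Task and essential-set accessors
#'
#' @param x a [TaskDefinition-class] or [TaskEssentialSet-class].
#' @name task-accessors
NULL

#' @rdname task-accessors
#' @export
setGeneric("taskId", function(x) standardGeneric("taskId"))
#' @rdname task-accessors
#' @export
setMethod("taskId", "TaskDefinition", function(x) x@id)
#' @rdname task-accessors
#' @export
setMethod("taskId", "TaskEssentialSet", function(x) x@taskId)

#' @rdname task-accessors
#' @export
taskInputs <- function(x) { stopifnot(is(x, "TaskDefinition")); x@inputs }
#' @rdname task-accessors
#' @export
taskOutputs <- function(x) { stopifnot(is(x, "TaskDefinition")); x@outputs }
#' @rdname task-accessors
#' @export
taskSystem <- function(x) { stopifnot(is(x, "TaskDefinition")); x@system }

#' @rdname task-accessors
#' @export
isFeasible <- function(x) { stopifnot(is(x, "TaskEssentialSet")); x@feasible }
#' @rdname task-accessors
#' @export
essentialReactions <- function(x) {
    stopifnot(is(x, "TaskEssentialSet")); x@reactions
}
#' @rdname task-accessors
#' @export
essentialGenes <- function(x) { stopifnot(is(x, "TaskEssentialSet")); x@genes }
#' @rdname task-accessors
#' @export
fluxValues <- function(x) { stopifnot(is(x, "TaskEssentialSet")); x@fluxes }

#' Task score result accessors
#'
#' @param x a [TaskScoreResult-class].
#' @return task-by-sample matrices: continuous scores, binary calls,
#'   combined (binary times continuous) scores, or reaction coverage.
#' @name score-accessors
NULL

#' @rdname score-accessors
#' @export
mtScores <- function(x) SummarizedExperiment::assay(x, "score")
#' @rdname score-accessors
#' @export
binaryActivity <- function(x) SummarizedExperiment::assay(x, "active")
#' @rdname score-accessors
#' @export
combinedScores <- function(x) SummarizedExperiment::assay(x, "combined")
#' @rdname score-accessors
#' @export
taskCoverage <- function(x) SummarizedExperiment::assay(x, "coverage")

#' Cluster accessors
#'
#' @param x a [MetabolicClusters-class].
#' @name cluster-accessors
NULL

#' @rdname cluster-accessors
#' @export
clusterAssignments <- function(x) {
    stopifnot(is(x, "MetabolicClusters")); x@assignment
}
#' @rdname cluster-accessors
#' @export
clusterSignatures <- function(x) {
    stopifnot(is(x, "MetabolicClusters")); x@signatures
}
#' @rdname cluster-accessors
#' @param label cluster label.
#' @export
clusterMembers <- function(x, label) {
    stopifnot(is(x, "MetabolicClusters"))
    names(x@assignment)[x@assignment == label]
}

setMethod("show", "MetabolicModel", function(object) {
    cat(sprintf("MetabolicModel: %d metabolites, %d reactions, %d genes\n",
                nrow(object@metabolites), nrow(object@reactions),
                length(object@genes)))
})

setMethod("show", "TaskDefinition", function(object) {
    cat(sprintf("TaskDefinition %s [%s]: %d input(s) -> %d output(s)\n",
                object@id, object@system, nrow(object@inputs),
                nrow(object@outputs)))
})

setMethod("show", "TaskEssentialSet", function(object) {
    if (object@feasible)
        cat(sprintf("TaskEssentialSet %s: %d reactions, %d genes\n",
                    object@taskId, length(object@reactions),
                    length(object@genes)))
    else cat(sprintf("TaskEssentialSet %s: infeasible\n", object@taskId))
})

setMethod("show", "GPRRule", function(object) {
    cat("GPRRule:", formatGPR(object), "\n")
})

setMethod("show", "MetabolicClusters", function(object) {
    cat(sprintf("MetabolicClusters: %d cluster(s) of %d sample(s) over %d task(s) (universe %d)\n",
                nrow(object@signatures), length(object@assignment),
                ncol(object@signatures), object@universeSize))
})
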