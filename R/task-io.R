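# Task list and task-essential-set I/O.

taskSchemaCols <- c("task_id", "description", "system", "subsystem",
                    "in_metabolite", "in_compartment", "in_lb", "in_ub",
                    "out_metabolite", "out_compartment", "out_lb", "out_ub")

#' Construct a task definition
#'
#' @param id task identifier.
#' @param inputs,outputs data.frames with columns \code{metabolite},
#'   \code{compartment}, \code{lb}, \code{ub}.  Input bounds are uptake
#'   magnitudes (non-negative); outputs state the required production range
#'   and at least one output must have \code{lb > 0}.
#' @param description,system,subsystem annotation.
#' @return a validated [TaskDefinition-class].
#' @export
makeTaskDefinition <- function(id, inputs, outputs, description = "",
                               system = "custom", subsystem = "") {
    shape <- function(df) {
        df <- as.data.frame(df, stringsAsFactors = FALSE)
        if (nrow(df) == 0)
            return(data.frame(metabolite = character(),
                              compartment = character(),
                              lb = numeric(), ub = numeric()))
        df$metabolite <- as.character(df$metabolite)
        df$compartment <- as.character(df$compartment)
        df$lb <- as.numeric(df$lb)
        df$ub <- as.numeric(df$ub)
        df[c("metabolite", "compartment", "lb", "ub")]
    }
    new("TaskDefinition", id = as.character(id),
        description = as.character(description),
        system = as.character(system), subsystem = as.character(subsystem),
        inputs = shape(inputs), outputs = shape(outputs))
}

#' Read a metabolic task list
#'
#' Reads the canonical tabular task schema.  CSV: one row per metabolite,
#' grouped by \code{task_id}, with columns \code{task_id, description,
#' system, subsystem, in_metabolite, in_compartment, in_lb, in_ub,
#' out_metabolite, out_compartment, out_lb, out_ub}; a row carries an input,
#' an output, or both (blank fields ignored).  JSON: an array of objects with
#' explicit \code{inputs}/\code{outputs} arrays.  Unknown columns produce a
#' warning and are ignored; a task without a strictly positive required
#' output is a schema error.
#'
#' @param path CSV or JSON file path.
#' @param quiet suppress the per-system count message.
#' @return a [TaskSet-class].
#' @export
readTaskList <- function(path, quiet = FALSE) {
    if (!file.exists(path))
        stop(sprintf("task file not found: %s", path), call. = FALSE)
    tasks <- if (grepl("\\.json$", path, ignore.case = TRUE))
        readTaskJSON(path) else readTaskCSV(path)
    ts <- TaskSet(tasks)
    if (!quiet) {
        sys <- vapply(as.list(ts), function(t) t@system, character(1))
        tab <- table(sys)
        message(sprintf("read %d tasks across %d systems (%s)", length(ts),
                        length(tab),
                        paste(sprintf("%s: %d", names(tab), tab),
                              collapse = ", ")))
    }
    ts
}

readTaskCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    unknown <- setdiff(names(df), taskSchemaCols)
    if (length(unknown)) {
        warning(sprintf("ignoring unknown task column(s): %s",
                        paste(unknown, collapse = ", ")), call. = FALSE)
        df <- df[intersect(names(df), taskSchemaCols)]
    }
    if (!"task_id" %in% names(df))
        stop("task CSV lacks required column task_id", call. = FALSE)
    for (col in setdiff(taskSchemaCols, names(df))) df[[col]] <- ""
    blank <- function(x) is.na(x) | !nzchar(trimws(x))
    num <- function(x, default) ifelse(blank(x), default,
                                       suppressWarnings(as.numeric(x)))
    ids <- unique(df$task_id)
    lapply(ids, function(tid) {
        rows <- df[df$task_id == tid, , drop = FALSE]
        first <- function(col) {
            v <- rows[[col]][!blank(rows[[col]])]
            if (length(v)) v[1] else ""
        }
        ins <- rows[!blank(rows$in_metabolite), , drop = FALSE]
        outs <- rows[!blank(rows$out_metabolite), , drop = FALSE]
        if (nrow(outs) == 0)
            stop(sprintf("task %s has no required output", tid), call. = FALSE)
        makeTaskDefinition(
            id = tid, description = first("description"),
            system = if (nzchar(first("system"))) first("system") else "custom",
            subsystem = first("subsystem"),
            inputs = data.frame(metabolite = ins$in_metabolite,
                                compartment = ins$in_compartment,
                                lb = num(ins$in_lb, 0),
                                ub = num(ins$in_ub, Inf)),
            outputs = data.frame(metabolite = outs$out_metabolite,
                                 compartment = outs$out_compartment,
                                 lb = num(outs$out_lb, 0),
                                 ub = num(outs$out_ub, Inf)))
    })
}

readTaskJSON <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(doc, function(t) {
        io <- function(part) {
            if (length(t[[part]]) == 0)
                return(data.frame(metabolite = character(),
                                  compartment = character(),
                                  lb = numeric(), ub = numeric()))
            do.call(rbind, lapply(t[[part]], function(e)
                data.frame(metabolite = e$metabolite,
                           compartment = e$compartment,
                           lb = if (is.null(e$lb)) 0 else as.numeric(e$lb),
                           ub = if (is.null(e$ub) ||
                                    identical(e$ub, "unbounded")) Inf
                                else as.numeric(e$ub))))
        }
        makeTaskDefinition(
            id = t$id,
            description = if (is.null(t$description)) "" else t$description,
            system = if (is.null(t$system)) "custom" else t$system,
            subsystem = if (is.null(t$subsystem)) "" else t$subsystem,
            inputs = io("inputs"), outputs = io("outputs"))
    })
}

#' Write a task list as canonical CSV
#'
#' @param tasks a [TaskSet-class] or list of [TaskDefinition-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTaskList <- function(tasks, path) {
    rows <- list()
    for (t in as.list(tasks)) {
        n <- max(nrow(t@inputs), nrow(t@outputs), 1L)
        pad <- function(df, pre) {
            out <- data.frame(met = character(n), comp = character(n),
                              lb = rep("", n), ub = rep("", n),
                              stringsAsFactors = FALSE)
            if (nrow(df)) {
                out$met[seq_len(nrow(df))] <- df$metabolite
                out$comp[seq_len(nrow(df))] <- df$compartment
                out$lb[seq_len(nrow(df))] <- format(df$lb, digits = 15,
                                                    trim = TRUE)
                out$ub[seq_len(nrow(df))] <- format(df$ub, digits = 15,
                                                    trim = TRUE)
            }
            names(out) <- paste0(pre, c("metabolite", "compartment", "lb", "ub"))
            out
        }
        rows[[length(rows) + 1L]] <- cbind(
            data.frame(task_id = rep(t@id, n),
                       description = c(t@description, rep("", n - 1L)),
                       system = c(t@system, rep("", n - 1L)),
                       subsystem = c(t@subsystem, rep("", n - 1L)),
                       stringsAsFactors = FALSE),
            pad(t@inputs, "in_"), pad(t@outputs, "out_"))
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
    invisible(path)
}

#' Write task-essential sets as a JSON artifact
#'
#' Serialization is canonical (tasks, reactions, genes and flux keys in
#' lexicographic order) so re-serializing a read artifact is byte-identical.
#' Empty gene lists are preserved as empty arrays.
#'
#' @param sets a [TaskEssentialSets-class] (or list of
#'   [TaskEssentialSet-class]).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeTaskEssentialSets <- function(sets, path) {
    sets <- as.list(sets)
    if (length(sets) == 0) stop("no essential sets to write", call. = FALSE)
    ids <- vapply(sets, function(s) s@taskId, character(1))
    doc <- lapply(sets[order(ids)], function(s) {
        fl <- s@fluxes[order(names(s@fluxes))]
        list(task_id = s@taskId, feasible = s@feasible,
             reactions = as.list(sort(s@reactions)),
             genes = as.list(sort(s@genes)),
             flux_values = as.list(fl))
    })
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = 2), path)
    invisible(path)
}

#' Read a task-essential-set JSON artifact
#'
#' @param path JSON path written by [writeTaskEssentialSets()].
#' @return a [TaskEssentialSets-class].
#' @export
readTaskEssentialSets <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    TaskEssentialSets(lapply(doc, function(s)
        new("TaskEssentialSet", taskId = s$task_id,
            feasible = isTRUE(s$feasible),
            reactions = as.character(unlist(s$reactions)),
            genes = as.character(unlist(s$genes)),
            fluxes = if (length(s$flux_values))
                unlist(s$flux_values) else stats::setNames(numeric(), character()))))
}

#' Packaged synthetic curated-task table
#'
#' Path to a vendored \emph{synthetic} stand-in for a curated human
#' metabolic-task collection: 195 tasks spanning the seven major metabolic
#' systems in the canonical CSV schema.  The table exercises the schema and
#' the documented collection shape; its biochemistry is synthetic, not
#' curated.
#'
#' @return file path of the packaged CSV.
#' @export
syntheticTaskTable <- function() {
    system.file("extdata", "tasks_synthetic_195.csv", package = "metaboTask",
                mustWork = TRUE)
}
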