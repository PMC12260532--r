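#' @describeIn RunConfig-class constructor with the standard study
#'   conditions as defaults: population 100, random 24-residue founders,
#'   the full evolutionary dictionary, fitness-proportional selection, stop
#'   at pLDDT >= 0.85 and pTM >= 0.75 (both inclusive, [0, 1] scale).
#' @param popSize population size N.
#' @param founderMode,founderLength,founderSeed founder settings (see
#'   [makeFounders()]).
#' @param dictionary an [EvolutionaryDictionary].
#' @param selection a [SelectionConfig].
#' @param constraints a [ConstraintParams].
#' @param evaluator a [StructureEvaluator].
#' @param partner fixed-partner [StructureModel] for dimer mode, or `NULL`.
#' @param plddtStop,ptmStop stop thresholds in [0, 1].
#' @param maxGenerations generation budget.
#' @param seed master seed.
#' @param snapshotEvery PDB snapshot cadence (0 = never).
#' @export
runConfig <- function(popSize = 100L, founderMode = "n_random",
                      founderLength = 24L, founderSeed = NA_character_,
                      dictionary = evolutionaryDictionary(),
                      selection = selectionConfig(),
                      constraints = constraintParams(),
                      evaluator = surrogateEvaluator(),
                      partner = NULL,
                      plddtStop = 0.85, ptmStop = 0.75,
                      maxGenerations = 100L, seed = 1L,
                      snapshotEvery = 0L) {
  new("RunConfig", popSize = as.integer(popSize), founderMode = founderMode,
      founderLength = as.integer(founderLength), founderSeed = founderSeed,
      dictionary = dictionary, selection = selection,
      constraints = constraints, evaluator = evaluator, partner = partner,
      plddtStop = plddtStop, ptmStop = ptmStop,
      maxGenerations = as.integer(maxGenerations), seed = as.integer(seed),
      snapshotEvery = as.integer(snapshotEvery))
}

## score one pool member: fitness terms + structure descriptors, as a
## numeric row (one data.frame is built per generation, not per member)
.score_member <- function(seqobj, model, config) {
  sel <- model@chain == "A"
  if (!any(sel)) sel <- model@chain == model@chain[1]
  ca <- model@ca[sel, , drop = FALSE]
  labs <- .assign_ss_chain(ca)
  terms <- .fitness_terms(residues(seqobj), model, config@constraints,
                          evolvingChain = "A", labs = labs)
  cen <- colMeans(ca)
  rg <- sqrt(mean((ca[, 1] - cen[1])^2 + (ca[, 2] - cen[2])^2 +
                  (ca[, 3] - cen[3])^2))
  c(terms, rg = rg, frac_h = mean(labs == "H"), frac_e = mean(labs == "E"),
    frac_c = mean(labs == "C"))
}

.event_df <- function(ev) {
  if (is.null(ev))
    return(data.frame(event_type = NA_character_, event_pos = NA_character_,
                      event_payload = NA_character_))
  data.frame(event_type = ev@type,
             event_pos = paste(ev@position, collapse = ":"),
             event_payload = if (nzchar(ev@payload)) ev@payload
                             else NA_character_)
}

.node_row <- function(id, parentId, generationIdx, res, ev, score) {
  e <- .event_df(ev)
  data.frame(id = id, parentId = parentId, generation = generationIdx,
             residues = res, eventType = e$event_type, eventPos = e$event_pos,
             eventPayload = e$event_payload, score = score,
             stringsAsFactors = FALSE)
}

## evaluate + score a list of ProteinSequence, with optional memoization
.evaluate_pool <- function(pop, state) {
  config <- state$config
  keys <- vapply(pop, residues, character(1))
  rows <- vector("list", length(pop))
  models <- vector("list", length(pop))
  todo <- seq_along(pop)
  if (!is.null(state$cache)) {
    hit <- vapply(keys, function(k)
      exists(k, envir = state$cache, inherits = FALSE), logical(1))
    for (i in which(hit)) {
      ent <- get(keys[i], envir = state$cache)
      rows[[i]] <- ent$row
      models[[i]] <- ent$model
    }
    todo <- which(!hit)
  }
  if (length(todo)) {
    fresh <- batchEvaluate(pop[todo], config@evaluator,
                           partner = config@partner)
    for (j in seq_along(todo)) {
      i <- todo[j]
      models[[i]] <- fresh[[j]]
      rows[[i]] <- .score_member(pop[[i]], fresh[[j]], config)
      if (!is.null(state$cache))
        assign(keys[i], list(row = rows[[i]], model = models[[i]]),
               envir = state$cache)
    }
  }
  list(rows = as.data.frame(do.call(rbind, rows)), models = models)
}

#' Run the evolutionary simulation
#'
#' The generation loop: every one of the N individuals produces exactly one
#' mutant, the mixed pool of 2N parents and offspring is evaluated and
#' scored, N survivors are selected, every selected individual is recorded
#' in the lineage tree, and the run stops as soon as a selected individual
#' reaches both stop thresholds (or at the generation budget). All
#' randomness flows through named streams derived from the master seed
#' (founders, mutation, selection), so runs are exactly reproducible and
#' adding draws to one purpose does not shift the others.
#'
#' @param config a [RunConfig].
#' @param outDir optional output directory: per-generation TSV log, final
#'   population FASTA, Newick lineage tree with edge annotation TSV, JSON
#'   run manifest, and best-structure PDB snapshots every
#'   `snapshotEvery` generations.
#' @param checkpointPath optional path for engine checkpoints; the state is
#'   also saved there when the evaluator fails mid-run.
#' @param checkpointEvery write a checkpoint every this many generations
#'   (0 = only on failure / at the end when `checkpointPath` is set).
#' @param memoize cache evaluations by residue string. Off by default:
#'   mutants are re-evaluated every generation like any other pool member;
#'   for deterministic backends the cache changes no result, only runtime.
#' @param quiet suppress the per-generation summary line.
#' @return an [EvolutionRun].
#' @export
runSimulation <- function(config, outDir = NULL, checkpointPath = NULL,
                          checkpointEvery = 0L, memoize = FALSE,
                          quiet = TRUE) {
  validObject(config)
  streams <- rngStreams(config@seed)
  founders <- withStream(streams, "founders",
    makeFounders(config@founderMode, config@founderLength, config@popSize,
                 config@dictionary,
                 seedSequence = if (is.na(config@founderSeed)) NULL
                                else config@founderSeed))
  for (i in seq_along(founders)) founders[[i]]@id <- sprintf("g0_%d", i)
  state <- list(config = config, streams = streams,
                parents = founders, generationIdx = 0L,
                records = list(), nodes = list(), stopId = NA_character_,
                cache = if (memoize) new.env(parent = emptyenv()) else NULL,
                outDir = outDir, checkpointPath = checkpointPath,
                checkpointEvery = as.integer(checkpointEvery),
                quiet = quiet)
  ev0 <- .evaluate_pool(founders, state)
  state$parentRows <- ev0$rows
  state$records[[1L]] <- cbind(
    data.frame(generation = 0L,
               id = vapply(founders, seqId, character(1)),
               parent_id = NA_character_, event_type = NA_character_,
               event_pos = NA_character_, event_payload = NA_character_,
               length = vapply(founders, nchar, integer(1))),
    ev0$rows, data.frame(selected_n = 1L, selected = TRUE))
  state$nodes[[1L]] <- do.call(rbind, lapply(seq_along(founders), function(i)
    .node_row(founders[[i]]@id, NA_character_, 0L,
              residues(founders[[i]]), NULL, ev0$rows$score[i])))
  .run_engine(state)
}

.run_engine <- function(state) {
  config <- state$config
  n <- config@popSize
  dict <- config@dictionary
  g <- state$generationIdx
  while (g < config@maxGenerations && is.na(state$stopId)) {
    g <- g + 1L
    offspring <- withStream(state$streams, "mutation", {
      lapply(seq_len(n), function(i) {
        ev <- drawMutation(state$parents[[i]], dict)
        child <- applyMutation(state$parents[[i]], ev)
        child@id <- sprintf("g%d_m%d", g, i)
        child@generation <- g
        attr(child, "event") <- ev
        child
      })
    })
    pool <- c(state$parents, offspring)
    evo <- tryCatch(.evaluate_pool(pool, state),
      error = function(e) {
        if (!is.null(state$checkpointPath))
          checkpointEngine(state, state$checkpointPath)
        stop(sprintf(
          "evaluator failed at generation %d (checkpoint %s): %s", g,
          if (is.null(state$checkpointPath)) "not requested"
          else state$checkpointPath, conditionMessage(e)), call. = FALSE)
      })
    poolRows <- evo$rows
    idx <- withStream(state$streams, "selection",
                      selectSurvivors(poolRows$score, n, config@selection))
    selCount <- tabulate(idx, nbins = 2L * n)   # multiplicity per pool member
    events <- c(rep(list(NULL), n),
                lapply(offspring, function(o) attr(o, "event")))
    recs <- cbind(
      data.frame(generation = g,
                 id = vapply(pool, seqId, character(1)),
                 parent_id = vapply(pool, parentId, character(1)),
                 event_type = vapply(events, function(e)
                   if (is.null(e)) NA_character_ else e@type, character(1)),
                 event_pos = vapply(events, function(e)
                   if (is.null(e)) NA_character_
                   else paste(e@position, collapse = ":"), character(1)),
                 event_payload = vapply(events, function(e)
                   if (is.null(e) || !nzchar(e@payload)) NA_character_
                   else e@payload, character(1)),
                 length = vapply(pool, nchar, integer(1))),
      poolRows, data.frame(selected_n = selCount, selected = selCount > 0L))
    state$records[[length(state$records) + 1L]] <- recs

    ## survivors: first selection of a pool member keeps its identity;
    ## with-replacement duplicates become clone nodes with an event-free
    ## edge, keeping the genealogy a tree
    survivors <- vector("list", n)
    survRows <- vector("list", n)
    seen <- integer(0)
    cloneCount <- 0L
    newNodes <- list()
    for (s in seq_along(idx)) {
      j <- idx[s]
      indiv <- pool[[j]]
      if (j %in% seen) {
        cloneCount <- cloneCount + 1L
        base <- if (j > n) pool[[j]] else state$parents[[j]]
        clone <- proteinSequence(residues(base),
                                 id = sprintf("g%d_c%d", g, cloneCount),
                                 generation = g, parentId = seqId(base))
        newNodes[[length(newNodes) + 1L]] <-
          .node_row(clone@id, seqId(base), g, residues(clone), NULL,
                    poolRows$score[j])
        survivors[[s]] <- clone
      } else {
        seen <- c(seen, j)
        if (j > n) {   # newly selected offspring enters the tree
          newNodes[[length(newNodes) + 1L]] <-
            .node_row(seqId(indiv), parentId(indiv), g, residues(indiv),
                      attr(indiv, "event"), poolRows$score[j])
        }
        survivors[[s]] <- indiv
      }
      survRows[[s]] <- poolRows[j, , drop = FALSE]
    }
    if (length(newNodes))
      state$nodes[[length(state$nodes) + 1L]] <- do.call(rbind, newNodes)
    state$parents <- survivors
    state$parentRows <- do.call(rbind, survRows)
    rownames(state$parentRows) <- NULL
    state$generationIdx <- g

    ## stop condition on the selected generation (both thresholds inclusive)
    hit <- which(state$parentRows$plddt_mean >= config@plddtStop &
                 state$parentRows$ptm >= config@ptmStop)
    if (length(hit)) {
      best <- hit[order(-state$parentRows$score[hit], hit)][1]
      state$stopId <- seqId(state$parents[[best]])
    }

    if (!state$quiet)
      message(sprintf(
        "gen %d | best %.4g | median %.4g | mean length %.1f | stop %s/%s",
        g, max(state$parentRows$score), stats::median(state$parentRows$score),
        mean(vapply(state$parents, nchar, integer(1))),
        format(max(state$parentRows$plddt_mean), digits = 3),
        format(max(state$parentRows$ptm), digits = 3)))

    if (!is.null(state$outDir) && config@snapshotEvery > 0L &&
        g %% config@snapshotEvery == 0L) {
      dir.create(state$outDir, showWarnings = FALSE, recursive = TRUE)
      bestj <- idx[which.max(poolRows$score[idx])]
      writeStructure(evo$models[[bestj]],
        file.path(state$outDir, sprintf("best_g%04d.pdb", g)))
    }
    if (!is.null(state$checkpointPath) && state$checkpointEvery > 0L &&
        g %% state$checkpointEvery == 0L)
      checkpointEngine(state, state$checkpointPath)
  }
  run <- .finish_run(state)
  if (!is.null(state$checkpointPath))
    checkpointEngine(state, state$checkpointPath)
  if (!is.null(state$outDir)) writeRunOutputs(run, state$outDir)
  run
}

.finish_run <- function(state) {
  records <- do.call(rbind, state$records)
  rownames(records) <- NULL
  nodes <- do.call(rbind, state$nodes)
  rownames(nodes) <- NULL
  run <- new("EvolutionRun", population = state$parents,
             tree = new("LineageTree", nodes = nodes), records = records,
             config = state$config, generations = state$generationIdx,
             stopId = state$stopId)
  attr(run, "engineState") <- .portable_state(state)
  run
}

## engine state with RNG streams flattened for serialization
.portable_state <- function(state) {
  out <- state[setdiff(names(state), c("streams", "cache"))]
  out$streamState <- .streams_state(state$streams)
  out$memoize <- !is.null(state$cache)
  out
}

#' Checkpoint and resume an engine state
#'
#' `checkpointEngine` serialises the full engine state (configuration,
#' population, records, lineage nodes, and the state of every RNG stream),
#' so a resumed run continues on exactly the trajectory of an uninterrupted
#' one. Checkpointing twice without stepping the engine writes identical
#' files.
#'
#' @param state an engine state (as stored in a checkpoint, or taken from a
#'   finished run via `attr(run, "engineState")`).
#' @param path checkpoint file.
#' @return `checkpointEngine`: `path` invisibly. `resumeSimulation`: the
#'   completed [EvolutionRun].
#' @export
checkpointEngine <- function(state, path) {
  if (!is.null(state$streams)) state <- .portable_state(state)
  state$foldevoCheckpoint <- TRUE
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(state, path, compress = FALSE)
  invisible(path)
}

#' @rdname checkpointEngine
#' @param maxGenerations optional new generation budget for the resumed
#'   run (defaults to the budget in the checkpointed config).
#' @export
resumeSimulation <- function(path, maxGenerations = NULL) {
  if (!file.exists(path)) stop("no checkpoint at ", path)
  state <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint at ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (!isTRUE(state$foldevoCheckpoint) || is.null(state$generationIdx))
    stop(sprintf(
      "corrupt checkpoint at %s (last valid generation: %s)", path,
      if (is.null(state$generationIdx)) "unknown"
      else state$generationIdx))
  state$foldevoCheckpoint <- NULL
  state$streams <- .streams_from_state(state$streamState)
  state$streamState <- NULL
  state$cache <- if (isTRUE(state$memoize)) new.env(parent = emptyenv())
                 else NULL
  state$memoize <- NULL
  if (!is.null(maxGenerations))
    state$config@maxGenerations <- as.integer(maxGenerations)
  .run_engine(state)
}
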