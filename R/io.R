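# On-disk containers. Array-heavy objects (trajectories, TTC stacks,
# latent tables, model checkpoints) are stored as R serialisations with a
# format tag and validated on read; results and configurations use JSON /
# plain key-value text so they remain human-readable.

FORMAT_VERSION <- 1L

write_tagged <- function(object, path, kind) {
  payload <- list(format = "specklematch", version = FORMAT_VERSION,
                  kind = kind, object = object)
  saveRDS(payload, path)
  invisible(path)
}

read_tagged <- function(path, kind, required = character()) {
  payload <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(payload) || !identical(payload$format, "specklematch") ||
      !identical(payload$kind, kind)) {
    stop(errorCondition(
      sprintf("'%s' is not a specklematch %s file", path, kind),
      class = "specklematch_format_error"))
  }
  obj <- payload$object
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    stop(errorCondition(
      sprintf("%s file '%s' is missing field(s): %s", kind, path,
              paste(missing, collapse = ", ")),
      class = "specklematch_format_error"))
  }
  obj
}

#' Write / read a simulation trajectory
#'
#' @param traj A \code{ch_trajectory}.
#' @param path File path.
#' @return \code{write_trajectory} returns the path invisibly;
#'   \code{read_trajectory} the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ch_trajectory"))
  write_tagged(unclass(traj), path, "trajectory")
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  obj <- read_tagged(path, "trajectory",
                     required = c("psi", "times", "config", "n_steps_executed"))
  obj$config <- structure(obj$config, class = "sim_config")
  structure(obj, class = "ch_trajectory")
}

#' Write / read a stack of TTC maps
#'
#' Stores a list of \code{ttc_map} or \code{preprocessed_ttc} with their
#' ring metadata. Reading validates that every item carries its
#' \code{q_center}.
#'
#' @param ttcs List of maps.
#' @param path File path.
#' @export
write_ttc_stack <- function(ttcs, path) {
  stopifnot(is.list(ttcs), length(ttcs) >= 1)
  items <- lapply(ttcs, function(t) {
    list(class = class(t)[1], data = unclass(t))
  })
  write_tagged(list(items = items), path, "ttc_stack")
}

#' @rdname write_ttc_stack
#' @export
read_ttc_stack <- function(path) {
  obj <- read_tagged(path, "ttc_stack", required = "items")
  lapply(seq_along(obj$items), function(i) {
    it <- obj$items[[i]]
    if (!"q_center" %in% names(it$data)) {
      stop(errorCondition(
        sprintf("TTC %d in '%s' is missing its q_center", i, path),
        class = "specklematch_format_error"))
    }
    structure(it$data, class = it$class)
  })
}

#' Write / read a latent table
#'
#' @param table A \code{latent_table}.
#' @param path File path.
#' @export
write_latent_table <- function(table, path) {
  stopifnot(inherits(table, "latent_table"))
  write_tagged(unclass(table), path, "latent_table")
}

#' @rdname write_latent_table
#' @export
read_latent_table <- function(path) {
  obj <- read_tagged(path, "latent_table",
                     required = c("eps", "psi_gel", "rings", "z", "latent_dim"))
  structure(obj, class = "latent_table")
}

#' Write / read an auto-encoder checkpoint
#'
#' The checkpoint carries the trained parameters together with the full
#' \code{\link{ae_config}}, so a reloaded model reproduces encodings
#' exactly.
#'
#' @param model An \code{ae_model}.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ae_model"))
  write_tagged(list(config = unclass(model$config), params = model$params,
                    trained = model$trained), path, "ae_model")
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- read_tagged(path, "ae_model", required = c("config", "params"))
  model <- build_autoencoder(structure(obj$config, class = "ae_config"))
  model$params <- obj$params
  model$trained <- isTRUE(obj$trained)
  model
}

#' Write / read a fixture dataset
#'
#' @param dataset A \code{fixture_dataset}.
#' @param path File path.
#' @export
write_fixture_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fixture_dataset"))
  write_tagged(unclass(dataset), path, "fixture_dataset")
}

#' @rdname write_fixture_dataset
#' @export
read_fixture_dataset <- function(path) {
  obj <- read_tagged(path, "fixture_dataset",
                     required = c("ttcs", "meta", "times"))
  obj$ttcs <- lapply(obj$ttcs, function(t) structure(t, class = "ttc_map"))
  structure(obj, class = "fixture_dataset")
}

#' Write / read a match result as JSON
#'
#' The report carries the fitted parameters, calibration, objective and
#' full provenance (bounds, seeds, iteration history) in plain JSON.
#'
#' @param result A \code{match_result}.
#' @param path File path.
#' @export
write_match_result <- function(result, path) {
  stopifnot(inherits(result, "match_result"))
  out <- list(
    format = "specklematch", version = FORMAT_VERSION, kind = "match_result",
    per_condition = result$per_condition,
    calibration = result$calibration,
    D = result$D, objective_value = result$objective_value,
    history = result$history, n_evals = result$n_evals,
    settings = result$settings, q_values = result$q_values
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_match_result
#' @export
read_match_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "match_result")) {
    stop(errorCondition(sprintf("'%s' is not a match-result file", path),
                        class = "specklematch_format_error"))
  }
  obj$per_condition <- tibble::as_tibble(obj$per_condition)
  obj$format <- NULL; obj$version <- NULL; obj$kind <- NULL
  structure(obj, class = "match_result")
}

#' Read a plain key-value simulation configuration
#'
#' Parses lines of the form \code{key = value} (\code{#} comments and
#' blank lines ignored) into a \code{\link{sim_config}}. Unknown keys are
#' rejected.
#'
#' @param path Path to the text file.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) {
    stop(errorCondition(
      sprintf("cannot parse line(s): %s", paste(lines[bad], collapse = "; ")),
      class = "specklematch_format_error"))
  }
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- as.numeric(vapply(kv, `[[`, character(1), 2))
  allowed <- names(formals(sim_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    stop(errorCondition(
      sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
      class = "specklematch_format_error"))
  }
  do.call(sim_config, as.list(stats::setNames(vals, keys)))
}
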