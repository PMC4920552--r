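## Delimited-text serialization of spike trains and result tables.

#' Write a spike train set to CSV with a JSON sidecar
#'
#' Serializes the trains as a long-format CSV with columns \code{fiber_id},
#' \code{fiber_class} (\code{"exc"} or \code{"inh"}) and
#' \code{spike_time_s}, plus a \code{<path>.json} sidecar holding the
#' metadata (duration, dt, seed, mode).
#'
#' @param x A \code{spike_train_set}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  rows <- function(trains, cls, off = 0L) {
    if (!length(trains)) return(NULL)
    data.frame(
      fiber_id = rep(seq_along(trains) + off, lengths(trains)),
      fiber_class = cls,
      spike_time_s = unlist(trains, use.names = FALSE))
  }
  df <- rbind(rows(x$exc_trains, "exc"),
              rows(x$inh_trains, "inh", off = length(x$exc_trains)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(duration = x$duration, dt = x$dt, seed = x$seed,
               mode = x$mode,
               n_exc = length(x$exc_trains), n_inh = length(x$inh_trains))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spike train set from CSV
#'
#' Reads trains written by \code{\link{write_spike_trains}}, or any CSV with
#' columns \code{fiber_id}, \code{fiber_class}, \code{spike_time_s}
#' (externally supplied spike trains can be fed to the neuron models this
#' way). The JSON sidecar is used for metadata when present; otherwise
#' \code{duration} must be given.
#'
#' @param path CSV path.
#' @param duration Trial duration in seconds (overrides the sidecar).
#' @param dt Time step in seconds (default from sidecar, else 2e-6).
#' @return A \code{spike_train_set}.
#' @export
read_spike_trains <- function(path, duration = NULL, dt = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("fiber_id", "fiber_class", "spike_time_s") %in% names(df)))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(duration)) duration <- meta$duration
  if (is.null(duration)) stop("'duration' not given and no JSON sidecar")
  if (is.null(dt)) dt <- if (!is.null(meta$dt)) meta$dt else 2e-6
  split_sorted <- function(sub) {
    lapply(split(sub$spike_time_s, sub$fiber_id), sort)
  }
  structure(list(
    exc_trains = unname(split_sorted(df[df$fiber_class == "exc", ])),
    inh_trains = unname(split_sorted(df[df$fiber_class == "inh", ])),
    duration = duration, dt = dt,
    seed = if (!is.null(meta$seed)) meta$seed else NA,
    mode = if (!is.null(meta$mode)) meta$mode else "external"),
    class = "spike_train_set")
}

#' Write an output spike train to CSV with a JSON sidecar
#'
#' @param x An \code{output_spike_train}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_output_train <- function(x, path) {
  stopifnot(inherits(x, "output_spike_train"))
  utils::write.csv(data.frame(spike_time_s = x$spike_times), path,
                   row.names = FALSE)
  meta <- list(duration = x$duration,
               params = unclass(x$params_used),
               model = if (inherits(x$params_used, "coincidence_params"))
                 "coincidence" else "integrator",
               n_spikes = length(x$spike_times),
               n_candidate_coincidences = x$n_candidate_coincidences,
               seed = x$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
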