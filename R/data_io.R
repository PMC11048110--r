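# Epoch containers: one subject's epoched EEG and multi-subject collections,
# with a validated single-file save/load format.

#' Create an epoched-EEG container for one subject
#'
#' Holds a `trials x channels x samples` array of epoched EEG (microvolts by
#' convention) with binary trial labels (1 = target, 0 = nontarget), the
#' sampling rate and channel names. All downstream modules (preprocessing,
#' encoding, evaluation) consume this container.
#'
#' @param data numeric array of shape `(n_trials, n_channels, n_samples)`.
#' @param labels integer/numeric vector of length `n_trials`, values in `{0, 1}`.
#' @param subject_id single string identifying the subject.
#' @param sfreq sampling rate in Hz (`> 0`).
#' @param channel_names character vector of length `n_channels`.
#' @return An object of class `epoch_set`.
#' @export
#' @examples
#' es <- epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)), c(0, 1), "S01", 100,
#'                 paste0("ch", 1:3))
#' n_trials(es)
epoch_set <- function(data, labels, subject_id, sfreq, channel_names) {
  x <- structure(
    list(data = data, labels = as.integer(labels), subject_id = subject_id,
         sfreq = sfreq, channel_names = as.character(channel_names)),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

validate_epoch_set <- function(x) {
  if (!is.array(x$data) || length(dim(x$data)) != 3L)
    stop_validation("field 'data' must be a 3-d array (trials, channels, samples)")
  d <- dim(x$data)
  if (length(x$labels) != d[1L])
    stop_validation("field 'labels' has length ", length(x$labels),
                    " but 'data' has ", d[1L], " trials")
  if (d[1L] > 0 && !all(x$labels %in% c(0L, 1L)))
    stop_validation("field 'labels' must contain only 0 and 1")
  if (!all(is.finite(x$data)))
    stop_validation("field 'data' contains non-finite values")
  if (!is_scalar_num(x$sfreq) || x$sfreq <= 0)
    stop_validation("field 'sfreq' must be a positive number")
  if (!is.character(x$subject_id) || length(x$subject_id) != 1L || !nzchar(x$subject_id))
    stop_validation("field 'subject_id' must be a non-empty string")
  if (length(x$channel_names) != d[2L])
    stop_validation("field 'channel_names' has length ", length(x$channel_names),
                    " but 'data' has ", d[2L], " channels")
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s: %d trials (%d targets) x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1L], sum(x$labels), d[2L], d[3L], x$sfreq))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Bundle several subjects' epoch sets into one collection
#'
#' All members must agree on sampling rate, channel set and epoch length, and
#' subject ids must be unique. Subjects are kept in lexicographic order of
#' `subject_id` so that any iteration over a collection is deterministic.
#'
#' @param subjects list of [epoch_set()] objects.
#' @return An object of class `subject_collection` (a named, ordered list).
#' @export
subject_collection <- function(subjects) {
  if (!is.list(subjects) || length(subjects) == 0L)
    stop_validation("a subject_collection needs at least one subject")
  for (s in subjects) validate_epoch_set(s)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_validation("duplicate subject_id: ", ids[duplicated(ids)][1L])
  names(subjects) <- ids
  subjects <- subjects[order(ids, method = "radix")]
  ref <- subjects[[1L]]
  for (s in subjects[-1L]) {
    if (!isTRUE(all.equal(s$sfreq, ref$sfreq)))
      stop_validation("field 'sfreq' differs between subjects ", ref$subject_id,
                      " and ", s$subject_id)
    if (!identical(dim(s$data)[2:3], dim(ref$data)[2:3]))
      stop_validation("field 'data' shape (channels, samples) differs between subjects ",
                      ref$subject_id, " and ", s$subject_id)
    if (!identical(s$channel_names, ref$channel_names))
      stop_validation("field 'channel_names' differs between subjects ",
                      ref$subject_id, " and ", s$subject_id)
  }
  structure(subjects, class = "subject_collection")
}

#' @export
print.subject_collection <- function(x, ...) {
  d <- dim(x[[1L]]$data)
  cat(sprintf("<subject_collection> %d subjects x (%d channels x %d samples) @ %g Hz\n",
              length(x), d[2L], d[3L], x[[1L]]$sfreq))
  for (s in x) print(s)
  invisible(x)
}

#' @export
`[.subject_collection` <- function(x, i) {
  out <- unclass(x)[i]
  if (length(out) == 0L || any(vapply(out, is.null, logical(1))))
    stop_validation("subsetting selects no valid subjects")
  # members of a validated collection stay valid; skip deep re-validation
  structure(out, class = "subject_collection")
}

#' Subject ids of a collection, in their stored (lexicographic) order
#' @param coll a `subject_collection`.
#' @return character vector.
#' @export
subject_ids <- function(coll) names(coll)

#' Save a subject collection to a single container file
#'
#' The container is a single self-describing file (R native serialization,
#' version 3) holding one record per subject with its `data`, `labels`,
#' `sfreq`, `channel_names` and `subject_id`, plus a format tag. Loading with
#' [load_collection()] round-trips the collection exactly. An optional JSON
#' manifest sidecar (`<path>.manifest.json`) lists subject ids and trial
#' counts for human inspection.
#'
#' @param coll a `subject_collection`.
#' @param path output file path.
#' @param manifest write the JSON manifest sidecar? Default `FALSE`.
#' @return `invisible(path)`.
#' @export
save_collection <- function(coll, path, manifest = FALSE) {
  if (!inherits(coll, "subject_collection"))
    coll <- subject_collection(coll)
  payload <- list(
    format = "protoerp-epochs",
    version = 1L,
    subjects = lapply(unclass(coll), unclass)
  )
  ok <- tryCatch({ saveRDS(payload, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write collection to '", path, "'")
  if (manifest) {
    man <- lapply(unclass(coll), function(s)
      list(subject_id = s$subject_id, n_trials = n_trials(s),
           n_targets = sum(s$labels)))
    jsonlite::write_json(unname(man), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Load a subject collection from a container file
#'
#' Validates every record (label alphabet, finite data, consistent shapes)
#' and returns the subjects in lexicographic `subject_id` order, so two loads
#' of the same file compare identical.
#'
#' @param path file written by [save_collection()].
#' @return a `subject_collection`.
#' @export
load_collection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_format("not a protoerp epoch container: ", path))
  if (!is.list(payload) || !identical(payload$format, "protoerp-epochs"))
    stop_format("missing format tag 'protoerp-epochs' in ", path)
  if (is.null(payload$subjects) || length(payload$subjects) == 0L)
    stop_format("missing item 'subjects' in ", path)
  subjects <- lapply(payload$subjects, function(rec) {
    for (field in c("data", "labels", "subject_id", "sfreq", "channel_names"))
      if (is.null(rec[[field]]))
        stop_format("missing item '", field, "' in subject record")
    epoch_set(rec$data, rec$labels, rec$subject_id, rec$sfreq, rec$channel_names)
  })
  subject_collection(subjects)
}
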