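# Plain-text (JSON) serialization of the package's domain objects.
#
# Every container file carries a schema name and version; loading a file
# whose schema does not match raises a classed error rather than returning
# silent garbage. Arrays round-trip losslessly (full double precision).

CONTAINER_VERSION <- 1L

rebuild_kernel <- function(payload) {
  w <- matrix(as.numeric(payload$weights),
              nrow = length(payload$lag_ms),
              dimnames = list(NULL, payload$channels))
  k <- new_trf_estimate(w, payload$lag_ms, payload$channels,
                        payload$condition, payload$subject_id)
  if (!is.null(payload$components) && length(payload$components) > 0)
    k$components <- lapply(payload$components, function(cp) {
      cp$topography <- unlist(cp$topography)
      cp
    })
  k
}

container_payload <- function(object) {
  if (inherits(object, "trf_kernel")) {
    list(schema = "trf_kernel",
         weights = as.vector(object$weights), lag_ms = object$lag_ms,
         channels = object$channels, condition = object$condition,
         subject_id = object$subject_id,
         components = object$components)
  } else if (inherits(object, "run_config")) {
    list(schema = "run_config",
         n_subjects = object$n_subjects,
         n_trials_per_condition = object$n_trials_per_condition,
         stim_config = unclass(object$stim_config),
         noise = unclass(object$noise),
         artifact_rate = object$artifact_rate,
         incorrect_rate = object$incorrect_rate,
         estimator = unclass(object$estimator),
         roi_map = object$roi_map,
         windows = object$windows,
         sim_rate = object$sim_rate,
         master_seed = object$master_seed,
         kernels = lapply(object$kernels, container_payload))
  } else if (inherits(object, "tsvep")) {
    list(schema = "tsvep",
         weights = as.vector(object$weights), lag_ms = object$lag_ms,
         channels = object$channels, contrast = object$contrast,
         subject_id = object$subject_id)
  } else if (inherits(object, "epoch_set")) {
    list(schema = "epoch_set",
         data = as.vector(object$data), dim = dim(object$data),
         time_ms = object$time_ms, sampling_rate = object$sampling_rate,
         channels = object$channels, retained = object$retained)
  } else if (inherits(object, "session_plan")) {
    list(schema = "session_plan",
         n_trials_per_condition = object$n_trials_per_condition,
         conditions = object$conditions,
         probe_fraction = object$probe_fraction,
         probe_onset_window = object$probe_onset_window,
         probe_duration = object$probe_duration,
         trial_duration = object$trial_duration,
         rng_seed = object$rng_seed,
         trial_records = as.list(object$trial_records))
  } else if (inherits(object, "luminance_pair")) {
    list(schema = "luminance_pair",
         foreground = object$foreground, background = object$background,
         frame_rate = object$frame_rate, duration = object$duration)
  } else if (inherits(object, "uniform_sequence")) {
    list(schema = "uniform_sequence",
         luminance = object$luminance,
         frame_rate = object$frame_rate, duration = object$duration)
  } else {
    abort_contract(paste("no container schema for class",
                         paste(class(object), collapse = "/")))
  }
}

#' Save a domain object to a schema-versioned JSON container
#'
#' @param object a `trf_kernel`, `tsvep`, `epoch_set`, `session_plan`,
#'   `luminance_pair`, `uniform_sequence` or `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_container <- function(object, path) {
  payload <- container_payload(object)
  payload$version <- CONTAINER_VERSION
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a domain object from a JSON container
#'
#' @param path file written by [save_container()].
#' @return the reconstructed object.
#' @export
load_container <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) abort_schema(paste("unreadable container:",
                                           conditionMessage(e))))
  if (is.null(payload$schema) || is.null(payload$version))
    abort_schema("file is not a lumitrf container (missing schema/version)")
  if (payload$version != CONTAINER_VERSION)
    abort_schema(sprintf("container version %s != supported version %d",
                         payload$version, CONTAINER_VERSION))
  switch(
    payload$schema,
    trf_kernel = rebuild_kernel(payload),
    run_config = {
      ks <- lapply(payload$kernels, rebuild_kernel)
      run_config(
        n_subjects = payload$n_subjects,
        n_trials_per_condition = payload$n_trials_per_condition,
        stim_config = do.call(stimulus_config, payload$stim_config),
        kernels = ks,
        noise = do.call(noise_model, payload$noise),
        artifact_rate = payload$artifact_rate,
        incorrect_rate = payload$incorrect_rate,
        estimator = do.call(estimator_config, payload$estimator),
        roi_map = payload$roi_map,
        windows = payload$windows,
        sim_rate = payload$sim_rate,
        master_seed = payload$master_seed)
    },
    tsvep = {
      w <- matrix(payload$weights, nrow = length(payload$lag_ms),
                  dimnames = list(NULL, payload$channels))
      structure(list(weights = w, lag_ms = payload$lag_ms,
                     channels = payload$channels,
                     contrast = payload$contrast,
                     subject_id = payload$subject_id),
                class = "tsvep")
    },
    epoch_set = {
      data <- array(as.numeric(payload$data), dim = payload$dim,
                    dimnames = list(NULL, payload$channels, NULL))
      new_epoch_set(data, payload$time_ms, payload$sampling_rate,
                    payload$channels, payload$retained)
    },
    session_plan = {
      out <- payload[c("n_trials_per_condition", "conditions",
                       "probe_fraction", "probe_onset_window",
                       "probe_duration", "trial_duration", "rng_seed")]
      rec <- payload$trial_records
      rec$probe_onset <- as.numeric(unlist(
        lapply(rec$probe_onset, function(v) if (is.null(v)) NA else v)))
      out$trial_records <- as.data.frame(rec, stringsAsFactors = FALSE)
      structure(out, class = "session_plan")
    },
    luminance_pair = structure(
      payload[c("foreground", "background", "frame_rate", "duration")],
      class = "luminance_pair"),
    uniform_sequence = structure(
      payload[c("luminance", "frame_rate", "duration")],
      class = "uniform_sequence"),
    abort_schema(paste("unknown container schema:", payload$schema))
  )
}
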