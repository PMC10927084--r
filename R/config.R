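# Run configuration (YAML), trace serialization and output manifests.

.default_config <- function() {
  list(
    model = list(fss_variant = "original",
                 alpha = list(k_max = 1, J_Caslmyo = 1, P_Ca = 1,
                              G_Ks = 1, I_NCX_bar = 1)),
    protocol = list(kind = "single", amplitude_pApF = 40, duration_ms = 1,
                    s1_interval_ms = 3000, s2_interval_ms = 2000, n_s1 = 3),
    integration = list(dt_ms = 0.01, t_end_ms = 10000, stride = 100),
    analysis = list(repol_threshold_mV = -75, ead_band_mV = c(-70, 20),
                    ead_min_amplitude_mV = 1, prominence_frac = 0.05),
    seed = 1)
}

.check_keys <- function(user, def, path = "") {
  bad <- setdiff(names(user), names(def))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "))
  for (k in names(user))
    if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(user[[k]]))
      .check_keys(user[[k]], def[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, checks every key against the known schema,
#' fills in defaults (an empty file yields the control model, a single
#' stimulus and the reference integration step of 0.01 ms), and records
#' for each top-level block whether it came from the file or from the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list; provenance in `attr(, "provenance")`.
#' @export
load_run_config <- function(path) {
  user <- if (!is.null(path) && file.exists(path)) yaml::read_yaml(path)
          else stop("config file not found: ", path)
  if (is.null(user)) user <- list()
  def <- .default_config()
  .check_keys(user, def)
  cfg <- modifyList(def, user)
  if (cfg$integration$dt_ms <= 0) stop("dt_ms must be positive")
  if (cfg$integration$t_end_ms <= 0) stop("t_end_ms must be positive")
  if (!cfg$model$fss_variant %in% c("original", "flattened"))
    stop("fss_variant must be 'original' or 'flattened'")
  if (!cfg$protocol$kind %in% c("single", "S1S1", "S1S2", "none"))
    stop("unknown protocol kind: ", cfg$protocol$kind)
  if (any(unlist(cfg$model$alpha) < 0))
    stop("alpha factors must be non-negative")
  prov <- stats::setNames(names(def) %in% names(user), names(def))
  attr(cfg, "provenance") <- ifelse(prov, "user", "default")
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Build model objects from a run configuration
#'
#' @param cfg a `run_config`.
#' @return List with `params` and `protocol`.
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  a <- unlist(cfg$model$alpha)
  params <- wg_params(alpha = a[a != 1], fss = cfg$model$fss_variant)
  if (!any(a != 1)) params <- wg_params(fss = cfg$model$fss_variant)
  pr <- cfg$protocol
  protocol <- switch(pr$kind,
    single = stim_single(pr$amplitude_pApF, pr$duration_ms),
    none = stim_none(),
    S1S1 = stim_s1s1(pr$s1_interval_ms, pr$n_s1, pr$amplitude_pApF,
                     pr$duration_ms),
    S1S2 = stim_s1s2(pr$s1_interval_ms, pr$s2_interval_ms, pr$n_s1,
                     pr$amplitude_pApF, pr$duration_ms))
  list(params = params, protocol = protocol)
}

#' Write and read traces as CSV with a JSON metadata sidecar
#'
#' The CSV holds the sampled series (`t_ms`, `V_m_mV`, `Ca_sub_mM` and any
#' further stored columns); the sidecar `<path>.json` holds the metadata
#' needed to re-run the simulation (scaling factors, f_ss variant, protocol,
#' integration settings, synthetic flag).
#'
#' @param trace a `wg_trace`.
#' @param path CSV file path.
#' @return `write_trace_csv` returns the path invisibly; `read_trace_csv`
#'   returns a `wg_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  params <- attr(trace, "params")
  protocol <- attr(trace, "protocol")
  meta <- list(
    synthetic = isTRUE(attr(trace, "synthetic")),
    alpha = if (!is.null(params)) as.list(params$alpha),
    fss = if (!is.null(params)) params$fss,
    protocol = if (!is.null(protocol)) protocol[c("kind", "amplitude",
                                                  "duration", "starts")],
    dt_ms = attr(trace, "dt"),
    stride = attr(trace, "stride"),
    spec = if (!is.null(attr(trace, "spec"))) unclass(attr(trace, "spec")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    attr(tr, "synthetic") <- isTRUE(meta$synthetic)
    attr(tr, "meta") <- meta
  }
  class(tr) <- c("wg_trace", "data.frame")
  tr
}

#' Write analysis outputs with a content manifest
#'
#' Writes each element of `results` (data.frames as CSV, everything else as
#' JSON) into `dir` and returns a manifest listing every artifact with its
#' MD5 content hash.  Two runs with identical inputs produce identical
#' manifests.
#'
#' @param results named list of data.frames and/or serializable lists.
#' @param dir output directory (created if missing).
#' @return data.frame manifest (`file`, `md5`), also written to
#'   `manifest.csv` in `dir`.
#' @export
write_outputs <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      write.csv(as.data.frame(x), f, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
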