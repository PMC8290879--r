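#' Run configuration for the SLA analysis pipeline
#'
#' Collects every tunable of the extraction and modelling pipeline in one
#' validated list: filter cutoffs and orders, the force-plate zeroing
#' threshold, the stride-selection target, grid-search bounds for the
#' within-subjects (10 x 10) and between-subjects (5 x 5) sparse PLS model
#' search, bootstrap count, confidence level and random seed. The
#' configuration (and its hash) is embedded in every file the pipeline
#' writes, so each output is traceable to the settings that produced it.
#'
#' @param marker_cutoff_hz Low-pass cutoff for marker trajectories (Hz).
#' @param grf_cutoff_hz Low-pass cutoff for ground reaction forces (Hz).
#' @param filter_order Effective order of the zero-phase Butterworth filter
#'   (must be even; applied as two passes of half the order).
#' @param fz_threshold_N Vertical force below which a sample is treated as
#'   unloaded: force zeroed, centre of pressure undefined (N).
#' @param min_peak_period_s Minimum separation between successive gait-event
#'   peaks; closer peaks are suppressed keeping the larger excursion (s).
#' @param n_strides Number of mid-trial strides retained per participant.
#' @param max_gap_frames Longest marker gap (frames) bridged by linear
#'   interpolation; longer gaps are an error.
#' @param grid_maxK_within,grid_max_keepX_within Grid bounds (components,
#'   nonzero loadings per component) for the stride-level analysis.
#' @param grid_maxK_between,grid_max_keepX_between Grid bounds for the
#'   participant-average analysis.
#' @param n_bootstrap Participant-bootstrap resample count.
#' @param ci_level Confidence level for all intervals.
#' @param seed Integer seed recorded in every output.
#' @param anthropometry Name of the anthropometric table
#'   (see [winter_anthropometrics()]).
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(marker_cutoff_hz = 10,
                        grf_cutoff_hz = 100,
                        filter_order = 4,
                        fz_threshold_N = 20,
                        min_peak_period_s = 0.4,
                        n_strides = 50,
                        max_gap_frames = 10,
                        grid_maxK_within = 10,
                        grid_max_keepX_within = 10,
                        grid_maxK_between = 5,
                        grid_max_keepX_between = 5,
                        n_bootstrap = 1000,
                        ci_level = 0.95,
                        seed = 1L,
                        anthropometry = "winter") {
  cfg <- list(
    marker_cutoff_hz = marker_cutoff_hz, grf_cutoff_hz = grf_cutoff_hz,
    filter_order = as.integer(filter_order), fz_threshold_N = fz_threshold_N,
    min_peak_period_s = min_peak_period_s, n_strides = as.integer(n_strides),
    max_gap_frames = as.integer(max_gap_frames),
    grid_maxK_within = as.integer(grid_maxK_within),
    grid_max_keepX_within = as.integer(grid_max_keepX_within),
    grid_maxK_between = as.integer(grid_maxK_between),
    grid_max_keepX_between = as.integer(grid_max_keepX_between),
    n_bootstrap = as.integer(n_bootstrap), ci_level = ci_level,
    seed = as.integer(seed), anthropometry = anthropometry
  )
  if (cfg$filter_order < 2 || cfg$filter_order %% 2L != 0L)
    stop_stridesla("parameter_error", "filter_order must be a positive even integer")
  if (any(c(cfg$grid_maxK_within, cfg$grid_max_keepX_within,
            cfg$grid_maxK_between, cfg$grid_max_keepX_between) < 1L))
    stop_stridesla("parameter_error", "grid bounds must be >= 1")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop_stridesla("parameter_error", "ci_level must be in (0, 1)")
  structure(cfg, class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config> hash", config_hash(x), "\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Short reproducibility hash of a configuration
#'
#' 32-bit FNV-1a over the serialized configuration, printed as 8 hex digits.
#' Used to stamp output files so results can be matched to the settings that
#' produced them.
#'
#' @param cfg A `gait_config`.
#' @return An 8-character hex string.
#' @export
config_hash <- function(cfg) {
  bytes <- serialize(unclass(cfg), connection = NULL, version = 2)
  # skip serialization header (R version fields) so the hash depends on content
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  prime <- 16777619
  for (b in as.integer(bytes)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)
    # multiply mod 2^32 in two 16-bit halves to stay within exact doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @param cfg A `gait_config`.
#' @return `read_config` returns a `gait_config`; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  do.call(gait_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# one comment header embedded at the top of every output file
file_header <- function(cfg) {
  sprintf("# stridesla output | config=%s seed=%d", config_hash(cfg), cfg$seed)
}
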