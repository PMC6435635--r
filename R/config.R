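#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline with validation:
#' sensitivity tiers must be sorted ascending within `(0, 1]`, the depth
#' floor must be at least 1, and the anchor k-mer length at least 15.
#'
#' @param seed Integer seed used by every stochastic component.
#' @param sensitivity_tiers Ascending fractions in `(0, 1]`; the
#'   minor-allele-frequency thresholds of the scans (by default the
#'   5/20/35%).
#' @param min_depth Minimum read depth for a site to be scanned.
#' @param min_segment_len Length (bp) from which a length difference is
#'   reported as a deleted/inserted segment rather than a DIP.
#' @param anchor_k K-mer length used to seed alignment anchors.
#' @param band Maximum inter-anchor gap (bp) closed by base-level
#'   alignment.
#' @param mean_depth Mean simulated coverage (reads).
#' @param error_rate Simulated per-base sequencing error rate.
#' @param out_dir Optional output directory for file-writing helpers.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sensitivity_tiers = c(0.05, 0.20, 0.35),
                       min_depth = 10L,
                       min_segment_len = 1000L,
                       anchor_k = 21L,
                       band = 5000L,
                       mean_depth = 78,
                       error_rate = 0.005,
                       out_dir = NULL) {
  seed <- as.integer(seed)
  tiers <- as.numeric(sensitivity_tiers)
  if (length(tiers) == 0L || any(tiers <= 0) || any(tiers > 1))
    stop("run_config: sensitivity tiers must lie in (0, 1]")
  if (is.unsorted(tiers, strictly = TRUE))
    stop("run_config: sensitivity tiers must be sorted strictly ascending")
  if (min_depth < 1L) stop("run_config: min_depth must be >= 1")
  if (anchor_k < 15L) stop("run_config: anchor_k must be >= 15")
  if (min_segment_len < 1L) stop("run_config: min_segment_len must be >= 1")
  structure(list(seed = seed, sensitivity_tiers = tiers,
                 min_depth = as.integer(min_depth),
                 min_segment_len = as.integer(min_segment_len),
                 anchor_k = as.integer(anchor_k),
                 band = as.integer(band),
                 mean_depth = mean_depth,
                 error_rate = error_rate,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `read_run_config()` merges the file's keys over [run_config()]
#' defaults; `write_run_config()` serialises the resolved configuration
#' (including the seed), which is how runs are logged for
#' reproducibility.
#'
#' @param path YAML file path.
#' @return For `read_run_config()`, a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
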