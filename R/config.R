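#' Load a run configuration from YAML or JSON
#'
#' Configuration files are YAML (or equivalently JSON, a YAML subset) with
#' the fields of [run_config()]; `seed` is required whenever any stochastic
#' step (simulation, PSA) is enabled.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `run_config` plus any extra fields (e.g. `preset`, `paths`)
#'   preserved as attributes-free list entries.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "delay_months", "psa", "psa_n", "pooling",
             "discount_rate", "half_cycle", "sd_scale")
  if (is.null(raw$seed) && (isTRUE(raw$psa) || !is.null(raw$preset)))
    stop("config ", basename(path),
         ": `seed` is required when stochastic steps are enabled",
         call. = FALSE)
  args <- raw[intersect(names(raw), known)]
  cfg <- do.call(run_config, args)
  extra <- raw[setdiff(names(raw), known)]
  cfg[names(extra)] <- extra
  cfg
}

#' @rdname load_config
#' @param config A `run_config` (or plain list).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
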