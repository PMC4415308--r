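#' Analysis configuration
#'
#' Defaults follow the measurement protocol: a 31-instance ViHS ensemble
#' (1 initial + `n = 30` scattered), vertex scattering uniform in a
#' 5 x 5 mm square (`half_width_mm = 2.5`), and an integration step of
#' 0.25 mm (the scale of the scanner's accuracy). All randomness flows from
#' the single `seed`.
#'
#' @param ... overrides of the nested defaults, e.g.
#'   `scatter = list(n = 0)` or `integration = list(h = 0.5)`.
#' @return Nested list of class `wound_config`.
#' @export
wound_config <- function(...) {
  cfg <- list(
    segmentation = list(
      backend = "grabcut",          # "ced", "growcut", "grabcut"
      channel = "G", t_low = 0.1, t_high = 0.3,
      close_radius = 3L, sigma = 1.4, gap_max = 10,
      growcut_max_iter = 500L, grabcut_iter = 5L),
    vihs = list(degree = 3L, n_ctrl = 8L, lambda = 0.1,
                margin_mm = 5, min_samples = 50L),
    scatter = list(n = 30L, half_width_mm = 2.5),
    integration = list(h = 0.25),
    edge = list(smooth_sigma_px = 2, offset = "auto", resample_to = 400L),
    frame = "vihs",                  # or "measured"
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = c("wound_config", "list"))
}

#' Read a configuration from YAML
#'
#' @param path YAML file with any subset of the [wound_config()] fields.
#' @return A `wound_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(wound_config, raw)
}

#' @export
print.wound_config <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}
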