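#' Study configuration for the synthetic capillary-bed generator
#'
#' Collects every tunable of the synthetic data generator. Defaults encode
#' the study conditions: a 160 um square imaged field, ~26 capillaries per
#' image, one pericyte soma every ~60 um (gamma-distributed gaps,
#' CV 0.35), per-capillary blockage probabilities of 3% (sham), 40%
#' (ischaemia) and 30% (ischaemia + adenosine), blockage offsets from somata
#' with median 3.6 um, sham soma diameter 5.38 um (s.d. 1.25 um,
#' s.e.m. x sqrt(n) at n = 20), soma/upstream diameter ratios of
#' 1.058 (s.d. 0.067, n = 20), 0.822 (s.d. 0.170, n = 60) and
#' 0.822 x 1.21 under adenosine, a 49% risk-zone (ROIs 7-10) perfusion
#' deficit under ischaemia with a 57% rescue under adenosine, and cohort
#' sizes of 5 / 6 / 8 hearts.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config(p_block = c(sham = 0, ischaemia = 0.5,
#'                                 ischaemia_adenosine = 0.25))
#' @export
study_config <- function(...) {
  cfg <- list(
    field_size = 160,            # um, square imaged field
    field_depth = 20,            # um, stack depth (metadata only)
    capillaries_per_image = 26,
    connector_prob = 0.15,       # per adjacent capillary pair
    intersoma_mean = 60,         # um
    intersoma_cv = 0.35,
    soma_coverage = c(parallel = 0.92, connector = 0.66),
    p_block = c(sham = 0.03, ischaemia = 0.40, ischaemia_adenosine = 0.30),
    block_distance_median = 3.6, # um, offset from the seeding soma
    block_offset_dist = "half_normal",  # or "exponential"
    d_soma = list(              # um: mean, sd per condition
      sham = c(mean = 5.38, sd = 1.25),
      ischaemia = c(mean = 5.38 * (1 - 0.37), sd = 1.25 * (1 - 0.37)),
      ischaemia_adenosine = c(mean = 5.38 * (1 - 0.37) * 1.21,
                              sd = 1.25 * (1 - 0.37) * 1.21)),
    ratio = list(               # d_soma / d_upstream: mean, sd
      sham = c(mean = 1.058, sd = 0.067),
      ischaemia = c(mean = 0.822, sd = 0.170),
      ischaemia_adenosine = c(mean = 0.822 * 1.21, sd = 0.170)),
    roi = list(
      posterior_elevation = 1.2,  # ROIs 4-6 relative to baseline
      risk_multiplier = c(sham = 1, ischaemia = 0.51,
                          ischaemia_adenosine = 0.51 * 1.57),
      noise_sd_heart = 0.10,      # log-normal, heart level
      noise_sd_roi = 0.10),       # log-normal, ROI level
    hearts = c(sham = 5, ischaemia = 6, ischaemia_adenosine = 8),
    stacks_per_heart = 3,
    profile = list(step = 0.25,   # um sampling step
                   length = 40,   # um profile window
                   width_10_90 = 3,  # um sigmoid fall width
                   noise_sd = 0.05,
                   background = 0.1))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$field_size > 0, cfg$capillaries_per_image >= 1,
            cfg$intersoma_mean > 0, cfg$intersoma_cv > 0,
            all(cfg$p_block >= 0 & cfg$p_block <= 1),
            all(cfg$soma_coverage >= 0 & cfg$soma_coverage <= 1),
            cfg$connector_prob >= 0, cfg$connector_prob <= 1,
            cfg$block_distance_median > 0,
            cfg$block_offset_dist %in% c("half_normal", "exponential"),
            all(vapply(cfg$d_soma, function(x) all(x > 0), TRUE)),
            all(vapply(cfg$ratio, function(x) all(x > 0), TRUE)),
            all(cfg$roi$risk_multiplier > 0),
            all(cfg$hearts >= 1), cfg$stacks_per_heart >= 1)
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  field %g um, %d capillaries/image, somata every %g um (CV %g)\n",
              x$field_size, x$capillaries_per_image, x$intersoma_mean,
              x$intersoma_cv))
  cat(sprintf("  p_block: sham %.2f, ischaemia %.2f, isch+ado %.2f\n",
              x$p_block[["sham"]], x$p_block[["ischaemia"]],
              x$p_block[["ischaemia_adenosine"]]))
  cat(sprintf("  hearts: %s; %d stacks/heart\n",
              paste(x$hearts, collapse = "/"), x$stacks_per_heart))
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' @param cfg a [study_config()].
#' @param path YAML file path.
#' @return `path` invisibly / a [study_config()].
#' @export
write_study_config <- function(cfg, path) {
  if (requireNamespace("yaml", quietly = TRUE) && !grepl("\\.json$", path)) {
    writeLines(yaml::as.yaml(named_to_maps(unclass(cfg)), precision = 17),
               path)
  } else {
    jsonlite::write_json(named_to_maps(unclass(cfg)), path,
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_raw(raw)
}

#' Rebuild a study configuration from a deserialized list
#'
#' Restores the named-vector fields that JSON/YAML deserialize as lists,
#' e.g. the `config` entry of a dataset manifest.
#'
#' @param raw a plain list with the fields of [study_config()].
#' @return a [study_config()].
#' @export
config_from_raw <- function(raw) {
  raw$d_soma <- lapply(raw$d_soma, unlist)
  raw$ratio <- lapply(raw$ratio, unlist)
  raw$p_block <- unlist(raw$p_block)
  raw$soma_coverage <- unlist(raw$soma_coverage)
  raw$hearts <- unlist(raw$hearts)
  raw$roi$risk_multiplier <- unlist(raw$roi$risk_multiplier)
  raw$profile <- lapply(raw$profile, unlist)
  do.call(study_config, raw)
}
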