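# Pipeline configuration: flat "key = value" text files, one key per line,
# '#' comments. Unknown keys are rejected so typos never silently fall back
# to defaults.

.config_defaults <- function() {
  list(
    window_size       = 50000,   # bp, sliding-window width
    window_step       = 25000,   # bp, slide
    q_threshold       = 0.05,    # FDR threshold for outlier calls
    proximity_bp      = 8000,    # gene-proximity distance
    n_permutations    = 1000,    # permutation-enrichment replicates
    str_maf_min       = 0.1,     # STR minor-allele-frequency filter
    snp_maf_min       = 0.05,    # iHS core-site derived-frequency bound
    ehh_cutoff        = 0.05,    # EHH decay cutoff
    ehh_gap_limit     = 200000,  # bp, max inter-site gap during integration
    ehh_max_extend    = 300000,  # bp, max EHH extension from the core
    ihs_bins          = 20,      # derived-allele-frequency bins
    min_support       = 2,       # windows per supported outlier region
    min_accessible    = 0.1,     # min accessible fraction per window
    sv_max_missing    = 0.2,     # per-SV missing-genotype ceiling
    tajima_population = "B",     # within-population statistics source
    seed              = 1L
  )
}

#' Load a pipeline configuration
#'
#' Reads a flat `key = value` configuration file, fills defaults, and
#' validates ranges. An empty or absent-path (`NULL`) configuration yields
#' the full default set.
#'
#' @param path path to the config file, or `NULL` for pure defaults.
#' @return named list of validated parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
      cfg[[key]] <- if (key == "tajima_population") val else as.numeric(val)
    }
  }
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  num <- function(k) cfg[[k]]
  if (is.na(num("window_size")) || num("window_size") <= 0) {
    stop("config key 'window_size' must be > 0")
  }
  if (is.na(num("window_step")) || num("window_step") <= 0) {
    stop("config key 'window_step' must be > 0")
  }
  if (num("window_step") > num("window_size")) {
    stop("config key 'window_step' must not exceed 'window_size'")
  }
  for (k in c("q_threshold", "str_maf_min", "snp_maf_min", "ehh_cutoff",
              "min_accessible", "sv_max_missing")) {
    if (is.na(num(k)) || num(k) < 0 || num(k) > 1) {
      stop("config key '", k, "' must be in [0, 1]")
    }
  }
  for (k in c("proximity_bp", "n_permutations", "ihs_bins", "min_support",
              "ehh_gap_limit", "ehh_max_extend")) {
    if (is.na(num(k)) || num(k) < 1) stop("config key '", k, "' must be >= 1")
  }
  if (!cfg$tajima_population %in% c("A", "B")) {
    stop("config key 'tajima_population' must be 'A' or 'B'")
  }
  invisible(TRUE)
}
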