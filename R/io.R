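# Plain-text I/O: one profile per file, tab-separated, '#' header lines
# carrying the experiment metadata.  Canonical formatting round-trips
# byte-identically.

.HEADER_KEYS <- c("spin", "nucleus", "b1_hz", "tex_s", "sfrq_mhz",
                  "carrier_ppm", "temperature_c")

#' Write a CEST profile to a TSV file
#'
#' File dialect: `# key: value` header lines (spin, nucleus, b1_hz, tex_s,
#' sfrq_mhz, carrier_ppm, temperature_c, optional b1_inhomogeneity),
#' followed by tab-separated columns `offset_hz`, `intensity` and, when
#' errors are present, `error`.  Newlines are `\n`.
#'
#' @param profile a [cest_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cest_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cest_profile"))
  ex <- profile$experiment
  hdr <- c(
    sprintf("# spin: %s", profile$spin_id),
    sprintf("# nucleus: %s", profile$nucleus),
    sprintf("# b1_hz: %.10g", ex$b1_hz),
    sprintf("# tex_s: %.10g", ex$tex_s),
    sprintf("# sfrq_mhz: %.10g", ex$sfrq_mhz),
    sprintf("# carrier_ppm: %.10g", ex$carrier_ppm),
    sprintf("# temperature_c: %.10g", ex$temperature_c))
  if (ex$b1_inhomogeneity > 0)
    hdr <- c(hdr, sprintf("# b1_inhomogeneity: %.10g", ex$b1_inhomogeneity))
  has_err <- !is.null(profile$errors)
  cols <- c("offset_hz", "intensity", if (has_err) "error")
  rows <- if (has_err) {
    sprintf("%.6f\t%.8f\t%.8f", ex$offsets_hz, profile$intensities,
            profile$errors)
  } else {
    sprintf("%.6f\t%.8f", ex$offsets_hz, profile$intensities)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), con, sep = "\n")
  invisible(path)
}

#' Write a list of profiles into a directory
#'
#' @param profiles list of [cest_profile()] objects.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_cest_profiles <- function(profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(profiles, function(p)
    file.path(dir, sprintf("%s_b1_%s.tsv", p$spin_id,
                           gsub("[^0-9A-Za-z.]", "_",
                                format(p$experiment$b1_hz)))),
    "")
  Map(write_cest_profile, profiles, paths)
  invisible(paths)
}

#' Read CEST profiles from TSV files
#'
#' Parses the dialect written by [write_cest_profile()].  Offset order is
#' preserved exactly as found (monotonicity is not required).
#'
#' @param paths character vector of file paths.
#' @return list of [cest_profile()] objects.
#' @export
read_cest_profiles <- function(paths) {
  lapply(paths, function(path) {
    lines <- readLines(path)
    hdr_lines <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (h in hdr_lines) {
      kv <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
      if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
    }
    missing <- setdiff(.HEADER_KEYS, names(meta))
    if (length(missing) > 0)
      stop("file ", path, " is missing mandatory header key(s): ",
           paste(missing, collapse = ", "))
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(body)]
    tab <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                      sep = "\t")
    ex <- cest_experiment(
      b1_hz = as.numeric(meta$b1_hz), tex_s = as.numeric(meta$tex_s),
      sfrq_mhz = as.numeric(meta$sfrq_mhz),
      carrier_ppm = as.numeric(meta$carrier_ppm),
      offsets_hz = tab$offset_hz,
      temperature_c = as.numeric(meta$temperature_c),
      b1_inhomogeneity = as.numeric(meta$b1_inhomogeneity %||n% "0"))
    cest_profile(ex, meta$spin, meta$nucleus, tab$intensity,
                 errors = tab$error)
  })
}

#' Read and validate a run configuration
#'
#' YAML configuration for a fitting run.  Recognized top-level keys:
#' `model` (with `level` and named `kinetics`; populations as fractions,
#' or strings with a `%` suffix which are converted), `spins` (per-spin
#' `omega_ppm`, `dw`, `r1`, `r2`), `seed`, `output_dir`, `profiles`
#' (paths or glob).  Unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "spins", "seed", "output_dir", "profiles")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model$level) ||
      !cfg$model$level %in% names(.LEVELS))
    stop("config must set model.level to one of: ",
         paste(names(.LEVELS), collapse = ", "))
  kin <- cfg$model$kinetics
  if (!is.null(kin)) {
    cfg$model$kinetics <- vapply(kin, function(v) {
      if (is.character(v) && grepl("%$", v))
        as.numeric(sub("%$", "", v)) / 100
      else as.numeric(v)
    }, 0)
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}
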