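# Residue-level statistics on fitted minor-state chemical-shift differences.
#
# A "shift table" is a plain data.frame with columns residue (integer),
# resname (character, optional), nucleus (character, from the supported
# set: 15N, 1HN, 1HA, 13CA, 13CO, 13CB, methyl-13C, methyl-1H) and
# delta_omega_ppm (signed, minor minus major).  Glycine contributes its two
# 1HA shifts as two rows, each counted as a separate term.

.check_shift_table <- function(x, arg = "shift table") {
  if (!is.data.frame(x) ||
      !all(c("residue", "nucleus", "delta_omega_ppm") %in% names(x)))
    stop(arg, " must have columns residue, nucleus, delta_omega_ppm")
  bad <- !x$nucleus %in% names(.NUCLEUS_BASE)
  if (any(bad))
    stop(arg, " contains unsupported nucleus label(s): ",
         paste(unique(x$nucleus[bad]), collapse = ", "))
  invisible(x)
}

#' Composite chemical-shift perturbation per residue
#'
#' The root of the mean squared standardized shift difference over the
#' nuclei available for each residue:
#' \deqn{\Delta\varpi_{RMS} =
#'   \sqrt{\frac{1}{N}\sum_{i=1}^{N}
#'   \left(\Delta\varpi_i / \varpi_{std,i}\right)^2},}
#' where \eqn{\varpi_{std,i}} is the standard deviation of reported
#' chemical shifts for nucleus class i, used as normalizer, and N counts
#' only the nuclei for which a shift difference is available (N varies per
#' residue).
#'
#' @param shifts a shift table (see above) for one state pair.
#' @param std named numeric vector mapping nucleus labels to
#'   \eqn{\varpi_{std}} values in ppm (all > 0).  Ship your own: the
#'   default normalizers used in the literature come from shift-database
#'   statistics and should be passed explicitly.
#' @return data.frame with columns `residue`, `rms` (dimensionless,
#'   conventionally quoted in ppm-normalized units) and `n_nuclei`.
#'   Residues with no usable nucleus are omitted with a warning.
#' @export
delta_omega_rms <- function(shifts, std) {
  .check_shift_table(shifts)
  if (is.null(names(std)) || any(std <= 0))
    stop("'std' must be a named vector of positive normalizers")
  usable <- shifts$nucleus %in% names(std)
  dropped <- unique(shifts$residue[!shifts$residue %in%
                                     shifts$residue[usable]])
  if (length(dropped) > 0)
    warning("residue(s) omitted (no nucleus with a defined std): ",
            paste(dropped, collapse = ", "))
  sh <- shifts[usable, , drop = FALSE]
  norm2 <- (sh$delta_omega_ppm / std[sh$nucleus])^2
  agg <- tapply(norm2, sh$residue, function(v) c(sqrt(mean(v)), length(v)))
  res <- as.integer(names(agg))
  out <- data.frame(residue = res,
                    rms = vapply(agg, `[`, 0, 1),
                    n_nuclei = as.integer(vapply(agg, `[`, 0, 2)))
  out[order(out$residue), , drop = FALSE]
}

#' Residues with composite shift perturbation above a threshold
#'
#' @param rms output of [delta_omega_rms()] (or any data.frame with
#'   `residue` and `rms` columns).
#' @param threshold classification cutoff; the conventional choice for
#'   backbone data is 0.5.
#' @return integer vector of residue numbers with `rms > threshold`.
#' @export
classify_perturbed <- function(rms, threshold = 0.5) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  if (nrow(rms) == 0) return(integer(0))
  sort(rms$residue[rms$rms > threshold])
}

#' RMS difference between two shift tables
#'
#' Root-mean-square of the pairwise `delta_omega_ppm` differences over the
#' (residue, nucleus) records shared by the two tables, optionally
#' restricted to one nucleus and excluding a set of residues (e.g. sites
#' adjacent to a mutation).
#'
#' @param a,b shift tables.
#' @param nucleus optional nucleus filter (e.g. `"15N"`).
#' @param exclude integer vector of residue numbers to drop.
#' @return RMSD in ppm.
#' @export
shift_rmsd <- function(a, b, nucleus = NULL, exclude = integer(0)) {
  .check_shift_table(a, "'a'"); .check_shift_table(b, "'b'")
  if (!is.null(nucleus)) {
    a <- a[a$nucleus %in% nucleus, , drop = FALSE]
    b <- b[b$nucleus %in% nucleus, , drop = FALSE]
  }
  a <- a[!a$residue %in% exclude, , drop = FALSE]
  b <- b[!b$residue %in% exclude, , drop = FALSE]
  m <- merge(a[c("residue", "nucleus", "delta_omega_ppm")],
             b[c("residue", "nucleus", "delta_omega_ppm")],
             by = c("residue", "nucleus"))
  if (nrow(m) == 0)
    stop("no shared (residue, nucleus) records after filtering")
  sqrt(mean((m$delta_omega_ppm.x - m$delta_omega_ppm.y)^2))
}

#' Reconstruct a minor-state peak list
#'
#' Converts fitted shift differences into absolute minor-state chemical
#' shifts, `minor = major + delta_omega` (the package-wide sign
#' convention: delta_omega is minor minus major).
#'
#' @param major data.frame of major-state shifts with columns `residue`,
#'   `nucleus`, `shift_ppm`.
#' @param shifts a shift table of `delta_omega_ppm` for the minor state.
#' @return data.frame `residue`, `nucleus`, `shift_ppm` for the minor
#'   state; records without a major-state shift are skipped with a
#'   warning.
#' @export
export_peaklist <- function(major, shifts) {
  .check_shift_table(shifts)
  if (!all(c("residue", "nucleus", "shift_ppm") %in% names(major)))
    stop("'major' must have columns residue, nucleus, shift_ppm")
  m <- merge(shifts[c("residue", "nucleus", "delta_omega_ppm")], major,
             by = c("residue", "nucleus"), all.x = TRUE)
  miss <- is.na(m$shift_ppm)
  if (any(miss)) {
    warning(sum(miss), " record(s) skipped: no major-state shift")
    m <- m[!miss, , drop = FALSE]
  }
  out <- data.frame(residue = m$residue, nucleus = m$nucleus,
                    shift_ppm = m$shift_ppm + m$delta_omega_ppm)
  out[order(out$residue, out$nucleus), , drop = FALSE]
}
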