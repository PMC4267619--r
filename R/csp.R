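#' Combined amide chemical-shift perturbation
#'
#' Combines a backbone amide proton and nitrogen shift difference into a
#' single perturbation value,
#' \deqn{\Delta\delta = \sqrt{\delta_{HN}^2 + (\delta_N / w)^2},}
#' where the nitrogen weight \eqn{w} (default 6.51) accounts for the wider
#' dispersion of the 15N dimension.
#'
#' @param delta_H proton shift difference (ppm); vectorised.
#' @param delta_N nitrogen shift difference (ppm); recycled against
#'   `delta_H`.
#' @param n_weight nitrogen scaling weight.
#' @return combined perturbation in ppm, always non-negative.
#' @examples
#' combined_csp(0.06, 0.651) # sqrt(0.0036 + 0.01)
#' @export
combined_csp <- function(delta_H, delta_N, n_weight = 6.51) {
  if (!all(is.finite(delta_H)) || !all(is.finite(delta_N)))
    stop("combined_csp: shift differences must be finite")
  sqrt(delta_H^2 + (delta_N / n_weight)^2)
}

#' Read a titration peak list
#'
#' Parses a single-state amide peak list into a data frame of peaks.
#' Two dialects are supported:
#' \describe{
#'   \item{`sparky`}{whitespace-separated `Assignment w1 w2 [height]`
#'     columns as exported from Sparky for a 15N-HSQC, with `w1` the 15N
#'     shift and `w2` the 1H shift. Assignments such as `T382N-H` are parsed
#'     for the residue number.}
#'   \item{`tabular`}{a TSV with a header naming at least `residue`,
#'     `shift_H` and `shift_N` (optionally `intensity`).}
#' }
#'
#' @param path file path.
#' @param dialect `"sparky"` or `"tabular"`.
#' @return data frame with columns `residue`, `shift_H`, `shift_N`,
#'   `intensity` (NA when absent).
#' @export
read_peaklist <- function(path, dialect = c("sparky", "tabular")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tabular") {
    keep <- nzchar(trimws(lines))
    if (!any(keep)) {
      warning("empty peak list: ", path)
      return(empty_peaks())
    }
    df <- utils::read.delim(text = lines[keep], stringsAsFactors = FALSE)
    need <- c("residue", "shift_H", "shift_N")
    if (!all(need %in% names(df)))
      stop("tabular peak list must have columns residue, shift_H, shift_N")
    if (is.null(df$intensity)) df$intensity <- NA_real_
    pk <- df[, c("residue", "shift_H", "shift_N", "intensity")]
  } else {
    body <- lines[nzchar(trimws(lines)) & !grepl("^\\s*Assignment", lines)]
    if (length(body) == 0L) {
      warning("empty peak list: ", path)
      return(empty_peaks())
    }
    pk <- parse_sparky_lines(body, lines)
  }
  pk$residue <- as.integer(pk$residue)
  bad <- !is.finite(pk$shift_H) | !is.finite(pk$shift_N)
  if (any(bad))
    stop("malformed shift fields in ", path, " for residue(s) ",
         paste(pk$residue[bad], collapse = ", "))
  dup <- unique(pk$residue[duplicated(pk$residue)])
  if (length(dup))
    stop("duplicate residue(s) in peak list: ", paste(dup, collapse = ", "))
  pk[order(pk$residue), , drop = FALSE]
}

empty_peaks <- function() {
  data.frame(residue = integer(), shift_H = numeric(),
             shift_N = numeric(), intensity = numeric())
}

parse_sparky_lines <- function(body, all_lines) {
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    lineno <- match(body[[i]], all_lines)
    if (length(f) < 3L)
      stop("line ", lineno, ": expected 'assignment w1 w2', got: ", body[[i]])
    res <- regmatches(f[1], regexpr("[0-9]+", f[1]))
    wN <- suppressWarnings(as.numeric(f[2]))
    wH <- suppressWarnings(as.numeric(f[3]))
    if (length(res) == 0L || is.na(wN) || is.na(wH))
      stop("line ", lineno, ": malformed peak entry: ", body[[i]])
    ht <- if (length(f) >= 4L) suppressWarnings(as.numeric(f[4])) else NA_real_
    out[[i]] <- data.frame(residue = as.integer(res), shift_H = wH,
                           shift_N = wN, intensity = ht)
  }
  do.call(rbind, out)
}

#' Construct a titration series
#'
#' Bundles peak lists recorded along a ligand titration with the sample
#' conditions. The first point must be the free state (ligand
#' concentration 0) and ligand concentrations must be non-decreasing.
#'
#' @param protein_conc protein concentration (molar).
#' @param points list of points, each a `list(ligand_conc =, peaks =)`
#'   where `peaks` is a peak data frame as returned by [read_peaklist()].
#' @param construct_range length-2 integer vector of first and last residue
#'   of the construct.
#' @param prolines residue indices of prolines (no amide, never assigned).
#' @return object of class `titration_series`.
#' @export
titration_series <- function(protein_conc, points,
                             construct_range = c(347L, 502L),
                             prolines = integer()) {
  stopifnot(protein_conc > 0, length(points) >= 1L)
  lc <- vapply(points, function(p) p$ligand_conc, numeric(1))
  if (lc[1] != 0)
    stop("first titration point must be the free state (ligand_conc = 0)")
  if (is.unsorted(lc))
    stop("ligand concentrations must be non-decreasing")
  for (p in points) {
    pk <- p$peaks
    r <- pk$residue[!is.na(pk$residue)]
    if (length(r) && (min(r) < construct_range[1] || max(r) > construct_range[2]))
      stop("peak residue index outside construct range ",
           construct_range[1], "-", construct_range[2])
  }
  structure(list(protein_conc = protein_conc, points = points,
                 construct_range = as.integer(construct_range),
                 prolines = as.integer(prolines)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("Titration series:", length(x$points), "points, protein",
      format(x$protein_conc * 1e3), "mM, construct",
      paste(x$construct_range, collapse = "-"), "\n")
  invisible(x)
}

#' Track peaks through a titration
#'
#' Follows each free-state amide peak through successive titration points by
#' nearest-neighbour chaining: at every step the peak position is matched to
#' the closest peak of the next point within a rectangular search radius.
#' A residue whose chain breaks (no candidate within the radius at some
#' step) is labelled `untracked` -- the behaviour of peaks broadened into
#' intermediate exchange. Ties between several candidates are broken by the
#' smallest combined-shift distance and flagged as ambiguous.
#'
#' @param series a [titration_series()].
#' @param radius named numeric `c(H =, N =)` search radius in ppm.
#' @return data frame of class `peak_tracking` with one row per free-state
#'   peak: `residue`, `status` (`tracked`/`untracked`), free and final
#'   shifts, `lost_at` (point index where the chain broke) and `ambiguous`.
#' @export
track_peaks <- function(series, radius = c(H = 0.05, N = 0.4)) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$points) < 2L)
    stop("track_peaks: need at least two titration points")
  free <- series$points[[1]]$peaks
  n <- nrow(free)
  status <- rep("tracked", n)
  lost_at <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  curH <- free$shift_H
  curN <- free$shift_N
  for (k in seq_along(series$points)[-1]) {
    pk <- series$points[[k]]$peaks
    for (i in seq_len(n)) {
      if (status[i] == "untracked") next
      dH <- abs(pk$shift_H - curH[i])
      dN <- abs(pk$shift_N - curN[i])
      cand <- which(dH <= radius[["H"]] & dN <= radius[["N"]])
      if (length(cand) == 0L) {
        status[i] <- "untracked"
        lost_at[i] <- k
      } else {
        if (length(cand) > 1L) ambiguous[i] <- TRUE
        d <- combined_csp(dH[cand], dN[cand])
        j <- cand[which.min(d)]
        curH[i] <- pk$shift_H[j]
        curN[i] <- pk$shift_N[j]
      }
    }
  }
  out <- data.frame(residue = free$residue, status = status,
                    free_H = free$shift_H, free_N = free$shift_N,
                    final_H = ifelse(status == "tracked", curH, NA_real_),
                    final_N = ifelse(status == "tracked", curN, NA_real_),
                    lost_at = lost_at, ambiguous = ambiguous)
  class(out) <- c("peak_tracking", "data.frame")
  out
}

#' Per-residue chemical-shift-perturbation profile
#'
#' Computes the combined perturbation of every construct residue between the
#' free state and the final titration point. Residues whose peak could be
#' followed get the measured value; residues lost during the titration
#' (intermediate exchange) are assigned the cap value (default 0.3 ppm);
#' prolines and residues unassigned in the free state carry status
#' `unassigned` and no numeric value.
#'
#' @param series a [titration_series()].
#' @param radius matching radius passed to [track_peaks()].
#' @param cap_value perturbation (ppm) assigned to untracked residues.
#' @param n_weight nitrogen weight of [combined_csp()].
#' @return data frame of class `csp_profile` with columns `residue`,
#'   `status` (`measured`, `untracked`, `unassigned`) and `value` (ppm; NA
#'   for unassigned).
#' @export
csp_profile <- function(series, radius = c(H = 0.05, N = 0.4),
                        cap_value = 0.3, n_weight = 6.51) {
  trk <- track_peaks(series, radius)
  residues <- seq(series$construct_range[1], series$construct_range[2])
  status <- rep("unassigned", length(residues))
  value <- rep(NA_real_, length(residues))
  idx <- match(trk$residue, residues)
  keep <- !is.na(idx)
  tracked <- keep & trk$status == "tracked"
  status[idx[tracked]] <- "measured"
  value[idx[tracked]] <- combined_csp(trk$final_H[tracked] - trk$free_H[tracked],
                                      trk$final_N[tracked] - trk$free_N[tracked],
                                      n_weight)
  untracked <- keep & trk$status == "untracked"
  status[idx[untracked]] <- "untracked"
  value[idx[untracked]] <- cap_value
  status[residues %in% series$prolines] <- "unassigned"
  value[residues %in% series$prolines] <- NA_real_
  new_csp_profile(residues, status, value, cap_value)
}

#' Construct a CSP profile directly
#'
#' Low-level constructor used by the synthetic-data generator and by code
#' importing externally computed perturbations.
#'
#' @param residue integer residue indices.
#' @param status per-residue status: `measured`, `untracked` or
#'   `unassigned`.
#' @param value perturbation in ppm (NA for unassigned residues).
#' @param cap_value cap used for untracked residues.
#' @return `csp_profile` data frame.
#' @export
new_csp_profile <- function(residue, status, value, cap_value = 0.3) {
  stopifnot(length(residue) == length(status), length(status) == length(value),
            all(status %in% c("measured", "untracked", "unassigned")))
  if (any(value[status == "measured"] < 0, na.rm = TRUE))
    stop("measured CSP values must be non-negative")
  value[status == "untracked"] <- cap_value
  out <- data.frame(residue = as.integer(residue), status = status,
                    value = value)
  attr(out, "cap_value") <- cap_value
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Numeric export of a CSP profile
#'
#' Returns the per-residue values used in downstream sums: measured values
#' as-is, untracked residues at the cap, unassigned residues as 0.
#'
#' @param profile a `csp_profile`.
#' @return numeric vector named by residue index.
#' @export
csp_values <- function(profile) {
  stopifnot(inherits(profile, "csp_profile"))
  v <- ifelse(profile$status == "unassigned", 0,
              ifelse(profile$status == "untracked",
                     attr(profile, "cap_value"), profile$value))
  names(v) <- profile$residue
  v
}

#' @export
print.csp_profile <- function(x, ...) {
  tab <- table(factor(x$status, c("measured", "untracked", "unassigned")))
  cat("CSP profile:", nrow(x), "residues (",
      tab[["measured"]], "measured,", tab[["untracked"]], "untracked,",
      tab[["unassigned"]], "unassigned ), cap",
      attr(x, "cap_value"), "ppm\n")
  m <- x$value[x$status == "measured"]
  if (length(m))
    cat("  measured range:", format(signif(range(m), 3)), "ppm\n")
  invisible(x)
}

#' Write a CSP profile to CSV
#'
#' Exports residue, status and value; unassigned residues carry an empty
#' value field (the sentinel column, rather than a negative bar).
#'
#' @param profile a `csp_profile`.
#' @param path output file.
#' @export
write_csp_csv <- function(profile, path) {
  stopifnot(inherits(profile, "csp_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, na = "")
  invisible(path)
}
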