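#' Single-position substitution panel
#'
#' One position of a scaffold-independent analysis: the four oligos that
#' substitute A, C, G or U at `position` of the scaffold hexamer, each with
#' the CSP profile its titration produced.
#'
#' @param position assayed position (1-6).
#' @param scaffold hexamer sequence carrying the winners fixed so far.
#' @param variants named list `A`/`C`/`G`/`U` of [csp_profile][new_csp_profile]
#'   objects; a variant may be `NULL` when explicitly missing.
#' @param ratio protein:RNA ratio reached, as RNA equivalents (e.g. 1.25,
#'   or 0.6 for a sub-stoichiometric panel); provenance metadata only.
#' @return object of class `oligo_panel`.
#' @export
oligo_panel <- function(position, scaffold, variants, ratio = 1.25) {
  stopifnot(position %in% 1:6, nchar(scaffold) == 6L)
  if (!setequal(names(variants), c("A", "C", "G", "U")))
    stop("variants must be named A, C, G, U (NULL allowed for missing)")
  ok <- vapply(variants, function(v)
    is.null(v) || inherits(v, "csp_profile"), logical(1))
  if (!all(ok)) stop("each variant must be a csp_profile or NULL")
  structure(list(position = as.integer(position),
                 scaffold = toupper(scaffold),
                 variants = variants[c("A", "C", "G", "U")],
                 ratio = ratio),
            class = "oligo_panel")
}

#' Variant sequence of a panel member
#' @param panel an [oligo_panel()].
#' @param nt nucleotide substituted at the panel position.
#' @return the hexamer assayed for that variant.
#' @export
variant_sequence <- function(panel, nt) {
  s <- strsplit(panel$scaffold, "")[[1]]
  s[panel$position] <- nt
  paste(s, collapse = "")
}

#' Score one substitution panel
#'
#' Sums the perturbations of each variant oligo over all residues (capped
#' values for untracked residues included, unassigned residues contribute
#' nothing) and normalises the four sums to the largest. The winning
#' nucleotide is called only when it beats the runner-up by the margin
#' `tau` on the normalised scale; otherwise the position is ambiguous (N).
#'
#' @param panel an [oligo_panel()].
#' @param margin winner-call margin `tau` on the normalised score scale:
#'   the runner-up must score below `1 - margin`.
#' @param min_csp optional minimum perturbation (ppm); measured residues
#'   below it are excluded from the sums. Off (0) by default.
#' @return list of class `sia_position_score` with elements `position`,
#'   `raw` and `normalized` scores, and `winner` (a nucleotide or `"N"`).
#' @export
score_position <- function(panel, margin = 0.2, min_csp = 0) {
  stopifnot(inherits(panel, "oligo_panel"))
  raw <- vapply(panel$variants, function(p) {
    if (is.null(p)) return(NA_real_)
    v <- csp_values(p)
    if (min_csp > 0) v[p$status == "measured" & v < min_csp] <- 0
    sum(v)
  }, numeric(1))
  mx <- max(raw, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    warning("all-zero panel at position ", panel$position, "; winner is N")
    normalized <- ifelse(is.na(raw), NA_real_, 0)
    winner <- "N"
  } else {
    normalized <- raw / mx
    ord <- order(normalized, decreasing = TRUE, na.last = TRUE)
    runner <- normalized[ord][2]
    winner <- if (!is.na(runner) && runner <= 1 - margin)
      names(normalized)[ord][1] else "N"
  }
  structure(list(position = panel$position, raw = raw,
                 normalized = normalized, winner = winner),
            class = "sia_position_score")
}

#' @export
print.sia_position_score <- function(x, ...) {
  cat("Position", x$position, "scores:",
      paste(sprintf("%s=%.2f", names(x$normalized), x$normalized),
            collapse = " "),
      "-> winner", x$winner, "\n")
  invisible(x)
}

#' Run a modified scaffold-independent analysis
#'
#' Scores the supplied panels in assay order, fixing each position's winning
#' nucleotide into the scaffold before the next position is interpreted,
#' and assembles the consensus hexamer. Each panel's scaffold is checked
#' against the winners already fixed: a panel whose scaffold contradicts a
#' previously called winner is an assay-design error.
#'
#' @param panels list of [oligo_panel()] objects, one per assayed position,
#'   supplied in assay order.
#' @param order integer vector of assayed positions, matching `panels`.
#' @param margin winner-call margin passed to [score_position()].
#' @param min_csp optional perturbation floor passed to [score_position()].
#' @return object of class `sia_result`: per-position scores, winners, the
#'   assay order and the length-6 IUPAC consensus (N at unassayed or
#'   ambiguous positions).
#' @export
run_sia <- function(panels, order = c(4L, 3L, 2L, 6L, 1L),
                    margin = 0.2, min_csp = 0) {
  stopifnot(length(panels) == length(order))
  pos_seen <- integer()
  winners <- character()
  scores <- vector("list", length(panels))
  for (k in seq_along(panels)) {
    panel <- panels[[k]]
    if (panel$position != order[k])
      stop("panel ", k, " assays position ", panel$position,
           " but the assay order expects position ", order[k])
    sc <- strsplit(panel$scaffold, "")[[1]]
    for (j in seq_along(pos_seen)) {
      w <- winners[[j]]
      if (w != "N" && sc[pos_seen[j]] != w)
        stop("panel for position ", panel$position,
             " has scaffold ", panel$scaffold,
             " inconsistent with fixed winner ", w,
             " at position ", pos_seen[j])
    }
    scores[[k]] <- score_position(panel, margin = margin, min_csp = min_csp)
    winners <- c(winners, scores[[k]]$winner)
    pos_seen <- c(pos_seen, panel$position)
  }
  consensus <- rep("N", 6L)
  consensus[pos_seen] <- winners
  structure(list(assay_order = order,
                 scores = stats::setNames(scores, paste0("pos", order)),
                 winners = stats::setNames(winners, order),
                 ratios = vapply(panels, function(p) p$ratio, numeric(1)),
                 consensus = paste(consensus, collapse = "")),
            class = "sia_result")
}

#' @export
print.sia_result <- function(x, ...) {
  cat("Scaffold-independent analysis\n")
  cat("  assay order:", paste(x$assay_order, collapse = ", "), "\n")
  for (s in x$scores) print(s)
  cat("  consensus: 5'-", x$consensus, "-3'\n", sep = "")
  invisible(x)
}

#' Per-position score table of an SIA result
#' @param x a `sia_result`.
#' @return data frame with one row per assayed position and the four
#'   normalised nucleotide scores plus the winner.
#' @export
sia_score_table <- function(x) {
  stopifnot(inherits(x, "sia_result"))
  do.call(rbind, lapply(x$scores, function(s)
    data.frame(position = s$position, t(s$normalized), winner = s$winner)))
}
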