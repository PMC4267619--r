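#' Construct a distance-restraint set
#'
#' @param df data frame with columns `chain_a`, `res_a`, `atom_a`,
#'   `chain_b`, `res_b`, `atom_b`, `upper` (angstrom) and optionally
#'   `hbond` (logical flag for hydrogen-bond restraints).
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(df) {
  need <- c("chain_a", "res_a", "atom_a", "chain_b", "res_b", "atom_b",
            "upper")
  if (!all(need %in% names(df)))
    stop("restraint table must have columns ", paste(need, collapse = ", "))
  if (any(df$upper <= 0)) stop("upper bounds must be positive")
  if (is.null(df$hbond)) df$hbond <- FALSE
  class(df) <- c("restraint_set", "data.frame")
  df
}

# Map residue numbers to chain ids via named residue ranges,
# e.g. list(A = c(347, 502), B = c(503, 508)).
chain_from_ranges <- function(resno, chains) {
  out <- rep(NA_character_, length(resno))
  for (ch in names(chains)) {
    rg <- chains[[ch]]
    out[is.na(out) & resno >= rg[1] & resno <= rg[2]] <- ch
  }
  if (anyNA(out))
    stop("residue(s) ", paste(unique(resno[is.na(out)]), collapse = ", "),
         " not covered by any chain range")
  out
}

#' Read CYANA upper-limit distance restraints
#'
#' Parses a `.upl` file (columns: residue number, residue name, atom name
#' for each partner, then the upper bound in angstrom). CYANA numbers all
#' chains in one sequence, so chain identity is recovered from residue
#' ranges supplied by the caller; lines whose comment contains `HB` are
#' flagged as hydrogen-bond restraints.
#'
#' @param path `.upl` file.
#' @param chains named list of length-2 residue ranges assigning residue
#'   number blocks to chains, e.g. `list(A = c(1, 156), B = c(157, 162))`.
#'   `NULL` puts everything in chain `"A"`.
#' @return a [restraint_set()].
#' @export
read_upl <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- lapply(which(keep), function(i) {
    ln <- lines[[i]]
    comment <- sub("^[^#]*", "", ln)
    f <- strsplit(trimws(sub("#.*", "", ln)), "\\s+")[[1]]
    if (length(f) < 7L)
      stop("line ", i, ": expected 7 fields in upl record, got ", length(f))
    ub <- suppressWarnings(as.numeric(f[7]))
    ra <- suppressWarnings(as.integer(f[1]))
    rb <- suppressWarnings(as.integer(f[4]))
    if (is.na(ub) || is.na(ra) || is.na(rb))
      stop("line ", i, ": malformed upl record: ", ln)
    data.frame(res_a = ra, name_a = f[2], atom_a = f[3],
               res_b = rb, name_b = f[5], atom_b = f[6],
               upper = ub, hbond = grepl("HB", comment, ignore.case = TRUE))
  })
  df <- do.call(rbind, rows)
  if (is.null(chains)) {
    df$chain_a <- "A"; df$chain_b <- "A"
  } else {
    df$chain_a <- chain_from_ranges(df$res_a, chains)
    df$chain_b <- chain_from_ranges(df$res_b, chains)
  }
  restraint_set(df[, c("chain_a", "res_a", "atom_a",
                       "chain_b", "res_b", "atom_b", "upper", "hbond")])
}

#' Read distance restraints from an NMR-STAR file
#'
#' Minimal reader for `_Gen_dist_constraint` loops: extracts the two
#' partners (entity assembly id as chain, component index as residue, atom
#' id) and the upper bound from each loop row.
#'
#' @param path NMR-STAR (v3) text file.
#' @return a [restraint_set()].
#' @export
read_star_restraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  loops <- grep("^\\s*loop_\\s*$", lines)
  out <- list()
  for (l0 in loops) {
    i <- l0 + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_Gen_dist_constraint\\.", tags))) next
    col <- function(tag) match(paste0("_Gen_dist_constraint.", tag), tags)
    needed <- c("Entity_assembly_ID_1", "Comp_index_ID_1", "Atom_ID_1",
                "Entity_assembly_ID_2", "Comp_index_ID_2", "Atom_ID_2",
                "Distance_upper_bound_val")
    ix <- vapply(needed, col, integer(1))
    if (anyNA(ix))
      stop("NMR-STAR distance-constraint loop lacks required tags")
    while (i <= length(lines) && !grepl("^\\s*stop_", lines[i])) {
      ln <- trimws(lines[i]); i <- i + 1L
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < max(ix)) next
      out[[length(out) + 1L]] <- data.frame(
        chain_a = f[ix[1]], res_a = as.integer(f[ix[2]]), atom_a = f[ix[3]],
        chain_b = f[ix[4]], res_b = as.integer(f[ix[5]]), atom_b = f[ix[6]],
        upper = as.numeric(f[ix[7]]), hbond = FALSE)
    }
  }
  if (length(out) == 0L)
    stop("no _Gen_dist_constraint loop found in ", path)
  restraint_set(do.call(rbind, out))
}

#' Classify distance restraints by residue separation
#'
#' Same-chain restraints are binned by the residue separation |i - j|:
#' intraresidual (0), sequential (1), medium range (1 < |i - j| < 5) and
#' long range (|i - j| >= 5); restraints between chains are intermolecular.
#' Hydrogen-bond-flagged restraints are reported as their own category and,
#' for reference, also folded into the |i - j| bins in the `with_hbonds`
#' attribute.
#'
#' @param rset a [restraint_set()].
#' @return named integer vector of class `restraint_counts` with elements
#'   `intraresidual`, `sequential`, `medium`, `long`, `hydrogen_bond`,
#'   `intermolecular` and `total`; categories partition the input.
#' @export
classify_restraints <- function(rset) {
  stopifnot(inherits(rset, "restraint_set"))
  cats <- c("intraresidual", "sequential", "medium", "long",
            "hydrogen_bond", "intermolecular")
  classify_one <- function(chain_a, res_a, chain_b, res_b, hbond) {
    if (chain_a != chain_b) return("intermolecular")
    if (isTRUE(hbond)) return("hydrogen_bond")
    d <- abs(res_a - res_b)
    if (d == 0) "intraresidual"
    else if (d == 1) "sequential"
    else if (d < 5) "medium"
    else "long"
  }
  if (nrow(rset) == 0L) {
    counts <- stats::setNames(integer(length(cats)), cats)
  } else {
    lab <- mapply(classify_one, rset$chain_a, rset$res_a,
                  rset$chain_b, rset$res_b, rset$hbond)
    counts <- table(factor(lab, levels = cats))
    counts <- stats::setNames(as.integer(counts), cats)
  }
  out <- c(counts, total = sum(counts))
  class(out) <- "restraint_counts"
  attr(out, "per_chain") <- if (nrow(rset))
    table(paste(rset$chain_a, rset$chain_b, sep = "-")) else NULL
  out
}

#' @export
print.restraint_counts <- function(x, ...) {
  cat("Distance restraints:", x[["total"]], "\n")
  lab <- c(intraresidual = "intraresidual",
           sequential = "sequential (|i-j| = 1)",
           medium = "medium range (1 < |i-j| < 5)",
           long = "long range (|i-j| >= 5)",
           hydrogen_bond = "hydrogen bonds",
           intermolecular = "intermolecular")
  for (k in names(lab))
    cat(sprintf("  %-30s %d\n", lab[[k]], x[[k]]))
  invisible(x)
}
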