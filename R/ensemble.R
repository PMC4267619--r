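# Residue-name sets used to decide polymer type and atom classes
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.nt <- c("A","C","G","U","M6A")
# N6-methyladenosine appears under several component codes in deposited files
.m6a_codes <- c("6MZ", "6MA", "M6A", "MA6")
.protein_backbone <- c("N", "CA", "C")
.rna_backbone <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Construct a coordinate ensemble
#'
#' A multi-model structure: an atom table shared by all models and one
#' coordinate row per model (bio3d xyz convention, 3 columns per atom).
#' N6-methyladenosine residues are normalised to the internal code `M6A`.
#'
#' @param xyz numeric matrix `n_models x (3 * n_atoms)`.
#' @param atoms data frame with columns `chain`, `resno`, `resname`,
#'   `name` (atom name) and optionally `element` (derived from the atom
#'   name when absent).
#' @return object of class `ensemble`.
#' @export
ensemble <- function(xyz, atoms) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one model")
  need <- c("chain", "resno", "resname", "name")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns chain, resno, resname, name")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate columns (", ncol(xyz), ") do not match atom count (",
         nrow(atoms), "): atom inventory inconsistent")
  atoms$resname <- ifelse(atoms$resname %in% .m6a_codes, "M6A", atoms$resname)
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$name)
  structure(list(xyz = xyz, atoms = atoms), class = "ensemble")
}

guess_element <- function(name) {
  e <- sub("^[0-9']*", "", toupper(name))
  substr(e, 1, 1)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Coordinate ensemble:", nrow(x$xyz), "models,", nrow(x$atoms),
      "atoms, chains:",
      paste(unique(x$atoms$chain), collapse = ", "), "\n")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens an [ensemble()].
#' @export
n_models <- function(ens) nrow(ens$xyz)

#' Coordinates of one model as an n_atoms x 3 matrix
#' @param ens an [ensemble()].
#' @param model model index.
#' @export
model_coords <- function(ens, model = 1L) {
  matrix(ens$xyz[model, ], ncol = 3L, byrow = TRUE)
}

#' Read a multi-model PDB file into an ensemble
#'
#' Loads all MODEL records of a PDB file (e.g. an NMR bundle) via bio3d and
#' validates that every model carries the same atom inventory. Residues
#' with unrecognised names are reported; known N6-methyladenosine component
#' codes are mapped to `M6A`.
#'
#' @param path PDB file.
#' @param resname_map optional named character vector mapping additional
#'   residue codes to internal names.
#' @return an [ensemble()].
#' @export
read_ensemble <- function(path, resname_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nmodel <- sum(grepl("^MODEL", lines))
  counts <- count_atoms_per_model(lines)
  if (length(unique(counts)) > 1L)
    stop("models differ in atom count (",
         paste(unique(counts), collapse = ", "),
         "): atom inventory must be identical across models")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom[, c("chain", "resno", "resid", "elety")]
  names(atoms) <- c("chain", "resno", "resname", "name")
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (!is.null(resname_map)) {
    hit <- atoms$resname %in% names(resname_map)
    atoms$resname[hit] <- resname_map[atoms$resname[hit]]
  }
  unknown <- setdiff(unique(atoms$resname), c(.aa3, .nt, .m6a_codes))
  if (length(unknown))
    message("read_ensemble: unrecognised residue code(s): ",
            paste(unknown, collapse = ", "))
  ensemble(pdb$xyz, atoms)
}

count_atoms_per_model <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L)
    return(sum(grepl("^(ATOM|HETATM)", lines)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) sum(grepl("^(ATOM|HETATM)", lines[s:e])),
         starts, ends[seq_along(starts)])
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens an [ensemble()].
#' @param path output file.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  at <- ens$atoms
  rec <- ifelse(at$resname %in% .aa3 | at$resname %in% c("A","C","G","U"),
                "ATOM  ", "HETATM")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL %8d", m), con)
    co <- model_coords(ens, m)
    nm <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 substr(at$name, 1, 4))
    writeLines(sprintf("%s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, seq_len(nrow(at)), nm,
                       substr(at$resname, 1, 4), at$chain, at$resno,
                       co[, 1], co[, 2], co[, 3], 1, 0,
                       guess_element(at$name)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selection for ensemble statistics
#'
#' @param chain chain id(s) to keep, or NULL for all.
#' @param resno length-2 residue interval, or NULL for all.
#' @param atom_class `"backbone"` (N, CA, C for protein; P, O5', C5', C4',
#'   C3', O3' for RNA), `"heavy"` (everything but hydrogen) or `"all"`.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, resno = NULL,
                           atom_class = c("backbone", "heavy", "all")) {
  structure(list(chain = chain, resno = resno,
                 atom_class = match.arg(atom_class)),
            class = "atom_selection")
}

#' Resolve an atom selection against an ensemble
#' @param ens an [ensemble()].
#' @param sel an [atom_selection()].
#' @return integer atom indices.
#' @export
resolve_selection <- function(ens, sel) {
  at <- ens$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$resno))
    keep <- keep & at$resno >= sel$resno[1] & at$resno <= sel$resno[2]
  if (sel$atom_class == "heavy") {
    keep <- keep & at$element != "H"
  } else if (sel$atom_class == "backbone") {
    is_prot <- at$resname %in% .aa3
    keep <- keep & ((is_prot & at$name %in% .protein_backbone) |
                    (!is_prot & at$name %in% .rna_backbone))
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("atom selection is empty")
  idx
}

# Optimal least-squares rotation (Kabsch, via SVD) mapping `mobile` onto
# `target` after centering; returns transformed full-atom coordinates.
kabsch_fit <- function(mobile_sel, target_sel, mobile_all) {
  cm <- colMeans(mobile_sel)
  ct <- colMeans(target_sel)
  A <- sweep(mobile_sel, 2, cm)
  B <- sweep(target_sel, 2, ct)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(sweep(mobile_all, 2, cm) %*% R, 2, ct, "+")
}

#' Superpose an ensemble onto its iteratively refined mean
#'
#' Least-squares superposition of every model onto the mean structure of the
#' selected atoms, iterated (fit, recompute mean, refit) until the mean
#' moves by less than `tol`. The rotation is computed on the selection and
#' applied to all atoms.
#'
#' @param ens an [ensemble()].
#' @param sel an [atom_selection()]; typically the structured region.
#' @param tol convergence threshold on the RMS mean shift (angstrom).
#' @param max_iter iteration cap.
#' @return the superposed [ensemble()], with attributes `mean_xyz` (the
#'   converged mean coordinates of all atoms, n_atoms x 3) and
#'   `iterations`.
#' @export
superpose <- function(ens, sel = atom_selection(), tol = 1e-6,
                      max_iter = 100L) {
  stopifnot(inherits(ens, "ensemble"))
  idx <- resolve_selection(ens, sel)
  if (length(idx) < 3L) stop("selection must resolve at least 3 atoms")
  coords <- lapply(seq_len(n_models(ens)), function(m) model_coords(ens, m))
  # collinear selections have no unique rotation
  sp <- svd(sweep(coords[[1]][idx, , drop = FALSE], 2,
                  colMeans(coords[[1]][idx, , drop = FALSE])))$d
  if (length(idx) >= 3L && sp[2] < 1e-8)
    stop("degenerate (collinear) selection")
  mean_sel <- coords[[1]][idx, , drop = FALSE]
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    coords <- lapply(coords, function(co)
      kabsch_fit(co[idx, , drop = FALSE], mean_sel, co))
    new_mean <- Reduce(`+`, lapply(coords, function(co)
      co[idx, , drop = FALSE])) / length(coords)
    shift <- sqrt(mean(rowSums((new_mean - mean_sel)^2)))
    mean_sel <- new_mean
    if (shift < tol || iterations >= max_iter) break
  }
  xyz <- do.call(rbind, lapply(coords, function(co) as.vector(t(co))))
  out <- ensemble(xyz, ens$atoms)
  attr(out, "mean_xyz") <- Reduce(`+`, coords) / length(coords)
  attr(out, "iterations") <- iterations
  out
}

#' RMSD of each model to the ensemble mean
#'
#' Per-model root-mean-square deviation from the mean structure over the
#' selected atoms. The ensemble should first be superposed (on the
#' structured region) with [superpose()]; the mean is recomputed from the
#' current coordinates.
#'
#' @param ens an [ensemble()], normally the output of [superpose()].
#' @param sel an [atom_selection()] naming the atoms to measure.
#' @return list of class `rmsd_stats`: `per_model` (angstrom), `mean`, `sd`.
#' @export
rmsd_to_mean <- function(ens, sel = atom_selection()) {
  stopifnot(inherits(ens, "ensemble"))
  idx <- resolve_selection(ens, sel)
  coords <- lapply(seq_len(n_models(ens)), function(m)
    model_coords(ens, m)[idx, , drop = FALSE])
  mean_xyz <- Reduce(`+`, coords) / length(coords)
  per_model <- vapply(coords, function(co)
    sqrt(mean(rowSums((co - mean_xyz)^2))), numeric(1))
  structure(list(per_model = per_model, mean = mean(per_model),
                 sd = stats::sd(per_model)),
            class = "rmsd_stats")
}

#' @export
print.rmsd_stats <- function(x, ...) {
  cat(sprintf("RMSD to mean: %.3f +/- %.3f A over %d models\n",
              x$mean, ifelse(is.na(x$sd), 0, x$sd), length(x$per_model)))
  invisible(x)
}
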