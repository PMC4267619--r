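#' Detect hydrogen bonds and hydrophobic contacts in one model
#'
#' Geometric contact detection on a single ensemble model. Hydrogen bonds
#' are reported for donor (N/O with a covalently attached hydrogen) /
#' acceptor (N/O) pairs with donor-acceptor distance at most `d_max` and
#' donor-H-acceptor angle at least `angle_min`. When the model carries no
#' hydrogens a distance-only fallback (`fallback_distance_only = TRUE`)
#' reports donor-acceptor pairs by distance alone with NA angles; with the
#' fallback disabled, missing hydrogens are an error. Hydrophobic contacts
#' are carbon-carbon pairs within `c_max`.
#'
#' @param ens an [ensemble()].
#' @param model model index to analyse.
#' @param d_max hydrogen-bond donor-acceptor distance cutoff (angstrom).
#' @param angle_min donor-H-acceptor angle cutoff (degrees).
#' @param c_max carbon-carbon distance cutoff for hydrophobic contacts.
#' @param interchain_only restrict the report to pairs spanning two chains.
#' @param fallback_distance_only allow hydrogen-free models.
#' @return object of class `contact_report`: data frames `hbonds`
#'   (donor/acceptor chain, residue, resname, atom, distance, angle) and
#'   `hydrophobic` (atom pair and distance).
#' @export
find_contacts <- function(ens, model = 1L, d_max = 3.5, angle_min = 120,
                          c_max = 4.5, interchain_only = TRUE,
                          fallback_distance_only = FALSE) {
  stopifnot(inherits(ens, "ensemble"))
  at <- ens$atoms
  co <- model_coords(ens, model)
  has_h <- any(at$element == "H")
  if (!has_h && !fallback_distance_only)
    stop("model has no hydrogens; enable fallback_distance_only to detect ",
         "hydrogen bonds from donor-acceptor distances alone")
  polar <- which(at$element %in% c("N", "O"))
  # hydrogens covalently attached to each polar atom (same residue, <1.3 A)
  attached_h <- function(i) {
    same <- which(at$element == "H" & at$chain == at$chain[i] &
                  at$resno == at$resno[i])
    if (!length(same)) return(integer())
    d <- sqrt(rowSums((co[same, , drop = FALSE] -
                       matrix(co[i, ], length(same), 3, byrow = TRUE))^2))
    same[d < 1.3]
  }
  hb <- list()
  for (i in polar) {
    hs <- if (has_h) attached_h(i) else integer()
    is_donor <- if (has_h) length(hs) > 0L else TRUE
    if (!is_donor) next
    for (j in polar) {
      if (j == i) next
      if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
      if (interchain_only && at$chain[i] == at$chain[j]) next
      dda <- sqrt(sum((co[i, ] - co[j, ])^2))
      if (dda > d_max) next
      ang <- NA_real_
      if (has_h) {
        angs <- vapply(hs, function(h) {
          v1 <- co[i, ] - co[h, ]; v2 <- co[j, ] - co[h, ]
          acos(min(max(sum(v1 * v2) /
            sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < angle_min) next
      }
      hb[[length(hb) + 1L]] <- data.frame(
        donor_chain = at$chain[i], donor_resno = at$resno[i],
        donor_resname = at$resname[i], donor_atom = at$name[i],
        acceptor_chain = at$chain[j], acceptor_resno = at$resno[j],
        acceptor_resname = at$resname[j], acceptor_atom = at$name[j],
        distance = dda, angle = ang)
    }
  }
  hbonds <- if (length(hb)) do.call(rbind, hb) else
    data.frame(donor_chain = character(), donor_resno = integer(),
               donor_resname = character(), donor_atom = character(),
               acceptor_chain = character(), acceptor_resno = integer(),
               acceptor_resname = character(), acceptor_atom = character(),
               distance = numeric(), angle = numeric())
  carbons <- which(at$element == "C")
  hp <- list()
  if (length(carbons) > 1L) {
    cc <- co[carbons, , drop = FALSE]
    dm <- as.matrix(stats::dist(cc))
    pair <- which(upper.tri(dm) & dm <= c_max, arr.ind = TRUE)
    for (k in seq_len(nrow(pair))) {
      i <- carbons[pair[k, 1]]; j <- carbons[pair[k, 2]]
      if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
      if (interchain_only && at$chain[i] == at$chain[j]) next
      hp[[length(hp) + 1L]] <- data.frame(
        chain_a = at$chain[i], resno_a = at$resno[i],
        resname_a = at$resname[i], atom_a = at$name[i],
        chain_b = at$chain[j], resno_b = at$resno[j],
        resname_b = at$resname[j], atom_b = at$name[j],
        distance = dm[pair[k, 1], pair[k, 2]])
    }
  }
  hydrophobic <- if (length(hp)) do.call(rbind, hp) else
    data.frame(chain_a = character(), resno_a = integer(),
               resname_a = character(), atom_a = character(),
               chain_b = character(), resno_b = integer(),
               resname_b = character(), atom_b = character(),
               distance = numeric())
  structure(list(hbonds = hbonds, hydrophobic = hydrophobic,
                 criteria = list(d_max = d_max, angle_min = angle_min,
                                 c_max = c_max)),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat("Contact report:", nrow(x$hbonds), "hydrogen bond(s),",
      nrow(x$hydrophobic), "hydrophobic contact(s)\n")
  if (nrow(x$hbonds)) {
    cat("Hydrogen bonds:\n")
    with(x$hbonds, cat(sprintf(
      "  %s%d %s %s -> %s%d %s %s  %.2f A%s\n",
      donor_chain, donor_resno, donor_resname, donor_atom,
      acceptor_chain, acceptor_resno, acceptor_resname, acceptor_atom,
      distance,
      ifelse(is.na(angle), "", sprintf("  %.0f deg", angle))), sep = ""))
  }
  invisible(x)
}
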