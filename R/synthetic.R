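# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Fraction of protein bound at equilibrium
#'
#' Exact two-state mass balance for P + L <-> PL:
#' \deqn{f_b = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4 P L}}{2 P}.}
#' Monotone increasing in ligand, decreasing in Kd, and confined to [0, 1].
#'
#' @param P total protein concentration (molar), > 0.
#' @param L total ligand concentration (molar), >= 0; vectorised.
#' @param Kd dissociation constant (molar), > 0.
#' @return fraction of protein in the complex, in [0, 1].
#' @export
fraction_bound <- function(P, L, Kd) {
  if (any(P <= 0) || any(L < 0) || any(Kd <= 0))
    stop("fraction_bound: P > 0, L >= 0, Kd > 0 required")
  s <- P + L + Kd
  fb <- (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * P)
  pmin(pmax(fb, 0), 1)
}

#' Synthetic titration model
#'
#' Draws a random protein construct for titration simulations: free-state
#' amide shifts uniform over realistic ranges (1H 7-10 ppm, 15N 105-130
#' ppm) and, for a subset of responder residues, bound-state shifts offset
#' by up to `max_dH`/`max_dN`.
#'
#' @param n_res number of residues.
#' @param kd dissociation constant (molar).
#' @param responder_frac fraction of residues that shift on binding.
#' @param max_dH,max_dN maximum binding-induced shift change (ppm).
#' @param first_residue index of the first residue.
#' @param seed RNG seed.
#' @return list of class `titration_model`: `free`, `bound` (data frames of
#'   residue/H/N), `kd`, `responders`.
#' @export
synthetic_titration_model <- function(n_res = 30L, kd = 1e-6,
                                      responder_frac = 0.5,
                                      max_dH = 0.2, max_dN = 1.2,
                                      first_residue = 347L, seed = NULL) {
  with_seed(seed, {
    residue <- seq(first_residue, length.out = n_res)
    free <- data.frame(residue = residue,
                       H = stats::runif(n_res, 7, 10),
                       N = stats::runif(n_res, 105, 130))
    responders <- sort(sample(residue, round(responder_frac * n_res)))
    on <- free$residue %in% responders
    dH <- ifelse(on, stats::runif(n_res, 0.3, 1) * max_dH *
                   sample(c(-1, 1), n_res, replace = TRUE), 0)
    dN <- ifelse(on, stats::runif(n_res, 0.3, 1) * max_dN *
                   sample(c(-1, 1), n_res, replace = TRUE), 0)
    bound <- data.frame(residue = residue, H = free$H + dH, N = free$N + dN)
    structure(list(free = free, bound = bound, kd = kd,
                   responders = responders),
              class = "titration_model")
  })
}

#' Simulate a two-state titration series
#'
#' Generates peak lists along a ligand titration under one of three
#' exchange regimes:
#' \describe{
#'   \item{fast}{one population-averaged peak per residue that moves from
#'     the free towards the bound position with the bound fraction.}
#'   \item{slow}{separate free- and bound-position peaks whose intensities
#'     trade as 1 - f_b and f_b; peaks below `intensity_cutoff` vanish
#'     from the list.}
#'   \item{intermediate}{as fast, but the residues named in
#'     `intermediate_residues` are broadened beyond detection (dropped)
#'     whenever f_b lies in `broaden_window`, so downstream tracking marks
#'     them untracked.}
#' }
#'
#' @param model a [synthetic_titration_model()].
#' @param regime exchange regime.
#' @param protein_conc protein concentration (molar).
#' @param ratios ligand:protein ratios of the titration points (first must
#'   be 0).
#' @param noise_sd named `c(H =, N =)` Gaussian shift noise (ppm).
#' @param intermediate_residues residues that broaden out (intermediate
#'   regime); defaults to the model's responders.
#' @param broaden_window f_b window in which those residues vanish.
#' @param intensity_cutoff minimum relative intensity of a visible peak
#'   (slow regime).
#' @param prolines,construct_range passed through to [titration_series()];
#'   the range defaults to the model's residue span.
#' @param seed RNG seed.
#' @return a [titration_series()].
#' @export
simulate_titration <- function(model,
                               regime = c("fast", "slow", "intermediate"),
                               protein_conc = 2e-4,
                               ratios = seq(0, 1.25, length.out = 11),
                               noise_sd = c(H = 0.002, N = 0.02),
                               intermediate_residues = NULL,
                               broaden_window = c(0.25, 0.75),
                               intensity_cutoff = 0.15,
                               prolines = integer(),
                               construct_range = NULL,
                               seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(inherits(model, "titration_model"), ratios[1] == 0)
  if (is.null(construct_range))
    construct_range <- range(model$free$residue)
  if (is.null(intermediate_residues))
    intermediate_residues <- model$responders
  with_seed(seed, {
    points <- lapply(ratios, function(r) {
      L <- r * protein_conc
      fb <- fraction_bound(protein_conc, L, model$kd)
      nr <- nrow(model$free)
      noisy <- function(H, N) data.frame(
        H = H + stats::rnorm(length(H), 0, noise_sd[["H"]]),
        N = N + stats::rnorm(length(N), 0, noise_sd[["N"]]))
      if (regime == "slow") {
        fr <- noisy(model$free$H, model$free$N)
        bo <- noisy(model$bound$H, model$bound$N)
        pk <- rbind(
          data.frame(residue = model$free$residue, shift_H = fr$H,
                     shift_N = fr$N, intensity = 1 - fb),
          data.frame(residue = NA_integer_, shift_H = bo$H,
                     shift_N = bo$N, intensity = fb))
        pk <- pk[pk$intensity >= intensity_cutoff, , drop = FALSE]
      } else {
        obs <- noisy(model$free$H + fb * (model$bound$H - model$free$H),
                     model$free$N + fb * (model$bound$N - model$free$N))
        pk <- data.frame(residue = model$free$residue, shift_H = obs$H,
                         shift_N = obs$N, intensity = 1)
        if (regime == "intermediate" &&
            fb >= broaden_window[1] && fb <= broaden_window[2])
          pk <- pk[!(pk$residue %in% intermediate_residues), , drop = FALSE]
      }
      list(ligand_conc = L, peaks = pk)
    })
    titration_series(protein_conc, points, construct_range, prolines)
  })
}

#' Simulate scaffold-independent-analysis panels
#'
#' Builds one substitution panel per assayed position from a planted
#' preference profile. Every variant oligo produces a CSP profile whose
#' per-residue magnitudes are a common response pattern scaled by the
#' variant's preference multiplier, with multiplicative Gaussian noise.
#' Panels are chained per the fixing rule: the nucleotide with the largest
#' multiplier at each assayed position is written into the scaffold before
#' the next panel is generated (kept only if its multiplier is strictly
#' largest; ties leave the scaffold base unchanged and plant no winner).
#'
#' @param profile named list mapping positions (`"1"`..`"6"`) to named
#'   multiplier vectors over `A`, `C`, `G`, `U`; positions not listed are
#'   uniform. Multipliers must be positive.
#' @param order assay order (positions actually titrated).
#' @param scaffold starting hexamer; defaults to a neutral poly-U scaffold.
#' @param base_csp per-residue response pattern (ppm) shared by all
#'   variants; default draws `n_res` values with half the residues
#'   responding at 0.05-0.4 ppm.
#' @param noise_frac multiplicative noise (sd as a fraction of the value).
#' @param n_res residues per synthetic construct.
#' @param first_residue index of the first residue.
#' @param cap_value cap carried by the generated profiles.
#' @param seed RNG seed.
#' @return list with `panels` (list of [oligo_panel()] in assay order) and
#'   `planted` (the consensus implied by the multipliers).
#' @export
simulate_sia_panels <- function(profile, order = c(4L, 3L, 2L, 6L, 1L),
                                scaffold = "UUUUUU", base_csp = NULL,
                                noise_frac = 0, n_res = 30L,
                                first_residue = 347L, cap_value = 0.3,
                                seed = NULL) {
  nts <- c("A", "C", "G", "U")
  mult_at <- function(pos) {
    m <- profile[[as.character(pos)]]
    if (is.null(m)) stats::setNames(rep(1, 4), nts) else {
      stopifnot(setequal(names(m), nts), all(m > 0))
      m[nts]
    }
  }
  with_seed(seed, {
    if (is.null(base_csp)) {
      on <- stats::runif(n_res) < 0.5
      base_csp <- ifelse(on, stats::runif(n_res, 0.05, 0.4), 0)
      if (!any(on)) base_csp[1] <- 0.2  # guarantee signal
    }
    residue <- seq(first_residue, length.out = length(base_csp))
    sc <- strsplit(toupper(scaffold), "")[[1]]
    planted <- rep("N", 6L)
    panels <- vector("list", length(order))
    for (k in seq_along(order)) {
      pos <- order[k]
      m <- mult_at(pos)
      variants <- lapply(stats::setNames(nts, nts), function(nt) {
        v <- base_csp * m[[nt]]
        if (noise_frac > 0)
          v <- pmax(v * (1 + stats::rnorm(length(v), 0, noise_frac)), 0)
        new_csp_profile(residue, rep("measured", length(v)), v, cap_value)
      })
      panels[[k]] <- oligo_panel(pos, paste(sc, collapse = ""), variants)
      top <- which(m == max(m))
      if (length(top) == 1L) {
        planted[pos] <- nts[top]
        sc[pos] <- nts[top]
      }
    }
    list(panels = panels, planted = paste(planted, collapse = ""))
  })
}

#' Simulate a noisy ITC experiment
#'
#' Forward-models per-injection heats with [one_site_heats()] and adds
#' i.i.d. Gaussian noise.
#'
#' @param kd dissociation constant (molar).
#' @param dH binding enthalpy (kcal/mol); negative for an exothermic
#'   reaction.
#' @param n_sites stoichiometry.
#' @param schedule an [injection_schedule()].
#' @param noise_sd Gaussian noise per injection (microcalories).
#' @param seed RNG seed.
#' @return an [itc_experiment()].
#' @export
simulate_itc <- function(kd, dH, n_sites = 1, schedule, noise_sd = 0,
                         seed = NULL) {
  stopifnot(kd > 0, noise_sd >= 0)
  h <- one_site_heats(1 / kd, dH, n_sites, schedule)
  with_seed(seed, itc_experiment(
    schedule, h + stats::rnorm(length(h), 0, noise_sd)))
}

#' Synthetic base structure for ensemble statistics
#'
#' Builds a single-model ensemble of an idealised alpha-helical backbone
#' (N, CA, C, O per residue, chain A): a geometrically plausible scaffold
#' for superposition and RMSD benchmarks.
#'
#' @param n_res number of residues.
#' @param first_residue index of the first residue.
#' @return an [ensemble()] with one model.
#' @export
synthetic_ensemble_base <- function(n_res = 30L, first_residue = 1L) {
  # ideal alpha helix: rise 1.5 A, 100 deg per residue, CA radius 2.3 A
  t <- (seq_len(n_res) - 1) * 100 * pi / 180
  z <- (seq_len(n_res) - 1) * 1.5
  ca <- cbind(2.3 * cos(t), 2.3 * sin(t), z)
  offs <- list(N = c(-0.8, -0.9, -0.5), CA = c(0, 0, 0),
               C = c(1.0, 0.6, 0.6), O = c(1.2, 1.7, 0.8))
  rows <- list(); coords <- list()
  for (i in seq_len(n_res)) {
    for (a in names(offs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = first_residue + i - 1L, resname = "ALA",
        name = a)
      coords[[length(coords) + 1L]] <- ca[i, ] + offs[[a]]
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- matrix(unlist(coords), nrow = 1)
  ensemble(xyz, atoms)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Perturb a base structure into a scattered ensemble
#'
#' Replicates the (first model of the) base structure `n_models` times with
#' isotropic Gaussian displacement of sd `sigma` per coordinate, optionally
#' followed by a random rigid-body rotation and translation of each model.
#'
#' @param base an [ensemble()] (its first model is used).
#' @param sigma per-coordinate displacement sd (angstrom), >= 0.
#' @param n_models number of models, >= 2.
#' @param rigid apply a random rigid-body motion per model.
#' @param seed RNG seed.
#' @return an [ensemble()] with `n_models` models.
#' @export
perturb_ensemble <- function(base, sigma, n_models = 20L, rigid = FALSE,
                             seed = NULL) {
  stopifnot(inherits(base, "ensemble"), sigma >= 0, n_models >= 2)
  co <- model_coords(base, 1L)
  with_seed(seed, {
    xyz <- do.call(rbind, lapply(seq_len(n_models), function(m) {
      p <- co + matrix(stats::rnorm(length(co), 0, sigma), ncol = 3)
      if (rigid) {
        R <- random_rotation()
        p <- sweep(p %*% R, 2, stats::runif(3, -5, 5), "+")
      }
      as.vector(t(p))
    }))
    ensemble(xyz, base$atoms)
  })
}
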