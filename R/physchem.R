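#' Net charge of a peptide at neutral pH
#'
#' Counts basic minus acidic residues: `count(K) + count(R) - count(D) -
#' count(E)`. Histidine contributes 0, matching the helical-wheel convention
#' used for cationicity screening.
#'
#' @param seq Amino-acid string (standard residues).
#' @return Integer net charge in elementary charges.
#' @examples
#' net_charge("SRRRFDFSRRRIYVARRRSLAFAHRRR")  # +11
#' @export
net_charge <- function(seq) {
  check_seq(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  as.integer(sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E")))
}

#' Mean hydrophobicity of a sequence
#'
#' Arithmetic mean of per-residue scale values. With the default
#' Fauchere-Pliska scale this reproduces HeliQuest's whole-sequence
#' hydrophobicity to 3 decimals.
#'
#' @param seq Amino-acid string.
#' @param scale An [aa_scale()]; residues absent from the scale are an error.
#' @return Unitless mean hydrophobicity.
#' @export
mean_hydrophobicity <- function(seq, scale = aa_scale("fauchere_pliska")) {
  check_seq(seq)
  mean(scale_values(seq, scale))
}

#' Eisenberg hydrophobic moment per residue
#'
#' The amphipathicity measure
#' \deqn{\mu_H = \frac{1}{N}\sqrt{\left(\sum_i H_i \sin(i\delta)\right)^2 +
#'   \left(\sum_i H_i \cos(i\delta)\right)^2}}
#' with residue `i = 0..N-1` placed at angle `i*delta_deg` around the helical
#' wheel. The default `delta_deg = 100` is the ideal alpha-helix twist;
#' the result is invariant to a global phase offset.
#'
#' @inheritParams mean_hydrophobicity
#' @param delta_deg Twist angle per residue, degrees.
#' @return Non-negative unitless moment per residue.
#' @export
hydrophobic_moment <- function(seq, scale = aa_scale("fauchere_pliska"),
                               delta_deg = 100) {
  check_seq(seq)
  h <- scale_values(seq, scale)
  ang <- (seq_along(h) - 1L) * delta_deg * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(h)
}

#' Residue-composition statistics used by the amphipathicity screen
#'
#' Counts polar residues (configurable set), uncharged polar residues
#' (S, T, N, Q, H), glycines, charged residues (D, E, K, R) and cysteines.
#'
#' @inheritParams mean_hydrophobicity
#' @param polar_set Character vector defining "polar" for `n_polar`.
#'   The default is D, E, K, R, H, N, Q, S, T, Y.
#' @return Named integer vector with elements `n_polar`,
#'   `n_uncharged_STNQH`, `n_gly`, `n_charged`, `n_cys`.
#' @export
composition_stats <- function(seq, polar_set = default_polar_set()) {
  check_seq(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(n_polar = sum(chars %in% polar_set),
    n_uncharged_STNQH = sum(chars %in% c("S", "T", "N", "Q", "H")),
    n_gly = sum(chars == "G"),
    n_charged = sum(chars %in% c("D", "E", "K", "R")),
    n_cys = sum(chars == "C"))
}

#' Default polar-residue set
#'
#' The screen's composition rule requires a minimum number of polar residues;
#' this set (charged + amide + hydroxyl + H + Y) is the package default and a
#' configuration knob.
#' @return Character vector of residue letters.
#' @export
default_polar_set <- function() {
  c("D", "E", "K", "R", "H", "N", "Q", "S", "T", "Y")
}

#' Full physicochemical profile of a sequence
#'
#' Single pass computing mean hydrophobicity, hydrophobic moment, net charge
#' and composition counts; equal to composing the individual operations.
#'
#' @inheritParams hydrophobic_moment
#' @inheritParams composition_stats
#' @return A list of class `"physchem_profile"` with fields `H`, `muH`, `z`,
#'   the five composition counts, and `length`.
#' @examples
#' physchem_profile("WWLSRRRSSLFYWR")
#' @export
physchem_profile <- function(seq, scale = aa_scale("fauchere_pliska"),
                             polar_set = default_polar_set(),
                             delta_deg = 100) {
  comp <- composition_stats(seq, polar_set)
  structure(
    c(list(H = mean_hydrophobicity(seq, scale),
           muH = hydrophobic_moment(seq, scale, delta_deg),
           z = net_charge(seq)),
      as.list(comp),
      list(length = nchar(seq))),
    class = "physchem_profile")
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat(sprintf("physchem profile (N=%d): H=%.3f  muH=%.3f  z=%+d\n",
              x$length, x$H, x$muH, x$z))
  cat(sprintf("  polar=%d uncharged(STNQH)=%d gly=%d charged=%d cys=%d\n",
              x$n_polar, x$n_uncharged_STNQH, x$n_gly, x$n_charged, x$n_cys))
  invisible(x)
}

#' @noRd
check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) ||
      nchar(seq) < 1L) {
    stop("seq must be a single non-empty string", call. = FALSE)
  }
  invisible(seq)
}
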