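#' Percent adsorption from an attachment assay
#'
#' Percentage of free phage lost to attachment over the assay:
#' 100 * (1 - pt / p0). A titer increase yields a negative percentage, which
#' is reported unchanged rather than clamped.
#'
#' @param p0 initial free-phage titer (PFU/mL), > 0.
#' @param pt free-phage titer at the end of the assay (PFU/mL).
#' @return percentage.
#' @export
percent_adsorption <- function(p0, pt) {
  if (p0 <= 0) stop("initial phage titer must be positive")
  100 * (1 - pt / p0)
}

#' Adsorption rate constant (single-hit exponential model)
#'
#' Free phage decay as P(t) = P0 * exp(-k * C * t) when attaching to cells at
#' density C; the per-cell rate constant is k = ln(p0/pt) / (C * t), with
#' units mL min^-1 per cell.
#'
#' @param p0 initial free-phage titer (PFU/mL), > 0.
#' @param pt final free-phage titer; 0 < pt <= p0.
#' @param cells cell density (cells/mL), > 0.
#' @param t assay duration in minutes, > 0.
#' @return rate constant k.
#' @export
adsorption_rate_constant <- function(p0, pt, cells, t) {
  if (p0 <= 0 || cells <= 0 || t <= 0) {
    stop("titers, cell density and time must be positive")
  }
  if (pt <= 0) stop("complete adsorption (pt = 0): rate constant unbounded")
  if (pt > p0) stop("pt > p0: exponential adsorption model does not apply")
  log(p0 / pt) / (cells * t)
}

#' Serial-transfer parameters
#'
#' Defaults mirror the experimental design: 1:100 dilution, 14 transfers,
#' and 4:1 (new:old) volumetric mixing of the external seed bank.
#'
#' @param dilution_factor dilution at each transfer (> 1; default 100).
#' @param n_transfers number of transfers (default 14).
#' @param seedbank_mix_new,seedbank_mix_old volumetric mixing weights of new
#'   and carried-over endospores (defaults 4 and 1).
#' @return a `transfer_scheme` list.
#' @export
transfer_scheme <- function(dilution_factor = 100, n_transfers = 14,
                            seedbank_mix_new = 4, seedbank_mix_old = 1) {
  stopifnot(dilution_factor > 1, n_transfers >= 0,
            seedbank_mix_new >= 0, seedbank_mix_old >= 0,
            seedbank_mix_new + seedbank_mix_old > 0)
  structure(list(dilution_factor = dilution_factor,
                 n_transfers = n_transfers,
                 seedbank_mix_new = seedbank_mix_new,
                 seedbank_mix_old = seedbank_mix_old),
            class = "transfer_scheme")
}

#' Cumulative host generations over a serial-transfer experiment
#'
#' Assuming regrowth to the pre-transfer density each cycle, every 1:D
#' dilution is regained by log2(D) doublings, so n transfers amount to
#' n * log2(D) generations (14 transfers at 1:100 give about 93).
#'
#' @param scheme a [transfer_scheme()].
#' @return number of doublings.
#' @export
cumulative_generations <- function(scheme = transfer_scheme()) {
  scheme$n_transfers * log2(scheme$dilution_factor)
}

#' Fraction of the external seed bank descending from a reference pool
#'
#' The external seed bank is refreshed each transfer by mixing new spores
#' with the previous bank at the scheme's volumetric ratio (default 4:1
#' new:old), so the legacy of the pre-infection pool decays geometrically:
#' (old / (new + old))^n = 0.2^n at defaults.
#'
#' @param scheme a [transfer_scheme()].
#' @param n transfers since the reference pool (>= 0; vectorised).
#' @return fraction(s) in [0, 1].
#' @export
seedbank_legacy_fraction <- function(scheme = transfer_scheme(), n) {
  stopifnot(all(n >= 0))
  old_frac <- scheme$seedbank_mix_old /
    (scheme$seedbank_mix_new + scheme$seedbank_mix_old)
  old_frac^n
}

#' Expected susceptibility curve under pure dilution
#'
#' Null expectation for the percentage of phage-susceptible clones in the
#' external seed bank if legacy spores are only lost to dilution (no
#' replication or death): the initial percentage scaled by the seed-bank
#' legacy fraction at each transfer. Observed excess over this curve
#' indicates ongoing sporulation by susceptible hosts.
#'
#' @param scheme a [transfer_scheme()].
#' @param initial_susceptible_pct percentage at the reference transfer
#'   (0-100).
#' @param horizon number of transfers to project.
#' @return numeric vector of percentages for transfers 1..horizon.
#' @export
expected_susceptible_curve <- function(scheme = transfer_scheme(),
                                       initial_susceptible_pct = 100,
                                       horizon = 4) {
  stopifnot(initial_susceptible_pct >= 0, initial_susceptible_pct <= 100)
  initial_susceptible_pct *
    seedbank_legacy_fraction(scheme, seq_len(horizon))
}
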