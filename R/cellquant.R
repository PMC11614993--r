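#' Volume of a sphere from its diameter
#'
#' Cells and nuclei are approximated as spheres when converting microscopy
#' diameters to volumes: `V = (pi/6) d^3`.
#'
#' @param diameter Diameter in micrometres; non-negative.
#' @return Volume in picolitres (1 pL = 1000 um^3).
#' @export
#' @examples
#' sphere_volume(17.0)  # ~2.57 pL, a typical HeLa cell
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) stop("'diameter' must be >= 0")
  (pi / 6) * diameter^3 / 1000
}

#' Nuclear fraction of the cellular volume
#'
#' For spherical cell and nucleus the volume fraction is the cubed diameter
#' ratio.
#'
#' @param nuclear_diameter,cell_diameter Diameters in micrometres, with
#'   `0 < nuclear_diameter <= cell_diameter`.
#' @return Percent of the cell volume that is nuclear.
#' @export
#' @examples
#' nuclear_volume_fraction(9.6, 17.0)  # 18.0%
nuclear_volume_fraction <- function(nuclear_diameter, cell_diameter) {
  if (nuclear_diameter <= 0 || nuclear_diameter > cell_diameter)
    stop("need 0 < nuclear_diameter <= cell_diameter")
  100 * (nuclear_diameter / cell_diameter)^3
}

#' Nuclear share of the total fluorescence signal
#'
#' Given a nucleus:cytoplasm concentration ratio and the nuclear volume
#' fraction `v`, the nucleus contributes
#' `c_n v / (c_n v + c_c (1 - v))` of the total signal.
#'
#' @param conc_nucleus,conc_cytoplasm Relative concentrations (any common
#'   unit), positive.
#' @param volume_fraction Nuclear volume fraction, in (0, 1).
#' @return Percent of total signal arising from the nucleus.
#' @export
#' @examples
#' nuclear_signal_fraction(65, 35, 0.18)  # ~29%
nuclear_signal_fraction <- function(conc_nucleus, conc_cytoplasm,
                                    volume_fraction) {
  stopifnot(conc_nucleus > 0, conc_cytoplasm > 0,
            volume_fraction > 0, volume_fraction < 1)
  v <- volume_fraction
  100 * conc_nucleus * v / (conc_nucleus * v + conc_cytoplasm * (1 - v))
}

#' Interstitial-medium fraction of a cell pellet
#'
#' Fraction of a pellet's volume that is medium rather than cells:
#' `(pellet - n_cells * per_cell) / pellet`.
#'
#' @param pellet_volume Pellet volume in mL.
#' @param cell_count Number of cells.
#' @param per_cell_volume Volume of one cell in pL.
#' @return Percent of the pellet volume that is interstitial medium.
#' @export
#' @examples
#' interstitial_fraction(0.47, 1e8, 2.5)  # ~46.8%
interstitial_fraction <- function(pellet_volume, cell_count, per_cell_volume) {
  cells_ml <- cell_count * per_cell_volume * 1e-9  # pL -> mL
  if (pellet_volume < cells_ml)
    stop("total cell volume exceeds the pellet volume")
  100 * (pellet_volume - cells_ml) / pellet_volume
}

#' Residual extracellular concentration after sequential washes
#'
#' Models washing of a pellet that retains a fixed interstitial carryover
#' volume: after each wash of volume `V` the carried-over concentration is
#' diluted by `carryover / (V + carryover)`, and the final supernatant
#' (carryover mixed into the resuspension volume) is diluted once more by
#' `carryover / (final_resuspension + carryover)`. The carryover is
#' `pellet_volume - cell_count * per_cell_volume` and is held constant
#' across washes (fixed pellet geometry). Multiplicative dilution is why
#' two washes of volume V always beat one wash of 2V.
#'
#' @param initial_conc Concentration before washing (uM).
#' @param pellet_volume Pellet volume (mL).
#' @param cell_count Number of cells in the pellet.
#' @param per_cell_volume Per-cell volume (pL).
#' @param wash_volumes Vector of wash volumes (mL); may be empty, in which
#'   case only the resuspension dilution applies.
#' @param final_resuspension Final resuspension volume (mL).
#' @return Concentration in the final surrounding medium (uM).
#' @export
#' @examples
#' # two 50 mL washes of a 0.47 mL pellet of 1e8 x 2.5 pL cells
#' washout_concentration(400, 0.47, 1e8, 2.5, c(50, 50), 0.6)  # ~0.002 uM
washout_concentration <- function(initial_conc, pellet_volume, cell_count,
                                  per_cell_volume, wash_volumes,
                                  final_resuspension) {
  stopifnot(initial_conc >= 0, pellet_volume > 0, final_resuspension > 0)
  carry <- pellet_volume - cell_count * per_cell_volume * 1e-9
  if (carry <= 0) stop("carryover volume must be positive")
  conc <- initial_conc
  for (V in wash_volumes) {
    if (V < 0) stop("wash volumes must be >= 0")
    conc <- conc * carry / (V + carry)
  }
  conc * carry / (final_resuspension + carry)
}

#' Fit a gel standard curve
#'
#' Ordinary least squares of background-subtracted fluorescence signal
#' against loaded quantity. Points whose raw signal exceeds a saturation
#' threshold (detector nonlinearity at the top of the dilution series) are
#' excluded before fitting; at least three usable points are required.
#'
#' @param quantity Loaded quantities (pmol), positive.
#' @param signal Fluorescence signals (arbitrary units).
#' @param background Autofluorescence background subtracted from every
#'   signal (e.g. from untransfected cells).
#' @param saturation_threshold Raw signals above this are excluded
#'   (default `Inf`: keep all).
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `excluded` (indices), and the `lm` fit.
#' @export
fit_standard_curve <- function(quantity, signal, background = 0,
                               saturation_threshold = Inf) {
  stopifnot(length(quantity) == length(signal))
  if (any(quantity <= 0)) stop("standard quantities must be positive")
  keep <- signal <= saturation_threshold
  if (sum(keep) < 3)
    stop("need at least 3 standard points below the saturation threshold")
  q <- quantity[keep]
  s <- signal[keep] - background
  m <- stats::lm(s ~ q)
  r2 <- 1 - sum(stats::residuals(m)^2) / sum((s - mean(s))^2)
  structure(list(slope = unname(stats::coef(m)[2]),
                 intercept = unname(stats::coef(m)[1]),
                 r_squared = r2,
                 excluded = which(!keep), model = m),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> signal = %.4g * pmol + %.4g (R^2 = %.3f, %d excluded)\n",
              x$slope, x$intercept, x$r_squared, length(x$excluded)))
  invisible(x)
}

#' Quantity of labelled material from a gel signal
#'
#' Inverts a [fit_standard_curve()]: `(signal - background - intercept) / slope`.
#'
#' @param curve A `standard_curve`.
#' @param signal Measured signal(s).
#' @param background Background to subtract (same convention as in the fit).
#' @return Quantity in pmol.
#' @export
quantity_from_signal <- function(curve, signal, background = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  (signal - background - curve$intercept) / curve$slope
}

#' Intracellular concentration from a labelled-fraction quantity
#'
#' Only a small share of the transfected duplex carries a fluorescent
#' label (1 labelled : `label_ratio` unlabelled, default 1:40, i.e. 2.5%
#' labelled). The total quantity is the labelled quantity times
#' `label_ratio` (the convention used when quoting the 1:40 mix; the
#' strict total, times `1 + label_ratio`, is available via
#' `strict_total = TRUE`), and the concentration follows by dividing by the
#' summed cell volume.
#'
#' @param labelled_quantity Labelled quantity from the gel (pmol).
#' @param cell_count Number of cells lysed, positive.
#' @param per_cell_volume Per-cell volume (pL).
#' @param label_ratio Unlabelled:labelled multiplier (default 40).
#' @param strict_total Multiply by `1 + label_ratio` instead of
#'   `label_ratio`.
#' @return Intracellular concentration in uM.
#' @export
#' @examples
#' intracellular_concentration(0.1, 1e6, 2.5)  # 1.6 uM
intracellular_concentration <- function(labelled_quantity, cell_count,
                                        per_cell_volume, label_ratio = 40,
                                        strict_total = FALSE) {
  stopifnot(labelled_quantity >= 0, per_cell_volume > 0, label_ratio > 0)
  if (cell_count <= 0) stop("'cell_count' must be positive")
  total <- labelled_quantity * (if (strict_total) 1 + label_ratio else label_ratio)
  # pmol / pL = mol/L; report uM
  total / (cell_count * per_cell_volume) * 1e6
}
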