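#' Breast-slice geometry and mass table of the torso phantom
#'
#' Dimensions and masses of the six breast slab attachments (three per
#' side; index 1 is chest-proximal, slabs are 2.5 cm thick). Ships as a
#' packaged CSV; per-side masses total 0.45 kg (left) and 0.55 kg (right).
#'
#' @return data.frame with columns side, index, mass_kg, length_cm,
#'   width_cm, height_cm.
#' @export
randoBreastSlices <- function() {
  path <- system.file("extdata", "rando_breast_slices.csv",
                      package = "filmdose", mustWork = TRUE)
  readBreastSlices(path)
}

#' Read a breast-slice table from CSV
#'
#' Expected header: \code{side,index,mass_kg,length_cm,width_cm,height_cm}.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readBreastSlices <- function(path) {
  if (!file.exists(path)) stop("slice table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side", "index", "mass_kg", "length_cm", "width_cm", "height_cm")
  if (!all(need %in% names(df)))
    stop("slice CSV must have columns: ", paste(need, collapse = ","))
  if (any(df$mass_kg <= 0)) stop("slice masses must be > 0")
  if (!all(df$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  for (sd in unique(df$side))
    if (anyDuplicated(df$index[df$side == sd]))
      stop("slice index must be unique per side")
  df
}

#' Mass-weighted mean dose of one breast
#'
#' Combines the per-slice mean doses l1..l3 into the side's organ dose
#' \eqn{\sum_i l_i m_i / \sum_i m_i}. Weights always derive from the
#' supplied mass table and are renormalized to sum to one; a custom weight
#' vector can be supplied instead (set \code{renormalize = FALSE} to use it
#' verbatim, e.g. to reproduce a non-normalized published weighting).
#'
#' @param doses numeric vector of per-slice mean doses in mGy, ordered by
#'   slice index (1 = chest-proximal).
#' @param slices slice table (see [randoBreastSlices()]).
#' @param side \code{"left"} or \code{"right"}.
#' @param weights optional explicit weights overriding the masses.
#' @param renormalize divide the weights by their sum (default TRUE).
#' @return organ dose of the side, mGy.
#' @export
breastDoseSide <- function(doses, slices = randoBreastSlices(),
                           side = c("left", "right"), weights = NULL,
                           renormalize = TRUE) {
  side <- match.arg(side)
  s <- slices[slices$side == side, , drop = FALSE]
  if (nrow(s) == 0) stop("no slices for side '", side, "' in the table")
  s <- s[order(s$index), , drop = FALSE]
  if (length(doses) != nrow(s))
    stop("got ", length(doses), " doses for ", nrow(s), " '", side,
         "' slices")
  if (any(doses < 0)) stop("slice doses must be >= 0")
  w <- if (is.null(weights)) s$mass_kg else as.numeric(weights)
  if (length(w) != length(doses)) stop("weights must match the doses")
  if (renormalize) w <- w / sum(w)
  sum(doses * w)
}

#' Overall breast dose from the two per-side doses
#'
#' Mass-weighted combination \eqn{(D_L m_L + D_R m_R) / (m_L + m_R)}; with
#' the default phantom masses (0.45 and 0.55 kg, totalling 1 kg) this is
#' \eqn{0.45 D_L + 0.55 D_R}.
#'
#' @param dLeft,dRight per-side organ doses, mGy.
#' @param mLeft,mRight breast masses, kg.
#' @return overall breast dose, mGy.
#' @examples
#' overallBreastDose(2.3, 1.17)  # 1.6785 -> 1.7 at reporting precision
#' @export
overallBreastDose <- function(dLeft, dRight, mLeft = 0.45, mRight = 0.55) {
  if (dLeft < 0 || dRight < 0) stop("doses must be >= 0")
  if (mLeft + mRight <= 0) stop("total mass must be > 0")
  (dLeft * mLeft + dRight * mRight) / (mLeft + mRight)
}

#' Percent dose asymmetry between two regions
#'
#' \code{100 * (dA - dB) / dB}: how much greater (or smaller) dose A is
#' relative to dose B.
#'
#' @param dA,dB doses, mGy; \code{dB} must be positive.
#' @return signed percent difference.
#' @export
asymmetryPercent <- function(dA, dB) {
  if (any(dB <= 0)) stop("reference dose must be > 0")
  100 * (dA - dB) / dB
}

#' DAP-normalized dose conversion factor
#'
#' @param organDose organ dose, mGy (>= 0).
#' @param dap dose-area product, Gy.cm2 (> 0).
#' @return conversion factor, mGy per Gy.cm2.
#' @examples
#' conversionFactor(2.3, 14.06)  # ~0.16 mGy/Gy.cm2
#' @export
conversionFactor <- function(organDose, dap) {
  if (any(dap <= 0)) stop("DAP must be > 0")
  if (any(organDose < 0)) stop("organ dose must be >= 0")
  organDose / dap
}

#' Aggregate per-slice doses into an organ-dose result with uncertainty
#'
#' Per-slice dose variance combines the ROI read standard error with the
#' calibration fit RMS in quadrature; slice errors are treated as
#' independent (each slice is a separate film), so side and overall
#' variances are the weight-squared sums.
#'
#' @param sliceDoses data.frame with columns side, index, dose_mgy and
#'   optionally se_mgy (per-slice standard error of the ROI mean).
#' @param slices slice mass table (see [randoBreastSlices()]).
#' @param calibrationRMS calibration fit RMS added to each slice error in
#'   quadrature, mGy.
#' @return an \linkS4class{OrganDoseResult}.
#' @export
organDose <- function(sliceDoses, slices = randoBreastSlices(),
                      calibrationRMS = 0) {
  need <- c("side", "index", "dose_mgy")
  if (!all(need %in% names(sliceDoses)))
    stop("sliceDoses must have columns: ", paste(need, collapse = ","))
  se <- if ("se_mgy" %in% names(sliceDoses)) sliceDoses$se_mgy else
    rep(NA_real_, nrow(sliceDoses))

  perSide <- function(side) {
    sd <- sliceDoses[sliceDoses$side == side, , drop = FALSE]
    sd <- sd[order(sd$index), , drop = FALSE]
    sl <- slices[slices$side == side, , drop = FALSE]
    sl <- sl[order(sl$index), , drop = FALSE]
    if (!identical(as.integer(sd$index), as.integer(sl$index)))
      stop("slice doses do not match the '", side, "' slice table")
    w <- sl$mass_kg / sum(sl$mass_kg)
    e <- if ("se_mgy" %in% names(sd)) sd$se_mgy else rep(NA_real_, nrow(sd))
    v <- if (all(is.finite(e))) sum(w^2 * (e^2 + calibrationRMS^2)) else
      NA_real_
    list(dose = sum(w * sd$dose_mgy), var = v, mass = sum(sl$mass_kg))
  }
  L <- perSide("left"); R <- perSide("right")
  mTot <- L$mass + R$mass
  dAll <- (L$dose * L$mass + R$dose * R$mass) / mTot
  relU <- NA_real_
  if (is.finite(L$var) && is.finite(R$var) && dAll > 0)
    relU <- sqrt((L$mass / mTot)^2 * L$var + (R$mass / mTot)^2 * R$var) /
      dAll
  new("OrganDoseResult", dLeft = L$dose, dRight = R$dose, dOverall = dAll,
      relativeUncertainty = relU)
}
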