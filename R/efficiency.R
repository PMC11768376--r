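# Water- and nitrogen-use efficiency indices.

#' Water use efficiency
#'
#' Yield per unit of water consumed, WUE = Y / ET.
#'
#' @param yield Yield, t ha^-1.
#' @param et Seasonal water consumption, mm; must be positive.
#' @return WUE in t ha^-1 mm^-1.
#' @export
wue <- function(yield, et) {
  if (any(et <= 0)) stop("et must be positive")
  if (any(yield < 0)) stop("yield must be non-negative")
  yield / et
}

#' Irrigation water use efficiency
#'
#' Yield per unit of irrigation applied, IWUE = Y / I.
#'
#' @param yield Yield, t ha^-1.
#' @param irrigation Seasonal irrigation, mm; must be positive.
#' @return IWUE in t ha^-1 mm^-1.
#' @export
iwue <- function(yield, irrigation) {
  if (any(irrigation <= 0)) stop("irrigation must be positive")
  if (any(yield < 0)) stop("yield must be non-negative")
  yield / irrigation
}

#' Nitrogen partial factor productivity
#'
#' Yield (kg) per kg of nitrogen fertilizer applied:
#' NPFP = 1000 Y / F_N, the factor 1000 converting yield from t ha^-1 to
#' kg ha^-1 so the index comes out in kg kg^-1.
#'
#' @param yield Yield, t ha^-1.
#' @param n_rate Nitrogen application rate, kg ha^-1; must be positive
#'   (the index is undefined for a zero-nitrogen control).
#' @return NPFP in kg kg^-1.
#' @export
npfp <- function(yield, n_rate) {
  if (any(n_rate <= 0))
    stop("NPFP is undefined for a zero-nitrogen control (n_rate must be > 0)")
  if (any(yield < 0)) stop("yield must be non-negative")
  1000 * yield / n_rate
}

#' Relative difference in percent
#'
#' Formalizes "a is r % higher/lower than b": (a - b) / b * 100.
#'
#' @param a Value compared.
#' @param b Reference value; must be non-zero.
#' @return Percent difference (positive: a exceeds b).
#' @export
relative_difference <- function(a, b) {
  if (any(b == 0)) stop("reference value must be non-zero")
  (a - b) / b * 100
}

#' Augment a treatment table with efficiency indices
#'
#' Adds WUE, IWUE and NPFP columns to a per-treatment data frame. NPFP is
#' \code{NA} where the nitrogen rate is zero (unfertilized control).
#'
#' @param df Data frame with columns \code{yield_t_ha}, \code{et_mm},
#'   \code{irrigation_mm}, \code{n_rate_kg_ha}.
#' @return The data frame with columns \code{wue}, \code{iwue}, \code{npfp}
#'   appended.
#' @export
efficiency_table <- function(df) {
  need <- c("yield_t_ha", "et_mm", "irrigation_mm", "n_rate_kg_ha")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  df$wue <- wue(df$yield_t_ha, df$et_mm)
  df$iwue <- iwue(df$yield_t_ha, df$irrigation_mm)
  df$npfp <- ifelse(df$n_rate_kg_ha > 0,
                    1000 * df$yield_t_ha / df$n_rate_kg_ha, NA_real_)
  df
}
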