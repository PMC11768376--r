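# Soil-water balance: gravimetric moisture, design irrigation depth, and
# stage crop water consumption. Moisture contents are mass fractions
# throughout; percent appears only in I/O formatting.

#' Gravimetric soil water content
#'
#' Mass water content from oven-drying: (wet - dry) / dry.
#'
#' @param wet_mass Fresh soil mass, g.
#' @param dry_mass Oven-dry soil mass, g; must be positive.
#' @return Water content as a mass fraction (0.25 means 25 %).
#' @examples
#' soil_water_content(125, 100)  # 0.25
#' @export
soil_water_content <- function(wet_mass, dry_mass) {
  if (any(dry_mass <= 0))
    stop("dry_mass must be positive")
  if (any(wet_mass < dry_mass))
    stop("wet_mass must be >= dry_mass")
  (wet_mass - dry_mass) / dry_mass
}

#' Design irrigation depth
#'
#' Depth of water needed to raise the planned wetted layer from a measured
#' moisture content to the design upper limit:
#' \deqn{M = 10 \gamma H P (\omega_j - \omega_i)}
#' with bulk density \eqn{\gamma} in g cm^-3, wetted depth \eqn{H} in cm,
#' wetting ratio \eqn{P} as a fraction and contents as mass fractions; the
#' factor 10 converts to mm. Demand is clamped at zero when the profile is
#' already at or above the target: drip scheduling never extracts water.
#'
#' @param bulk_density Bulk density of the wetted layer, g cm^-3.
#' @param wetted_depth Planned wetted depth, cm (default 60, the root-active
#'   0--60 cm profile).
#' @param wetting_ratio Drip design wetting ratio in (0, 1].
#' @param target Design upper moisture limit, mass fraction.
#' @param measured Measured moisture content, mass fraction.
#' @return Irrigation depth, mm.
#' @examples
#' irrigation_volume(1.48, 60, 1, target = 0.192, measured = 0.172)  # 17.76
#' @export
irrigation_volume <- function(bulk_density, wetted_depth = 60,
                              wetting_ratio = 1, target, measured) {
  stopifnot(bulk_density > 0, wetted_depth > 0)
  if (wetting_ratio <= 0 || wetting_ratio > 1)
    stop("wetting_ratio must be in (0, 1]")
  if (any(target < 0) || any(measured < 0) || any(target >= 1) ||
      any(measured >= 1))
    stop("moisture contents must be fractions in [0, 1)")
  pmax(0, 10 * bulk_density * wetted_depth * wetting_ratio *
         (target - measured))
}

#' Stage water record
#'
#' Bundles what the water balance needs for one growth stage: the layered
#' soil-moisture storage change plus the stage water inputs and outputs.
#'
#' @param layers Data frame with one row per soil layer and columns
#'   \code{bulk_density} (g cm^-3), \code{thickness} (cm),
#'   \code{content_start}, \code{content_end} (mass fractions).
#' @param irrigation Irrigation depth over the stage, mm.
#' @param rainfall Effective rainfall over the stage, mm (taken as given;
#'   no effectiveness coefficient is estimated here).
#' @param recharge Groundwater recharge, mm. Defaults to 0: with a water
#'   table deeper than 20 m the crop cannot reach it.
#' @param percolation Deep percolation, mm. Defaults to 0: deficit drip
#'   scheduling keeps applications below field capacity.
#' @return An object of class \code{stage_water_record}.
#' @export
stage_water_record <- function(layers, irrigation = 0, rainfall = 0,
                               recharge = 0, percolation = 0) {
  layers <- as.data.frame(layers)
  need <- c("bulk_density", "thickness", "content_start", "content_end")
  if (nrow(layers) == 0L)
    stop("layer list must be non-empty")
  if (!all(need %in% names(layers)))
    stop("layers must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(layers$bulk_density > 0), all(layers$thickness > 0),
            irrigation >= 0, rainfall >= 0, recharge >= 0, percolation >= 0)
  structure(list(layers = layers, irrigation = irrigation,
                 rainfall = rainfall, recharge = recharge,
                 percolation = percolation),
            class = "stage_water_record")
}

#' Stage crop water consumption by soil-water balance
#'
#' \deqn{ET = 10 \sum_i \gamma_i H_i (\omega_{i1} - \omega_{i2}) + M + P + K - C}
#' Storage drawn down over the stage plus irrigation \eqn{M}, effective
#' rainfall \eqn{P} and groundwater recharge \eqn{K}, minus deep percolation
#' \eqn{C}; all in mm.
#'
#' @param record A \code{\link{stage_water_record}}.
#' @return Stage water consumption, mm.
#' @examples
#' rec <- stage_water_record(
#'   data.frame(bulk_density = 1.48, thickness = 20,
#'              content_start = 0.20, content_end = 0.18),
#'   irrigation = 30, rainfall = 10)
#' stage_water_consumption(rec)  # 45.92
#' @export
stage_water_consumption <- function(record) {
  stopifnot(inherits(record, "stage_water_record"))
  L <- record$layers
  storage <- 10 * sum(L$bulk_density * L$thickness *
                        (L$content_start - L$content_end))
  storage + record$irrigation + record$rainfall +
    record$recharge - record$percolation
}

#' Seasonal total water consumption
#'
#' @param stage_et Numeric vector of per-stage water consumption, mm.
#' @return Their sum, mm.
#' @export
total_water_consumption <- function(stage_et) {
  if (length(stage_et) == 0L)
    stop("no stages supplied")
  sum(stage_et)
}

#' Read layered soil-moisture records
#'
#' Reads a moisture CSV (columns \code{stage}, \code{layer_top_cm},
#' \code{layer_bottom_cm}, \code{bulk_density}, \code{content_start},
#' \code{content_end}) and an events CSV (columns \code{stage},
#' \code{irrigation_mm}, \code{rainfall_mm}), and assembles one
#' \code{\link{stage_water_record}} per stage in the order stages first
#' appear in the moisture file.
#'
#' @param moisture_path,events_path CSV paths.
#' @return Named list of \code{stage_water_record} objects.
#' @export
read_moisture_records <- function(moisture_path, events_path) {
  mo <- utils::read.csv(moisture_path, stringsAsFactors = FALSE)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  need <- c("stage", "layer_top_cm", "layer_bottom_cm", "bulk_density",
            "content_start", "content_end")
  if (!all(need %in% names(mo)))
    stop("moisture file must have columns: ", paste(need, collapse = ", "))
  if (!all(c("stage", "irrigation_mm", "rainfall_mm") %in% names(ev)))
    stop("events file must have columns: stage, irrigation_mm, rainfall_mm")
  stages <- unique(mo$stage)
  out <- lapply(stages, function(s) {
    m <- mo[mo$stage == s, ]
    e <- ev[ev$stage == s, ]
    if (nrow(e) != 1L)
      stop("expected exactly one events row for stage '", s, "'")
    stage_water_record(
      data.frame(bulk_density = m$bulk_density,
                 thickness = m$layer_bottom_cm - m$layer_top_cm,
                 content_start = m$content_start,
                 content_end = m$content_end),
      irrigation = e$irrigation_mm, rainfall = e$rainfall_mm)
  })
  stats::setNames(out, stages)
}

#' Seasonal water consumption from stage records
#'
#' @param records List of \code{\link{stage_water_record}} objects.
#' @return Named list with per-stage ET (mm) and the seasonal total (mm).
#' @export
season_water_consumption <- function(records) {
  et <- vapply(records, stage_water_consumption, numeric(1))
  list(stage_et = et, total = total_water_consumption(et))
}
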