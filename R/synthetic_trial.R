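# Seeded generators producing data with the statistical structure the
# analysis assumes: a 3x3 water-by-nitrogen factorial with interior-optimum
# (concave quadratic) yield/quality responses, water consumption monotone in
# irrigation level, and soil-moisture seasons whose water balance returns a
# known ET by construction.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Specification of a synthetic water-by-nitrogen trial
#'
#' Water levels are encoded by the midpoints of their field-capacity bands
#' (55, 65, 75 % FC for moderate deficit, mild deficit and full irrigation)
#' and nitrogen levels by rate (215, 270, 325 kg ha^-1). Yield and the two
#' quality indicators follow concave quadratic response surfaces with an
#' interior optimum (defaults: 65 % FC, 270 kg ha^-1, the mild-deficit /
#' medium-nitrogen cell); water consumption rises linearly with the water
#' level and weakly with nitrogen. Gaussian noise is added per indicator;
#' default standard deviations follow the replicate scatter of the packaged
#' trial tables (yield about 2 t ha^-1, ET about 6 mm).
#'
#' @param water_fc Ordered water-level intensities, % of field capacity.
#' @param n_rates Ordered nitrogen rates, kg ha^-1.
#' @param optimum Length-2 vector (water % FC, N rate) locating the yield /
#'   quality optimum; must lie strictly inside the design ranges.
#' @param yield_max Yield at the optimum, t ha^-1.
#' @param yield_curv Curvatures (per (%FC)^2, per (kg ha^-1)^2); both must
#'   be positive so the surface is concave with an interior optimum.
#' @param interaction Water-by-nitrogen interaction coefficient for yield.
#' @param et_base,et_per_fc,et_per_n Linear water-consumption model
#'   (mm; mm per % FC, must be positive; mm per kg N ha^-1).
#' @param tss_max,tss_curv,vc_max,vc_curv Quality surfaces, same
#'   parameterization as yield.
#' @param noise_sd Named vector of Gaussian noise standard deviations for
#'   \code{ET}, \code{Y}, \code{TSS}, \code{VC}.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class \code{synthetic_trial_spec}.
#' @export
synthetic_trial_spec <- function(water_fc = c(55, 65, 75),
                                 n_rates = c(215, 270, 325),
                                 optimum = c(65, 270),
                                 yield_max = 87,
                                 yield_curv = c(0.15, 0.0035),
                                 interaction = 0,
                                 et_base = 110, et_per_fc = 2.9,
                                 et_per_n = 0.025,
                                 tss_max = 4.9, tss_curv = c(0.002, 1.5e-4),
                                 vc_max = 63, vc_curv = c(0.04, 0.0026),
                                 noise_sd = c(ET = 6, Y = 2,
                                              TSS = 0.1, VC = 2),
                                 seed = 1L) {
  if (length(water_fc) < 2L || length(n_rates) < 2L)
    stop("need at least 2 water and 2 nitrogen levels")
  if (any(c(yield_curv, tss_curv, vc_curv) <= 0))
    stop("curvatures must be positive (concave response, interior optimum)")
  if (et_per_fc <= 0)
    stop("et_per_fc must be positive (ET monotone in irrigation level)")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (optimum[1] < min(water_fc) || optimum[1] > max(water_fc) ||
      optimum[2] < min(n_rates) || optimum[2] > max(n_rates))
    stop("optimum must lie inside the design ranges")
  structure(list(water_fc = water_fc, n_rates = n_rates, optimum = optimum,
                 yield_max = yield_max, yield_curv = yield_curv,
                 interaction = interaction, et_base = et_base,
                 et_per_fc = et_per_fc, et_per_n = et_per_n,
                 tss_max = tss_max, tss_curv = tss_curv,
                 vc_max = vc_max, vc_curv = vc_curv,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_trial_spec")
}

.quad_surface <- function(w, n, peak, curv, opt, inter = 0) {
  peak - curv[1] * (w - opt[1])^2 - curv[2] * (n - opt[2])^2 +
    inter * (w - opt[1]) * (n - opt[2])
}

#' Generate a synthetic trial indicator table
#'
#' Produces the factorial treatment-mean table the pipeline consumes:
#' ET, Y, TSS and VC drawn from the spec's response surfaces plus Gaussian
#' noise, with WUE and NPFP derived through the efficiency functions.
#' Treatments are labelled W<i>N<j> and ordered with nitrogen varying
#' slowest, matching the packaged trial tables.
#'
#' @param spec A \code{\link{synthetic_trial_spec}}.
#' @return An \code{\link{indicator_table}} with columns ET, Y, WUE, NPFP,
#'   TSS, VC and all-benefit directions.
#' @examples
#' tab <- generate_indicator_table(synthetic_trial_spec(seed = 7))
#' ewm_topsis(tab)$result
#' @export
generate_indicator_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  grid <- expand.grid(wi = seq_along(spec$water_fc),
                      ni = seq_along(spec$n_rates))
  w <- spec$water_fc[grid$wi]
  n <- spec$n_rates[grid$ni]
  m <- nrow(grid)
  .with_seed(spec$seed, {
    et <- spec$et_base + spec$et_per_fc * w + spec$et_per_n * n +
      stats::rnorm(m, 0, spec$noise_sd["ET"])
    y <- .quad_surface(w, n, spec$yield_max, spec$yield_curv, spec$optimum,
                       spec$interaction) +
      stats::rnorm(m, 0, spec$noise_sd["Y"])
    tss <- .quad_surface(w, n, spec$tss_max, spec$tss_curv, spec$optimum) +
      stats::rnorm(m, 0, spec$noise_sd["TSS"])
    vc <- .quad_surface(w, n, spec$vc_max, spec$vc_curv, spec$optimum) +
      stats::rnorm(m, 0, spec$noise_sd["VC"])
  })
  y <- pmax(y, 0.1)
  et <- pmax(et, 1)
  vals <- cbind(ET = et, Y = y, WUE = wue(y, et), NPFP = npfp(y, n),
                TSS = tss, VC = vc)
  rownames(vals) <- paste0("W", grid$wi, "N", grid$ni)
  indicator_table(vals, "benefit", year = "synthetic")
}

#' Generate a soil-moisture season with known water consumption
#'
#' Emits layered start/end moisture contents such that the soil-water
#' balance applied to the records returns the specified true per-stage ET
#' exactly. The storage change each stage needs, ET - M - P, is spread over
#' the layers in proportion to their water capacity (bulk density times
#' thickness); each stage starts where the previous one ended. Optional
#' Gaussian measurement noise on the emitted contents makes recovered ET a
#' noisy, unbiased estimate of the truth.
#'
#' @param true_et Per-stage true water consumption, mm.
#' @param irrigation,rainfall Per-stage depths, mm (recycled if scalar).
#' @param layers Data frame with \code{bulk_density} (g cm^-3) and
#'   \code{thickness} (cm) per soil layer; default three 20-cm layers at
#'   1.48 g cm^-3, the loam profile of the packaged trial.
#' @param start_content Initial moisture content (mass fraction) of every
#'   layer; default 0.192 (80 % of a 24 % field capacity).
#' @param saturation Feasibility ceiling for contents, mass fraction.
#' @param content_noise_sd Standard deviation of measurement noise added to
#'   every emitted content; 0 (default) gives exact recovery.
#' @param seed Seed for the noise; ignored when \code{content_noise_sd = 0}.
#' @return List of \code{\link{stage_water_record}} objects, one per stage.
#' @export
generate_soil_moisture_season <- function(true_et, irrigation = 0,
                                          rainfall = 0,
                                          layers = data.frame(
                                            bulk_density = rep(1.48, 3),
                                            thickness = rep(20, 3)),
                                          start_content = 0.192,
                                          saturation = 0.45,
                                          content_noise_sd = 0,
                                          seed = NULL) {
  ns <- length(true_et)
  irrigation <- rep_len(irrigation, ns)
  rainfall <- rep_len(rainfall, ns)
  cap <- 10 * layers$bulk_density * layers$thickness  # mm per unit content
  share <- cap / sum(cap)
  content <- rep_len(start_content, nrow(layers))
  .with_seed(seed, {
    records <- vector("list", ns)
    for (s in seq_len(ns)) {
      storage_change <- true_et[s] - irrigation[s] - rainfall[s]  # mm drawn
      end <- content - storage_change * share / cap
      if (any(end < 0) || any(end > saturation) ||
          any(content > saturation))
        stop("infeasible moisture trajectory at stage ", s,
             ": content outside [0, saturation]")
      cs <- content
      ce <- end
      if (content_noise_sd > 0) {
        cs <- cs + stats::rnorm(length(cs), 0, content_noise_sd)
        ce <- ce + stats::rnorm(length(ce), 0, content_noise_sd)
      }
      records[[s]] <- stage_water_record(
        data.frame(bulk_density = layers$bulk_density,
                   thickness = layers$thickness,
                   content_start = cs, content_end = ce),
        irrigation = irrigation[s], rainfall = rainfall[s])
      content <- end
    }
  })
  names(records) <- paste0("stage", seq_len(ns))
  records
}

#' Generate an entropy-weighting stress matrix
#'
#' Builds an indicator table in which designated columns carry almost no
#' ranking information while the rest discriminate strongly, for testing
#' that the entropy method assigns uninformative columns near-zero weight.
#' An uninformative column is a plateau with tiny jitter and a single
#' slightly lower object: after min-max standardization its proportions are
#' nearly uniform over the plateau (entropy close to ln(m-1)/ln(m), the
#' maximum a standardized column can attain). An informative column singles
#' out one object far above the rest (entropy far below 1).
#'
#' @param m Number of objects (at least 3).
#' @param n Number of indicators.
#' @param near_constant Indices of the uninformative columns.
#' @param seed Integer seed.
#' @return An \code{\link{indicator_table}} with all-benefit directions.
#' @export
generate_weighting_stress_matrix <- function(m, n, near_constant = integer(),
                                             seed = 1L) {
  if (m < 3L) stop("need m >= 3 objects")
  stopifnot(all(near_constant %in% seq_len(n)))
  .with_seed(seed, {
    vals <- sapply(seq_len(n), function(j) {
      if (j %in% near_constant) {
        tiny <- 1e-4
        x <- 100 + stats::rnorm(m, 0, tiny)
        x[sample.int(m, 1)] <- x[1] - 50 * tiny
        x
      } else {
        x <- stats::runif(m) * 0.05
        x[sample.int(m, 1)] <- 1 + stats::runif(1) * 0.2
        x
      }
    })
  })
  colnames(vals) <- paste0("X", seq_len(n))
  rownames(vals) <- paste0("obj", seq_len(m))
  indicator_table(vals, "benefit", year = "synthetic")
}
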