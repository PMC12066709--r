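# Seeded generators for every input the analysis consumes: grain outlines
# with controlled hull roughness, colonization maps, two-channel ratio
# image stacks generated through the Stern-Volmer forward model, and site
# parameter tables spanning the field envelope.

#' Specification for the synthetic-data generators
#'
#' Grain diameters are sampled log-normally (median
#' `grain_diameter_median_um`, geometric standard deviation
#' `grain_diameter_gsd`); outlines get a band-limited radial perturbation
#' of peak amplitude `roughness_amplitude_um`; colonized perimeter splits
#' into `consumer_fraction` net O2 consumers and `producer_fraction` net
#' producers; ratio stacks carry multiplicative Gaussian noise of
#' coefficient of variation `noise_cv` per channel.
#'
#' @param seed integer seed threading every generator.
#' @param grain_count number of grains.
#' @param grain_diameter_median_um,grain_diameter_gsd log-normal diameter
#'   distribution parameters (defaults 290 um, GSD 1.3).
#' @param roughness_amplitude_um peak radial perturbation (um, >= 0).
#' @param colonized_fraction fraction of the grain perimeter covered by
#'   colonies (default 1/2).
#' @param consumer_fraction,producer_fraction split of the colonized
#'   perimeter (defaults 2/3 and 1/3; must sum to <= 1).
#' @param colony_pairs colony pairs per grain.
#' @param areal_cell_density_mean,areal_cell_density_sd cells cm^-2.
#' @param noise_cv multiplicative image noise CV per channel.
#' @param frame_times_h strictly increasing imaging times, hours.
#' @param o2_initial_umol_L homogeneous O2 concentration at the first
#'   frame.
#' @param pixel_size_um image pixel size.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           grain_count = 50L,
                           grain_diameter_median_um = 290,
                           grain_diameter_gsd = 1.3,
                           roughness_amplitude_um = 10,
                           colonized_fraction = 0.5,
                           consumer_fraction = 2 / 3,
                           producer_fraction = 1 / 3,
                           colony_pairs = 4L,
                           areal_cell_density_mean = 8.57e5,
                           areal_cell_density_sd = 2.8e5,
                           noise_cv = 0.02,
                           frame_times_h = c(0, 1),
                           o2_initial_umol_L = 100,
                           pixel_size_um = 2) {
  if (grain_diameter_median_um <= 0 || grain_diameter_gsd < 1)
    stop("invalid grain-size distribution parameters", call. = FALSE)
  if (roughness_amplitude_um < 0)
    stop("roughness amplitude must be >= 0", call. = FALSE)
  if (consumer_fraction < 0 || producer_fraction < 0 ||
      consumer_fraction + producer_fraction > 1 + 1e-12)
    stop("consumer_fraction + producer_fraction must be <= 1", call. = FALSE)
  if (colonized_fraction < 0 || colonized_fraction > 1)
    stop("colonized_fraction must be in [0, 1]", call. = FALSE)
  if (is.unsorted(frame_times_h, strictly = TRUE))
    stop("frame_times_h must be strictly increasing", call. = FALSE)
  if (noise_cv < 0 || o2_initial_umol_L < 0 || pixel_size_um <= 0)
    stop("invalid noise, O2 or pixel-size value", call. = FALSE)
  structure(list(seed = as.integer(seed), grain_count = as.integer(grain_count),
                 grain_diameter_median_um = grain_diameter_median_um,
                 grain_diameter_gsd = grain_diameter_gsd,
                 roughness_amplitude_um = roughness_amplitude_um,
                 colonized_fraction = colonized_fraction,
                 consumer_fraction = consumer_fraction,
                 producer_fraction = producer_fraction,
                 colony_pairs = as.integer(colony_pairs),
                 areal_cell_density_mean = areal_cell_density_mean,
                 areal_cell_density_sd = areal_cell_density_sd,
                 noise_cv = noise_cv, frame_times_h = frame_times_h,
                 o2_initial_umol_L = o2_initial_umol_L,
                 pixel_size_um = pixel_size_um),
            class = "synthetic_spec")
}

#' Generate one grain outline polygon
#'
#' Samples a grain radius from the spec's log-normal size distribution and
#' perturbs it radially with a band-limited Fourier series (modes 5-25,
#' random amplitudes and phases) rescaled so the peak radial deviation
#' equals the spec's roughness amplitude.  With zero amplitude the outline
#' is a regular polygonal circle (convex; hull roughness zero).
#'
#' @param spec a [synthetic_spec()].
#' @param index grain index (also seeds the per-grain RNG stream).
#' @param n_vertices outline vertices (open ring).
#' @return data frame with `x_um`, `y_um` and attributes `grain_id` and
#'   `radius_um` (the unperturbed sampled radius).
#' @export
make_grain_outline <- function(spec, index = 1L, n_vertices = 256L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$grain_diameter_median_um <= 0)
    stop("invalid spec: non-positive diameter", call. = FALSE)
  with_seed(combine_seed(spec$seed, index), {
    d <- stats::rlnorm(1, log(spec$grain_diameter_median_um),
                       log(spec$grain_diameter_gsd))
    r0 <- d / 2
    th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    dr <- numeric(n_vertices)
    if (spec$roughness_amplitude_um > 0) {
      modes <- 5:25
      amp <- stats::runif(length(modes))
      phase <- stats::runif(length(modes), 0, 2 * pi)
      for (m in seq_along(modes))
        dr <- dr + amp[m] * cos(modes[m] * th + phase[m])
      dr <- dr / max(abs(dr)) * spec$roughness_amplitude_um
    }
    r <- r0 + dr
    out <- data.frame(x_um = r * cos(th), y_um = r * sin(th))
    attr(out, "grain_id") <- as.integer(index)
    attr(out, "radius_um") <- r0
    out
  })
}

#' Colonization map of one grain perimeter
#'
#' Lays out alternating consumer and producer arcs (with bare gaps) around
#' the grain, matching the spec's colonized fraction and consumer/producer
#' split.  With the defaults on a 290 um grain this gives four 76 um
#' consumer arcs and four 38 um producer arcs.
#'
#' @param spec a [synthetic_spec()].
#' @param grain_diameter_um grain diameter (default the spec median).
#' @return data frame with one row per arc: `class` (consumer / producer /
#'   bare), `colony_index` (NA for bare), `start_angle_rad`,
#'   `end_angle_rad`, `arc_length_um`.
#' @export
make_colonization_map <- function(spec,
                                  grain_diameter_um =
                                    spec$grain_diameter_median_um) {
  stopifnot(inherits(spec, "synthetic_spec"))
  r <- grain_diameter_um / 2
  n_pairs <- spec$colony_pairs
  per_pair_rad <- 2 * pi / n_pairs
  cons_rad <- spec$colonized_fraction * spec$consumer_fraction *
    2 * pi / n_pairs
  prod_rad <- spec$colonized_fraction * spec$producer_fraction *
    2 * pi / n_pairs
  rows <- list()
  for (k in seq_len(n_pairs)) {
    base <- (k - 1) * per_pair_rad
    gap <- (per_pair_rad - cons_rad - prod_rad) / 2
    segs <- list(
      list("consumer", k, base, base + cons_rad),
      list("bare", NA_integer_, base + cons_rad, base + cons_rad + gap),
      list("producer", k, base + cons_rad + gap,
           base + cons_rad + gap + prod_rad),
      list("bare", NA_integer_, base + cons_rad + gap + prod_rad,
           base + per_pair_rad))
    for (s in segs) {
      if (s[[4]] - s[[3]] <= 1e-12) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = s[[1]], colony_index = s[[2]],
        start_angle_rad = s[[3]], end_angle_rad = s[[4]],
        arc_length_um = (s[[4]] - s[[3]]) * r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a two-channel ratio image time series from a known rate field
#'
#' Forward model for the ratiometric module: starting from a homogeneous
#' O2 concentration at the first frame, each pixel evolves linearly with
#' its volumetric rate (clipped at zero O2), is mapped through the
#' Stern-Volmer calibration to a red/green ratio, and is emitted as
#' separate indicator (red) and reference (green) channels with
#' multiplicative Gaussian noise of CV `noise_cv` per channel.
#'
#' @param rate_field matrix of volumetric O2 rates, umol L^-1 h^-1
#'   (negative = consumption).
#' @param cal a calibration curve ([fit_calibration()] object or a list
#'   with `model`, `R0`, `K_sv`, `f`).
#' @param spec a [synthetic_spec()] (frame times, noise, initial O2, seed).
#' @param green_base mean reference-channel intensity.
#' @return ratio stack: list with `frames` (list of `time_h`, `red`,
#'   `green`), `pixel_size_um`, and the `true_o2` matrices per frame.
#' @export
make_ratio_series <- function(rate_field, cal, spec, green_base = 1000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rate_field <- as.matrix(rate_field)
  with_seed(combine_seed(spec$seed, 7919L), {
    frames <- vector("list", length(spec$frame_times_h))
    true_o2 <- vector("list", length(spec$frame_times_h))
    for (k in seq_along(spec$frame_times_h)) {
      t_h <- spec$frame_times_h[k]
      C <- pmax(spec$o2_initial_umol_L + rate_field * t_h, 0)
      ratio <- o2_to_ratio(cal, C)
      # noise_cv is the effective CV of the emitted red/green ratio; each
      # channel carries an independent multiplicative share of cv/sqrt(2)
      noise <- function() {
        ones <- matrix(1, nrow(C), ncol(C))
        if (spec$noise_cv == 0) ones
        else ones + matrix(stats::rnorm(length(C), 0,
                                        spec$noise_cv / sqrt(2)), nrow(C))
      }
      green <- green_base * noise()
      red <- ratio * green_base * noise()
      frames[[k]] <- list(time_h = t_h, red = red, green = green)
      true_o2[[k]] <- C
    }
    list(frames = frames, pixel_size_um = spec$pixel_size_um,
         true_o2 = true_o2)
  })
}

#' Generate a synthetic site table for the upscaling chain
#'
#' Draws `n_sites` records inside the field envelope: grain sizes
#' 102-700 um, bottom-water velocities 0.1-0.2 m s^-1, volumetric
#' denitrification rates 0.04-11.8 umol N L^-1 h^-1 (log-uniform),
#' plausible marine temperature/salinity, and bottom-water O2 at air
#' saturation for (T, S) unless overridden.
#'
#' @param seed integer seed.
#' @param n_sites number of sites (>= 1).
#' @param overrides optional named list of column overrides (recycled).
#' @return data frame of site records (see [validate_site_record()]).
#' @export
make_site_table <- function(seed = 1L, n_sites = 10L, overrides = NULL) {
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  tbl <- with_seed(combine_seed(seed, 104729L), {
    T_C <- stats::runif(n_sites, 4, 25)
    S <- stats::runif(n_sites, 30, 36)
    data.frame(
      site_id = sprintf("site_%02d", seq_len(n_sites)),
      d_g_um = stats::runif(n_sites, 102, 700),
      U_bw_m_s = stats::runif(n_sites, 0.1, 0.2),
      T_C = T_C, S = S,
      theta = stats::runif(n_sites, 0.35, 0.45),
      C_O2_umol_L = o2_saturation(T_C, S),
      C_NO3_umol_L = stats::runif(n_sites, 2, 30),
      R_O2_umol_L_h = stats::runif(n_sites, 5, 80),
      R_den_umolN_L_h = exp(stats::runif(n_sites, log(0.04), log(11.8))))
  })
  if (!is.null(overrides)) {
    for (nm in names(overrides)) tbl[[nm]] <- overrides[[nm]]
  }
  for (i in seq_len(nrow(tbl)))
    validate_site_record(tbl[i, , drop = FALSE])
  tbl
}
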