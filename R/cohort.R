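#' Synthetic cohort configuration
#'
#' Distributions and protocol for the seeded synthetic specimen cohort:
#' four groups (CON, BP, NR, PEP) of `n_per_group` bone-disc-bone specimens.
#' Bone segment length defaults follow the reported fabrication tolerances
#' (superior 15.72 mm, SD 1.49; inferior 15.44 mm, SD 2.27). The vertebral
#' greyscale distribution is calibrated so that mapped moduli average
#' 409 MPa. Disc diameter/height defaults (30 mm, 8 mm) are synthetic
#' stand-ins: no disc dimensions are measured here. A per-specimen lognormal
#' "hydration" multiplier scatters the annulus and nucleus stiffnesses; NR
#' specimens additionally draw an annulus collapse factor with a larger
#' log-scale spread, encoding how much annulus collapses into the nucleotomy
#' void. Measurement noise is proportional Gaussian on force.
#'
#' @param n_per_group Specimens per group (>= 2, default 6).
#' @param seed Integer seed; a fixed seed gives a bit-identical cohort.
#' @param disc_diameter_mean,disc_diameter_sd Disc diameter distribution, mm.
#' @param disc_height_mean,disc_height_sd Disc height distribution, mm.
#' @param bone_length_sup_mean,bone_length_sup_sd Superior bone segment
#'   length distribution, mm.
#' @param bone_length_inf_mean,bone_length_inf_sd Inferior bone segment
#'   length distribution, mm.
#' @param greyscale_mean,greyscale_sd Vertebral mean-greyscale distribution
#'   (clipped to `[0, 255]`); the default mean maps to 409 MPa.
#' @param hydration_sdlog Log-SD of the lognormal stiffness multiplier
#'   applied to annulus `c10` and nucleus `(c10, c01)`.
#' @param collapse_meanlog,collapse_sdlog Lognormal parameters of the NR
#'   annulus collapse factor.
#' @param noise_sd Proportional Gaussian SD on force (default 0.01 = 1%).
#' @param protocol A [load_protocol()].
#' @param map A [greyscale_map()] calibration for bone.
#' @param annulus,nucleus Baseline material parameter sets.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 6, seed = 1,
                          disc_diameter_mean = 30, disc_diameter_sd = 1.5,
                          disc_height_mean = 8, disc_height_sd = 0.5,
                          bone_length_sup_mean = 15.72, bone_length_sup_sd = 1.49,
                          bone_length_inf_mean = 15.44, bone_length_inf_sd = 2.27,
                          greyscale_mean = (409 - 10) / (900 / 255),
                          greyscale_sd = 15,
                          hydration_sdlog = 0.1,
                          collapse_meanlog = log(0.5), collapse_sdlog = 0.3,
                          noise_sd = 0.01,
                          protocol = load_protocol(),
                          map = greyscale_map(),
                          annulus = holzapfel_params(),
                          nucleus = mooney_rivlin_params()) {
  stopifnot(n_per_group >= 2,
            disc_diameter_sd >= 0, disc_height_sd >= 0,
            bone_length_sup_sd >= 0, bone_length_inf_sd >= 0,
            greyscale_sd >= 0, hydration_sdlog >= 0, collapse_sdlog >= 0,
            noise_sd >= 0,
            inherits(protocol, "load_protocol"),
            inherits(map, "greyscale_map"),
            inherits(annulus, "holzapfel_params"),
            inherits(nucleus, "mooney_rivlin_params"))
  structure(as.list(environment()), class = "cohort_config")
}

# Deterministic substream seed for (cohort seed, specimen index, block).
# Blocks are drawn in the documented order geometry (1) -> materials (2)
# -> noise (3); per-specimen substreams mean adding specimens never changes
# earlier draws.
substream_seed <- function(seed, i, block) {
  ((as.numeric(seed) %% 65011) * 33013 + i * 7907 + block * 611953) %% 2147483587
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one specimen (CON configuration + group modification) from the config.
draw_specimen <- function(config, i, group) {
  set.seed(substream_seed(config$seed, i, 1)) # geometry substream
  dd <- clip(stats::rnorm(1, config$disc_diameter_mean, config$disc_diameter_sd),
             5, Inf)
  dh <- clip(stats::rnorm(1, config$disc_height_mean, config$disc_height_sd),
             2, Inf)
  bls <- clip(stats::rnorm(1, config$bone_length_sup_mean, config$bone_length_sup_sd),
              5, Inf)
  bli <- clip(stats::rnorm(1, config$bone_length_inf_mean, config$bone_length_inf_sd),
              5, Inf)
  gs <- clip(stats::rnorm(2, config$greyscale_mean, config$greyscale_sd), 0, 255)

  set.seed(substream_seed(config$seed, i, 2)) # materials substream
  hyd <- stats::rlnorm(1, 0, config$hydration_sdlog)
  collapse <- stats::rlnorm(1, config$collapse_meanlog, config$collapse_sdlog)

  ann <- config$annulus
  ann$c10 <- ann$c10 * hyd
  nuc <- config$nucleus
  nuc$c10 <- nuc$c10 * hyd
  nuc$c01 <- nuc$c01 * hyd

  base <- specimen(
    id = sprintf("%s-%02d", group, ((i - 1) %% config$n_per_group) + 1),
    group = "CON",
    geometry = specimen_geometry(disc_diameter = dd, disc_height = dh,
                                 bone_length_sup = bls, bone_length_inf = bli),
    vertebra_sup = vertebra_props(gs[1], bls, config$map),
    vertebra_inf = vertebra_props(gs[2], bli, config$map),
    annulus = ann, nucleus = nuc
  )
  apply_group(base, group, collapse_factor = collapse)
}

# Proportional Gaussian force noise for specimen i (noise substream).
draw_noise <- function(config, i, n) {
  set.seed(substream_seed(config$seed, i, 3))
  stats::rnorm(n, 0, config$noise_sd)
}

#' Generate a seeded synthetic specimen cohort
#'
#' Draws `4 * n_per_group` specimens (groups CON, BP, NR, PEP) and computes,
#' for each, the noise-free forward-model force-displacement curve
#' (`curve`, the "computational" arm) and a noisy measured curve
#' (`curve_noisy`, the "experimental" arm: same displacements, forces
#' perturbed by proportional Gaussian noise). Deterministic under a fixed
#' seed; with `noise_sd = 0` the two arms coincide exactly.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `fsu_cohort` with columns `id`, `group`,
#'   `specimen` (list of `fsu_specimen`), `curve` and `curve_noisy` (lists of
#'   [fd_curve()] tibbles); the configuration is attached as attribute
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_per_group = 2))
#' dplyr::count(coh, group)
#' }
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(fsu_groups, each = config$n_per_group)
  specs <- purrr::imap(groups, function(g, i) draw_specimen(config, i, g))
  curves <- purrr::map(specs, specimen_response, protocol = config$protocol)
  noisy <- purrr::imap(curves, function(cv, i) {
    eps <- draw_noise(config, i, nrow(cv))
    fd_curve(cv$displacement_mm, cv$force_N * (1 + eps), strict = FALSE)
  })
  out <- tibble::tibble(
    id = purrr::map_chr(specs, "id"),
    group = factor(groups, levels = fsu_groups),
    specimen = specs,
    curve = curves,
    curve_noisy = noisy
  )
  attr(out, "config") <- config
  class(out) <- c("fsu_cohort", class(out))
  out
}

# ---- serialization ---------------------------------------------------------

specimen_to_list <- function(s) {
  list(
    id = s$id, group = s$group,
    geometry = s$geometry[c("disc_diameter", "disc_height", "nucleus_diameter",
                            "bone_length_sup", "bone_length_inf")],
    vertebra_sup = s$vertebra_sup[c("mean_greyscale", "length")],
    vertebra_inf = s$vertebra_inf[c("mean_greyscale", "length")],
    map = unclass(s$vertebra_sup$map),
    annulus = unclass(s$annulus),
    nucleus = if (is.null(s$nucleus)) NULL else unclass(s$nucleus),
    plug_modulus_factor = s$plug_modulus_factor,
    annulus_collapse_factor = s$annulus_collapse_factor
  )
}

specimen_from_list <- function(l) {
  map <- do.call(greyscale_map, l$map)
  s <- specimen(
    id = l$id, group = "CON",
    geometry = do.call(specimen_geometry, l$geometry),
    vertebra_sup = vertebra_props(l$vertebra_sup$mean_greyscale,
                                  l$vertebra_sup$length, map),
    vertebra_inf = vertebra_props(l$vertebra_inf$mean_greyscale,
                                  l$vertebra_inf$length, map),
    annulus = do.call(holzapfel_params, l$annulus),
    nucleus = if (is.null(l$nucleus)) mooney_rivlin_params()
              else do.call(mooney_rivlin_params, l$nucleus)
  )
  s$group <- l$group
  if (l$group == "NR") s$nucleus <- NULL
  s$plug_modulus_factor <- l$plug_modulus_factor
  s$annulus_collapse_factor <- l$annulus_collapse_factor
  # plug factor is already baked into the stored greyscale-mapped modulus at
  # generation time only through the factor field, so re-apply it here
  s$vertebra_sup$effective_modulus <-
    s$vertebra_sup$effective_modulus * l$plug_modulus_factor
  s
}

#' Write a cohort to a directory
#'
#' Writes `manifest.json` (specimen metadata + provenance) and two CSV files
#' per specimen (`<id>.csv` noise-free, `<id>_noisy.csv` noisy arm) with
#' columns `displacement_mm, force_N` (header row, dot decimal separator).
#'
#' @param cohort An `fsu_cohort`.
#' @param dir Directory path (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fsu_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- attr(cohort, "config")
  manifest <- list(
    seed = config$seed,
    n_per_group = config$n_per_group,
    noise_sd = config$noise_sd,
    protocol = unclass(config$protocol),
    specimens = purrr::map(cohort$specimen, specimen_to_list)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  purrr::pwalk(list(cohort$id, cohort$curve, cohort$curve_noisy),
               function(id, cv, cvn) {
                 readr::write_csv(cv, file.path(dir, paste0(id, ".csv")))
                 readr::write_csv(cvn, file.path(dir, paste0(id, "_noisy.csv")))
               })
  invisible(dir)
}

#' Read a single force-displacement curve CSV
#'
#' Expects the two-column dialect `displacement_mm, force_N` with a header
#' row; externally supplied curves in the same dialect load interchangeably
#' with synthetic ones.
#'
#' @param path CSV file path.
#' @param strict Enforce non-decreasing force (default `FALSE`, measured
#'   curves may jitter).
#' @return An [fd_curve()].
#' @export
read_curve_csv <- function(path, strict = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("displacement_mm", "force_N")
  if (!all(need %in% names(df))) {
    rlang::abort(paste0("curve file ", path, " is missing column(s): ",
                        paste(setdiff(need, names(df)), collapse = ", ")),
                 class = "fsuaxial_error_parse")
  }
  fd_curve(df$displacement_mm, df$force_N, strict = strict)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and the per-specimen CSVs.
#' @return An `fsu_cohort` tibble equal to the written one to numeric
#'   round-trip tolerance.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    rlang::abort(paste0("no manifest.json in ", dir),
                 class = "fsuaxial_error_parse")
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  specs <- purrr::map(manifest$specimens, specimen_from_list)
  ids <- purrr::map_chr(specs, "id")
  curves <- purrr::map(ids, function(id)
    read_curve_csv(file.path(dir, paste0(id, ".csv")), strict = TRUE))
  noisy <- purrr::map(ids, function(id)
    read_curve_csv(file.path(dir, paste0(id, "_noisy.csv")), strict = FALSE))
  out <- tibble::tibble(
    id = ids,
    group = factor(purrr::map_chr(specs, "group"), levels = fsu_groups),
    specimen = specs, curve = curves, curve_noisy = noisy
  )
  attr(out, "manifest") <- manifest[c("seed", "n_per_group", "noise_sd",
                                      "protocol")]
  class(out) <- c("fsu_cohort", class(out))
  out
}
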