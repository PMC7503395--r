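# Multi-animal age-cohort generation: the study-design emulator used by the
# end-to-end recovery tests (groups x animals x cells, each cell with a
# seal test, a current-step protocol and an AIS line profile).

#' Specify one age group of a synthetic cohort
#'
#' Cell-level parameters are drawn independently from normal distributions
#' `c(mean, sd)` and truncated away from non-physical values. Parameters:
#' `Cm_true` (pF), `Rm` (MOhm), `Rs` (MOhm), `threshold_depol` (mV),
#' `erest` (mV), `ais_length` (um), `ais_diameter` (um), `is_component`
#' (V/s), `is_sd_ratio` (unitless, IS/SD).
#'
#' @param label Group label (e.g. `"P2-5"`).
#' @param n_animals Number of animals (biological replicates), >= 1.
#' @param n_cells_per_animal Cells recorded per animal, >= 1.
#' @param params Named list of `c(mean, sd)` pairs; unset entries fall back
#'   to the young-regime defaults.
#' @return A list of class `"age_group_spec"`.
#' @export
age_group_spec <- function(label, n_animals, n_cells_per_animal,
                           params = list()) {
  if (n_animals < 1 || n_cells_per_animal < 1) {
    stop("spec error: need at least one animal and one cell per animal",
         call. = FALSE)
  }
  defaults <- list(Cm_true = c(60, 12), Rm = c(600, 100), Rs = c(8, 1),
                   threshold_depol = c(16, 1.5), erest = c(-58, 2),
                   ais_length = c(13, 1.5), ais_diameter = c(1.0, 0.1),
                   is_component = c(150, 25), is_sd_ratio = c(1, 0))
  p <- utils::modifyList(defaults, params)
  bad <- vapply(p, function(v) length(v) != 2L || v[2] < 0 ||
                  !all(is.finite(v)), logical(1))
  if (any(bad)) {
    stop("spec error: invalid distribution parameters for ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(label = label, n_animals = n_animals,
                 n_cells_per_animal = n_cells_per_animal, params = p),
            class = "age_group_spec")
}

#' Specify a synthetic multi-group cohort
#'
#' @param age_groups List of [age_group_spec()] objects.
#' @param seed Integer master seed; all cohort randomness derives from it.
#' @param signals Character subset of `c("sealtest", "steps", "ais", "ap")`:
#'   which raw data to generate per cell (`"ap"` is a single-AP voltage
#'   trace from [simulate_ap_waveform()] carrying the cell's IS/SD
#'   structure).
#' @param step_amplitudes Injected amplitudes (pA) of the rheobase protocol.
#' @param sealtest_noise_sd Seal-test current noise, pA.
#' @param ais_psf_sigma_um,ais_pixel_um,ais_noise_sd Imaging parameters of
#'   the generated profiles.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(age_groups, seed = 1,
                        signals = c("sealtest", "steps", "ais", "ap"),
                        step_amplitudes = seq(5, 250, by = 5),
                        sealtest_noise_sd = 2,
                        ais_psf_sigma_um = 0.4, ais_pixel_um = 0.2,
                        ais_noise_sd = 0.02) {
  ok <- vapply(age_groups, inherits, logical(1), what = "age_group_spec")
  if (!length(age_groups) || !all(ok)) {
    stop("spec error: `age_groups` must be a list of age_group_spec objects",
         call. = FALSE)
  }
  signals <- match.arg(signals, several.ok = TRUE)
  structure(list(age_groups = age_groups, seed = seed, signals = signals,
                 step_amplitudes = step_amplitudes,
                 sealtest_noise_sd = sealtest_noise_sd,
                 ais_psf_sigma_um = ais_psf_sigma_um,
                 ais_pixel_um = ais_pixel_um, ais_noise_sd = ais_noise_sd),
            class = "cohort_spec")
}

#' Default two-group ("young" vs "adult") cohort specification
#'
#' Parameter regimes follow the qualitative maturation pattern of layer-V
#' pyramidal neurons: adults have larger capacitance, lower membrane
#' resistance, more hyperpolarized rest, longer and wider AIS and a larger
#' initial-segment dV/dt component, while the depolarization needed to reach
#' threshold is common to both groups.
#'
#' @param n_animals,n_cells_per_animal Cohort size per group.
#' @param seed Master seed.
#' @param ... Passed on to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
young_adult_cohort_spec <- function(n_animals = 4, n_cells_per_animal = 5,
                                    seed = 1, ...) {
  young <- age_group_spec("young", n_animals, n_cells_per_animal,
                          params = list(Cm_true = c(60, 12),
                                        Rm = c(600, 100),
                                        erest = c(-58, 2),
                                        ais_length = c(13, 1.5),
                                        ais_diameter = c(1.0, 0.1),
                                        is_component = c(150, 25),
                                        is_sd_ratio = c(1, 0)))
  adult <- age_group_spec("adult", n_animals, n_cells_per_animal,
                          params = list(Cm_true = c(180, 25),
                                        Rm = c(150, 30),
                                        erest = c(-70, 2),
                                        ais_length = c(27, 2),
                                        ais_diameter = c(1.4, 0.12),
                                        is_component = c(320, 40),
                                        is_sd_ratio = c(0.55, 0.08)))
  cohort_spec(list(young, adult), seed = seed, ...)
}

draw_truncnorm <- function(n, ms, lower) {
  x <- stats::rnorm(n, ms[1], ms[2])
  pmax(x, lower)
}

#' Generate a synthetic cohort
#'
#' Draws per-cell ground-truth parameters, generates the requested raw data
#' (seal test, current-step protocol driven by a leaky integrate-and-fire
#' cell, AIS intensity profile) and assembles a manifest of all true
#' parameters. Fully reproducible from `(spec, spec$seed)`; when `dir` is
#' given the cohort is also written to disk under
#' `group/animal/cell/{sealtest.csv, steps/step_NNN.csv, ais_profile.csv}`
#' plus `manifest.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @return Invisibly for written cohorts, otherwise a list with `manifest`
#'   (data.frame of true parameters) and `cells` (list of per-cell data).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  # Draw all cell parameters and per-cell noise seeds up front under the
  # master seed, then run the (individually seeded) generators.
  draws <- with_seed(spec$seed, {
    lapply(spec$age_groups, function(g) {
      n <- g$n_animals * g$n_cells_per_animal
      ps <- g$params
      data.frame(
        group = g$label,
        animal = rep(paste0("a", seq_len(g$n_animals)),
                     each = g$n_cells_per_animal),
        cell = paste0("c", seq_len(n)),
        Cm_true = draw_truncnorm(n, ps$Cm_true, 5),
        Rm = draw_truncnorm(n, ps$Rm, 20),
        Rs = draw_truncnorm(n, ps$Rs, 1),
        threshold_depol = draw_truncnorm(n, ps$threshold_depol, 2),
        erest = stats::rnorm(n, ps$erest[1], ps$erest[2]),
        ais_length = draw_truncnorm(n, ps$ais_length, 2),
        ais_diameter = draw_truncnorm(n, ps$ais_diameter, 0.2),
        is_component = draw_truncnorm(n, ps$is_component, 10),
        is_sd_ratio = pmin(draw_truncnorm(n, ps$is_sd_ratio, 0.05), 1),
        seed_cell = sample.int(.Machine$integer.max - 1L, n),
        stringsAsFactors = FALSE)
    })
  })
  manifest <- do.call(rbind, draws)
  manifest$rheobase_true_pA <- NA_real_
  cells <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cell <- list(group = row$group, animal = row$animal, cell = row$cell,
                 truth = as.list(row))
    if ("sealtest" %in% spec$signals) {
      cell$sealtest <- simulate_seal_test(
        rc_circuit_params(Rs = row$Rs, Rm = row$Rm, Cm_true = row$Cm_true),
        noise_sd = spec$sealtest_noise_sd, seed = row$seed_cell)
    }
    if ("steps" %in% spec$signals) {
      tau_m <- row$Rm * row$Cm_true / 1000    # MOhm * pF = us -> ms
      cell$steps <- simulate_lif_steps(
        Rin = row$Rm, tau_m = tau_m, Erest = row$erest,
        threshold_depol = row$threshold_depol,
        amplitudes = spec$step_amplitudes, seed = row$seed_cell + 1L)
      manifest$rheobase_true_pA[i] <- cell$steps$meta$truth$rheobase_pA
    }
    if ("ap" %in% spec$signals) {
      mono <- row$is_sd_ratio >= 0.99
      cell$ap <- simulate_ap_waveform(
        erest = row$erest, threshold = row$erest + row$threshold_depol,
        is_vps = row$is_component,
        sd_vps = if (mono) NULL else row$is_component / row$is_sd_ratio,
        ahp_shape = if (mono) "mono" else "tri",
        noise_sd = 0.01, seed = row$seed_cell + 3L)
    }
    if ("ais" %in% spec$signals) {
      cell$ais <- generate_ais_profile(
        ais_geometry_truth(start_um = 5, end_um = 5 + row$ais_length,
                           diameter_um = row$ais_diameter,
                           psf_sigma_um = spec$ais_psf_sigma_um,
                           pixel_size_um = spec$ais_pixel_um,
                           noise_sd = spec$ais_noise_sd),
        seed = row$seed_cell + 2L)
    }
    cells[[i]] <- cell
  }
  out <- list(manifest = manifest, cells = cells)
  if (!is.null(dir)) {
    write_cohort(out, dir)
    return(invisible(out))
  }
  out
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cell in cohort$cells) {
    cdir <- file.path(dir, cell$group, cell$animal, cell$cell)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cell$sealtest)) {
      write_trace(cell$sealtest, file.path(cdir, "sealtest.csv"))
    }
    if (!is.null(cell$steps)) {
      sdir <- file.path(cdir, "steps")
      dir.create(sdir, showWarnings = FALSE)
      for (k in seq_along(cell$steps$traces)) {
        write_trace(cell$steps$traces[[k]],
                    file.path(sdir, sprintf("step_%03d.csv", k)))
      }
    }
    if (!is.null(cell$ap)) {
      write_trace(cell$ap, file.path(cdir, "ap.csv"))
    }
    if (!is.null(cell$ais)) {
      write_intensity_profile(cell$ais, file.path(cdir, "ais_profile.csv"))
    }
  }
  man <- cohort$manifest
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
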