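#' Simulation scenario
#'
#' Describes a synthetic exposure study: the compounds with their
#' ground-truth Hill (4PL) parameters, the concentration series, the
#' replicate structure and the noise model.  Defaults mirror the study
#' design this package targets: a 7-point 0/0.5/1/5/10/20/50 uM series,
#' three biological x three technical replicates, DMSO vehicle controls,
#' and multiplicative lognormal well noise with 10 % CV.
#'
#' @param seed integer seed; a fixed seed makes every generated byte
#'   reproducible.
#' @param compounds data frame with columns `id, class, n_cl, top, bottom,
#'   hill, ic50_um` (ground truth per compound).
#' @param conc_grid positive exposure concentrations, uM.
#' @param n_bio,n_tech biological/technical replicates (>= 1).
#' @param noise `"lognormal"` (multiplicative, mean 1) or `"gaussian"`
#'   (additive).
#' @param cv coefficient of variation of the well noise (>= 0); for
#'   gaussian noise, the SD relative to the control signal.
#' @param n_control DMSO control wells per plate.
#' @param control_signal expected blank-corrected absorbance of a control
#'   well, AU.
#' @param blank_signal background (650 nm reference) absorbance, AU.
#' @param assay `"MTT"` (24-well layout) or `"LDH"` (96-well layout with
#'   low/high controls).
#' @param groups labels of independently simulated exposure groups (e.g.
#'   `c("male", "female")`); default a single `"all"` group.
#' @param ldh_low,ldh_high expected low-control (spontaneous) and
#'   high-control (maximum release) LDH signals, AU.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(seed,
                                compounds = default_scenario_compounds(),
                                conc_grid = DEFAULT_CONC_GRID,
                                n_bio = 3, n_tech = 3,
                                noise = c("lognormal", "gaussian"),
                                cv = 0.1, n_control = 3,
                                control_signal = 1.0, blank_signal = 0.05,
                                assay = c("MTT", "LDH"),
                                groups = "all",
                                ldh_low = 0.1, ldh_high = 1.1) {
  check_number(seed, "seed")
  noise <- match.arg(noise)
  assay <- match.arg(assay)
  check_number(cv, "cv", min = 0)
  check_number(n_bio, "n_bio", min = 1)
  check_number(n_tech, "n_tech", min = 1)
  check_number(n_control, "n_control", min = 1)
  if (!is.data.frame(compounds) ||
      !all(c("id", "top", "bottom", "hill", "ic50_um") %in% names(compounds))) {
    abort_validation("compounds must be a data frame with columns ",
                     "id, top, bottom, hill, ic50_um")
  }
  if (any(conc_grid <= 0)) {
    abort_validation("conc_grid must be positive (the vehicle control at 0 ",
                     "is added automatically)")
  }
  structure(list(seed = as.integer(seed), compounds = compounds,
                 conc_grid = sort(conc_grid), n_bio = n_bio, n_tech = n_tech,
                 noise = noise, cv = cv, n_control = n_control,
                 control_signal = control_signal, blank_signal = blank_signal,
                 assay = assay, groups = groups,
                 ldh_low = ldh_low, ldh_high = ldh_high),
            class = "simulation_scenario")
}

#' Default ground-truth compounds for simulation
#'
#' A tetrachlorobiphenyl-like triplet (parent, hydroxylated, sulfated) with
#' midpoints spanning the toxic range of the tested series, plus one
#' no-effect compound whose midpoint lies far beyond the tested range (the
#' censoring path).
#'
#' @return data frame usable as the `compounds` field of
#'   [simulation_scenario()].
#' @export
default_scenario_compounds <- function() {
  data.frame(
    id = c("parent_cl4", "oh_cl4", "sulfate_cl4", "inert_cl1"),
    class = c("parent", "hydroxylated", "sulfated", "parent"),
    n_cl = c(4L, 4L, 4L, 1L),
    top = 100, bottom = 0, hill = -1,
    ic50_um = c(8.8, 2.2, 8.4, 1000),
    stringsAsFactors = FALSE)
}

# plate formats: wells available per plate
plate_capacity <- function(assay) if (assay == "MTT") 24 else 96
plate_rows <- function(assay) if (assay == "MTT") LETTERS[1:4] else LETTERS[1:8]
plate_cols <- function(assay) if (assay == "MTT") 6 else 12

noise_factor <- function(scenario, n) {
  if (scenario$cv == 0) return(rep(1, n))
  if (scenario$noise == "lognormal") {
    sdlog <- sqrt(log(1 + scenario$cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
  } else {
    rep(1, n)  # gaussian noise is additive; handled separately
  }
}

#' Generate synthetic plate readings
#'
#' Lays out one plate per compound x biological replicate x group (24-well
#' MTT or 96-well LDH format), with `n_control` vehicle/low+high control
#' wells and `n_tech` technical-replicate wells per concentration.  The
#' expected blank-corrected signal of a well is proportional to the
#' ground-truth 4PL response at its concentration; well noise is applied
#' per the scenario's noise model.  Byte-identical output under a fixed
#' seed.
#'
#' @param scenario a [simulation_scenario()].
#' @return data frame of well readings in the long plate format consumed
#'   by [mtt_percent_viability()] / [ldh_percent_cytotoxicity()].
#' @export
generate_plate <- function(scenario) {
  if (!inherits(scenario, "simulation_scenario")) {
    abort_validation("scenario must be a simulation_scenario object")
  }
  assay <- scenario$assay
  n_ctrl_wells <- if (assay == "MTT") scenario$n_control else 2 * scenario$n_control
  wells_needed <- n_ctrl_wells + length(scenario$conc_grid) * scenario$n_tech
  if (wells_needed > plate_capacity(assay)) {
    abort_validation("scenario needs ", wells_needed, " wells per plate but ",
                     "the ", assay, " format has ", plate_capacity(assay))
  }
  set.seed(scenario$seed)

  plates <- list()
  for (g in scenario$groups) {
    for (ci in seq_len(nrow(scenario$compounds))) {
      cmp <- scenario$compounds[ci, ]
      for (b in seq_len(scenario$n_bio)) {
        if (assay == "MTT") {
          treatment <- c(rep("DMSO", scenario$n_control),
                         rep(cmp$id, length(scenario$conc_grid) * scenario$n_tech))
          conc <- c(rep(0, scenario$n_control),
                    rep(scenario$conc_grid, each = scenario$n_tech))
          tech <- c(seq_len(scenario$n_control),
                    rep(seq_len(scenario$n_tech), times = length(scenario$conc_grid)))
        } else {
          treatment <- c(rep("low_control", scenario$n_control),
                         rep("high_control", scenario$n_control),
                         rep(cmp$id, length(scenario$conc_grid) * scenario$n_tech))
          conc <- c(rep(0, 2 * scenario$n_control),
                    rep(scenario$conc_grid, each = scenario$n_tech))
          tech <- c(seq_len(scenario$n_control), seq_len(scenario$n_control),
                    rep(seq_len(scenario$n_tech), times = length(scenario$conc_grid)))
        }
        nwell <- length(treatment)
        idx <- seq_len(nwell) - 1
        ncol_fmt <- plate_cols(assay)
        resp <- ifelse(
          treatment %in% c("DMSO", "low_control", "high_control"),
          ifelse(treatment == "high_control", 100,
                 ifelse(treatment == "low_control", 0, 100)),
          four_pl(pmax(conc, .Machine$double.eps), cmp$top, cmp$bottom,
                  cmp$hill, log10(cmp$ic50_um)))

        if (assay == "MTT") {
          true_corrected <- scenario$control_signal * resp / 100
          if (scenario$noise == "gaussian" && scenario$cv > 0) {
            signal <- scenario$blank_signal + true_corrected +
              stats::rnorm(nwell, 0, scenario$cv * scenario$control_signal)
          } else {
            signal <- scenario$blank_signal +
              true_corrected * noise_factor(scenario, nwell)
          }
          signal_ref <- rep(scenario$blank_signal, nwell)
        } else {
          true_signal <- scenario$ldh_low +
            (scenario$ldh_high - scenario$ldh_low) * resp / 100
          if (scenario$noise == "gaussian" && scenario$cv > 0) {
            signal <- true_signal +
              stats::rnorm(nwell, 0, scenario$cv *
                             (scenario$ldh_high - scenario$ldh_low))
          } else {
            signal <- true_signal * noise_factor(scenario, nwell)
          }
          signal_ref <- rep(NA_real_, nwell)
        }

        plates[[length(plates) + 1]] <- data.frame(
          plate_id = paste(assay, g, cmp$id, "b", b, sep = "_"),
          assay = assay,
          row = plate_rows(assay)[idx %/% ncol_fmt + 1],
          col = idx %% ncol_fmt + 1,
          treatment = treatment, conc_um = conc,
          bio_rep = b, tech_rep = tech, group = g,
          signal = signal, signal_ref = signal_ref,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic compound library
#'
#' Builds `n_per_class` parent congeners (1-4 chlorines) with matched
#' hydroxylated and sulfated metabolites.  Descriptor gradients emulate
#' the physicochemical structure of the real compound panel: parents gain
#' hydrophobicity (V, L, E) and lose H-bond basicity with each chlorine
#' and carry Henry's law constants that decrease with chlorination;
#' hydroxylation adds H-bond acidity/basicity and polarity; sulfation adds
#' strong basicity and polarity so the sulfates stay in the aqueous
#' medium.  Small seeded jitter distinguishes congeners with equal
#' chlorine counts.
#'
#' @param seed integer seed.
#' @param n_per_class parents per library (>= 1); each gets one
#'   hydroxylated and one sulfated metabolite.
#' @return data frame in the compound-table layout of
#'   [read_compound_table()], with a `parent_id` column.
#' @export
generate_compound_library <- function(seed, n_per_class = 5) {
  check_number(seed, "seed")
  check_number(n_per_class, "n_per_class", min = 1)
  set.seed(as.integer(seed))
  n_cl <- rep(1:4, length.out = n_per_class)

  jit <- function(n, amp) stats::runif(n, -amp, amp)
  parents <- data.frame(
    id = sprintf("P%02d_cl%d", seq_len(n_per_class), n_cl),
    name = sprintf("parent congener %d (%d Cl)", seq_len(n_per_class), n_cl),
    class = "parent", n_cl = n_cl,
    E = 1.36 + 0.12 * n_cl + jit(n_per_class, 0.02),
    S = 0.99 + 0.06 * n_cl + jit(n_per_class, 0.02),
    A = 0,
    B = pmax(0, 0.26 - 0.04 * n_cl + jit(n_per_class, 0.01)),
    V = 1.3242 + 0.1224 * n_cl,
    L = 6.014 + 0.66 * n_cl + jit(n_per_class, 0.05),
    H_ref = 50 * 0.88^(n_cl - 1) * stats::runif(n_per_class, 0.9, 1.1),
    T_ref = 298.15,
    dU_aw = 52000 + 1000 * n_cl,
    smiles = NA_character_, parent_id = NA_character_,
    stringsAsFactors = FALSE)

  oh <- parents
  oh$id <- sub("^P", "H", parents$id)
  oh$name <- sub("parent congener", "hydroxylated metabolite of congener",
                 parents$name)
  oh$class <- "hydroxylated"
  oh$E <- parents$E + 0.15
  oh$S <- parents$S + 0.55
  oh$A <- 0.60
  oh$B <- parents$B + 0.28
  oh$V <- parents$V + 0.1175
  oh$L <- parents$L + 0.70
  oh$H_ref <- NA_real_; oh$T_ref <- NA_real_; oh$dU_aw <- NA_real_
  oh$parent_id <- parents$id

  su <- parents
  su$id <- sub("^P", "S", parents$id)
  su$name <- sub("parent congener", "sulfated metabolite of congener",
                 parents$name)
  su$class <- "sulfated"
  su$E <- parents$E + 0.30
  su$S <- parents$S + 1.70
  su$A <- 0
  su$B <- parents$B + 1.80
  su$V <- parents$V + 0.467
  su$L <- parents$L + 2.00
  su$H_ref <- NA_real_; su$T_ref <- NA_real_; su$dU_aw <- NA_real_
  su$parent_id <- parents$id

  out <- rbind(parents, oh, su)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study bundle
#'
#' Composes [generate_compound_library()] and [generate_plate()] into a
#' ready-to-run input set and (optionally) writes every external-interface
#' file: the compound table, the plate readings, the geometry config, the
#' PP-LFER registry and the scenario record.
#'
#' @param scenario a [simulation_scenario()].
#' @param dir output directory; created if needed.  `NULL` skips writing.
#' @param geom a [system_geometry()] for the partition side of the bundle.
#' @param registry PP-LFER registry to ship with the bundle.
#' @param n_per_class parents per class in the generated compound library.
#' @return list with `compounds`, `plates`, `geom`, `registry`, `scenario`
#'   and, when `dir` is given, `paths`.
#' @export
generate_study <- function(scenario, dir = NULL,
                           geom = system_geometry(),
                           registry = default_pplfer_registry(),
                           n_per_class = 5) {
  if (!inherits(scenario, "simulation_scenario")) {
    abort_validation("scenario must be a simulation_scenario object")
  }
  compounds <- generate_compound_library(scenario$seed + 1L, n_per_class)
  plates <- generate_plate(scenario)
  bundle <- list(compounds = compounds, plates = plates, geom = geom,
                 registry = registry, scenario = scenario)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      compounds = file.path(dir, "compounds.csv"),
      plates = file.path(dir, "plates.csv"),
      geometry = file.path(dir, "geometry.yml"),
      registry = file.path(dir, "registry.yml"),
      scenario = file.path(dir, "scenario.yml"))
    utils::write.csv(compounds, paths$compounds, row.names = FALSE)
    utils::write.csv(plates, paths$plates, row.names = FALSE)
    write_geometry(geom, paths$geometry)
    write_pplfer_registry(registry, paths$registry)
    scen <- unclass(scenario)
    scen$compounds <- lapply(seq_len(nrow(scenario$compounds)), function(i) {
      as.list(scenario$compounds[i, ])
    })
    yaml::write_yaml(scen, paths$scenario)
    bundle$paths <- paths
  }
  bundle
}
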