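#' Cellular composition
#'
#' Per-cell volumes of the three intracellular phases.  Defaults are the
#' measured protein, lipid and water content of C6 glioma cells
#' (1.18e-4, 9.57e-5 and 2.84e-6 uL/cell).
#'
#' @param v_pro,v_lip,v_wat per-cell protein/lipid/water volumes, uL/cell,
#'   all >= 0.
#' @return An object of class `cell_composition`.
#' @export
cell_composition <- function(v_pro = DEFAULT_V_PRO_PER_CELL,
                             v_lip = DEFAULT_V_LIP_PER_CELL,
                             v_wat = DEFAULT_V_WAT_PER_CELL) {
  check_number(v_pro, "v_pro", min = 0)
  check_number(v_lip, "v_lip", min = 0)
  check_number(v_wat, "v_wat", min = 0)
  structure(list(v_pro = v_pro, v_lip = v_lip, v_wat = v_wat),
            class = "cell_composition")
}

#' Exposure-system geometry
#'
#' Abiotic and biotic dimensions of one exposure well: medium volume,
#' headspace air volume, cell number, temperature, and the per-cell phase
#' composition.  Defaults describe a 24-well format (500 uL medium, 2000 uL
#' headspace, 2e5 cells) at 37 C.
#'
#' @param V_m medium volume, uL (> 0).
#' @param V_a air headspace volume, uL (>= 0).
#' @param n_cells number of cells (>= 0).
#' @param T temperature, K.
#' @param composition a [cell_composition()].
#' @return An object of class `system_geometry`.
#' @export
system_geometry <- function(V_m = DEFAULT_V_MEDIUM, V_a = DEFAULT_V_AIR,
                            n_cells = DEFAULT_N_CELLS,
                            T = DEFAULT_TEMPERATURE_K,
                            composition = cell_composition()) {
  check_number(V_m, "V_m")
  if (V_m <= 0) abort_validation("V_m must be > 0")
  check_number(V_a, "V_a", min = 0)
  check_number(n_cells, "n_cells", min = 0)
  check_number(T, "T")
  if (T <= 0) abort_validation("T must be > 0")
  if (!inherits(composition, "cell_composition")) {
    abort_validation("composition must be a cell_composition object")
  }
  structure(list(V_m = V_m, V_a = V_a, n_cells = n_cells, T = T,
                 composition = composition),
            class = "system_geometry")
}

#' Dimensionless phase loadings of the exposure system
#'
#' Converts geometry into the dimensionless ratios that multiply the
#' partition coefficients in the mass balance: the volumetric protein,
#' lipid and water concentrations of the cells in the medium
#' (`n_cells * v_x / V_m`) and the headspace/medium volume ratio
#' (`V_a / V_m`).
#'
#' @param geom a [system_geometry()].
#' @return An object of class `phase_loadings` with fields `pro_frac`,
#'   `lip_frac`, `wat_frac`, `air_ratio`.
#' @export
phase_loadings <- function(geom) {
  if (!inherits(geom, "system_geometry")) {
    abort_validation("geom must be a system_geometry object")
  }
  comp <- geom$composition
  structure(list(pro_frac = geom$n_cells * comp$v_pro / geom$V_m,
                 lip_frac = geom$n_cells * comp$v_lip / geom$V_m,
                 wat_frac = geom$n_cells * comp$v_wat / geom$V_m,
                 air_ratio = geom$V_a / geom$V_m),
            class = "phase_loadings")
}

as_phase_loadings <- function(loads) {
  if (inherits(loads, "phase_loadings")) return(loads)
  for (nm in c("pro_frac", "lip_frac", "wat_frac", "air_ratio")) {
    check_number(loads[[nm]], nm, min = 0)
  }
  structure(loads[c("pro_frac", "lip_frac", "wat_frac", "air_ratio")],
            class = "phase_loadings")
}

as_partition_set <- function(k) {
  if (inherits(k, "partition_coefficient_set")) return(k)
  partition_coefficient_set(k$K_lip_w, k$K_pro_w, k$K_air_w)
}

#' Equilibrium phase fractions of the exposure system
#'
#' Closed-form solution of the equilibrium mass balance.  With
#' `D = 1 + K_pro/w * pro_frac + K_lip/w * lip_frac + K_air/w * air_ratio`,
#' the mass fractions are `f_fre = 1/D`, `f_pro = K_pro/w * pro_frac / D`,
#' `f_lip = K_lip/w * lip_frac / D` and `f_air = K_air/w * air_ratio / D`;
#' they sum to one.  The grouped cell-associated fraction adds the cytosolic
#' share of the freely dissolved pool:
#' `f_cell = f_pro + f_lip + f_fre * wat_frac`.
#'
#' @param k a [partition_coefficient_set()] (or a list with `K_lip_w`,
#'   `K_pro_w`, `K_air_w`).
#' @param loads a [phase_loadings()] (or a list with the four ratios).
#' @return An object of class `system_fractions` with fields `f_fre`,
#'   `f_pro`, `f_lip`, `f_air`, `f_cell`.
#' @export
system_fractions <- function(k, loads) {
  k <- as_partition_set(k)
  loads <- as_phase_loadings(loads)
  D <- 1 + k$K_pro_w * loads$pro_frac + k$K_lip_w * loads$lip_frac +
    k$K_air_w * loads$air_ratio
  f_fre <- 1 / D
  f_pro <- k$K_pro_w * loads$pro_frac / D
  f_lip <- k$K_lip_w * loads$lip_frac / D
  f_air <- k$K_air_w * loads$air_ratio / D
  structure(list(f_fre = f_fre, f_pro = f_pro, f_lip = f_lip, f_air = f_air,
                 f_cell = f_pro + f_lip + f_fre * loads$wat_frac),
            class = "system_fractions")
}

#' Intracellular distribution of a chemical
#'
#' Distribution at equilibrium over the three phases inside the cell
#' (storage lipid, protein, cytosolic water): with
#' `Z = K_lip/w * v_lip + K_pro/w * v_pro + v_wat`,
#' `g_lip = K_lip/w * v_lip / Z`, `g_pro = K_pro/w * v_pro / Z`,
#' `g_wat = v_wat / Z`.  The three fractions sum to one.
#'
#' @param k a [partition_coefficient_set()].
#' @param comp a [cell_composition()]; at least one per-cell volume must be
#'   positive.
#' @return An object of class `cell_fractions` with `g_lip`, `g_pro`,
#'   `g_wat`.
#' @export
intracellular_fractions <- function(k, comp = cell_composition()) {
  k <- as_partition_set(k)
  if (!inherits(comp, "cell_composition")) {
    abort_validation("comp must be a cell_composition object")
  }
  num_lip <- k$K_lip_w * comp$v_lip
  num_pro <- k$K_pro_w * comp$v_pro
  num_wat <- comp$v_wat
  Z <- num_lip + num_pro + num_wat
  if (Z <= 0) {
    abort_validation("degenerate cell composition: all intracellular phase ",
                     "capacities are zero")
  }
  structure(list(g_lip = num_lip / Z, g_pro = num_pro / Z, g_wat = num_wat / Z),
            class = "cell_fractions")
}

#' Partition profile of a compound library
#'
#' Runs [build_partition_set()], [system_fractions()] and
#' [intracellular_fractions()] for every compound and returns one tidy row
#' per compound with the coefficients used, the system-level fractions
#' (medium/protein/lipid/air plus the grouped cell fraction) and the
#' intracellular distribution.
#'
#' @param compounds a list of [compound_record()] or a compound-table data
#'   frame ([read_compound_table()], [generate_compound_library()]).
#' @param geom a [system_geometry()].
#' @param registry a PP-LFER registry list (see [default_pplfer_registry()]).
#' @param ... passed to [build_partition_set()].
#' @return data frame with columns `id, class, n_cl, K_lip_w, K_pro_w,
#'   K_air_w, f_fre, f_pro, f_lip, f_air, f_cell, g_lip, g_pro, g_wat`.
#' @export
partition_profile <- function(compounds, geom = system_geometry(),
                              registry = default_pplfer_registry(), ...) {
  if (is.data.frame(compounds)) compounds <- as_compound_records(compounds)
  loads <- phase_loadings(geom)
  rows <- lapply(compounds, function(cmp) {
    k <- tryCatch(
      build_partition_set(cmp, registry, T = geom$T, ...),
      pcbtox_error = function(e) {
        stop_pcbtox(paste0("compound '", cmp$id, "': ", conditionMessage(e)),
                    class(e)[1])
      })
    fr <- system_fractions(k, loads)
    gr <- intracellular_fractions(k, geom$composition)
    data.frame(id = cmp$id, class = cmp$class, n_cl = cmp$n_cl,
               K_lip_w = k$K_lip_w, K_pro_w = k$K_pro_w, K_air_w = k$K_air_w,
               f_fre = fr$f_fre, f_pro = fr$f_pro, f_lip = fr$f_lip,
               f_air = fr$f_air, f_cell = fr$f_cell,
               g_lip = gr$g_lip, g_pro = gr$g_pro, g_wat = gr$g_wat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(), class = character(),
                      n_cl = integer(), K_lip_w = numeric(),
                      K_pro_w = numeric(), K_air_w = numeric(),
                      f_fre = numeric(), f_pro = numeric(),
                      f_lip = numeric(), f_air = numeric(),
                      f_cell = numeric(), g_lip = numeric(),
                      g_pro = numeric(), g_wat = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a partition profile with metadata sidecar
#'
#' Writes the tidy CSV plus a JSON metadata block (geometry, registry hash
#' and provenance notes, package version) so a profile is reproducible from
#' its outputs alone.
#'
#' @param profile data frame from [partition_profile()].
#' @param path output CSV path; metadata goes to `<path>.meta.json`.
#' @param geom,registry the inputs the profile was computed from.
#' @return `path`, invisibly.
#' @export
write_partition_profile <- function(profile, path, geom, registry) {
  utils::write.csv(profile, path, row.names = FALSE)
  meta <- list(
    geometry = list(V_m = geom$V_m, V_a = geom$V_a, n_cells = geom$n_cells,
                    T = geom$T, v_pro = geom$composition$v_pro,
                    v_lip = geom$composition$v_lip,
                    v_wat = geom$composition$v_wat),
    registry = lapply(registry, function(co) {
      list(phase_pair = co$phase_pair, basis = co$basis, note = co$note)
    }),
    registry_hash = config_hash(lapply(registry, unclass)),
    package_version = as.character(utils::packageVersion("pcbtox"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
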