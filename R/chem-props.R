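#' Abraham solute descriptors
#'
#' Bundle of the six Abraham solute descriptors used by polyparameter linear
#' free-energy relationships (PP-LFERs): excess molar refraction `E`,
#' dipolarity/polarizability `S`, hydrogen-bond acidity `A` and basicity `B`,
#' McGowan characteristic volume `V` (cm3/mol/100) and the log
#' hexadecane/air partition constant `L`.
#'
#' @param E,S,A,B,V,L finite numerics; `V` must be positive.
#' @return An object of class `abraham_descriptors`.
#' @examples
#' abraham_descriptors(E = 1.48, S = 1.05, A = 0, B = 0.22, V = 1.45, L = 6.67)
#' @export
abraham_descriptors <- function(E, S, A, B, V, L) {
  for (nm in c("E", "S", "A", "B", "V", "L")) {
    check_number(get(nm), nm)
  }
  if (V <= 0) abort_validation("V (McGowan volume) must be > 0")
  structure(list(E = E, S = S, A = A, B = B, V = V, L = L),
            class = "abraham_descriptors")
}

#' PP-LFER phase-pair coefficient set
#'
#' System coefficients of a polyparameter linear free-energy relationship
#' for one phase pair, `log10 K = c + e*E + s*S + a*A + b*B + v*V` (or
#' `+ l*L` for air-side systems).  Exactly one of `v`/`l` must be given;
#' the active coefficient determines which solute descriptor enters the
#' volume/cavity term.
#'
#' @param phase_pair label, e.g. `"lipid/water"`, `"protein/water"`,
#'   `"air/water"`.
#' @param c,e,s,a,b finite system coefficients.
#' @param v,l volume-type coefficient; supply exactly one.
#' @param basis `"volume"` if the LFER yields a dimensionless
#'   volume-per-volume K, `"mass"` if it yields L/kg (then `density` in kg/L
#'   is required to convert).
#' @param density phase density in kg/L, required when `basis = "mass"`.
#' @param note free-text provenance note carried into output metadata.
#' @return An object of class `pplfer_coefficients`.
#' @export
pplfer_coefficients <- function(phase_pair, c, e, s, a, b,
                                v = NULL, l = NULL,
                                basis = c("volume", "mass"),
                                density = NULL, note = "") {
  check_string(phase_pair, "phase_pair")
  for (nm in c("c", "e", "s", "a", "b")) check_number(get(nm), nm)
  basis <- match.arg(basis)
  if (is.null(v) == is.null(l)) {
    abort_validation("exactly one of 'v' or 'l' must be supplied for ",
                     phase_pair)
  }
  vol_type <- if (!is.null(v)) "v" else "l"
  vol_coef <- if (!is.null(v)) check_number(v, "v") else check_number(l, "l")
  if (basis == "mass") {
    check_number(density, "density", min = 0)
    if (density <= 0) abort_validation("density must be > 0")
  }
  structure(list(phase_pair = phase_pair, c = c, e = e, s = s, a = a, b = b,
                 vol_type = vol_type, vol_coef = vol_coef,
                 basis = basis, density = density, note = note),
            class = "pplfer_coefficients")
}

#' Evaluate a PP-LFER
#'
#' Computes `log10 K = c + e*E + s*S + a*A + b*B + v*V` (or `+ l*L`,
#' depending on which volume-type coefficient the set carries).
#'
#' @param d an [abraham_descriptors()] object.
#' @param coeff a [pplfer_coefficients()] object.
#' @return log10 of the partition coefficient (dimensionless on the set's
#'   `basis`).
#' @examples
#' d <- abraham_descriptors(E = 1.5, S = 1, A = 0, B = 0.2, V = 2, L = 7)
#' k <- pplfer_coefficients("lipid/water", c = 0.5, e = 1, s = -1, a = 0,
#'                          b = -3, v = 2)
#' pplfer_log_k(d, k)  # 4.4
#' @export
pplfer_log_k <- function(d, coeff) {
  if (!inherits(d, "abraham_descriptors")) {
    abort_validation("d must be an abraham_descriptors object")
  }
  if (!inherits(coeff, "pplfer_coefficients")) {
    abort_validation("coeff must be a pplfer_coefficients object")
  }
  vol_descr <- if (coeff$vol_type == "v") d$V else d$L
  coeff$c + coeff$e * d$E + coeff$s * d$S + coeff$a * d$A + coeff$b * d$B +
    coeff$vol_coef * vol_descr
}

#' Henry's law constant record
#'
#' @param H_ref Henry's law constant at the reference temperature,
#'   Pa m3/mol; must be >= 0.
#' @param T_ref reference temperature in K (default 298.15).
#' @param delta_U_aw internal energy of air-water transfer, J/mol; optional.
#'   When absent, temperature correction falls back to a configured default.
#' @return An object of class `henry_constant`.
#' @export
henry_constant <- function(H_ref, T_ref = 298.15, delta_U_aw = NULL) {
  check_number(H_ref, "H_ref", min = 0)
  check_number(T_ref, "T_ref")
  if (T_ref <= 0) abort_validation("T_ref must be > 0")
  if (!is.null(delta_U_aw)) check_number(delta_U_aw, "delta_U_aw")
  structure(list(H_ref = H_ref, T_ref = T_ref, delta_U_aw = delta_U_aw),
            class = "henry_constant")
}

#' Temperature-correct a Henry's law constant
#'
#' van't Hoff correction
#' `H(T) = H_ref * exp(-dU_aw/R * (1/T - 1/T_ref))`, with `dU_aw` the
#' internal energy of air-water transfer.  Reference-temperature constants
#' (typically 25 C) are corrected to the 37 C of the exposure system this
#' way.
#'
#' @param h a [henry_constant()] object.
#' @param T_target target temperature in K.
#' @param default_delta_U_aw value of `dU_aw` (J/mol) applied when `h`
#'   carries none.
#' @return Henry's law constant at `T_target`, Pa m3/mol.
#' @export
correct_henry_temperature <- function(h, T_target,
                                      default_delta_U_aw = DEFAULT_DELTA_U_AW) {
  if (!inherits(h, "henry_constant")) {
    abort_validation("h must be a henry_constant object")
  }
  check_number(T_target, "T_target")
  if (T_target <= 0) abort_validation("T_target must be > 0")
  dU <- if (is.null(h$delta_U_aw)) default_delta_U_aw else h$delta_U_aw
  h$H_ref * exp(-dU / R_GAS * (1 / T_target - 1 / h$T_ref))
}

#' Dimensionless air/water partition coefficient from a Henry's law constant
#'
#' `K_aw = H / (R T)` with R = 8.314 J/(mol K).
#'
#' @param H Henry's law constant, Pa m3/mol (>= 0).
#' @param T temperature, K (> 0).
#' @return dimensionless K_air/water.
#' @export
henry_to_kaw <- function(H, T) {
  check_number(H, "H", min = 0)
  check_number(T, "T")
  if (T <= 0) abort_validation("T must be > 0")
  H / (R_GAS * T)
}

#' Compound record
#'
#' One chemical of the study: a parent lower-chlorinated PCB congener or a
#' hydroxylated/sulfated metabolite, with its Abraham descriptors and
#' (optionally) a Henry's law constant.
#'
#' @param id short unique identifier.
#' @param class one of `"parent"`, `"hydroxylated"`, `"sulfated"`.
#' @param n_cl number of chlorine substituents (0-10).
#' @param descriptors an [abraham_descriptors()] object.
#' @param name display name (defaults to `id`).
#' @param henry optional [henry_constant()]; the preferred air/water route
#'   for volatile parents.
#' @param smiles optional SMILES string (not interpreted).
#' @param parent_id optional id of the parent congener for metabolites.
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(id, class, n_cl, descriptors, name = id,
                            henry = NULL, smiles = NULL, parent_id = NULL) {
  check_string(id, "id")
  check_class_label(class)
  check_number(n_cl, "n_cl", min = 0)
  if (n_cl != round(n_cl) || n_cl > 10) {
    abort_validation("n_cl must be an integer between 0 and 10")
  }
  if (!inherits(descriptors, "abraham_descriptors")) {
    abort_validation("descriptors must be an abraham_descriptors object")
  }
  if (!is.null(henry) && !inherits(henry, "henry_constant")) {
    abort_validation("henry must be a henry_constant object or NULL")
  }
  structure(list(id = id, name = name, class = class, n_cl = as.integer(n_cl),
                 descriptors = descriptors, henry = henry, smiles = smiles,
                 parent_id = parent_id),
            class = "compound_record")
}

#' Partition coefficient set
#'
#' The three dimensionless (volume/volume) equilibrium partition
#' coefficients of one chemical at system temperature: lipid/water,
#' protein/water and air/water.
#'
#' @param K_lip_w,K_pro_w,K_air_w dimensionless coefficients, all >= 0.
#' @param T system temperature in K (metadata).
#' @param meta optional list of provenance notes.
#' @return An object of class `partition_coefficient_set`.
#' @export
partition_coefficient_set <- function(K_lip_w, K_pro_w, K_air_w,
                                      T = DEFAULT_TEMPERATURE_K, meta = list()) {
  check_number(K_lip_w, "K_lip_w", min = 0)
  check_number(K_pro_w, "K_pro_w", min = 0)
  check_number(K_air_w, "K_air_w", min = 0)
  structure(list(K_lip_w = K_lip_w, K_pro_w = K_pro_w, K_air_w = K_air_w,
                 T = T, meta = meta),
            class = "partition_coefficient_set")
}

# convert a PP-LFER log10 K to the dimensionless volume basis
lfer_k_volume_basis <- function(log_k, coeff) {
  k <- 10^log_k
  if (coeff$basis == "mass") k <- k * coeff$density  # L/kg * kg/L
  k
}

#' Assemble the partition coefficients of one compound
#'
#' `K_lip/w` and `K_pro/w` come from the registry's lipid/water and
#' protein/water PP-LFERs (converted from a mass basis to the dimensionless
#' volume basis using the registry's phase densities).  `K_air/w` is routed
#' by compound class: sulfated metabolites are treated as non-volatile
#' (`K_air/w = 0`, ionized at medium pH) unless `sulfate_nonvolatile =
#' FALSE`; otherwise a Henry's law constant, when present, is
#' temperature-corrected and divided by RT; otherwise the registry's
#' air/water PP-LFER is used.
#'
#' @param compound a [compound_record()].
#' @param registry a named list of [pplfer_coefficients()] with entries
#'   `lipid_water`, `protein_water` and optionally `air_water`; see
#'   [read_pplfer_registry()] and [default_pplfer_registry()].
#' @param T system temperature, K.
#' @param sulfate_nonvolatile force `K_air/w = 0` for class `"sulfated"`.
#' @param default_delta_U_aw passed to [correct_henry_temperature()].
#' @return A [partition_coefficient_set()].
#' @export
build_partition_set <- function(compound, registry,
                                T = DEFAULT_TEMPERATURE_K,
                                sulfate_nonvolatile = TRUE,
                                default_delta_U_aw = DEFAULT_DELTA_U_AW) {
  if (!inherits(compound, "compound_record")) {
    abort_validation("compound must be a compound_record object")
  }
  check_number(T, "T")
  for (need in c("lipid_water", "protein_water")) {
    if (is.null(registry[[need]])) {
      abort_config("coefficient registry is missing the '", need,
                   "' phase pair")
    }
  }
  d <- compound$descriptors
  K_lip <- lfer_k_volume_basis(pplfer_log_k(d, registry$lipid_water),
                               registry$lipid_water)
  K_pro <- lfer_k_volume_basis(pplfer_log_k(d, registry$protein_water),
                               registry$protein_water)

  if (compound$class == "sulfated" && sulfate_nonvolatile) {
    K_air <- 0
    air_route <- "nonvolatile (sulfated class default)"
  } else if (!is.null(compound$henry)) {
    H_T <- correct_henry_temperature(compound$henry, T,
                                     default_delta_U_aw = default_delta_U_aw)
    K_air <- henry_to_kaw(H_T, T)
    air_route <- "henry"
  } else if (!is.null(registry$air_water)) {
    K_air <- lfer_k_volume_basis(pplfer_log_k(d, registry$air_water),
                                 registry$air_water)
    air_route <- "pplfer"
  } else {
    abort_config("no air/water route for compound '", compound$id,
                 "': no Henry constant and the registry has no ",
                 "'air_water' phase pair")
  }

  partition_coefficient_set(
    K_lip, K_pro, K_air, T = T,
    meta = list(air_route = air_route,
                lipid_basis = registry$lipid_water$basis,
                protein_basis = registry$protein_water$basis)
  )
}

# ---------------------------------------------------------------------------
# registry and compound-table IO

#' Default PP-LFER coefficient registry
#'
#' Synthetic coefficient sets patterned on published storage-lipid/water and
#' muscle-protein/water systems (mass basis, converted with densities
#' 0.905 and 1.36 kg/L) and an L-based air/water system.  Illustrative, not
#' authoritative: real analyses should supply a registry from curated LFER
#' sources via [read_pplfer_registry()].
#'
#' @return Named list with `lipid_water`, `protein_water`, `air_water`.
#' @export
default_pplfer_registry <- function() {
  list(
    lipid_water = pplfer_coefficients(
      "lipid/water", c = 0.55, e = 0.78, s = -1.10, a = -0.25, b = -3.90,
      v = 3.35, basis = "mass", density = DEFAULT_LIPID_DENSITY,
      note = "synthetic; patterned on storage lipid/water systems"),
    protein_water = pplfer_coefficients(
      "protein/water", c = -0.50, e = 0.60, s = -0.60, a = -0.40, b = -2.40,
      v = 1.85, basis = "mass", density = DEFAULT_PROTEIN_DENSITY,
      note = "synthetic; patterned on muscle protein/water systems"),
    air_water = pplfer_coefficients(
      "air/water", c = 1.271, e = -0.822, s = -2.743, a = -3.904, b = -4.814,
      l = 0.213, basis = "volume",
      note = "synthetic; patterned on L-based air/water systems")
  )
}

#' Read a PP-LFER coefficient registry from YAML
#'
#' Expected layout: top-level keys are phase pairs (`lipid_water`,
#' `protein_water`, optionally `air_water`), each mapping to
#' `{c, e, s, a, b, v|l, basis, density, note}`.
#'
#' @param path YAML file path.
#' @return Named list of [pplfer_coefficients()].
#' @export
read_pplfer_registry <- function(path) {
  if (!file.exists(path)) abort_config("registry file not found: ", path)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    for (need in c("c", "e", "s", "a", "b")) {
      if (is.null(entry[[need]])) {
        abort_config("registry entry '", nm, "' is missing coefficient '",
                     need, "'")
      }
    }
    pplfer_coefficients(
      phase_pair = if (is.null(entry$phase_pair)) gsub("_", "/", nm) else entry$phase_pair,
      c = entry$c, e = entry$e, s = entry$s, a = entry$a, b = entry$b,
      v = entry$v, l = entry$l,
      basis = if (is.null(entry$basis)) "volume" else entry$basis,
      density = entry$density,
      note = if (is.null(entry$note)) "" else entry$note)
  })
  names(out) <- names(raw)
  out
}

#' Write a PP-LFER registry to YAML
#' @param registry named list of [pplfer_coefficients()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pplfer_registry <- function(registry, path) {
  raw <- lapply(registry, function(co) {
    entry <- list(phase_pair = co$phase_pair, c = co$c, e = co$e, s = co$s,
                  a = co$a, b = co$b)
    entry[[co$vol_type]] <- co$vol_coef
    entry$basis <- co$basis
    if (!is.null(co$density)) entry$density <- co$density
    entry$note <- co$note
    entry
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Read a compound table
#'
#' CSV with header `id, name, class, n_cl, E, S, A, B, V, L, H_ref, T_ref,
#' dU_aw, smiles` (extra columns such as `parent_id` are preserved).
#' Missing numeric cells must be empty, not zero; they are read as `NA`.
#'
#' @param path CSV path.
#' @return A data frame, one row per compound.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) abort_config("compound table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("id", "class", "n_cl", "E", "S", "A", "B", "V", "L")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_config("compound table is missing columns: ",
                 paste(miss, collapse = ", "))
  }
  df
}

#' Convert compound-table rows to compound records
#' @param df data frame as from [read_compound_table()] or
#'   [generate_compound_library()].
#' @return List of [compound_record()] objects.
#' @export
as_compound_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    henry <- NULL
    if (!is.null(row$H_ref) && !is.na(row$H_ref)) {
      henry <- henry_constant(
        H_ref = row$H_ref,
        T_ref = if (!is.null(row$T_ref) && !is.na(row$T_ref)) row$T_ref else 298.15,
        delta_U_aw = if (!is.null(row$dU_aw) && !is.na(row$dU_aw)) row$dU_aw else NULL)
    }
    compound_record(
      id = row$id,
      name = if (!is.null(row$name) && !is.na(row$name)) row$name else row$id,
      class = row$class, n_cl = row$n_cl,
      descriptors = abraham_descriptors(row$E, row$S, row$A, row$B,
                                        row$V, row$L),
      henry = henry,
      smiles = if (!is.null(row$smiles) && !is.na(row$smiles)) row$smiles else NULL,
      parent_id = if (!is.null(row$parent_id) && !is.na(row$parent_id)) row$parent_id else NULL)
  })
}
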