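# shared fixtures and independent oracles

fixture_compound_path <- function() {
  system.file("extdata", "compounds_synthetic.csv", package = "pcbtox")
}

fixture_registry_path <- function() {
  system.file("extdata", "pplfer_registry_synthetic.yml", package = "pcbtox")
}

# a descriptor set with distinct, easy-to-track values
make_descriptors <- function() {
  abraham_descriptors(E = 1.5, S = 1.0, A = 0.3, B = 0.2, V = 2.0, L = 7.0)
}

# registry whose LFERs are already on the volume basis (no density conversion)
make_volume_registry <- function(c_lip = 4, c_pro = 2, c_air = -2) {
  list(
    lipid_water = pplfer_coefficients("lipid/water", c = c_lip, e = 0, s = 0,
                                      a = 0, b = 0, v = 0),
    protein_water = pplfer_coefficients("protein/water", c = c_pro, e = 0,
                                        s = 0, a = 0, b = 0, v = 0),
    air_water = pplfer_coefficients("air/water", c = c_air, e = 0, s = 0,
                                    a = 0, b = 0, l = 0))
}

# small MTT plate: 3 DMSO controls plus treated wells, one plate/bio rep
make_mtt_plate <- function(control = c(0.5, 0.55, 0.45),
                           treated = data.frame(conc_um = 5, signal = 0.25),
                           blank = 0, plate_id = "p1", bio_rep = 1,
                           treatment = "cmpA") {
  ctrl <- data.frame(plate_id = plate_id, assay = "MTT",
                     row = "A", col = seq_along(control),
                     treatment = "DMSO", conc_um = 0, bio_rep = bio_rep,
                     tech_rep = seq_along(control),
                     signal = control + blank, signal_ref = blank,
                     stringsAsFactors = FALSE)
  trt <- data.frame(plate_id = plate_id, assay = "MTT",
                    row = "B", col = seq_len(nrow(treated)),
                    treatment = treatment, conc_um = treated$conc_um,
                    bio_rep = bio_rep, tech_rep = seq_len(nrow(treated)),
                    signal = treated$signal + blank, signal_ref = blank,
                    stringsAsFactors = FALSE)
  rbind(ctrl, trt)
}

# noiseless normalized 4PL dataset at the study concentration series
make_4pl_dataset <- function(top = 100, bottom = 0, hill = -1, ic50 = 10,
                             conc = c(0.5, 1, 5, 10, 20, 50), n_rep = 3) {
  df <- expand.grid(conc_um = conc, bio_rep = seq_len(n_rep))
  df$response <- four_pl(df$conc_um, top, bottom, hill, log10(ic50))
  df
}

# numerical mass-balance oracle: fix a total mass, solve for the freely
# dissolved concentration with a root finder, recompute each phase mass
# directly from the concentration products, and report mass fractions.
oracle_system_fractions <- function(K_lip_w, K_pro_w, K_air_w,
                                    pro_frac, lip_frac, wat_frac, air_ratio,
                                    V_m = 1000, m_tot = 1) {
  mass_at <- function(C_fre) {
    m_fre <- C_fre * V_m
    m_pro <- K_pro_w * C_fre * pro_frac * V_m
    m_lip <- K_lip_w * C_fre * lip_frac * V_m
    m_air <- K_air_w * C_fre * air_ratio * V_m
    c(fre = m_fre, pro = m_pro, lip = m_lip, air = m_air)
  }
  f <- function(C_fre) sum(mass_at(C_fre)) - m_tot
  upper <- m_tot / V_m
  sol <- stats::uniroot(f, lower = 0, upper = upper, tol = 1e-16)
  m <- mass_at(sol$root)
  fr <- m / m_tot
  list(f_fre = fr[["fre"]], f_pro = fr[["pro"]], f_lip = fr[["lip"]],
       f_air = fr[["air"]],
       f_cell = fr[["pro"]] + fr[["lip"]] + fr[["fre"]] * wat_frac)
}

# exhaustive grid-search 4PL oracle: dense (log10_ic50, hill) grid with the
# plateaus profiled by ordinary lm() under the same constraints the model
# defines (bottom >= bottom_min, canonical top >= bottom); independent of
# the package fitter
oracle_grid_4pl <- function(conc_um, y, bottom_min = 0,
                            l50_grid = seq(-2, 3, by = 0.05),
                            hill_grid = seq(-4, 4, by = 0.1)) {
  lx <- log10(conc_um)
  best <- list(sse = Inf)
  for (h in hill_grid) {
    if (abs(h) < 1e-9) next
    for (l50 in l50_grid) {
      theta <- 1 / (1 + 10^(h * (l50 - lx)))
      fit <- stats::lm(y ~ theta)
      bottom <- unname(stats::coef(fit)[1])
      top <- unname(sum(stats::coef(fit)))
      if (bottom < bottom_min) {
        fit0 <- stats::lm(I(y - bottom_min) ~ 0 + theta)
        bottom <- bottom_min
        top <- bottom_min + unname(stats::coef(fit0)[1])
        sse <- sum(stats::resid(fit0)^2)
      } else {
        sse <- sum(stats::resid(fit)^2)
      }
      if (!is.finite(top) || !is.finite(bottom)) next  # degenerate theta
      if (top < bottom) next  # mirrored duplicate exists at -h
      if (sse < best$sse) {
        best <- list(sse = sse, log10_ic50 = l50, hill = h,
                     bottom = bottom, top = top)
      }
    }
  }
  best
}

random_partition_instance <- function() {
  list(K_lip_w = 10^stats::runif(1, -3, 7),
       K_pro_w = 10^stats::runif(1, -3, 5),
       K_air_w = 10^stats::runif(1, -6, 1),
       pro_frac = stats::runif(1, 0, 0.2),
       lip_frac = stats::runif(1, 0, 0.2),
       wat_frac = stats::runif(1, 0, 0.05),
       air_ratio = stats::runif(1, 0, 10))
}
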