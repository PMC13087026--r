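#' Default run configuration
#'
#' The full set of tunable parameters with their defaults, as a nested
#' list mirroring the JSON configuration layout: `solver` (N, Nt,
#' harmonics), `rheology` (beta, gamma, delta), `scales` (rho, nu_zz, R,
#' omega0, G0), `ec` (A_EC, V_EC), `curvature` (kappa_low, kappa_high,
#' mode), and `flow` (artery or explicit alpha/waveform).
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(solver = list(N = 150, Nt = 256),
       rheology = list(beta = 0.1, gamma = 0.1, delta = 1),
       scales = list(rho = .awflow_defaults$rho,
                     nu_zz = .awflow_defaults$nu_zz,
                     R = 0.012,
                     omega0 = .awflow_defaults$omega0,
                     G0 = .awflow_defaults$G0),
       ec = list(A_EC = 1e-10, V_EC = 1e-16),
       curvature = list(kappa_low = 0.35, kappa_high = 0.70,
                        mode = "bound"),
       flow = list(artery = "Thoracic Aorta"))
}

# recursively overlay user values on defaults
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a run configuration from JSON
#'
#' Reads a JSON configuration file and overlays it on [default_config()];
#' keys not present in the file keep their defaults.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- .merge_config(cfg, user)
  }
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  stopifnot(cfg$solver$N >= 2, cfg$solver$Nt >= 4)
  anisotropy_ratios(cfg$rheology$beta, cfg$rheology$gamma,
                    cfg$rheology$delta)
  with(cfg$scales, physical_scales(R = R, rho = rho, nu_zz = nu_zz,
                                   omega0 = omega0, G0 = G0))
  ec_geometry(cfg$ec$A_EC, cfg$ec$V_EC)
  stopifnot(cfg$curvature$kappa_low >= 0, cfg$curvature$kappa_high < 1,
            cfg$curvature$mode %in% c("bound", "scaling"))
  invisible(TRUE)
}

#' Write a configuration to JSON
#'
#' Round-trips with [load_run_config()].
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# deterministic CSV writer: 12 significant digits, unit-annotated headers
.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write result tables with a content manifest
#'
#' Writes each data.frame as CSV with deterministic 12-significant-digit
#' formatting, plus a `manifest.json` listing every artifact with its MD5
#' content hash.
#'
#' @param tables named list of data.frames; names become file names
#'   (without extension).
#' @param run_dir output directory (created if needed).
#' @return Invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
write_results <- function(tables, run_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    p <- file.path(run_dir, paste0(nm, ".csv"))
    .write_table(tables[[nm]], p)
    files <- c(files, p)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}

#' Run the classical-validation protocol
#'
#' Isotropic mono-harmonic solves compared against the Bessel-form
#' solution over a range of Womersley numbers.
#'
#' @param alpha_list Womersley numbers (default 3..20).
#' @param N collocation order.
#' @return A data.frame with columns `alpha` and `linf_error`.
#' @export
run_validation <- function(alpha_list = 3:20, N = 150) {
  err <- vapply(alpha_list, function(a) womersley_linf_error(a, N = N),
                numeric(1))
  data.frame(alpha = alpha_list, linf_error = err)
}

#' Run one physiological forces protocol
#'
#' Solves an artery case, computes the endothelial force series, wall
#' traction and ratio/angle diagnostics, and the force spectrum.
#'
#' @inheritParams solve_artery
#' @return List with `field_long` (r, t, u_z, u_theta, omega_theta,
#'   omega_z, ell_r, f_r long-format data.frame), `series` (t, F_EC_pN,
#'   tau_w_Pa, chi, phi), and `spectrum`.
#' @export
run_forces <- function(name, beta = 0.1, gamma = beta, delta = 1,
                       N = 150, Nt = 256, scales = NULL) {
  case <- solve_artery(name, beta, gamma, delta, N, Nt, scales)
  field <- case$field
  scales <- case$scales
  w <- vorticity(field)
  ell <- lamb_radial(field)
  f_r <- scales$rho * ell * scales$U0^2 / scales$R
  fser <- ec_force(field, scales)
  tensor <- tensor_from_ratios(scales$nu_zz,
                               anisotropy_ratios(beta, gamma, delta))
  tau_w <- wall_traction(field, tensor, scales)
  Fz <- abs(tau_w) * 1e-10                      # A_ref = 100 um^2
  Fr <- near_wall_force_proxy(field, scales)
  ra <- force_ratio_angle(Fr, Fz)
  nds <- field$grid$nodes
  field_long <- data.frame(
    r = rep(nds, times = length(field$times)),
    t = rep(field$times, each = length(nds)),
    u_z = as.vector(field$uz), u_theta = as.vector(field$utheta),
    omega_theta = as.vector(w$omega_theta),
    omega_z = as.vector(w$omega_z),
    ell_r = as.vector(ell), f_r_N_m3 = as.vector(f_r))
  series <- data.frame(t = field$times, F_EC_pN = fser$F_EC_pN,
                       tau_w_Pa = tau_w, chi = ra$chi, phi_rad = ra$phi)
  list(field_long = field_long, series = series,
       spectrum = force_spectrum(fser, H_report = 6), case = case)
}

#' Reproduce the full analysis suite
#'
#' Runs validation, the mono-harmonic sweep, the grid-independence study,
#' the six-artery force/statistics protocol and the dominance comparison,
#' writing every table plus the effective configuration and a manifest
#' into `out_dir`. Problem sizes are configurable; the defaults match the
#' production settings.
#'
#' @param out_dir output directory.
#' @param cfg configuration list from [load_run_config()].
#' @param sweep_alpha,sweep_beta sweep grids.
#' @return Invisibly, the manifest data.frame.
#' @export
reproduce_all <- function(out_dir, cfg = default_config(),
                          sweep_alpha = seq(1, 25, by = 0.5),
                          sweep_beta = seq(0, 0.1, by = 0.0125)) {
  N <- cfg$solver$N
  Nt <- cfg$solver$Nt
  beta <- cfg$rheology$beta
  gamma <- cfg$rheology$gamma
  delta <- cfg$rheology$delta
  reg <- artery_registry()

  tables <- list()
  tables$validation <- run_validation(N = N)
  tables$sweep <- sweep_mono(sweep_alpha, sweep_beta, N = N)
  tables$grid_independence <- grid_independence(beta = beta)

  groups <- list()
  spec_rows <- list()
  for (nm in reg$name) {
    fr <- run_forces(nm, beta, gamma, delta, N = N, Nt = Nt)
    key <- gsub("[^a-z0-9]+", "_", tolower(nm))
    tables[[paste0("forces_", key)]] <- fr$series
    groups[[nm]] <- fr$series$F_EC_pN
    spec_rows[[nm]] <- cbind(artery = nm, fr$spectrum)
  }
  tables$spectrum <- do.call(rbind, c(spec_rows, make.row.names = FALSE))

  aortic <- solve_artery("Aortic Root", beta, gamma, delta, N = N, Nt = Nt)
  tables$dominance <- dominance_spectrum(
    aortic$field, aortic$scales, ec_geometry(cfg$ec$A_EC, cfg$ec$V_EC),
    kappa_low = cfg$curvature$kappa_low,
    kappa_high = cfg$curvature$kappa_high,
    mode = cfg$curvature$mode)

  kw <- kruskal_wallis(groups)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(kw, file.path(out_dir, "kruskal.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_config(cfg, file.path(out_dir, "effective_config.json"))
  manifest <- write_results(tables, out_dir)
  invisible(manifest)
}
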