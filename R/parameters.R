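#' Physiological and geometric parameters of the cortisol transport model
#'
#' Constructs the parameter set of the blood-to-sweat cortisol transport
#' model. Defaults are literature values for a lumped single-gland system:
#' capillary Starling filtration, free-cortisol exchange into the
#' interstitial fluid (ISF), advection-diffusion through the ISF, Fickian
#' exchange across the sweat-gland wall, dilution on entry into the duct,
#' and a first-order enzymatic (11beta-HSD2) sink along the duct.
#'
#' All values are SI except pressures (mmHg, as conventional for Starling
#' calculations; the hydraulic conductivity `L_pc` carries the matching
#' per-mmHg unit so products are SI).
#'
#' @param P_c Capillary hydrostatic pressure \[mmHg\].
#' @param P_ISF Interstitial hydrostatic pressure \[mmHg\].
#' @param L_pc Capillary hydraulic conductivity \[m s^-1 mmHg^-1\].
#' @param k_DE Generalized dermal clearance constant for steroids \[s^-1\].
#' @param D_sg_wall Cortisol diffusion coefficient across the gland wall
#'   \[m^2 s^-1\].
#' @param D_ISF Cortisol diffusion coefficient in the ISF \[m^2 s^-1\].
#' @param D_sg Cortisol diffusion coefficient in sweat \[m^2 s^-1\].
#' @param A_sg Luminal (effective) area of the sweat gland \[m^2\].
#' @param A_c Effective capillary surface area \[m^2\].
#' @param A_ISF Effective ISF cross-sectional area \[m^2\].
#' @param V_p Effective capillary compartment volume \[m^3\].
#' @param V_ISF Effective ISF compartment volume \[m^3\].
#' @param alpha Free-cortisol fraction of total blood cortisol
#'   (dimensionless, 0-1). About 5% of circulating cortisol is unbound to
#'   CBG/albumin and available for transport.
#' @param K_wc Water-to-cortisol volumetric flow-rate ratio (dimensionless);
#'   controls dilution at the duct entry.
#' @param h_sg Sweat-gland wall thickness \[m\].
#' @param S_enzyme 11beta-HSD2 turnover rate \[s^-1\]; first-order
#'   cortisol-to-cortisone conversion along the duct. No literature value
#'   is available; the default 0 disables the sink, and the rate is
#'   typically personalized or supplied via configuration.
#' @param u_passive Passive-sweating reference velocity \[m s^-1\] used to
#'   normalize duct sweat velocity. Default is the duct velocity obtained
#'   at unit normalized sweat velocity with the default geometry, so that
#'   `u_sg_n = u_sweat_n` at defaults.
#' @param L_ISF ISF transport-path length (capillary-to-gland spacing
#'   scale) \[m\].
#' @param L_sg Sweat-gland duct length \[m\].
#'
#' @return An object of class `transport_parameters` (a named list).
#' @examples
#' p <- transport_parameters()
#' p$alpha
#' transport_parameters(alpha = 0.113)$alpha
#' @export
transport_parameters <- function(P_c = 30,
                                 P_ISF = -3,
                                 L_pc = 6.5e-10,
                                 k_DE = 1.01e-3,
                                 D_sg_wall = 2.84e-10,
                                 D_ISF = 2.84e-10,
                                 D_sg = 2.84e-10,
                                 A_sg = 1.96e-11,
                                 A_c = 1.5e-8,
                                 A_ISF = 2.2e-8,
                                 V_p = 3.02e-13,
                                 V_ISF = 6.0e-13,
                                 alpha = 0.05,
                                 K_wc = 20,
                                 h_sg = 5e-5,
                                 S_enzyme = 0,
                                 u_passive = 6.5e-10 * 1.5e-8 * 33 / 1.96e-11,
                                 L_ISF = 1e-4,
                                 L_sg = 2e-3) {
  p <- list(
    P_c = P_c, P_ISF = P_ISF, L_pc = L_pc, k_DE = k_DE,
    D_sg_wall = D_sg_wall, D_ISF = D_ISF, D_sg = D_sg,
    A_sg = A_sg, A_c = A_c, A_ISF = A_ISF,
    V_p = V_p, V_ISF = V_ISF,
    alpha = alpha, K_wc = K_wc, h_sg = h_sg,
    S_enzyme = S_enzyme, u_passive = u_passive,
    L_ISF = L_ISF, L_sg = L_sg
  )
  validate_transport_parameters(p)
  structure(p, class = "transport_parameters")
}

validate_transport_parameters <- function(p) {
  num1 <- function(nm) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
  }
  for (nm in names(p)) num1(nm)
  pos <- c("L_pc", "k_DE", "D_sg_wall", "D_ISF", "D_sg", "A_sg", "A_c",
           "A_ISF", "V_p", "V_ISF", "h_sg", "u_passive", "L_ISF", "L_sg")
  for (nm in pos) {
    if (p[[nm]] <= 0) {
      stop(sprintf("parameter '%s' must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (p$alpha < 0 || p$alpha > 1) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  if (p$K_wc < 0) stop("'K_wc' must be non-negative", call. = FALSE)
  if (p$S_enzyme < 0) stop("'S_enzyme' must be non-negative", call. = FALSE)
  invisible(p)
}

#' Update a transport parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p A [transport_parameters()] object.
#' @param ... Named parameter replacements.
#' @return A `transport_parameters` object.
#' @examples
#' p <- update_parameters(transport_parameters(), alpha = 0.08)
#' @export
update_parameters <- function(p, ...) {
  stopifnot(inherits(p, "transport_parameters"))
  repl <- list(...)
  if (length(repl) == 0L) return(p)
  if (is.null(names(repl)) || any(names(repl) == "")) {
    stop("all replacements must be named", call. = FALSE)
  }
  bad <- setdiff(names(repl), names(p))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p[names(repl)] <- repl
  validate_transport_parameters(p)
  structure(p, class = "transport_parameters")
}

#' @export
print.transport_parameters <- function(x, ...) {
  cat("Cortisol transport model parameters\n")
  df <- data.frame(value = unlist(x))
  print(format(df, digits = 4))
  invisible(x)
}

#' Read transport parameters from a YAML or JSON configuration file
#'
#' Keys must be named exactly as the fields of [transport_parameters()];
#' omitted keys take the defaults. The shipped fixture
#' `system.file("extdata", "table1.yaml", package = "sweatcort")` holds
#' the literature parameter table.
#'
#' @param path Path to a YAML (or JSON, which YAML parses) file.
#' @return A `transport_parameters` object.
#' @examples
#' cfg <- system.file("extdata", "table1.yaml", package = "sweatcort")
#' read_transport_config(cfg)$K_wc
#' @export
read_transport_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(transport_parameters))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(transport_parameters, lapply(vals, as.numeric))
}

#' Spatial discretization and steady-state solver controls
#'
#' The forward model is solved by the method of lines on uniform 1-D grids
#' over the ISF path and the gland duct, integrated in time with a stiff
#' solver until the surface sweat cortisol concentration stops changing.
#'
#' @param n_ISF Grid points along the ISF transport path (>= 3).
#' @param n_sg Grid points along the sweat-gland duct (>= 3).
#' @param steady_tol Relative change of the surface concentration over one
#'   characteristic-time checkpoint below which the solution is declared
#'   steady (dimensionless, > 0).
#' @param max_time Simulated-time cap \[s\] before the solver gives up and
#'   flags non-convergence.
#' @return An object of class `discretization`.
#' @examples
#' discretization(n_ISF = 60, n_sg = 90)
#' @export
discretization <- function(n_ISF = 40, n_sg = 60,
                           steady_tol = 1e-8, max_time = 1e7) {
  stopifnot(is.numeric(n_ISF), length(n_ISF) == 1L, n_ISF >= 3,
            is.numeric(n_sg), length(n_sg) == 1L, n_sg >= 3,
            is.numeric(steady_tol), steady_tol > 0,
            is.numeric(max_time), max_time > 0)
  structure(list(n_ISF = as.integer(n_ISF), n_sg = as.integer(n_sg),
                 steady_tol = steady_tol, max_time = max_time),
            class = "discretization")
}

#' Unit conversions between nmol/L and mol/m^3
#'
#' Internal model state is SI (mol m^-3); measurement I/O uses nmol L^-1.
#' The fixed conversion is 1 nmol L^-1 = 1e-6 mol m^-3.
#'
#' @param x Numeric vector of concentrations.
#' @return Converted numeric vector.
#' @examples
#' nmol_l_to_mol_m3(355)   # 3.55e-4
#' mol_m3_to_nmol_l(1e-6)  # 1
#' @export
nmol_l_to_mol_m3 <- function(x) x * 1e-6

#' @rdname nmol_l_to_mol_m3
#' @export
mol_m3_to_nmol_l <- function(x) x * 1e6
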