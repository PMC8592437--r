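# Parameter containers for the two disease models. Values are plain named
# lists with a class tag; `free_names` marks the patient-specific subset that
# mechanistic refitting optimizes (the remaining parameters are global
# treatment-dynamics constants shared by the whole cohort).

.AML_PAR_NAMES <- c("t_QA_H", "t_AQ_H", "p_H", "d_H",
                    "t_QA_L", "t_AQ_L", "p_L", "d_L",
                    "K_Q", "K_A", "c")
.CML_PAR_NAMES <- c("p_XY", "p_YX", "p_Y", "K_Y", "e_TKI",
                    "m", "p_Z", "K_Z", "r_Z", "a",
                    "X0", "Y0", "Z0")
.AML_FREE_DEFAULT <- c("p_L", "t_QA_L")
.CML_FREE_DEFAULT <- c("p_XY", "p_YX", "e_TKI", "m", "p_Z", "K_Z", "Z0")

#' AML model parameters
#'
#' Eleven parameters of the four-compartment AML stem-cell model: healthy
#' (`_H`) and leukemic (`_L`) cells switch between a quiescent state Q
#' (carrying capacity `K_Q`) and an active state A (carrying capacity `K_A`)
#' with activation rates `t_QA_*` and deactivation rates `t_AQ_*`; active
#' cells proliferate with rate `p_*`, differentiate out of the stem-cell
#' pool with rate `d_*`, and are killed with rate `c` while chemotherapy is
#' administered. All rates are per day, capacities in cells.
#'
#' @param t_QA_H,t_AQ_H,p_H,d_H healthy-cell rates (per day).
#' @param t_QA_L,t_AQ_L,p_L,d_L leukemic-cell rates (per day).
#' @param K_Q,K_A carrying capacities of the quiescent and active niche.
#' @param c chemotherapy kill rate (per day) acting on active cells.
#' @param free_names names of the patient-specific parameters (default
#'   `p_L` and `t_QA_L`: regrowth speed and quiescence exit of the leukemic
#'   clone, the two quantities that shape nadir depth and relapse kinetics).
#' @return an object of class `aml_parameters`.
#' @export
aml_parameters <- function(t_QA_H = 0.02, t_AQ_H = 0.05, p_H = 0.15,
                           d_H = 0.05, t_QA_L = 0.1, t_AQ_L = 0.002,
                           p_L = 0.15, d_L = 0.05, K_Q = 1e5, K_A = 1e6,
                           c = 1.2, free_names = .AML_FREE_DEFAULT) {
  p <- list(t_QA_H = t_QA_H, t_AQ_H = t_AQ_H, p_H = p_H, d_H = d_H,
            t_QA_L = t_QA_L, t_AQ_L = t_AQ_L, p_L = p_L, d_L = d_L,
            K_Q = K_Q, K_A = K_A, c = c)
  validate_parameters(p, .AML_PAR_NAMES, free_names)
  structure(c(p, list(free_names = free_names)), class = "aml_parameters")
}

#' CML model parameters
#'
#' Thirteen quantities of the three-compartment CML model: quiescent (`X`)
#' and active (`Y`) leukemic stem cells exchange with rates `p_XY` (X to Y)
#' and `p_YX` (Y to X); active cells grow logistically with maximal rate
#' `p_Y` and capacity `K_Y`, are killed by TKI therapy at rate
#' `e_TKI * dose(t)` and by immune effector cells `Z` at rate `m * Z`.
#' Immune cells are produced at rate `r_Z`, decay at rate `a`, and are
#' recruited following an immune-window response `p_Z * Z * Y / (K_Z + Y^2)`
#' that peaks at an intermediate leukemia level `Y = sqrt(K_Z)`. All rates
#' are per month. `X0`, `Y0`, `Z0` are the initial cell counts at diagnosis.
#'
#' @param p_XY,p_YX,p_Y,K_Y,e_TKI,m,p_Z,K_Z,r_Z,a model rates and constants.
#' @param X0,Y0,Z0 initial conditions (cells).
#' @param free_names patient-specific subset (default: the seven quantities
#'   governing reservoir exchange, TKI response and immune control).
#' @return an object of class `cml_parameters`.
#' @export
cml_parameters <- function(p_XY = 0.03, p_YX = 0.005, p_Y = 1.0, K_Y = 1e6,
                           e_TKI = 2.5, m = 0.01, p_Z = 60, K_Z = 1e4,
                           r_Z = 20, a = 0.2, X0 = 1e4, Y0 = 1e6, Z0 = 100,
                           free_names = .CML_FREE_DEFAULT) {
  p <- list(p_XY = p_XY, p_YX = p_YX, p_Y = p_Y, K_Y = K_Y, e_TKI = e_TKI,
            m = m, p_Z = p_Z, K_Z = K_Z, r_Z = r_Z, a = a,
            X0 = X0, Y0 = Y0, Z0 = Z0)
  validate_parameters(p, .CML_PAR_NAMES, free_names)
  structure(c(p, list(free_names = free_names)), class = "cml_parameters")
}

validate_parameters <- function(p, expected, free_names) {
  if (!identical(names(p), expected))
    stop("parameter set must contain exactly: ", paste(expected, collapse = ", "))
  vals <- unlist(p)
  stopif_nonfinite(vals, "parameter set")
  if (any(vals < 0)) stop("all rates and capacities must be >= 0")
  caps <- intersect(c("K_Q", "K_A", "K_Y"), expected)
  if (any(unlist(p[caps]) <= 0)) stop("carrying capacities must be > 0")
  if (!all(free_names %in% expected))
    stop("unknown free parameter name(s): ",
         paste(setdiff(free_names, expected), collapse = ", "))
  if (anyDuplicated(free_names)) stop("duplicated free parameter names")
  invisible(TRUE)
}

disease_of <- function(params) {
  if (inherits(params, "aml_parameters")) return("AML")
  if (inherits(params, "cml_parameters")) return("CML")
  stop("params must be aml_parameters or cml_parameters")
}

# rate vectors in the order the compiled integrator expects
aml_rate_vector <- function(p) unlist(p[.AML_PAR_NAMES])
cml_rate_vector <- function(p) unlist(p[.CML_PAR_NAMES[1:10]])

# replace a subset of parameters, preserving class and free_names
set_parameters <- function(params, values) {
  for (nm in names(values)) params[[nm]] <- unname(values[nm])
  params
}
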