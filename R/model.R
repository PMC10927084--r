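# Model parameters, scaling factors and the explicit-Euler simulation wrapper.

# parameter order must match the ParIdx enum in src/wg_model.cpp
.wg_param_names <- c(
  "k_max", "J_Caslmyo", "P_Ca", "G_Ks", "I_NCX_bar",
  "G_Na", "G_Nab", "G_Cab", "G_tof", "G_Kr", "G_K1", "I_NaK_bar", "I_pCa_bar",
  "V_max_up", "K_mf", "K_mr", "h_up", "tau_tr", "k_leak", "J_Cajuncsl",
  "Na_i", "K_i", "Na_o", "K_o", "Ca_o", "Temp",
  "k_oCa", "k_om", "k_iCa", "k_im", "EC50_SR", "Max_SR", "Min_SR",
  "K_dact", "K_mCai", "K_mCao", "K_mNai", "K_mNao", "k_sat", "nu",
  "K_mNaip", "K_mKo", "p_NaK", "F_junc", "F_jCaL",
  "tau_xs_scale", "tau_f_scale", "k_fCa", "H_oCa", "fss_vhalf", "fss_slope",
  "fss_flattened", "block_ca_transmembrane")

# the five adjustable parameters exposed to multiplicative scaling
.wg_alpha_names <- c("k_max", "J_Caslmyo", "P_Ca", "G_Ks", "I_NCX_bar")

.wg_control_values <- function() {
  v <- c(
    k_max      = 0.2,         # ms^-1, maximal SR release rate constant
    J_Caslmyo  = 7.4485e-13,  # l/ms, SL <-> cytosol Ca diffusive strength
    P_Ca       = 0.00027,     # cm/s, L-type Ca permeability
    G_Ks       = 1.23,        # mS/uF, maximal I_Ks conductance
    I_NCX_bar  = 5,           # A/F, NCX current density
    G_Na       = 16,
    G_Nab      = 2.97e-4,
    G_Cab      = 2.513e-4,
    G_tof      = 0.06,
    G_Kr       = 0.022,
    G_K1       = 0.6,
    I_NaK_bar  = 1.90719,
    I_pCa_bar  = 0.0673,
    V_max_up   = 5.3114e-3,   # mM/ms (cytosolic volume)
    K_mf       = 2.46e-4,
    K_mr       = 1.7,
    h_up       = 1.787,
    tau_tr     = 25,          # ms, NSR -> JSR refill
    k_leak     = 5e-6,        # ms^-1, JSR leak
    J_Cajuncsl = 1.65e-13,    # l/ms, JXN <-> SL diffusion
    Na_i       = 10,
    K_i        = 135,
    Na_o       = 140,
    K_o        = 5.4,
    Ca_o       = 1.8,
    Temp       = 310,
    k_oCa      = 3000,        # mM^-H ms^-1, RyR opening rate coefficient
    k_om       = 0.03,
    k_iCa      = 0.5,         # mM^-1 ms^-1, RyR inactivation
    k_im       = 0.005,
    EC50_SR    = 0.3,         # mM, luminal regulation midpoint
    Max_SR     = 30,
    Min_SR     = 1,
    K_dact     = 2.56e-4,     # mM, NCX allosteric Ca activation
    K_mCai     = 3.59e-3,
    K_mCao     = 1.3,
    K_mNai     = 12.29,
    K_mNao     = 87.5,
    k_sat      = 0.27,
    nu         = 0.35,
    K_mNaip    = 11,
    K_mKo      = 1.5,
    p_NaK      = 0.01833,
    F_junc     = 0.11,        # junctional membrane fraction (non-CaL)
    F_jCaL     = 0.9,         # junctional fraction of I_CaL
    tau_xs_scale = 4,         # slow delayed-rectifier activation slowdown
    tau_f_scale  = 1,         # voltage-dependent I_CaL inactivation slowdown
    k_fCa        = 1.3,       # mM^-1 ms^-1, Ca-dependent inactivation rate
    H_oCa        = 3,         # Hill exponent of RyR Ca-dependent opening
    fss_vhalf    = 28,        # mV, midpoint of the decreasing limb of f_ss
    fss_slope    = 5,         # mV, slope of the decreasing limb of f_ss
    fss_flattened = 0,
    block_ca_transmembrane = 0)
  stopifnot(identical(names(v), .wg_param_names))
  v
}

#' Model parameter set
#'
#' Builds the control parameter set of the ventricular myocyte model, with
#' optional multiplicative scaling factors applied to the five adjustable
#' parameters and an optional variant of the voltage-dependent steady-state
#' inactivation curve of the L-type Ca current.
#'
#' The five adjustable parameters and their control values are
#' `k_max` (0.2 ms^-1, maximal SR release rate constant),
#' `J_Caslmyo` (7.4485e-13 l/ms, submembrane-to-cytosol Ca diffusion),
#' `P_Ca` (0.00027 cm/s, L-type Ca permeability),
#' `G_Ks` (1.23 mS/uF, slow delayed-rectifier conductance) and
#' `I_NCX_bar` (5 A/F, Na/Ca-exchanger current density).
#'
#' @param alpha named numeric vector of non-negative multiplicative factors;
#'   names restricted to the five adjustable parameters.
#' @param fss `"original"` for the non-monotonic steady-state inactivation
#'   curve, `"flattened"` to hold the curve at its minimum for voltages above
#'   the argmin.
#' @param overrides named list of direct replacements for any other constant
#'   (used e.g. to zero a current in characterization protocols).
#' @return An object of class `wg_params`.
#' @export
wg_params <- function(alpha = NULL, fss = c("original", "flattened"),
                      overrides = NULL) {
  fss <- match.arg(fss)
  values <- .wg_control_values()
  if (fss == "flattened") values[["fss_flattened"]] <- 1
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), .wg_param_names)
    if (length(bad))
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    values[names(overrides)] <- unlist(overrides)
  }
  if (any(values[setdiff(.wg_param_names,
                         c("fss_flattened", "block_ca_transmembrane"))] <= 0))
    stop("all control constants must be strictly positive")
  obj <- structure(
    list(values = values,
         alpha = stats::setNames(rep(1, length(.wg_alpha_names)),
                                 .wg_alpha_names),
         scaled = FALSE,
         fss = fss),
    class = "wg_params")
  if (!is.null(alpha)) obj <- apply_scaling(obj, alpha)
  obj
}

#' Apply multiplicative scaling factors to a parameter set
#'
#' Multiplies the control value of each listed adjustable parameter by its
#' factor.  A derived parameter set carries a flag so that scaling cannot be
#' applied twice (which would compound the factors).
#'
#' @param params a `wg_params` object that has not been scaled yet.
#' @param alpha named numeric vector; names restricted to
#'   `k_max`, `J_Caslmyo`, `P_Ca`, `G_Ks`, `I_NCX_bar`; values must be
#'   non-negative.
#' @return A scaled `wg_params` object with `scaled = TRUE`.
#' @export
apply_scaling <- function(params, alpha) {
  stopifnot(inherits(params, "wg_params"))
  if (isTRUE(params$scaled))
    stop("parameter set already carries scaling factors; ",
         "apply_scaling must only be applied once")
  if (is.null(names(alpha)) || any(!nzchar(names(alpha))))
    stop("alpha must be a named vector")
  bad <- setdiff(names(alpha), .wg_alpha_names)
  if (length(bad))
    stop("alpha names must be among {",
         paste(.wg_alpha_names, collapse = ", "), "}; offending: ",
         paste(bad, collapse = ", "))
  if (any(alpha < 0)) stop("scaling factors must be non-negative")
  params$values[names(alpha)] <- params$values[names(alpha)] * alpha
  params$alpha[names(alpha)] <- alpha
  params$scaled <- TRUE
  params
}

#' @export
print.wg_params <- function(x, ...) {
  cat("<wg_params> fss =", x$fss,
      if (x$scaled) "(scaled)" else "(control)", "\n")
  a <- x$alpha[x$alpha != 1]
  if (length(a))
    cat("  alpha:", paste(names(a), "=", signif(a, 4), collapse = ", "), "\n")
  invisible(x)
}

# state order must match the StateIdx enum in src/wg_model.cpp
.wg_state_names <- c(
  "V_m", "m", "h", "j", "d", "f", "fCaB_jxn", "fCaB_sl", "x_to", "y_to",
  "x_kr", "x_ks", "ryr_r", "ryr_o", "ryr_i",
  "Ca_jxn", "Ca_sl", "Ca_i", "Ca_jsr", "Ca_nsr")

#' Resting state of the control model
#'
#' The quiescent steady state of the control parameter set, obtained by
#' integrating the unstimulated model for 60 s and frozen into the package.
#' All simulations start from this single initial condition unless another
#' is supplied.
#'
#' @return Named numeric vector of all state variables.
#' @export
wg_initial_state <- function() {
  # frozen unstimulated rest at control parameters (dt = 0.01 ms)
  stats::setNames(.wg_rest_values, .wg_state_names)
}

# crude pre-equilibration seed; only used by tools/freeze_rest.R to produce
# the frozen rest state above
.wg_seed_state <- function() {
  stats::setNames(c(
    -85, 1e-3, 0.98, 0.99, 1e-6, 1.0, 0.02, 0.01, 4e-3, 0.95,
    8e-3, 6e-3, 0.9, 1e-6, 1e-7,
    1e-4, 1e-4, 1e-4, 0.55, 0.55), .wg_state_names)
}

.as_clamp_list <- function(clamps) {
  if (is.null(clamps)) return(list())
  if (inherits(clamps, "clamp_directive")) clamps <- list(clamps)
  stopifnot(all(vapply(clamps, inherits, TRUE, "clamp_directive")))
  tg <- vapply(clamps, function(c) c$target, "")
  if (anyDuplicated(tg))
    stop("at most one clamp directive per target")
  lapply(clamps, unclass)
}

#' Evaluate the model right-hand side and currents at a state
#'
#' Returns the time derivative of every state variable together with a
#' snapshot of all membrane currents, the L-type Ca gating quantities
#' (d/f steady states and time constants, the Ca-dependent inactivation
#' factor and the voltage-dependent steady-state inactivation) and the SR
#' fluxes.  For a clamped state variable the returned derivative is exactly
#' zero; a clamped current is substituted in both the voltage equation and
#' the ion-flux equations.
#'
#' @param state named state vector (see [wg_initial_state()]).
#' @param params a `wg_params` object.
#' @param clamps optional list of [clamp_constant()] directives; only
#'   constant clamps are meaningful for a single evaluation.
#' @param t time (ms), used to decide which clamp windows are active.
#' @param I_sti stimulus current density (A/F) at this instant.
#' @return List with `deriv`, `currents`, `I_ion`, `I_sti`, `gating`,
#'   `sr_fluxes`.
#' @export
wg_derivatives <- function(state, params, clamps = NULL, t = 0, I_sti = 0) {
  stopifnot(inherits(params, "wg_params"))
  if (any(!is.finite(state))) stop("non-finite state entries")
  cl <- .as_clamp_list(clamps)
  ca <- v <- ical <- incx <- FALSE
  ical_v <- incx_v <- 0
  for (c in cl) {
    if (t < c$t_on || t >= c$t_off) next
    if (c$target == "Ca_sub") {
      ca <- TRUE
      if (is.finite(c$value)) state[c("Ca_jxn", "Ca_sl")] <- c$value
    } else if (c$target == "V_m") {
      v <- TRUE
      if (is.finite(c$value)) state["V_m"] <- c$value
    } else if (c$target == "I_CaL") {
      if (c$mode != 0L || !is.finite(c$value))
        stop("wg_derivatives supports constant current clamps with an ",
             "explicit value only")
      ical <- TRUE; ical_v <- c$value
    } else if (c$target == "I_NCX") {
      if (c$mode != 0L || !is.finite(c$value))
        stop("wg_derivatives supports constant current clamps with an ",
             "explicit value only")
      incx <- TRUE; incx_v <- c$value
    } else stop("unknown clamp target: ", c$target)
  }
  out <- .wg_rhs_cpp(unname(state[.wg_state_names]), params$values, I_sti,
                     ca, v, ical, ical_v, incx, incx_v)
  names(out$deriv) <- .wg_state_names
  out
}

#' Simulate an action potential
#'
#' Integrates the model with the explicit Euler method (reference time step
#' 0.01 ms) under a stimulation protocol and an optional set of clamp
#' directives, and returns the stored trajectory as a trace.
#'
#' @param params a `wg_params` object.
#' @param protocol a stimulation protocol from [stim_single()],
#'   [stim_s1s1()] or [stim_s1s2()].
#' @param clamps list of clamp directives (see [clamp_constant()],
#'   [make_scaled_trace_clamp()], [make_ramp_clamp()]).
#' @param t_end simulation horizon (ms).
#' @param dt integration step (ms).
#' @param stride store every `stride`-th step (default 100, i.e. 1 ms at the
#'   reference step).
#' @param init initial state; defaults to the frozen control rest state.
#' @param stop_at_repol if TRUE, stop once the AP has repolarized below
#'   `repol_threshold` and no further stimulus is pending (used by scans).
#' @param repol_threshold repolarization threshold (mV).
#' @param on_divergence `"error"` to signal numerical blow-up (|V_m| >
#'   500 mV or non-finite state) as an error carrying the failure time,
#'   `"keep"` to return the truncated trace flagged as diverged.
#' @return A `wg_trace` data.frame with columns `t_ms`, `V_m_mV`,
#'   `Ca_sub_mM`, per-compartment Ca concentrations and the stored currents;
#'   metadata (parameters, protocol, clamps, integration settings, final
#'   state) in attributes.
#' @export
simulate_ap <- function(params, protocol = stim_single(), clamps = list(),
                        t_end = 10000, dt = 0.01, stride = 100,
                        init = wg_initial_state(),
                        stop_at_repol = FALSE, repol_threshold = -75,
                        on_divergence = c("error", "keep")) {
  stopifnot(inherits(params, "wg_params"), inherits(protocol, "stim_protocol"))
  on_divergence <- match.arg(on_divergence)
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive")
  cl <- .as_clamp_list(clamps)
  res <- .wg_integrate_cpp(params$values, unname(init[.wg_state_names]),
                           t_end, dt, as.integer(stride),
                           protocol$starts, protocol$amplitude,
                           protocol$duration, cl,
                           stop_at_repol, repol_threshold)
  if (res$diverged && on_divergence == "error")
    stop(sprintf("numerical divergence at t = %.2f ms", res$t_diverged))
  tr <- as.data.frame(res$trace)
  attr(tr, "params") <- params
  attr(tr, "protocol") <- protocol
  attr(tr, "clamps") <- clamps
  attr(tr, "dt") <- dt
  attr(tr, "stride") <- stride
  attr(tr, "final_state") <- stats::setNames(res$final_state, .wg_state_names)
  attr(tr, "diverged") <- res$diverged
  attr(tr, "t_diverged") <- res$t_diverged
  attr(tr, "synthetic") <- FALSE
  class(tr) <- c("wg_trace", "data.frame")
  tr
}

#' @export
print.wg_trace <- function(x, ...) {
  cat(sprintf("<wg_trace> %d samples, t = [%g, %g] ms%s%s\n",
              nrow(x), x$t_ms[1], x$t_ms[nrow(x)],
              if (isTRUE(attr(x, "diverged"))) " [diverged]" else "",
              if (isTRUE(attr(x, "synthetic"))) " [synthetic]" else ""))
  print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Steady-state inactivation curve of the L-type Ca current
#'
#' Tabulates f_ss over a voltage grid for the original (non-monotonic)
#' formulation or the flattened variant.
#'
#' @param variant `"original"` or `"flattened"`.
#' @param v voltage grid (mV).
#' @return A `gating_curve` data.frame with columns `V_m_mV`, `f_ss` and a
#'   `variant` attribute.
#' @export
fss_curve <- function(variant = c("original", "flattened"),
                      v = seq(-90, 70, by = 0.5), params = wg_params()) {
  variant <- match.arg(variant)
  out <- data.frame(V_m_mV = v,
                    f_ss = .wg_fss_cpp(v, variant == "flattened",
                                       params$values[["fss_vhalf"]],
                                       params$values[["fss_slope"]]))
  attr(out, "variant") <- variant
  class(out) <- c("gating_curve", "data.frame")
  out
}

#' Total calcium content of a state
#'
#' Free plus rapid-equilibrium-buffered Ca over all compartments, weighted by
#' compartment volumes (mmol).  Used to verify that total Ca changes only
#' through transmembrane Ca fluxes.
#'
#' @param state named state vector.
#' @return Total Ca (mmol).
#' @export
wg_total_ca <- function(state) {
  .wg_ca_mass_cpp(unname(state[.wg_state_names]))
}

#' Cell geometry
#'
#' Compartment volumes (liters) and membrane capacitance (F).
#' @return Named numeric vector.
#' @export
wg_geometry <- function() .wg_geometry_cpp()
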