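#' Point-separator specification
#'
#' The separator at the end of the tank train is modelled as an ideal point
#' separator with a size threshold: components finer than the threshold leave
#' with the effluent at the feed concentration, components coarser than it
#' are returned with the underflow (concentrated by the flow ratio). An 8 nm
#' threshold represents a membrane at its effective filtration size and
#' retains the captured soluble pools `S_IC`/`S_HC` along with all
#' particulates; a 450 nm threshold represents gravity settling and lets the
#' captured soluble pools pass. Dissolved oxygen always passes.
#'
#' @param threshold_nm Separation threshold (nm).
#' @param escape_mg_L Particulate COD allowed to escape with the effluent
#'   (mg COD/L, default 0 = ideal separation), allocated over retained
#'   particulate components in proportion to their feed concentrations.
#' @param pass Optional explicit character vector of passing components,
#'   overriding the threshold rule.
#' @return Object of class `"separator_spec"`: list with `threshold_nm`,
#'   `pass`, `retain`, `escape_mg_L`.
#' @export
separator_spec <- function(threshold_nm = 8, escape_mg_L = 0, pass = NULL) {
  comps <- masm_components()
  if (is.null(pass)) {
    size_of <- c(fine = 2, colloid = 100, particulate = 1000, gas = 0)
    pass <- comps[size_of[component_size_class()[comps]] < threshold_nm]
  } else {
    unknown <- setdiff(pass, comps)
    if (length(unknown))
      stop("unknown component(s) in pass set: ", paste(unknown, collapse = ", "))
  }
  if (escape_mg_L < 0) stop("escape_mg_L must be non-negative")
  structure(list(threshold_nm = threshold_nm, pass = pass,
                 retain = setdiff(comps, pass), escape_mg_L = escape_mg_L),
            class = "separator_spec")
}

#' Plant configuration
#'
#' Flowsheet of the simulated plant: `n_tanks` equal completely mixed tanks
#' in series, a point separator after the last tank, return sludge to tank 1
#' at `recycle_ratio * Q`, and hydraulic wastage from the last tank at
#' `V_total / srt_d` for sludge-age control. Exactly one of `hrt_h` /
#' `V_total` must be given. Variant defaults follow practice: the membrane
#' plant (`"masm"`) uses an 8 nm threshold and recycle ratio 4, the
#' gravity-settled plant (`"asm1_mod"`) a 450 nm threshold and recycle
#' ratio 1.
#'
#' @param srt_d Sludge age theta_X (d); may be `Inf` (no wastage).
#' @param hrt_h Hydraulic retention time theta_H (h), `V_total / Q`.
#' @param V_total Total reactor volume (m^3); alternative to `hrt_h`.
#' @param Q Influent flow (m^3/d).
#' @param n_tanks Number of equal tanks in series.
#' @param variant Model variant, `"masm"` or `"asm1_mod"`.
#' @param recycle_ratio Return-sludge flow as a multiple of `Q`; default 4
#'   for `"masm"`, 1 for `"asm1_mod"`.
#' @param separator A [separator_spec()]; default by variant as above.
#' @param do_mg_L Dissolved oxygen held in all tanks (mg O2/L). Oxygen is
#'   supplied in excess and never rate-limiting; only its consumption flux is
#'   accounted.
#' @param primary_settler If `TRUE`, settleable COD `X_SS` is removed from
#'   the influent before the tanks (zeroed).
#' @return Object of class `"plant_config"`.
#' @export
plant_config <- function(srt_d, hrt_h = NULL, V_total = NULL, Q = 10000,
                         n_tanks = 3, variant = c("masm", "asm1_mod"),
                         recycle_ratio = NULL, separator = NULL,
                         do_mg_L = 8, primary_settler = FALSE) {
  variant <- match.arg(variant)
  if (Q <= 0) stop("Q must be positive")
  if (n_tanks < 1) stop("need at least one tank")
  if (is.null(hrt_h) == is.null(V_total))
    stop("give exactly one of hrt_h or V_total")
  theta_H <- if (is.null(V_total)) hrt_h / 24 else V_total / Q
  if (theta_H <= 0) stop("hydraulic retention time must be positive")
  if (srt_d < theta_H)
    stop("srt_d must be >= the hydraulic retention time (",
         signif(theta_H, 4), " d): wastage would exceed the influent flow")
  if (is.null(recycle_ratio))
    recycle_ratio <- if (variant == "masm") 4 else 1
  if (recycle_ratio < 0) stop("recycle_ratio must be non-negative")
  if (is.null(separator))
    separator <- separator_spec(if (variant == "masm") 8 else 450)
  structure(list(Q = Q, n_tanks = n_tanks, theta_H_d = theta_H,
                 V_total = Q * theta_H, srt_d = srt_d,
                 recycle_ratio = recycle_ratio, separator = separator,
                 variant = variant, do_mg_L = do_mg_L,
                 primary_settler = primary_settler),
            class = "plant_config")
}

#' Wastage flow for sludge-age control
#'
#' Hydraulic sludge-age control: mixed liquor is withdrawn from the last tank
#' at `Q_w = V_total / srt_d`, so that for equal tanks at equal retained
#' concentration the retained inventory divided by the wastage flux equals
#' the sludge age.
#'
#' @param config A [plant_config()].
#' @return Wastage flow (m^3/d).
#' @export
wastage_flow_for_srt <- function(config) {
  if (config$srt_d < config$theta_H_d)
    stop("sludge age below hydraulic retention time: infeasible wastage")
  if (is.infinite(config$srt_d)) 0 else config$V_total / config$srt_d
}

# Separator outlet concentrations from the feed concentration vector.
# F = Qe + Qr (feed), mass conserved per component.
separator_split <- function(cN, sep, F, Qe, Qr) {
  comps <- names(cN)
  eff <- cN
  eff[sep$retain] <- 0
  if (sep$escape_mg_L > 0) {
    part <- intersect(sep$retain,
                      names(which(component_size_class() == "particulate")))
    tot <- sum(cN[part])
    if (tot > 0)
      eff[part] <- pmin(cN[part], sep$escape_mg_L * cN[part] / tot)
  }
  und <- cN
  if (Qr > 0) und <- (F * cN - Qe * eff) / Qr
  list(effluent = eff, underflow = und)
}

# Time derivatives of all tank states (concentrations stacked tank-major).
# Flow terms are linear; reaction terms come from the Petersen contraction.
# Dissolved oxygen is held fixed (derivative zero).
plant_derivs <- function(y, ctx) {
  nc <- length(ctx$comps)
  C <- matrix(pmax(y, 0), nrow = nc, ncol = ctx$n,
              dimnames = list(ctx$comps, NULL))
  sp <- separator_split(C[, ctx$n], ctx$sep, ctx$F_sep, ctx$Qe, ctx$Qr)
  dy <- matrix(0, nrow = nc, ncol = ctx$n)
  Qthrough <- ctx$Q + ctx$Qr
  for (i in seq_len(ctx$n)) {
    inflow <- if (i == 1) ctx$Q * ctx$influent + ctx$Qr * sp$underflow
              else Qthrough * C[, i - 1]
    rx <- drop(crossprod(ctx$stoich, process_rates_fast(C[, i], ctx)))
    dy[, i] <- (inflow - Qthrough * C[, i]) / ctx$v + rx
  }
  dy[ctx$io_fixed, ] <- 0
  as.numeric(dy)
}

# Rate evaluation specialised for the solver loop (avoids repeated
# class checks on the hot path; same expressions as process_rates()).
process_rates_fast <- function(c_i, ctx) {
  p <- ctx$params
  XH <- c_i[["X_H"]]
  r <- numeric(6)
  SS <- c_i[["S_S"]]
  r[1] <- p$mu_H_hat * SS / (p$K_S + SS) * XH
  hyd <- function(C, k, K) {
    den <- K * XH + C
    if (den <= 0) 0 else k * C * XH / den
  }
  r[2] <- hyd(c_i[["S_H"]], p$k_hS, p$K_hS)
  if (ctx$variant == "masm") r[3] <- hyd(c_i[["S_HC"]], p$k_hS, p$K_hS)
  r[4] <- hyd(c_i[["X_S"]], p$k_hX, p$K_hX)
  r[5] <- hyd(c_i[["X_SS"]], p$k_hX, p$K_hX)
  r[6] <- p$b_H * XH
  r
}

#' Solve the plant to steady state
#'
#' Integrates the tank train with a stiff solver to `t_factor` sludge ages,
#' then polishes the stationary point with a damped Newton iteration on the
#' steady-state balances (finite-difference Jacobian, non-negativity
#' preserved). The converged state satisfies, for every tank and component,
#' inflow - outflow + reaction * V_tank = 0 to `tol` relative to the influent
#' loading scale.
#'
#' @param config A [plant_config()].
#' @param influent A [cod_fractionation()] (mapped through
#'   [to_influent_state()] with the config's variant) or a [state_vector()].
#' @param params A [kinetic_params()] object.
#' @param tol Relative residual tolerance.
#' @param t_factor Integration horizon in sludge ages before polishing.
#' @param max_newton Newton iteration budget.
#' @return Object of class `"masm_steady"`: list with per-tank states
#'   (`tanks`, components x tanks matrix), `effluent` and `underflow` state
#'   vectors, flows (`Q`, `Q_e`, `Q_r`, `Q_w`), `S_TE` and `S_HE` (mg/L),
#'   `mlss` (mg/L), `oxygen_demand_kg_d`, `closure_defect`, `converged`,
#'   `residual`, `washout`, plus the inputs used.
#' @examples
#' cfg <- plant_config(srt_d = 6, hrt_h = 6.5, variant = "masm")
#' fit <- steady_state_solve(cfg, textile_fractionation(), kinetic_params())
#' fit$S_HE
#' @export
steady_state_solve <- function(config, influent, params = kinetic_params(),
                               tol = 1e-8, t_factor = 50, max_newton = 60) {
  stopifnot(inherits(config, "plant_config"))
  if (inherits(influent, "cod_fractionation"))
    influent <- to_influent_state(influent, config$variant)
  influent <- as_state_vector(influent)
  if (config$primary_settler) influent[["X_SS"]] <- 0
  if (!inherits(params, "kinetic_params"))
    params <- do.call(kinetic_params, params)

  comps <- masm_components()
  mat <- build_petersen(params, config$variant)
  Qw <- wastage_flow_for_srt(config)
  Qr <- config$recycle_ratio * config$Q
  if (Qr <= 0 && any(influent[setdiff(config$separator$retain, "S_O")] > 0))
    stop("recycle_ratio must be > 0 when the separator retains influent material")
  ctx <- list(comps = comps, n = config$n_tanks,
              v = config$V_total / config$n_tanks,
              Q = config$Q, Qr = Qr, Qw = Qw,
              Qe = config$Q - Qw, F_sep = config$Q + Qr - Qw,
              sep = config$separator, influent = as.numeric(influent),
              stoich = mat$stoich, params = params, variant = config$variant,
              io_fixed = which(comps == "S_O"))
  names(ctx$influent) <- comps

  # deterministic initial guess: influent-fed tanks seeded with biomass
  y0 <- rep(as.numeric(influent), ctx$n)
  y0[rep(comps, ctx$n) == "X_H"] <- 500
  y0[rep(comps, ctx$n) == "S_O"] <- config$do_mg_L

  horizon <- t_factor * min(max(config$srt_d, config$theta_H_d), 1000)
  sol <- deSolve::lsoda(y = y0, times = c(0, horizon),
                        func = function(t, y, parms) list(plant_derivs(y, ctx)),
                        rtol = 1e-8, atol = 1e-6)
  y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)

  scale <- ctx$Q * max(sum(influent[cod_components()]), 1) / ctx$v
  resid <- function(y) plant_derivs(y, ctx) / scale
  free <- which(rep(comps, ctx$n) != "S_O")
  g <- resid(y)
  it <- 0
  while (max(abs(g)) > tol && it < max_newton) {
    it <- it + 1
    J <- fd_jacobian(function(z) { yy <- y; yy[free] <- z; resid(yy)[free] },
                     y[free])
    step <- tryCatch(solve(J, -g[free]), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      y_try <- y
      y_try[free] <- pmax(y[free] + lambda * step, 0)
      g_try <- resid(y_try)
      if (max(abs(g_try)) < max(abs(g)) || lambda < 2^-10) break
      lambda <- lambda / 2
    }
    if (max(abs(g_try)) >= max(abs(g))) break
    y <- y_try; g <- g_try
  }
  converged <- max(abs(g)) <= tol

  C <- matrix(y, nrow = length(comps), ncol = ctx$n,
              dimnames = list(comps, paste0("tank", seq_len(ctx$n))))
  sp <- separator_split(C[, ctx$n], ctx$sep, ctx$F_sep, ctx$Qe, ctx$Qr)
  eff <- as_state_vector(pmax(sp$effluent, 0))
  our_tanks <- vapply(seq_len(ctx$n), function(i)
    -sum(ctx$stoich[, "S_O"] * process_rates_fast(C[, i], ctx)), 0)
  o2_kg_d <- sum(our_tanks) * ctx$v / 1000

  sol_cod <- intersect(cod_components(),
                       names(which(component_size_class() != "particulate")))
  res <- structure(list(
    tanks = C, effluent = eff,
    underflow = as_state_vector(pmax(sp$underflow, 0)),
    Q = ctx$Q, Q_e = ctx$Qe, Q_r = ctx$Qr, Q_w = Qw,
    S_TE = sum(eff[sol_cod]), S_HE = eff[["S_H"]],
    mlss = NA_real_, oxygen_demand_kg_d = o2_kg_d,
    closure_defect = NA_real_, converged = converged,
    residual = max(abs(g)), newton_iterations = it,
    washout = max(C["X_H", ]) < 1e-6,
    config = config, params = params, influent = influent,
    matrix = mat), class = "masm_steady")
  res$mlss <- mlss_estimate(res)
  res$closure_defect <- mass_balance_report(res)$defect
  res
}

# forward-difference Jacobian of f at x
fd_jacobian <- function(f, x) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- max(1e-7 * abs(x[j]), 1e-7)
    xj <- x; xj[j] <- xj[j] + h
    J[, j] <- (f(xj) - f0) / h
  }
  J
}

#' Mixed liquor suspended solids estimate
#'
#' Converts the particulate COD inventory (`X_I + X_S + X_SS + X_P + X_H`,
#' averaged over the tanks) to suspended solids. The captured soluble pools
#' `S_HC`/`S_IC` are excluded: they are colloids below 450 nm and do not
#' register as suspended solids.
#'
#' @param result A `"masm_steady"` object.
#' @param cod_to_vss COD content of volatile solids (mg COD/mg VSS).
#' @param vss_to_tss Volatile fraction of the suspended solids (-).
#' @return MLSS (mg/L).
#' @export
mlss_estimate <- function(result, cod_to_vss = 1.42, vss_to_tss = 0.8) {
  if (cod_to_vss <= 0 || vss_to_tss <= 0)
    stop("conversion factors must be positive")
  part <- names(which(component_size_class() == "particulate"))
  mean(colSums(result$tanks[part, , drop = FALSE])) / cod_to_vss / vss_to_tss
}

#' Global COD mass-balance audit
#'
#' Closure of the plant-wide COD balance at steady state: influent COD load
#' must equal effluent load plus wastage load plus oxygen consumed,
#' `defect = |Q C_T,in - (Q_e COD_e + Q_w COD_w + O2 flux)| / (Q C_T,in)`.
#'
#' @param result A `"masm_steady"` object.
#' @return List with the four fluxes (kg COD/d or kg O2/d) and the relative
#'   `defect`.
#' @export
mass_balance_report <- function(result) {
  codc <- cod_components()
  in_flux <- result$Q * sum(result$influent[codc]) / 1000
  eff_flux <- result$Q_e * sum(result$effluent[codc]) / 1000
  waste_flux <- result$Q_w * sum(result$tanks[codc, result$config$n_tanks]) / 1000
  o2_flux <- result$oxygen_demand_kg_d
  defect <- if (in_flux > 0)
    abs(in_flux - eff_flux - waste_flux - o2_flux) / in_flux else 0
  list(influent_kg_d = in_flux, effluent_kg_d = eff_flux,
       wastage_kg_d = waste_flux, oxygen_kg_d = o2_flux, defect = defect)
}

#' @export
print.masm_steady <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Steady state, variant \"%s\": %d tank(s), SRT %.3g d, HRT %.3g h, R %.3g\n",
              cfg$variant, cfg$n_tanks, cfg$srt_d, cfg$theta_H_d * 24,
              cfg$recycle_ratio))
  cat(sprintf("  effluent S_H  %8.2f mg/L\n", x$S_HE))
  cat(sprintf("  effluent S_T  %8.2f mg/L (total soluble COD)\n", x$S_TE))
  cat(sprintf("  MLSS          %8.0f mg/L\n", x$mlss))
  cat(sprintf("  oxygen demand %8.0f kg O2/d\n", x$oxygen_demand_kg_d))
  cat(sprintf("  COD closure defect %.2e%s%s\n", x$closure_defect,
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$washout) "  [biomass washout]" else ""))
  invisible(x)
}

#' @export
summary.masm_steady <- function(object, ...) {
  print(object)
  cat("\nPer-tank states (mg/L):\n")
  print(round(object$tanks, 2))
  cat("\nEffluent composition (mg/L):\n")
  print(round(unclass(object$effluent), 3))
  mb <- mass_balance_report(object)
  cat(sprintf("\nCOD fluxes (kg/d): in %.1f = effluent %.1f + wastage %.1f + oxygen %.1f\n",
              mb$influent_kg_d, mb$effluent_kg_d, mb$wastage_kg_d,
              mb$oxygen_kg_d))
  invisible(object)
}

#' @export
coef.masm_steady <- function(object, ...) unlist(unclass(object$params))

#' Steady-state residuals
#'
#' Net accumulation rate (mg/L/d) of every component in every tank at the
#' reported state; all entries are ~0 for a converged solution.
#' @param object A `"masm_steady"` object.
#' @param ... Unused.
#' @export
residuals.masm_steady <- function(object, ...) {
  cfg <- object$config
  ctx <- list(comps = masm_components(), n = cfg$n_tanks,
              v = cfg$V_total / cfg$n_tanks, Q = cfg$Q,
              Qr = object$Q_r, Qw = object$Q_w, Qe = object$Q_e,
              F_sep = cfg$Q + object$Q_r - object$Q_w,
              sep = cfg$separator, influent = as.numeric(object$influent),
              stoich = object$matrix$stoich, params = object$params,
              variant = cfg$variant,
              io_fixed = which(masm_components() == "S_O"))
  names(ctx$influent) <- ctx$comps
  matrix(plant_derivs(as.numeric(object$tanks), ctx),
         nrow = length(ctx$comps), dimnames = dimnames(object$tanks))
}

#' Plot effluent COD composition
#'
#' Stacked bar of the soluble effluent COD fractions.
#' @param x A `"masm_steady"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.masm_steady <- function(x, ...) {
  sol <- c("S_I", "S_IC", "S_S", "S_H", "S_HC", "S_P")
  vals <- x$effluent[sol]
  vals <- vals[vals > 1e-9]
  graphics::barplot(as.matrix(vals), beside = FALSE,
                    legend.text = names(vals),
                    ylab = "effluent COD (mg/L)",
                    main = sprintf("Effluent soluble COD, %s", x$config$variant),
                    ...)
  invisible(x)
}
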