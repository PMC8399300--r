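# Shared fixtures. Steady-state solves are cached per test file via these
# helpers so the same scenario is never solved twice.

textile <- textile_fractionation()
domestic <- domestic_fractionation()
default_params <- kinetic_params()

# near-zero kinetics: freezes all biological conversion while satisfying the
# strict-positivity contract of kinetic_params()
frozen_kinetics <- function() {
  kinetic_params(mu_H_hat = 1e-9, b_H = 1e-9, k_hS = 1e-9, k_hX = 1e-9)
}

solve_cache <- new.env(parent = emptyenv())
cached_solve <- function(variant, srt_d, hrt_h, influent = textile,
                         params = default_params, ...) {
  key <- paste(variant, srt_d, hrt_h, substr(digest_args(list(...)), 1, 8))
  if (is.null(solve_cache[[key]])) {
    cfg <- plant_config(srt_d = srt_d, hrt_h = hrt_h, variant = variant, ...)
    solve_cache[[key]] <- steady_state_solve(cfg, influent, params)
  }
  solve_cache[[key]]
}
digest_args <- function(x) paste(deparse(x), collapse = "")

# Brute-force oracle for the steady-state solver: forward-Euler march of the
# 3-tank settled-plant textile scenario with all balances written out by hand
# (flow arithmetic and ASM1-type stoichiometry re-derived inline, nothing
# shared with the solver's derivative code). The readily biodegradable pool
# is a fast mode when biomass is high, so the step must stay well inside
# 2/(mu_H/(K_S*Y_H)*X_H) ~ 2e-3 d. Computed once and cached.
march_oracle <- function() {
  if (!is.null(solve_cache$march)) return(solve_cache$march)
  res <- cached_solve("asm1_mod", 1, 3.6)
  p <- default_params
  comps <- masm_components()
  inf <- as.numeric(res$influent); names(inf) <- comps
  n <- 3; V <- 10000 * 3.6 / 24; v <- V / n
  Q <- 10000; Qr <- Q; Qw <- V / 1; Qe <- Q - Qw; Fs <- Q + Qr - Qw
  pass <- c("S_I", "S_S", "S_H", "S_P", "S_O", "S_IC", "S_HC")
  C <- matrix(rep(inf, n), ncol = n, dimnames = list(comps, NULL))
  C["X_H", ] <- 500
  dt <- 7.5e-4
  for (step in seq_len(ceiling(200 / dt))) {
    eff <- C[, n]; eff[!(comps %in% pass)] <- 0
    und <- (Fs * C[, n] - Qe * eff) / Qr
    XH <- C["X_H", ]; SS <- C["S_S", ]
    growth <- p$mu_H_hat * SS / (p$K_S + SS) * XH
    hyd <- function(cc, k, K) k * cc * XH / (K * XH + cc + 1e-300)
    h_SH <- hyd(C["S_H", ], p$k_hS, p$K_hS)
    h_XS <- hyd(C["X_S", ], p$k_hX, p$K_hX)
    h_XSS <- hyd(C["X_SS", ], p$k_hX, p$K_hX)
    decay <- p$b_H * XH
    R <- matrix(0, nrow = length(comps), ncol = n,
                dimnames = list(comps, NULL))
    R["S_S", ] <- -growth / p$Y_H + h_SH + h_XS + h_XSS
    R["S_H", ] <- -h_SH
    R["X_S", ] <- -h_XS
    R["X_SS", ] <- -h_XSS
    R["X_H", ] <- growth - decay
    R["X_P", ] <- p$f_X * decay
    R["S_P", ] <- p$f_S * decay
    inflow <- cbind(Q * inf + Qr * und, (Q + Qr) * C[, -n])
    C <- pmax(C + dt * ((inflow - (Q + Qr) * C) / v + R), 0)
    C["S_O", ] <- inf["S_O"]
  }
  solve_cache$march <- list(tanks = C, res = res)
  solve_cache$march
}

# random non-negative state on a realistic concentration scale
random_state <- function() {
  comps <- masm_components()
  vals <- stats::runif(length(comps), 0, 2000)
  names(vals) <- comps
  do.call(state_vector, as.list(vals))
}
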