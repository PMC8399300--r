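# masm

Biokinetic modelling of activated sludge plants with membrane separation.

## The problem

Activated sludge models of the ASM family divide chemical oxygen demand
(COD) into "soluble" and "particulate" at a single 450 nm threshold and
assume that whatever is soluble and not biodegraded leaves with the
effluent. A membrane bioreactor violates that assumption: the membrane plus
its cake layer acts as a filter with an *effective filtration size* of
about 8 nm, so a large share of the nominally soluble COD — hydrocolloids
between 8 and 450 nm — is physically **captured** in the reactor and leaves
with the waste sludge, under sludge-age control, instead of escaping with
the effluent under hydraulic control. For strong industrial wastewaters
(the bundled denim-processing reference carries 1340 mg/L total COD, with
78% of its soluble hydrolysable pool above 8 nm) this changes predicted
effluent quality by large factors.

`masm` is for process modellers and researchers who need to quantify that
effect. It provides:

* a 6-process × 12-component Petersen matrix model in two variants — the
  membrane model, with captured soluble hydrolysable (`S_HC`) and captured
  soluble inert (`S_IC`) COD as first-class components, and an ASM1-type
  variant modified for endogenous decay for conventional gravity-settled
  plants — with COD-continuity auditing;
* modified COD fractionation tables (passing/captured splits of each
  soluble pool) with additivity validation, plus particle-size-distribution
  utilities to derive the effective filtration size and captured fractions
  from cumulative sequential-filtration curves;
* a steady-state simulator of the standard comparison flowsheet: N
  completely mixed tanks in series, an ideal point separator defined by its
  size threshold, return sludge, and hydraulic wastage for sludge-age
  control;
* scenario runners reproducing the published sludge-age sweeps (each system
  at its design footprint, or both at matched HRT) and effluent COD
  breakdowns;
* deterministic synthetic generators for influent fractionations and PSD
  curves, so everything runs self-contained.

### The model in brief

Heterotrophic growth follows Monod kinetics,
`rho = mu_H * S_S/(K_S + S_S) * X_H`, with yield `Y_H`; endogenous decay
`b_H * X_H` leaves soluble (`f_S`) and particulate (`f_X`) residual
products; each hydrolysable pool `C` is converted by surface-saturation
kinetics `k_h (C/X_H)/(K_h + C/X_H) X_H`. In the membrane variant the
captured pool obeys a sludge-age-controlled balance
(`Q S_HC1 − V S_HC/theta_X − V rho_hyd = 0`), while the passing pool obeys
the usual hydraulic balance (`Q S_H1 − Q S_HE − V rho_hyd = 0`): capture
moves part of the soluble COD from HRT control to SRT control, which is the
entire point.

## Worked example

```r
library(masm)

frac <- textile_fractionation()
captured_share(frac, "hydrolysable")   # 78  (% of S_HT1 above 8 nm)
soluble_hydrolysable_share(frac)       # 48  (% of total soluble COD)

fit <- steady_state_solve(plant_config(srt_d = 6, hrt_h = 6.5, variant = "masm"),
                          frac, kinetic_params())
fit
#> Steady state, variant "masm": 3 tank(s), SRT 6 d, HRT 6.5 h, R 4
#>   effluent S_H      8.12 mg/L
#>   effluent S_T    159.45 mg/L (total soluble COD)
#>   MLSS              9214 mg/L
#>   oxygen demand     6157 kg O2/d
#>   COD closure defect 1.02e-10

effluent_breakdown(fit)
#>         S_I         S_P         S_S         S_H
#> 135.0000000  15.5246100   0.8053559   8.1207026
removal_percent(fit$S_HE, frac, "masm")
#> [1] 92
```

A conventional membrane plant (sludge age 6 d, HRT 6.5 h) discharges
8.1 mg/L of soluble hydrolysable COD — 92% removal of the fraction that can
bypass the membrane — and 159 mg/L total soluble COD, dominated by the
passing influent inert (135 mg/L) plus residual microbial products. The
gravity-settled equivalent discharges ~247 mg/L because the captured inert
fraction (90 mg/L) escapes it. Sweeping both systems over sludge ages at
matched HRT:

```r
tab <- run_matched_hrt_table(frac)
tab[tab$srt_d %in% c(1, 6), c("label","srt_d","variant","hrt_h","S_HE","removal_pct","S_TE","mlss")]
#>           label srt_d  variant hrt_h  S_HE removal_pct S_TE mlss
#> 1     superfast     1 asm1_mod   3.6 86.95          81  319 3836
#> 2     superfast     1     masm   3.6 17.05          83  160 3992
#> 9  conventional     6 asm1_mod  14.4  5.47          99  247 4192
#> 10 conventional     6     masm  14.4  2.48          98  154 4184
```

At a 1 d sludge age the membrane plant's effluent hydrolysable COD is five
times lower at identical volume, purely because 78% of the pool is captured
and given a 1 d solids residence instead of a 3.6 h hydraulic one.

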