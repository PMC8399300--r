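# Standard sequential filtration/ultrafiltration size grid (nm), from the
# coarsest membrane down to the finest ultrafiltration step.
psd_default_grid <- function() c(1600, 450, 220, 100, 45, 22, 8, 2)

#' Cumulative particle-size distribution of soluble COD
#'
#' A PSD curve, as produced by sequential filtration/ultrafiltration, records
#' for each filter size the COD remaining in the filtrate, i.e. the cumulative
#' COD smaller than that size. Sizes run from coarse (~1600 nm) down to fine
#' (~2 nm); cumulative values are non-increasing along that direction.
#'
#' @param size_nm Strictly decreasing positive sizes (nm), length >= 3.
#' @param cumulative_mg_L COD below each size (mg/L), non-increasing as size
#'   decreases, non-negative.
#' @return Object of class `"psd_curve"`: data frame with columns `size_nm`,
#'   `cumulative_mg_L`.
#' @export
psd_curve <- function(size_nm, cumulative_mg_L) {
  if (length(size_nm) < 2 || length(size_nm) != length(cumulative_mg_L))
    stop("need matching size and cumulative vectors (length >= 2)")
  if (any(size_nm <= 0)) stop("sizes must be positive")
  if (any(diff(size_nm) >= 0)) stop("sizes must be strictly decreasing")
  if (any(diff(cumulative_mg_L) > 1e-9))
    stop("cumulative COD must be non-increasing as size decreases")
  if (any(cumulative_mg_L < 0)) stop("cumulative COD must be non-negative")
  structure(data.frame(size_nm = size_nm, cumulative_mg_L = cumulative_mg_L),
            class = c("psd_curve", "data.frame"))
}

# Cumulative COD below `size`, piecewise-linear in log10(size).
psd_cumulative_at <- function(curve, size_nm) {
  s <- rev(curve$size_nm)             # increasing
  c_ <- rev(curve$cumulative_mg_L)    # non-decreasing
  if (size_nm <= s[1]) return(c_[1])
  if (size_nm >= s[length(s)]) return(c_[length(c_)])
  stats::approx(log10(s), c_, xout = log10(size_nm), ties = "ordered")$y
}

#' Effective filtration size from a permeate COD value
#'
#' Locates the size at which the cumulative PSD curve of the reactor-soluble
#' COD equals the permeate COD, by monotone piecewise-linear interpolation on
#' log10(size). The membrane plus its cake layer behaves as a filter of this
#' size, typically far below the nominal pore size.
#'
#' @param curve A [psd_curve()].
#' @param permeate_mg_L Permeate COD (mg/L); must lie within the curve's
#'   cumulative range.
#' @return Size in nm, between two adjacent grid sizes.
#' @export
effective_filtration_size <- function(curve, permeate_mg_L) {
  s <- rev(curve$size_nm)
  c_ <- rev(curve$cumulative_mg_L)
  if (permeate_mg_L < c_[1] || permeate_mg_L > c_[length(c_)])
    stop("permeate COD outside the curve's cumulative range: ",
         "curve and permeate are inconsistent")
  hit <- which(abs(c_ - permeate_mg_L) == 0)
  if (length(hit)) return(s[hit[1]])
  i <- findInterval(permeate_mg_L, c_)      # c_[i] <= value < c_[i+1]
  if (c_[i + 1] == c_[i]) return(s[i])
  w <- (permeate_mg_L - c_[i]) / (c_[i + 1] - c_[i])
  10^(log10(s[i]) + w * (log10(s[i + 1]) - log10(s[i])))
}

#' Captured fraction of a pool from its PSD curve
#'
#' Fraction of the pool's mass at or above `threshold_nm` — the part a
#' separator with that threshold retains. Thresholds below the finest grid
#' size capture nothing; thresholds above the coarsest capture everything.
#'
#' @inheritParams effective_filtration_size
#' @param threshold_nm Separation threshold (nm).
#' @return Fraction in `[0, 1]`.
#' @export
psd_captured_fraction <- function(curve, threshold_nm) {
  total <- max(curve$cumulative_mg_L)
  if (total <= 0) stop("curve carries no mass")
  smin <- min(curve$size_nm); smax <- max(curve$size_nm)
  if (threshold_nm < smin) return(0)
  if (threshold_nm > smax) return(1)
  1 - psd_cumulative_at(curve, threshold_nm) / total
}

#' Generate a synthetic cumulative PSD curve
#'
#' Builds a smooth monotone cumulative curve on the sequential-filtration
#' grid from a logistic mass profile in log10(size), mimicking measured
#' soluble-COD size fingerprints. Deterministic for a given seed: the
#' midpoint and spread are jittered reproducibly.
#'
#' @param seed Integer seed.
#' @param total Total soluble COD carried by the curve (mg/L).
#' @param midpoint_nm Median particle size (nm) before jitter.
#' @param spread Logistic spread in log10(nm) units.
#' @param grid Size grid (nm), strictly decreasing.
#' @return A [psd_curve()].
#' @export
generate_synthetic_psd <- function(seed, total, midpoint_nm = 30,
                                   spread = 0.6, grid = psd_default_grid()) {
  if (total <= 0) stop("total must be positive")
  with_seed(seed, {
    mid <- log10(midpoint_nm) + stats::runif(1, -0.2, 0.2)
    spr <- spread * stats::runif(1, 0.8, 1.25)
    cum <- total * stats::plogis((log10(grid) - mid) / spr)
    # pin the ends so the curve carries the full total at the coarse end
    cum <- total * (cum - min(cum)) / (max(cum) - min(cum))
    psd_curve(grid, cummin(cum))
  })
}
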