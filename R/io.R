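# Run a block with a private RNG state: seeds deterministically, restores
# the caller's .Random.seed afterwards. All package randomness goes through
# this; nothing touches the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Read a COD fractionation table from CSV
#'
#' Expects a `parameter,<source>,...` layout with one row per fractionation
#' symbol (`C_T1`, `S_T1`, ...), mirroring the published two-wastewater
#' table. The loaded column is audited with [validate_fractionation()];
#' violations are reported with the offending identity.
#'
#' @param path CSV file path.
#' @param source Column to read (e.g. `"textile"`, `"domestic"`); default the
#'   first value column.
#' @param tol Additivity tolerance (mg/L) passed to the audit.
#' @return A validated [cod_fractionation()].
#' @export
load_fractionation_csv <- function(path, source = NULL, tol = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"parameter" %in% names(tab))
    stop("fractionation CSV needs a 'parameter' column")
  if (is.null(source)) source <- setdiff(names(tab), "parameter")[1]
  if (!source %in% names(tab)) stop("no column '", source, "' in ", path)
  vals <- tab[[source]]
  if (!is.numeric(vals)) stop("non-numeric cells in column '", source, "'")
  names(vals) <- tab$parameter
  missing <- setdiff(fractionation_fields(), names(vals))
  if (length(missing))
    stop("missing fractionation row(s): ", paste(missing, collapse = ", "))
  frac <- do.call(cod_fractionation, as.list(vals[fractionation_fields()]))
  rep <- validate_fractionation(frac, tol = tol)
  if (!attr(rep, "valid"))
    stop("additivity violation beyond ", tol, " mg/L in ", path, ": ",
         paste(rep$identity[!rep$ok], collapse = "; "))
  frac
}

#' Write a COD fractionation table to CSV
#'
#' @param frac A [cod_fractionation()] (or a named list of several, written
#'   as one column each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fractionation_csv <- function(frac, path) {
  if (inherits(frac, "cod_fractionation")) frac <- list(value = frac)
  tab <- data.frame(parameter = fractionation_fields())
  for (nm in names(frac)) tab[[nm]] <- as.numeric(frac[[nm]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a PSD curve as two-column CSV
#'
#' Columns `size_nm`, `cumulative_mg_L`.
#' @param path CSV path.
#' @return [load_psd_csv()]: a [psd_curve()]; [write_psd_csv()]: `path`.
#' @export
load_psd_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("size_nm", "cumulative_mg_L") %in% names(tab)))
    stop("PSD CSV needs columns size_nm, cumulative_mg_L")
  psd_curve(tab$size_nm, tab$cumulative_mg_L)
}

#' @rdname load_psd_csv
#' @param curve A [psd_curve()].
#' @export
write_psd_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    plant = list(Q = 10000, n_tanks = 3, srt_d = 6, hrt_h = NULL,
                 V_total = NULL, recycle_ratio = NULL, variant = "masm",
                 do_mg_L = 8, primary_settler = FALSE),
    kinetics = as.list(unclass(kinetic_params())),
    influent = list(csv = NULL, source = NULL),
    separator = list(threshold_nm = NULL, escape_mg_L = 0),
    output = list(dir = ".", prefix = "masm", verbosity = 1))
}

#' Load and resolve a run configuration
#'
#' YAML run configuration with sections `plant`, `kinetics`, `influent`,
#' `separator`, `output`. Unknown sections or keys are rejected; missing
#' optional keys are filled from the documented defaults. The fully resolved
#' configuration is attached as attribute `"resolved"` (and can be re-dumped
#' with [dump_run_config()]) so every run records its effective settings.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Resolved configuration list with class `"masm_run_config"`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- run_config_defaults()
  bad_sec <- setdiff(names(cfg), names(defaults))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ", paste(bad, collapse = ", "))
    defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  if (is.null(defaults$plant$hrt_h) && is.null(defaults$plant$V_total))
    stop("config must set plant.hrt_h or plant.V_total")
  structure(defaults, class = "masm_run_config")
}

#' @rdname load_run_config
#' @param config A resolved `"masm_run_config"`.
#' @param path Output YAML path.
#' @export
dump_run_config <- function(config, path) {
  yaml::write_yaml(drop_nulls(unclass(config)), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_nulls)
  x[!vapply(x, is.null, TRUE)]
}

#' Execute a resolved run configuration
#'
#' Builds the plant, kinetics and influent from a [load_run_config()] result
#' and solves to steady state.
#'
#' @param config A `"masm_run_config"` (or path to one).
#' @param influent Optional [cod_fractionation()] overriding the config's
#'   influent CSV.
#' @return A `"masm_steady"` object.
#' @export
run_from_config <- function(config, influent = NULL) {
  if (is.character(config) || !inherits(config, "masm_run_config"))
    config <- load_run_config(config)
  p <- config$plant
  sep <- if (is.null(config$separator$threshold_nm)) NULL
         else separator_spec(config$separator$threshold_nm,
                             config$separator$escape_mg_L)
  cfg <- plant_config(srt_d = p$srt_d, hrt_h = p$hrt_h, V_total = p$V_total,
                      Q = p$Q, n_tanks = p$n_tanks, variant = p$variant,
                      recycle_ratio = p$recycle_ratio, separator = sep,
                      do_mg_L = p$do_mg_L, primary_settler = p$primary_settler)
  if (is.null(influent)) {
    if (is.null(config$influent$csv))
      stop("config has no influent.csv and no influent was supplied")
    influent <- load_fractionation_csv(config$influent$csv,
                                       config$influent$source)
  }
  steady_state_solve(cfg, influent, do.call(kinetic_params, config$kinetics))
}

#' Generate a synthetic influent fractionation
#'
#' Draws a random but internally consistent modified COD fractionation:
#' totals are sampled in a window around a reference strength profile and
#' every pool is then split by random fractions, so all additivity identities
#' hold by construction. Deterministic for a given seed.
#'
#' The profiles centre on the two reference wastewaters: `"textile-like"`
#' (strong, ~1340 mg/L total COD, soluble-dominated with a large captured
#' hydrolysable share) and `"domestic-like"` (~415 mg/L, particulate-
#' dominated). Totals vary by +/-30%, splits by +/-30% around the reference
#' proportions.
#'
#' @param seed Integer seed.
#' @param profile `"textile-like"` or `"domestic-like"`.
#' @return A [cod_fractionation()].
#' @export
generate_synthetic_influent <- function(seed,
                                        profile = c("textile-like",
                                                    "domestic-like")) {
  profile <- match.arg(profile)
  ref <- if (profile == "textile-like") textile_fractionation()
         else domestic_fractionation()
  with_seed(seed, {
    jitter <- function(x, amount = 0.3) x * stats::runif(1, 1 - amount, 1 + amount)
    split2 <- function(total, f_ref) {
      f <- min(max(jitter(f_ref), 0), 1)
      c(total * f, total * (1 - f))
    }
    C_T1 <- jitter(ref[["C_T1"]])
    st <- split2(C_T1, ref[["S_T1"]] / ref[["C_T1"]])      # soluble/particulate
    s_s <- split2(st[1], ref[["S_S1"]] / ref[["S_T1"]])    # readily biodeg / rest
    s_hi <- split2(s_s[2], ref[["S_HT1"]] / (ref[["S_HT1"]] + ref[["S_IT1"]]))
    sh <- split2(s_hi[1], ref[["S_HC1"]] / ref[["S_HT1"]]) # captured/passing
    si <- split2(s_hi[2], ref[["S_IC1"]] / ref[["S_IT1"]])
    xs <- split2(st[2], ref[["X_ST1"]] / ref[["X_T1"]])
    xh <- split2(xs[1], ref[["X_SS1"]] / ref[["X_ST1"]])   # settleable/suspended
    xi <- split2(xs[2], ref[["X_IS1"]] / ref[["X_IT1"]])
    fractionation_from_parts(
      S_S1 = s_s[1], S_H1 = sh[2], S_HC1 = sh[1],
      S_I1 = si[2], S_IC1 = si[1],
      X_S1 = xh[2], X_SS1 = xh[1], X_I1 = xi[2], X_IS1 = xi[1])
  })
}
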