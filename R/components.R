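#' Model components
#'
#' The model tracks twelve components in each completely mixed tank. All are
#' measured as COD (mg COD/L) except dissolved oxygen `S_O` (mg O2/L), which
#' enters the continuity balance as negative COD. The order is fixed and is
#' identical to the column order of the stoichiometric matrix.
#'
#' @return Character vector of the twelve component labels, in matrix order.
#' @export
masm_components <- function() {
  c("S_I", "S_IC", "X_I", "S_S", "S_H", "X_S",
    "S_O", "X_P", "S_P", "X_SS", "S_HC", "X_H")
}

# COD-measured components (everything except dissolved oxygen)
cod_components <- function() setdiff(masm_components(), "S_O")

# Nominal size class per component, used to derive separator pass/retain sets.
# "fine" solubles sit below the membrane's effective filtration size (~8 nm),
# "colloid" solubles between that and the classical 450 nm soluble/particulate
# threshold, "particulate" above 450 nm. S_O is a dissolved gas and always
# passes.
component_size_class <- function() {
  c(S_I = "fine", S_IC = "colloid", X_I = "particulate", S_S = "fine",
    S_H = "fine", X_S = "particulate", S_O = "gas", X_P = "particulate",
    S_P = "fine", X_SS = "particulate", S_HC = "colloid", X_H = "particulate")
}

#' Construct a state vector
#'
#' A state vector holds the concentration of every model component in one
#' completely mixed tank, in mg COD/L (mg O2/L for `S_O`).
#'
#' @param ... Named component concentrations; unnamed components default to 0.
#'   Names must be a subset of [masm_components()].
#' @return Named numeric vector of length 12 in fixed component order, with
#'   class `"masm_state"`.
#' @examples
#' state_vector(S_S = 280, X_H = 1000)
#' @export
state_vector <- function(...) {
  vals <- c(...)
  comps <- masm_components()
  x <- stats::setNames(numeric(length(comps)), comps)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals))))
      stop("all state components must be named")
    unknown <- setdiff(names(vals), comps)
    if (length(unknown))
      stop("unknown component(s): ", paste(unknown, collapse = ", "))
    x[names(vals)] <- as.numeric(vals)
  }
  if (any(x < 0)) stop("component concentrations must be non-negative")
  structure(x, class = c("masm_state", "numeric"))
}

as_state_vector <- function(x) {
  comps <- masm_components()
  if (is.null(names(x))) {
    stopifnot(length(x) == length(comps))
    names(x) <- comps
  }
  if (identical(names(x), comps)) {       # fast path for ordered vectors
    x <- as.numeric(x)
    names(x) <- comps
    if (any(x < 0)) stop("component concentrations must be non-negative")
    return(structure(x, class = c("masm_state", "numeric")))
  }
  do.call(state_vector, as.list(x[comps]))
}
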