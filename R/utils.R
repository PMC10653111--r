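# Boltzmann constant in kcal/(mol K)
KB_KCAL <- 0.0019872041

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in kelvin (default 300).
#' @return kT in kcal/mol.
#' @examples
#' kT(300) # 0.59616...
#' @export
kT <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}

# inverse temperature in mol/kcal
beta_of <- function(temperature) 1 / kT(temperature)

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# structured warnings with machine-readable codes
# W001 low overlap, W002 per-lambda duration < 2 ps, W003 protocol below
# recommendations
neqfe_warn <- function(code, message) {
  warning(warningCondition(
    sprintf("%s: %s", code, message),
    class = c(paste0("neqfe_", tolower(code)), "neqfe_warning")
  ))
}

neqfe_stop <- function(message, class = "neqfe_error") {
  stop(errorCondition(message, class = c(class, "neqfe_error")))
}

# polynomial evaluation, coefficients in increasing powers
polyval_inc <- function(coefficients, x) {
  y <- rep(0, length(x))
  for (i in rev(seq_along(coefficients))) y <- y * x + coefficients[i]
  y
}

fmt_num <- function(x) sprintf("%.17g", x)
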