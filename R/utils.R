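# Unit conversions live here and nowhere else.
# 1 mOsm = 1e-6 osmol/cm^3; 1 mM = 1e-6 mol/cm^3.
mosm_to_osm_cm3 <- function(x) x * 1e-6
mm_to_mol_cm3 <- function(x) x * 1e-6

# Evaluate `code` under a local RNG seed, restoring global RNG state afterwards.
# All generators route randomness through this; no global random state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stop(sprintf("`%s` must be %s %s, got %g", name,
                 if (strict) ">" else ">=", format(lower), x), call. = FALSE)
  invisible(x)
}

# lognormal with mean `m` and coefficient of variation `cv` (cv = 0 degenerates
# to the constant m)
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}
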