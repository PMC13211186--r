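#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  abort_if(!is_number(seed), "'seed' must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; keeps results < 2^31 and decorrelates
# per-dish / per-stage streams.
derive_seed <- function(seed, ...) {
  key <- c(seed, ...)
  s <- 0
  for (k in key) s <- (s * 1103515245 + as.numeric(k) + 12345) %% 2147483647
  as.integer(s)
}

#' Convert a mass concentration to nanomolar
#'
#' Converts pg/mL to nM given a molar mass, e.g. for relating measured serum
#' concentrations of a compound to the molar doses used in an exposure design.
#'
#' @param pg_per_ml Mass concentration in picograms per millilitre.
#' @param mw_g_per_mol Molar mass in g/mol.
#' @return Concentration in nanomoles per litre (nM).
#' @examples
#' # 229 pg/mL of BTBPE (687.6 g/mol) is ~0.33 nM
#' molar_concentration_nM(229, 687.6)
#' @export
molar_concentration_nM <- function(pg_per_ml, mw_g_per_mol) {
  abort_if(!is.numeric(pg_per_ml) || any(pg_per_ml < 0),
           "'pg_per_ml' must be non-negative")
  abort_if(!is.numeric(mw_g_per_mol) || any(mw_g_per_mol <= 0),
           "'mw_g_per_mol' must be positive")
  # pg/mL = 1e-9 g/L; divide by g/mol -> 1e-9 mol/L = nM
  pg_per_ml / mw_g_per_mol
}
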