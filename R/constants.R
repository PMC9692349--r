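#' Physical constants used throughout the package
#'
#' A single record of the physical constants the electrochemical relations
#' rely on, so every module draws the same values.
#'
#' @format A named list:
#' \describe{
#'   \item{F}{Faraday constant, C mol^-1 (96485.332)}
#'   \item{R}{molar gas constant, J mol^-1 K^-1 (8.314462)}
#'   \item{k_B}{Boltzmann constant, J K^-1 (1.380649e-23)}
#'   \item{h}{Planck constant, J s (6.62607e-34)}
#' }
#' @examples
#' pfv_constants$F / pfv_constants$R
#' @export
pfv_constants <- list(
  F   = 96485.332,
  R   = 8.314462,
  k_B = 1.380649e-23,
  h   = 6.62607e-34
)

# F/(RT), the inverse thermal voltage in V^-1
.f_over_rt <- function(temperature) {
  pfv_constants$F / (pfv_constants$R * temperature)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert <- function(cond, msg, class = "pfv_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
}
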