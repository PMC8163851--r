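#' Century-month codes
#'
#' Integer month index counted from January 1900 (the DHS date convention):
#' January 1900 is 1, January 2000 is 1201. All event and field timestamps in
#' the package are century-month codes (CMC), so every date operation is exact
#' integer arithmetic at monthly resolution.
#'
#' @param year,month calendar year and month (1-12).
#' @param cmc integer century-month code(s).
#' @return `cmc()` returns the integer code; `cmc_year()` and `cmc_month()`
#'   invert it.
#' @examples
#' cmc(2000, 1)        # 1201
#' cmc_year(1201)      # 2000
#' cmc_month(1212)     # 12
#' @export
cmc <- function(year, month = 1L) {
  stopifnot(all(month >= 1L), all(month <= 12L))
  as.integer((year - 1900L) * 12L + month)
}

#' @rdname cmc
#' @export
cmc_year <- function(cmc) 1900L + (as.integer(cmc) - 1L) %/% 12L

#' @rdname cmc
#' @export
cmc_month <- function(cmc) (as.integer(cmc) - 1L) %% 12L + 1L

# Derive a stage seed from a root seed; keeps results < 2^31 and stage-local.
stage_seed <- function(seed, stage) {
  offs <- c(fields = 11L, mothers = 23L, exposure = 37L, cohort = 51L,
            fit = 67L, impact = 83L)
  off <- offs[[stage]]
  as.integer((as.numeric(seed) * 101L + off) %% .Machine$integer.max)
}
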