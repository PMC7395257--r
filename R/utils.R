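#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom tidyr unnest nest
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 imap pmap
#' @importFrom stats setNames rbinom rpois runif
#' @importFrom utils head tail
NULL

# Semantic groups recognised throughout the package. "other" is the catch-all
# assigned to concepts with no metadata.
EHR_GROUPS <- c("disorders", "procedures", "chemicals_drugs", "physiology",
                "anatomy", "other")

# Groups kept by default when filtering a cohort (anatomy is kept at the
# filtering stage; it is only omitted from *stratified evaluation*).
DEFAULT_KEEP_GROUPS <- c("disorders", "physiology", "chemicals_drugs",
                         "procedures", "anatomy")

# Strata reported by default in stratified evaluation (anatomy omitted:
# predicting an anatomical site is not clinically actionable).
DEFAULT_STRATA <- c("all", "disorders", "procedures", "chemicals_drugs",
                    "physiology")

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(min), format(max)))
  }
  invisible(x)
}

as_concept_set <- function(x) {
  x <- unique(as.character(x))
  x[!is.na(x) & nzchar(x)]
}
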