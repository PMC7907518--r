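#' @keywords internal
#' @useDynLib demscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Class labels used throughout; NONAD first so it is the reference level and
# the documented tie-break target.
.labels <- c("NONAD", "AD")

#' Run code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's random stream.
#' @noRd
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-subject seed derived from a corpus seed and subject index.
# Stated hash: (seed * 131071 + index * 7919) mod (2^31 - 1), kept positive.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 131071 + as.numeric(index) * 7919) %%
               (2^31 - 1))
}

assert_label <- function(label) {
  if (!is.null(label) && !label %in% .labels) {
    stop("label must be one of ", paste(.labels, collapse = ", "),
         ", got '", label, "'", call. = FALSE)
  }
  label
}

as_label_factor <- function(x) factor(as.character(x), levels = .labels)
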